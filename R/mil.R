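#' Train the multi-instance-learning cytological atypia classifier
#'
#' A small feed-forward network (one tanh hidden layer) scores each
#' instance (ROI feature vector) in `[0,1]`; the bag (tissue) score pools
#' instance logits through a smooth maximum (log-sum-exp with sharpness
#' `pool_r`, or noisy-OR), and the network is trained by full-batch Adam on
#' bag-level cross-entropy. Only bag labels are required. Deterministic
#' given the seed.
#'
#' @param bags list of numeric matrices (instances x features), one per bag.
#' @param bag_labels 0/1 vector (1 = positive bag).
#' @param hidden hidden layer width.
#' @param pool `"lse"` (log-sum-exp) or `"noisy_or"`.
#' @param pool_r sharpness of the log-sum-exp pooling.
#' @param epochs,lr,l2 optimizer settings.
#' @param seed integer; initialization and any shuffling derive from it.
#' @return object of class `mil_model` (weights, feature normalization
#'   statistics, architecture description, training seed).
#' @export
train_mil <- function(bags, bag_labels, hidden = 8L, pool = c("lse", "noisy_or"),
                      pool_r = 4, epochs = 400L, lr = 0.01, l2 = 1e-4,
                      seed = 42L) {
  pool <- match.arg(pool)
  stopifnot(length(bags) == length(bag_labels),
            all(bag_labels %in% c(0, 1)))
  if (length(unique(bag_labels)) < 2)
    stop("degenerate single-class training set")
  ni <- vapply(bags, nrow, integer(1))
  stopifnot(all(ni > 0))
  X <- do.call(rbind, bags)
  bag_of <- rep(seq_along(bags), ni)
  d <- ncol(X)
  centre <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, centre), 2, scale, "/")
  y <- as.numeric(bag_labels)
  B <- length(bags)

  with_op_seed(seed, "train_mil", {
    W1 <- matrix(stats::rnorm(d * hidden, 0, 1 / sqrt(d)), d, hidden)
    b1 <- numeric(hidden)
    w2 <- matrix(stats::rnorm(hidden, 0, 1 / sqrt(hidden)), hidden, 1)
    b2 <- 0
    ms <- list(W1 = W1 * 0, b1 = b1 * 0, w2 = w2 * 0, b2 = 0)
    vs <- ms
    beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
    for (ep in seq_len(epochs)) {
      Z1 <- sweep(Xs %*% W1, 2, b1, "+")
      A <- tanh(Z1)
      z <- as.vector(A %*% w2) + b2
      if (pool == "lse") {
        # per-bag smooth max of logits
        zmax <- tapply(z, bag_of, max)[as.character(seq_len(B))]
        ez <- exp(pool_r * (z - zmax[bag_of]))
        sez <- as.vector(rowsum(ez, bag_of))
        Lb <- as.vector(zmax) + log(sez / ni) / pool_r
        p <- 1 / (1 + exp(-Lb))
        wgt <- ez / sez[bag_of]           # d Lb / d z_i
        dz <- (p - y)[bag_of] * wgt / B
      } else {
        s <- 1 / (1 + exp(-z))
        log1ms <- log(pmax(1 - s, 1e-12))
        logq <- as.vector(rowsum(log1ms, bag_of))
        p <- 1 - exp(logq)
        # d p / d z_i = (1 - p) * s_i ; dL/dp = (p - y)/(p(1-p))
        dLdp <- (p - y) / pmax(p * (1 - p), 1e-8) / B
        dz <- dLdp[bag_of] * (1 - p)[bag_of] * s
      }
      dw2 <- crossprod(A, dz) + 2 * l2 * w2
      db2 <- sum(dz)
      dA <- dz %*% t(w2)
      dZ1 <- dA * (1 - A^2)
      dW1 <- crossprod(Xs, dZ1) + 2 * l2 * W1
      db1 <- colSums(dZ1)
      upd <- function(m, v, g) {
        m <- beta1 * m + (1 - beta1) * g
        v <- beta2 * v + (1 - beta2) * g^2
        mh <- m / (1 - beta1^ep); vh <- v / (1 - beta2^ep)
        list(m = m, v = v, step = lr * mh / (sqrt(vh) + eps))
      }
      u <- upd(ms$W1, vs$W1, dW1); ms$W1 <- u$m; vs$W1 <- u$v; W1 <- W1 - u$step
      u <- upd(ms$b1, vs$b1, db1); ms$b1 <- u$m; vs$b1 <- u$v; b1 <- b1 - u$step
      u <- upd(ms$w2, vs$w2, dw2); ms$w2 <- u$m; vs$w2 <- u$v; w2 <- w2 - u$step
      u <- upd(ms$b2, vs$b2, db2); ms$b2 <- u$m; vs$b2 <- u$v; b2 <- b2 - u$step
    }
    structure(list(W1 = W1, b1 = b1, w2 = as.vector(w2), b2 = b2,
                   centre = centre, scale = scale,
                   feature_names = colnames(X),
                   hidden = hidden, pool = pool, pool_r = pool_r,
                   epochs = epochs, lr = lr, l2 = l2, seed = seed),
              class = "mil_model")
  })
}

#' Score instances with a MIL model
#'
#' @param model a [train_mil()] model.
#' @param features numeric matrix (instances x features) or data.frame with
#'   the model's feature columns.
#' @return numeric vector of per-instance scores in `[0,1]`.
#' @export
score_rois <- function(model, features) {
  stopifnot(inherits(model, "mil_model"))
  X <- as.matrix(features)
  if (ncol(X) != length(model$centre))
    stop("feature length mismatch: model expects ", length(model$centre),
         ", got ", ncol(X))
  if (nrow(X) == 0) return(numeric(0))
  Xs <- sweep(sweep(X, 2, model$centre), 2, model$scale, "/")
  z <- as.vector(tanh(sweep(Xs %*% model$W1, 2, model$b1, "+")) %*%
                   model$w2) + model$b2
  1 / (1 + exp(-z))
}

#' Bag-level score under a MIL model (smooth max of instance logits)
#' @param model a `mil_model`.
#' @param features instance feature matrix of one bag.
#' @return bag probability in `[0,1]`.
#' @export
score_bag <- function(model, features) {
  s <- score_rois(model, features)
  if (length(s) == 0) return(0)
  z <- stats::qlogis(clamp(s, 1e-9, 1 - 1e-9))
  if (model$pool == "lse") {
    zm <- max(z)
    1 / (1 + exp(-(zm + log(mean(exp(model$pool_r * (z - zm)))) / model$pool_r)))
  } else 1 - prod(1 - s)
}

#' Serialize / restore a MIL model as JSON
#' @param model a `mil_model`.
#' @param path JSON file.
#' @export
write_mil_model <- function(model, path) {
  x <- unclass(model)
  x$W1 <- as.vector(x$W1)
  x$d <- length(x$centre)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mil_model
#' @export
read_mil_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$W1 <- matrix(x$W1, x$d, x$hidden)
  x$d <- NULL
  structure(x, class = "mil_model")
}

#' The packaged default MIL model
#'
#' Trained on a fixed-seed synthetic cohort (see `data-raw/`); suitable for
#' classifying generator tissues out of the box. Synthetic: it has never
#' seen real histology.
#' @return a `mil_model`.
#' @export
default_mil_model <- function() {
  read_mil_model(system.file("extdata", "default_mil_model.json",
                             package = "glandscreen", mustWork = TRUE))
}
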