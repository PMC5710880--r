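#' Combine structural, cytological and quality results into the final class
#'
#' Rule order: (1) unusable quality -> Unclassifiable; (2) structural high
#' OR cytological high -> Positive (the higher atypia level is adopted
#' preferentially); (3) structural middle -> Adenoma; (4) structural low
#' AND cytological low -> Negative; (5) structural unclassifiable AND
#' cytological low -> Unclassifiable. Cytology has no middle level, so
#' Adenoma can only arise from structure.
#'
#' @param structural `"low"`, `"middle"`, `"high"` or `"unclassifiable"`.
#' @param cyto `"low"` or `"high"`.
#' @param quality a `quality_verdict` or one of `"ok"`,
#'   `"partial_degraded"`, `"unusable"`.
#' @return list with `final_class` (one of `Positive`, `Adenoma`,
#'   `Negative`, `Unclassifiable`) and `explanation` (ordered rule firings).
#' @export
combine_results <- function(structural, cyto, quality) {
  q <- if (inherits(quality, "quality_verdict")) quality$status else quality
  if (!structural %in% c("low", "middle", "high", "unclassifiable"))
    stop("unknown structural level: ", structural)
  if (!cyto %in% c("low", "high"))
    stop("unknown cytological level: ", cyto)
  if (!q %in% c("ok", "partial_degraded", "unusable"))
    stop("unknown quality status: ", q)
  expl <- character(0)
  if (q == "unusable") {
    expl <- "rule1: quality unusable -> Unclassifiable"
    return(list(final_class = "Unclassifiable", explanation = expl))
  }
  if (structural == "high" || cyto == "high") {
    expl <- sprintf("rule2: %s atypia high -> Positive",
                    if (structural == "high") "structural" else "cytological")
    return(list(final_class = "Positive", explanation = expl))
  }
  if (structural == "middle") {
    return(list(final_class = "Adenoma",
                explanation = "rule3: structural middle -> Adenoma"))
  }
  if (structural == "low") {
    return(list(final_class = "Negative",
                explanation = "rule4: structural low and cytological low -> Negative"))
  }
  list(final_class = "Unclassifiable",
       explanation = "rule5: structural unclassifiable and cytological low -> Unclassifiable")
}

#' Map a pathologist diagnosis label to the truth class vocabulary
#'
#' Group 1 and Group 2 map to N, Group 3 to A, Group 4 and Group 5 to P,
#' Group X to X. Lymphoma and carcinoid (non-epithelial neoplasia) map to P
#' for bookkeeping but are excluded from the Group-specific screening-index
#' denominators.
#'
#' @param label character vector over `Group1`..`Group5`, `GroupX`,
#'   `lymphoma`, `carcinoid`.
#' @return character vector over `P`, `A`, `N`, `X`.
#' @export
map_diagnosis <- function(label) {
  tab <- c(Group1 = "N", Group2 = "N", Group3 = "A", Group4 = "P",
           Group5 = "P", GroupX = "X", lymphoma = "P", carcinoid = "P")
  bad <- setdiff(unique(label), names(tab))
  if (length(bad)) stop("unknown diagnosis label(s): ",
                        paste(bad, collapse = ", "))
  unname(tab[label])
}

#' Classify one tissue image end to end
#'
#' Pipeline order: quality control -> colour normalization -> structural
#' atypia -> cytological atypia -> overall classification. Unusable
#' tissues short-circuit to Unclassifiable without running the atypia
#' analyses; partially degraded tissues proceed with degraded tiles masked
#' (painted to background white) in both analyses.
#'
#' @param tissue a [tissue_image()].
#' @param model MIL model for cytology (default: packaged model).
#' @param config pipeline configuration.
#' @param highmag optional finer-magnification image of the same region.
#' @param tissue_id identifier carried into the report.
#' @return object of class `tissue_classification`: `tissue_id`,
#'   `final_class`, `structural_level`, `cyto_level`, `quality_status`,
#'   `explanation`, and the stage results (`quality`, `structural`,
#'   `cyto`).
#' @export
classify_tissue <- function(tissue, model = default_mil_model(),
                            config = default_config(), highmag = NULL,
                            tissue_id = "tissue") {
  quality <- check_quality(tissue, config)
  if (quality$status == "unusable") {
    comb <- combine_results("low", "low", quality)
    return(structure(list(tissue_id = tissue_id,
                          final_class = comb$final_class,
                          structural_level = NA_character_,
                          cyto_level = NA_character_,
                          quality_status = quality$status,
                          explanation = comb$explanation,
                          quality = quality, structural = NULL, cyto = NULL),
                     class = "tissue_classification"))
  }
  work <- tissue
  exclude <- NULL
  if (quality$status == "partial_degraded") {
    ts <- quality$tile_size_px
    d <- dim(tissue$pixels)[1:2]
    exclude <- matrix(FALSE, d[1], d[2])
    dt <- which(quality$degraded_tiles, arr.ind = TRUE)
    for (i in seq_len(nrow(dt))) {
      rs <- ((dt[i, 1] - 1) * ts + 1):min(dt[i, 1] * ts, d[1])
      cs <- ((dt[i, 2] - 1) * ts + 1):min(dt[i, 2] * ts, d[2])
      exclude[rs, cs] <- TRUE
    }
    px <- work$pixels
    for (k in 1:3) {
      chn <- px[, , k]; chn[exclude] <- 1; px[, , k] <- chn
    }
    work <- tissue_image(px, tissue$um_per_px, tissue$region_id,
                         tissue$provenance)
  }
  norm <- tryCatch(
    normalize_stains(work, config$stain$reference),
    error = function(e) work)
  structural <- analyze_structural(norm, config, highmag)
  cyto <- analyze_cyto(norm, model, config, exclude)
  comb <- combine_results(structural$level, cyto$level, quality)
  structure(list(tissue_id = tissue_id,
                 final_class = comb$final_class,
                 structural_level = structural$level,
                 cyto_level = cyto$level,
                 quality_status = quality$status,
                 explanation = comb$explanation,
                 quality = quality, structural = structural, cyto = cyto),
            class = "tissue_classification")
}

#' @export
print.tissue_classification <- function(x, ...) {
  cat(sprintf("%s: %s (structural=%s, cyto=%s, quality=%s)\n", x$tissue_id,
              x$final_class, x$structural_level, x$cyto_level,
              x$quality_status))
  invisible(x)
}

#' Classify every tissue of a synthetic cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @param model MIL model.
#' @param config pipeline configuration.
#' @param verbose log progress to stderr.
#' @return data.frame `tissue_id, class, final_class, structural_level,
#'   cyto_level, quality_status, max_level, max_arrangement, cyto_aggregate`.
#' @export
classify_cohort <- function(cohort, model = default_mil_model(),
                            config = default_config(), verbose = FALSE) {
  n <- nrow(cohort$manifest)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    t0 <- Sys.time()
    img <- cohort_tissue(cohort, i)
    tc <- classify_tissue(img, model, config,
                          tissue_id = cohort$manifest$tissue_id[i])
    rows[[i]] <- data.frame(
      tissue_id = tc$tissue_id,
      class = cohort$manifest$class[i],
      final_class = tc$final_class,
      structural_level = ifelse(is.na(tc$structural_level), "NA",
                                tc$structural_level),
      cyto_level = ifelse(is.na(tc$cyto_level), "NA", tc$cyto_level),
      quality_status = tc$quality_status,
      max_level = if (!is.null(tc$structural) && !is.na(tc$structural$max_level))
        tc$structural$max_level else NA_integer_,
      max_arrangement = if (!is.null(tc$structural))
        tc$structural$max_arrangement else NA_real_,
      cyto_aggregate = if (!is.null(tc$cyto)) tc$cyto$aggregate else NA_real_)
    if (verbose)
      message(sprintf("[classify] %s %s -> %s (%.2fs)",
                      tc$tissue_id, cohort$manifest$class[i], tc$final_class,
                      as.numeric(Sys.time() - t0, units = "secs")))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a per-tissue JSON report
#' @param classification a `tissue_classification`.
#' @param path JSON file.
#' @export
write_tissue_report <- function(classification, path) {
  x <- classification
  rep <- list(
    tissue_id = x$tissue_id,
    final_class = x$final_class,
    quality = list(status = x$quality_status,
                   blurred_fraction = x$quality$blurred_fraction,
                   pen_mark_fraction = x$quality$pen_mark_fraction,
                   shadow_fraction = x$quality$shadow_fraction),
    structural = if (is.null(x$structural)) NULL else list(
      level = x$structural$level,
      components = lapply(x$structural$components, function(cp)
        list(component_id = cp$component_id, thickness_um = cp$thickness_um,
             gland_level = cp$gland_level)),
      arrangement_scores = vapply(x$structural$segmentations,
                                  function(s) s$arrangement_score, numeric(1))),
    cyto = if (is.null(x$cyto)) NULL else list(
      scores = x$cyto$roi_scores, aggregate = x$cyto$aggregate,
      level = x$cyto$level, threshold = x$cyto$threshold_used),
    explanation = x$explanation)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
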