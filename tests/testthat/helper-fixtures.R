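# Shared fixtures, rendered once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

fx_config <- function() fixture("config", default_config())

# A moderately atypical adenoma tissue: the workhorse fixture.
fx_adenoma <- function() fixture("adenoma", {
  render_tissue(tissue_phenotype("adenoma", 5, 2.4, 0.3, 0, 7.5, seed = 31),
                size_px = c(512, 512))
})

fx_negative <- function() fixture("negative", {
  render_tissue(tissue_phenotype("negative", 6, 1.2, 0.05, 0, 6.5, seed = 9),
                size_px = c(512, 512))
})

# Gland-free poorly differentiated / signet-ring pattern, ~200 cells.
fx_signet <- function() fixture("signet", {
  render_tissue(tissue_phenotype("carcinoma", 0, 1, 0,
                                 dissociated_cell_density = 1.2,
                                 nuclear_size_um = 10, seed = 7),
                size_px = c(512, 512))
})

fx_adenoma_norm <- function() fixture("adenoma_norm", {
  normalize_stains(fx_adenoma()$image, fx_config()$stain$reference)
})

# Brute-force screening-index oracles working on the raw pair list.
oracle_indices <- function(truth, pred) {
  rhu <- function(x) sign(x) * floor(abs(x) * 10 + 0.5) / 10
  g5 <- truth == "Group5"
  g3 <- truth == "Group3"
  g1 <- truth == "Group1"
  carc <- if (!any(g5)) NA_real_ else
    rhu(100 * sum(g5 & pred %in% c("A", "N")) / sum(g5))
  aden <- if (!any(g3)) NA_real_ else
    rhu(100 * sum(g3 & pred == "N") / sum(g3))
  over <- if (length(truth) == 0) NA_real_ else
    rhu(100 * sum((g3 & pred == "P") | (g1 & pred == "P") |
                    (g1 & pred == "A") | (g3 & pred == "X") |
                    (g1 & pred == "X")) / length(truth))
  c(carc, aden, over)
}
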