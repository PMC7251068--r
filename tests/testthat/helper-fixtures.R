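# Shared fixtures, built once per test run. Everything is generated in
# code under fixed seeds; nothing is read from disk.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

fx_regions <- function() fixture("regions", function() {
  build_region_table("cortical66")
})

fx_connectome <- function() fixture("connectome", function() {
  simulate_connectome(fx_regions(), seed = 1)
})

# 40-subject default-condition cohort used by several analysis tests
fx_cohort <- function() fixture("cohort", function() {
  simulate_cohort(fx_regions(), fx_connectome(), cohort_spec(n = 40),
                  seed = 7)
})

# small fast ESM grid for unit tests (not the fitting default)
fx_grid_small <- function() {
  esm_grid(beta = exp(seq(log(0.1), log(2), length.out = 5)),
           delta = exp(seq(log(0.05), log(1), length.out = 5)),
           t_eff = c(5, 10, 15, 20))
}

# a minimal hand-made region table (for geometry-level tests)
make_region_table <- function(xyz, base = NULL) {
  k <- nrow(xyz)
  base <- base %||% paste0("reg", seq_len(k))
  tab <- data.frame(
    region_id = seq_len(2 * k),
    name = c(paste("left", base), paste("right", base)),
    base_name = rep(base, 2),
    hemisphere = rep(c("L", "R"), each = k),
    tissue_class = "cortical",
    limbic = FALSE,
    braak_stage = 1L,
    x = c(-xyz[, 1], xyz[, 1]), y = rep(xyz[, 2], 2),
    z = rep(xyz[, 3], 2),
    stringsAsFactors = FALSE
  )
  class(tab) <- c("region_table", "data.frame")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a
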