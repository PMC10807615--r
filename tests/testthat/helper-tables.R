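# small in-code fixtures shared across tests

# a minimal well-formed exposure/outcome table pair on the same 3 SNPs
tiny_tables <- function() {
  ex <- sumstats(tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.3, 0.4, 0.2),
    beta = c(0.10, -0.08, 0.05),
    se = c(0.01, 0.012, 0.009),
    pval = c(1e-20, 1e-12, 1e-9),
    n_total = 408815), "exposure", "continuous")
  ou <- sumstats(tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    eaf = c(0.31, 0.39, 0.21),
    beta = c(0.05, -0.03, 0.02),
    se = c(0.02, 0.025, 0.018),
    pval = c(0.01, 0.2, 0.3),
    n_total = 98715, n_cases = 52775), "outcome", "binary")
  list(exposure = ex, outcome = ou)
}

# harmonised set built directly from effect arrays (for estimator tests)
make_h <- function(bx, by, sx, sy, eaf = NULL, outcome_type = "continuous") {
  k <- length(bx)
  structure(
    tibble::tibble(rsid = sprintf("rs%03d", seq_len(k)),
                   beta_exp = bx, se_exp = sx, beta_out = by, se_out = sy,
                   eaf_exp = eaf %||% rep(NA_real_, k)),
    class = c("mr_harmonised", class(tibble::tibble())),
    exposure_label = "x", outcome_label = "y", outcome_type = outcome_type,
    dropped = tibble::tibble(rsid = character(0), reason = character(0)))
}

# random harmonised instance for property-based checks
random_h <- function(k = 20, seed = NULL) {
  gen <- function() {
    bx <- rnorm(k, 0.05, 0.03)
    bx[bx == 0] <- 0.01
    make_h(bx = bx, by = rnorm(k, 0, 0.05),
           sx = runif(k, 0.005, 0.02), sy = runif(k, 0.01, 0.05))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

`%||%` <- rlang::`%||%`
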