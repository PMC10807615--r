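# Summary-level simulator for two-sample MR with known causal structure.
#
# Emulates the design the estimators assume: independent (post-clumping)
# instruments for a standardised continuous exposure measured in one large
# sample, and an outcome (continuous, or binary on the log-odds scale)
# measured in a non-overlapping sample, with configurable causal effect and
# horizontal pleiotropy.

#' Simulate a two-sample GWAS summary-statistic pair
#'
#' Per SNP `j`: effect-allele frequency `f_j ~ U(maf_range)`; SNP-exposure
#' effects `gamma_j` are drawn `N(0, 1)`, oriented so the effect allele is
#' the exposure-increasing allele, and rescaled so the variance explained
#' `sum 2 f (1 - f) gamma^2` equals `h2x` exactly. Direct (pleiotropic)
#' SNP-outcome effects are
#' `alpha_j = Bernoulli(pi) * (mu_alpha + sigma_alpha * Z_j) + psi * gamma_j`
#' (`psi != 0` violates the InSIDE condition). True SNP-outcome effects are
#' `theta * gamma_j + alpha_j`. Observed betas are drawn independently
#' around the truths with standard errors `1 / sqrt(2 f (1-f) n)` for
#' continuous traits and `1 / sqrt(2 f (1-f) n K (1-K))` on the log-odds
#' scale for binary outcomes (case fraction `K`); the two samples never
#' overlap. Deterministic under `seed`.
#'
#' @param J Number of independent instruments (default 200).
#' @param maf_range Range of effect-allele frequencies (default 0.05-0.5).
#' @param h2x Exposure variance explained by the instruments (default 0.02).
#' @param theta True causal effect per 1-SD exposure (log-odds for binary
#'   outcomes).
#' @param pleiotropy List with elements `pi` (fraction of SNPs with direct
#'   effects), `mu_alpha`, `sigma_alpha`, `psi` (InSIDE-violating coupling of
#'   the direct effect to `gamma`); defaults all 0.
#' @param n_exp Exposure GWAS sample size (default 408815).
#' @param n_out Outcome GWAS sample size.
#' @param outcome_type `"binary"` or `"continuous"`.
#' @param case_fraction Case fraction `K` for binary outcomes (default 0.5).
#' @param exposure_label,outcome_label Trait labels for the returned tables.
#' @param seed Integer seed (required).
#' @return A list: `exposure` and `outcome` (`mr_sumstats` tables) and
#'   `truth` (list of class `mr_sim_truth`: `gamma`, `alpha`, `theta`,
#'   `h2x`, `maf`, `seed`).
#' @export
simulate_pair <- function(J = 200, maf_range = c(0.05, 0.5), h2x = 0.02,
                          theta = 0,
                          pleiotropy = list(pi = 0, mu_alpha = 0,
                                            sigma_alpha = 0, psi = 0),
                          n_exp = 408815, n_out = 100000,
                          outcome_type = c("binary", "continuous"),
                          case_fraction = 0.5,
                          exposure_label = "simulated exposure",
                          outcome_label = "simulated outcome",
                          seed) {
  outcome_type <- match.arg(outcome_type)
  stopifnot(h2x > 0, h2x < 1, J >= 1)
  pl <- utils::modifyList(list(pi = 0, mu_alpha = 0, sigma_alpha = 0, psi = 0),
                          pleiotropy)
  stopifnot(pl$pi >= 0, pl$pi <= 1)
  if (outcome_type == "binary")
    stopifnot(case_fraction > 0, case_fraction < 1)
  if (missing(seed)) abort("seed is required", class = "mrkit_config_error")

  withr::with_seed(seed, {
    f <- runif(J, maf_range[1], maf_range[2])
    # effect allele = exposure-increasing allele (standard instrument coding)
    gamma <- abs(rnorm(J))
    gamma <- gamma * sqrt(h2x / sum(2 * f * (1 - f) * gamma^2))
    alpha <- rbinom(J, 1, pl$pi) * (pl$mu_alpha + pl$sigma_alpha * rnorm(J)) +
      pl$psi * gamma
    big_gamma <- theta * gamma + alpha

    se_x <- 1 / sqrt(2 * f * (1 - f) * n_exp)
    K <- case_fraction
    se_y <- if (outcome_type == "binary")
      1 / sqrt(2 * f * (1 - f) * n_out * K * (1 - K))
    else 1 / sqrt(2 * f * (1 - f) * n_out)

    bx <- rnorm(J, gamma, se_x)
    by <- rnorm(J, big_gamma, se_y)

    # non-palindromic allele pairs so harmonisation is lossless
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample.int(nrow(pairs), J, replace = TRUE)
    rsid <- sprintf("rs%06d", seq_len(J))

    exposure <- sumstats(
      tibble(rsid = rsid, effect_allele = pairs[pick, 1],
             other_allele = pairs[pick, 2], eaf = f,
             beta = bx, se = se_x, pval = pmax(2 * pnorm(-abs(bx / se_x)), 1e-300),
             n_total = n_exp),
      trait_label = exposure_label, trait_type = "continuous")
    outcome <- sumstats(
      tibble(rsid = rsid, effect_allele = pairs[pick, 1],
             other_allele = pairs[pick, 2], eaf = f,
             beta = by, se = se_y, pval = pmax(2 * pnorm(-abs(by / se_y)), 1e-300),
             n_total = n_out,
             n_cases = if (outcome_type == "binary") round(n_out * K) else NA_real_),
      trait_label = outcome_label, trait_type = outcome_type)

    truth <- structure(list(gamma = gamma, alpha = alpha, theta = theta,
                            h2x = h2x, maf = f, seed = seed,
                            pleiotropy = pl),
                       class = "mr_sim_truth")
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Simulate summary statistics for two genetically correlated exposures
#'
#' Generates one joint instrument panel affecting two standardised
#' continuous exposures whose SNP effects are bivariate normal with
#' correlation `rg` (emulating genetically correlated traits such as a
#' sedentary behaviour and educational attainment), each column rescaled so
#' its variance explained equals `h2x` exactly, plus an outcome whose true
#' SNP effects are `theta[1] * gamma1 + theta[2] * gamma2`. All tables carry
#' the same allele orientation, so the multivariable set builder sees the
#' clean two-sample structure the estimator assumes.
#'
#' @param J Number of instruments in the joint panel.
#' @param h2x Length-2 (or recycled) variance explained per exposure.
#' @param rg Genetic correlation of the SNP effects on the two exposures.
#' @param theta Length-2 true direct causal effects on the outcome.
#' @param n_exp,n_out Sample sizes (exposures measured in `n_exp`; outcome
#'   in a non-overlapping `n_out`).
#' @param outcome_type,case_fraction As in [simulate_pair()].
#' @param labels Length-2 exposure labels.
#' @param seed Integer seed (required).
#' @return A list: `exposures` (named list of two `mr_sumstats`), `outcome`,
#'   and `truth` (`gamma` k x 2 matrix, `theta`, `rg`, `maf`, `seed`).
#' @export
simulate_mv_pair <- function(J = 200, h2x = c(0.02, 0.02), rg = 0,
                             theta = c(0, 0), n_exp = 408815, n_out = 100000,
                             outcome_type = c("continuous", "binary"),
                             case_fraction = 0.5,
                             labels = c("exposure1", "exposure2"), seed) {
  outcome_type <- match.arg(outcome_type)
  h2x <- rep_len(h2x, 2)
  stopifnot(abs(rg) <= 1, length(theta) == 2)
  if (missing(seed)) abort("seed is required", class = "mrkit_config_error")

  withr::with_seed(seed, {
    f <- runif(J, 0.05, 0.5)
    z1 <- rnorm(J)
    z2 <- rg * z1 + sqrt(1 - rg^2) * rnorm(J)
    # effects stay signed: the joint estimator is orientation-free and
    # flipping would distort the effect correlation away from rg
    g <- cbind(z1, z2)
    for (l in 1:2)
      g[, l] <- g[, l] * sqrt(h2x[l] / sum(2 * f * (1 - f) * g[, l]^2))
    big_gamma <- drop(g %*% theta)

    se_x <- 1 / sqrt(2 * f * (1 - f) * n_exp)
    K <- case_fraction
    se_y <- if (outcome_type == "binary")
      1 / sqrt(2 * f * (1 - f) * n_out * K * (1 - K))
    else 1 / sqrt(2 * f * (1 - f) * n_out)
    bx <- cbind(rnorm(J, g[, 1], se_x), rnorm(J, g[, 2], se_x))
    by <- rnorm(J, big_gamma, se_y)

    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"))
    pick <- sample.int(nrow(pairs), J, replace = TRUE)
    rsid <- sprintf("rs%06d", seq_len(J))

    mk_exp <- function(l) sumstats(
      tibble(rsid = rsid, effect_allele = pairs[pick, 1],
             other_allele = pairs[pick, 2], eaf = f,
             beta = bx[, l], se = se_x,
             pval = pmax(2 * pnorm(-abs(bx[, l] / se_x)), 1e-300), n_total = n_exp),
      trait_label = labels[l], trait_type = "continuous")
    exposures <- list(mk_exp(1), mk_exp(2))
    names(exposures) <- labels
    outcome <- sumstats(
      tibble(rsid = rsid, effect_allele = pairs[pick, 1],
             other_allele = pairs[pick, 2], eaf = f,
             beta = by, se = se_y, pval = pmax(2 * pnorm(-abs(by / se_y)), 1e-300),
             n_total = n_out,
             n_cases = if (outcome_type == "binary") round(n_out * K) else NA_real_),
      trait_label = "simulated outcome", trait_type = outcome_type)
    truth <- structure(list(gamma = g, theta = theta, rg = rg, maf = f,
                            h2x = h2x, seed = seed),
                       class = "mr_sim_truth")
    list(exposures = exposures, outcome = outcome, truth = truth)
  })
}

#' Inject outlier effects into an outcome table
#'
#' Shifts the outcome beta of the chosen SNPs by `offset_in_se_units` times
#' their standard error (recomputing the p-values), recording which rows
#' were modified in the `injected_outliers` attribute. Ground truth for
#' outlier-detection benchmarks.
#'
#' @param outcome An `mr_sumstats` outcome table.
#' @param indices Row indices of the SNPs to perturb.
#' @param offset_in_se_units Shift in units of each SNP's `se`.
#' @return The modified table, same class and attributes.
#' @export
inject_outliers <- function(outcome, indices, offset_in_se_units) {
  if (any(indices < 1 | indices > nrow(outcome)))
    abort("outlier index out of range", class = "mrkit_config_error")
  out <- outcome
  out$beta[indices] <- out$beta[indices] +
    offset_in_se_units * out$se[indices]
  out$pval[indices] <- 2 * pnorm(-abs(out$beta[indices] / out$se[indices]))
  attr(out, "injected_outliers") <- tibble(
    row = indices, rsid = out$rsid[indices],
    offset_in_se_units = offset_in_se_units)
  out
}
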