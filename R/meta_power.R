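# Fixed-effect subgroup meta-analysis and a priori power for binary
# outcomes under the standard normal-approximation for MR with a genetic
# score explaining R^2 of the exposure variance.

#' Fixed-effect meta-analysis of subgroup estimates
#'
#' Pools log-scale estimates (e.g. IVW log-ORs for cancer subtypes, subsites
#' or sexes) with inverse-variance weights and reports between-group
#' heterogeneity: `Q_between` on chi-square with `m - 1` df and
#' `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param estimates A data frame with columns `beta` and `se` (one row per
#'   subgroup; an optional `label` column is carried through), or a list of
#'   `mr_estimate` objects.
#' @return A list of class `mr_meta`: `beta`, `se`, `pval`, `m`,
#'   `Q_between`, `df`, `p_het`, `I2`, and the input tibble `groups`.
#' @export
subgroup_meta <- function(estimates) {
  if (is.list(estimates) && !is.data.frame(estimates) &&
      all(vapply(estimates, inherits, logical(1), "mr_estimate"))) {
    estimates <- dplyr::bind_rows(lapply(estimates, function(e)
      tibble(label = e$method, beta = e$beta, se = e$se)))
  }
  est <- as_tibble(estimates)
  m <- nrow(est)
  if (m < 2) abort("subgroup meta-analysis needs at least 2 groups",
                   class = "mrkit_insufficient_error")
  w <- 1 / est$se^2
  beta <- sum(w * est$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  Q <- sum(w * (est$beta - beta)^2)
  df <- m - 1L
  structure(list(beta = beta, se = se,
                 pval = 2 * pnorm(-abs(beta / se)), m = m,
                 Q_between = Q, df = df,
                 p_het = pchisq(Q, df, lower.tail = FALSE),
                 I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0,
                 groups = est),
            class = "mr_meta")
}

#' @export
print.mr_meta <- function(x, ...) {
  cat(sprintf("<mr_meta> pooled beta = %.4f (se %.4f), p = %.3g; m = %d\n",
              x$beta, x$se, x$pval, x$m))
  cat(sprintf("  Q_between = %.2f (df %d), p-het = %.3g, I2 = %.1f%%\n",
              x$Q_between, x$df, x$p_het, x$I2))
  invisible(x)
}

#' A priori power for MR with a binary outcome
#'
#' Normal-approximation power for a two-sample MR of a binary outcome
#' (case fraction `K = n_cases / n_total`) on a standardised exposure whose
#' instruments explain `r2` of its variance:
#' `power = Phi(|ln OR| * sqrt(n_total * r2 * K * (1 - K)) - z_{1 - alpha/2})`.
#'
#' @param or_alt Alternative-hypothesis odds ratio per 1-SD of exposure.
#' @param n_total,n_cases Outcome GWAS sample size and case count.
#' @param r2 Variance of the exposure explained by the instruments, in (0,1).
#' @param alpha Two-sided type-1 error (default 0.05).
#' @return Power in (0, 1); vectorised over `or_alt`.
#' @export
mr_power <- function(or_alt, n_total, n_cases, r2, alpha = 0.05) {
  stopifnot(all(or_alt > 0), n_cases > 0, n_cases < n_total,
            r2 > 0, r2 < 1, alpha > 0, alpha < 1)
  K <- n_cases / n_total
  ncp <- abs(log(or_alt)) * sqrt(n_total * r2 * K * (1 - K))
  pnorm(ncp - qnorm(1 - alpha / 2))
}

#' Minimum detectable odds ratio
#'
#' Grid search upward from OR = 1.00 in `or_grid_step` increments for the
#' first odds ratio whose [mr_power()] exceeds `target_power`; the
#' closed-form threshold
#' `exp((z_{1-alpha/2} + z_{power}) / sqrt(n_total * r2 * K * (1 - K)))`
#' is returned alongside (the grid value is that threshold rounded up to the
#' grid).
#'
#' @inheritParams mr_power
#' @param target_power Required power (default 0.80).
#' @param or_grid_step Grid resolution (default 0.01).
#' @param or_max Upper search bound (default 10).
#' @return A list: `or` (grid result), `or_closed_form`, `power_at_or`.
#' @export
min_detectable_or <- function(n_total, n_cases, r2, alpha = 0.05,
                              target_power = 0.80, or_grid_step = 0.01,
                              or_max = 10) {
  K <- n_cases / n_total
  denom <- sqrt(n_total * r2 * K * (1 - K))
  closed <- exp((qnorm(1 - alpha / 2) + qnorm(target_power)) / denom)
  grid <- round(seq(1, or_max, by = or_grid_step), 10)
  pw <- mr_power(grid, n_total, n_cases, r2, alpha)
  hit <- which(pw > target_power)[1]
  if (is.na(hit)) abort("no OR on the grid reaches the target power",
                        class = "mrkit_empty_set_error")
  list(or = grid[hit], or_closed_form = closed, power_at_or = pw[hit])
}
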