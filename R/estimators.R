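# Univariable two-sample MR estimators on a harmonised SNP set.
#
# All causal effects are on the scale of the outcome per 1-SD increment of
# the exposure; for binary outcomes (log-odds betas) the odds-ratio view
# exp(beta) with exponentiated CI is attached.

.z975 <- function() qnorm(0.975)

.mr_estimate <- function(method, beta, se, pval, k, outcome_type = "continuous",
                         extra = list()) {
  ci <- c(beta - .z975() * se, beta + .z975() * se)
  out <- c(list(method = method, beta = beta, se = se,
                ci_low = ci[1], ci_high = ci[2], pval = pval, k = k,
                outcome_type = outcome_type,
                or = exp(beta), or_low = exp(ci[1]), or_high = exp(ci[2])),
           extra)
  class(out) <- c(paste0("mr_", sub("_.*", "", method)), "mr_estimate")
  out
}

#' Per-SNP Wald ratios
#'
#' The single-SNP causal estimate `beta_out / beta_exp` with first-order
#' delta-method standard error `se_out / |beta_exp|`.
#'
#' @param h An `mr_harmonised` set.
#' @return A tibble with columns `rsid`, `ratio`, `se`.
#' @export
wald_ratios <- function(h) {
  zero <- h$rsid[h$beta_exp == 0]
  if (length(zero) > 0)
    abort(paste0("degenerate instrument(s) with zero exposure effect: ",
                 paste(head(zero, 5), collapse = ", ")),
          class = "mrkit_degenerate_error")
  tibble(rsid = h$rsid,
         ratio = h$beta_out / h$beta_exp,
         se = h$se_out / abs(h$beta_exp))
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (theta_j - theta_ivw)^2` with `w_j = 1/se_j^2` over per-SNP
#' ratios, referred to chi-square with `k - 1` df;
#' `I2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param ratios,ses Per-SNP causal estimates and their standard errors.
#' @return A list `Q`, `df`, `pval`, `I2`.
#' @export
cochran_q <- function(ratios, ses) {
  k <- length(ratios)
  if (k < 2) abort("Cochran's Q needs at least 2 estimates",
                   class = "mrkit_insufficient_error")
  w <- 1 / ses^2
  pooled <- sum(w * ratios) / sum(w)
  Q <- sum(w * (ratios - pooled)^2)
  df <- k - 1L
  list(Q = Q, df = df,
       pval = pchisq(Q, df, lower.tail = FALSE),
       I2 = if (Q > 0) max(0, (Q - df) / Q) * 100 else 0)
}

#' Inverse-variance-weighted causal estimate
#'
#' Pools per-SNP Wald ratios with weights `1/se^2` (equivalently a weighted
#' regression of outcome on exposure betas through the origin). The fixed
#' model uses `se = (sum w)^{-1/2}`; the random (multiplicative) model
#' inflates it by `max(1, sqrt(Q/df))`; `model = "auto"` follows the common
#' rule of switching to random effects when the Q p-value is at or below
#' 0.05. A single SNP returns its Wald ratio with Q undefined.
#'
#' @param h An `mr_harmonised` set.
#' @param model `"auto"` (default), `"fixed"` or `"random"`.
#' @return An object of class `mr_ivw`/`mr_estimate` with fields `beta`,
#'   `se`, `ci_low`, `ci_high`, `pval`, `k`, odds-ratio view, `model`
#'   (model actually used), and heterogeneity `Q`, `Q_df`, `Q_pval`, `I2`.
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  if (nrow(h) == 0) abort("empty harmonised set", class = "mrkit_empty_set_error")
  wr <- wald_ratios(h)
  k <- nrow(wr)
  otype <- attr(h, "outcome_type") %||% "continuous"
  if (k == 1) {
    est <- .mr_estimate("ivw_fixed", wr$ratio, wr$se,
                        2 * pnorm(-abs(wr$ratio / wr$se)), 1L, otype,
                        extra = list(model = "fixed", Q = NA_real_,
                                     Q_df = NA_integer_, Q_pval = NA_real_,
                                     I2 = NA_real_))
    return(est)
  }
  w <- 1 / wr$se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se_fixed <- sqrt(1 / sum(w))
  q <- cochran_q(wr$ratio, wr$se)
  use_random <- switch(model,
                       fixed = FALSE,
                       random = TRUE,
                       auto = q$pval <= 0.05)
  se <- if (use_random) se_fixed * max(1, sqrt(q$Q / q$df)) else se_fixed
  method <- if (use_random) "ivw_random" else "ivw_fixed"
  .mr_estimate(method, beta, se, 2 * pnorm(-abs(beta / se)), k, otype,
               extra = list(model = if (use_random) "random" else "fixed",
                            Q = q$Q, Q_df = q$df, Q_pval = q$pval, I2 = q$I2))
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome betas on the exposure betas with an
#' unconstrained intercept (weights `1/se_out^2`), after orienting every SNP
#' so its exposure beta is non-negative. The intercept estimates the average
#' directional pleiotropic effect (its deviation from zero is the pleiotropy
#' test, on t with `k - 2` df); the slope estimates the causal effect under
#' the InSIDE assumption (normal p after multiplicative overdispersion
#' scaling of both standard errors by `max(1, sqrt(RSS_w / (k - 2)))`).
#'
#' @param h An `mr_harmonised` set with at least 3 SNPs.
#' @return An object of class `mr_egger`/`mr_estimate` for the slope, with
#'   fields `intercept`, `intercept_se`, `intercept_pval` and `sigma` (the
#'   overdispersion scale).
#' @export
mr_egger <- function(h) {
  k <- nrow(h)
  if (k < 3) abort("MR-Egger needs at least 3 instruments",
                   class = "mrkit_insufficient_error")
  flip <- h$beta_exp < 0
  bx <- ifelse(flip, -h$beta_exp, h$beta_exp)
  by <- ifelse(flip, -h$beta_out, h$beta_out)
  w <- 1 / h$se_out^2

  # closed-form weighted simple regression with intercept
  sw <- sum(w)
  xbar <- sum(w * bx) / sw
  ybar <- sum(w * by) / sw
  sxx <- sum(w * (bx - xbar)^2)
  if (sxx == 0) abort("exposure betas are constant; Egger slope undefined",
                      class = "mrkit_degenerate_error")
  slope <- sum(w * (bx - xbar) * (by - ybar)) / sxx
  intercept <- ybar - slope * xbar
  resid <- by - intercept - slope * bx
  rss_w <- sum(w * resid^2)
  sigma <- max(1, sqrt(rss_w / (k - 2)))
  se_slope <- sigma * sqrt(1 / sxx)
  se_int <- sigma * sqrt(1 / sw + xbar^2 / sxx)
  p_slope <- 2 * pnorm(-abs(slope / se_slope))
  p_int <- 2 * pt(-abs(intercept / se_int), df = k - 2)
  .mr_estimate("egger_slope", slope, se_slope, p_slope, k,
               attr(h, "outcome_type") %||% "continuous",
               extra = list(intercept = intercept, intercept_se = se_int,
                            intercept_pval = p_int, sigma = sigma,
                            rss_w = rss_w))
}

# weighted-median point estimate from ratios/weights (midpoint convention)
.weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  th <- ratio[ord]
  wn <- w[ord] / sum(w)
  s_mid <- cumsum(wn) - wn / 2
  approx(s_mid, th, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median causal estimate
#'
#' The causal effect at the 50th percentile of the inverse-variance-weighted,
#' sorted Wald ratios (linear interpolation with the midpoint cumulative-
#' weight convention). Consistent when at least 50% of the total weight comes
#' from valid instruments. The standard error is the standard deviation of
#' the estimate over `n_boot` parametric-bootstrap resamples, drawing each
#' SNP's exposure and outcome betas from normal distributions centred on the
#' observed values.
#'
#' @param h An `mr_harmonised` set with at least 3 SNPs.
#' @param n_boot Bootstrap resamples for the SE (default 1000; `0` returns
#'   the point estimate with `se = NA`).
#' @param seed Integer seed for the bootstrap (required when `n_boot > 0`).
#' @return An object of class `mr_weighted`/`mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  k <- nrow(h)
  if (k < 3) abort("weighted median needs at least 3 instruments",
                   class = "mrkit_insufficient_error")
  wr <- wald_ratios(h)
  w <- 1 / wr$se^2
  est <- .weighted_median_point(wr$ratio, w)
  se <- NA_real_
  if (n_boot > 0) {
    if (is.null(seed)) abort("seed is required for the bootstrap SE",
                             class = "mrkit_config_error")
    boots <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        bx <- rnorm(k, h$beta_exp, h$se_exp)
        by <- rnorm(k, h$beta_out, h$se_out)
        bx[bx == 0] <- .Machine$double.eps
        r <- by / bx
        wb <- (abs(bx) / h$se_out)^2
        .weighted_median_point(r, wb)
      }, numeric(1))
    })
    se <- stats::sd(boots)
  }
  pval <- if (is.na(se)) NA_real_ else 2 * pnorm(-abs(est / se))
  .mr_estimate("weighted_median", est, se, pval, k,
               attr(h, "outcome_type") %||% "continuous",
               extra = list(n_boot = n_boot, seed = seed))
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat("<mr_estimate> method: ", x$method, ", k = ", x$k, "\n", sep = "")
  cat(sprintf("  beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g\n",
              x$beta, x$se, x$ci_low, x$ci_high, x$pval))
  if (identical(x$outcome_type, "binary"))
    cat(sprintf("  OR per 1-SD = %.2f [%.2f, %.2f]\n",
                x$or, x$or_low, x$or_high))
  if (!is.null(x$intercept))
    cat(sprintf("  intercept = %.4f (se %.4f), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_pval))
  if (!is.null(x$Q) && !is.na(x$Q))
    cat(sprintf("  Q = %.2f (df %d, p = %.3g), I2 = %.1f%%\n",
                x$Q, x$Q_df, x$Q_pval, x$I2))
  invisible(x)
}
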