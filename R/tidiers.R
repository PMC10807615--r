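# broom-style tidiers for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.mr_estimate <- function(x, ...) {
  out <- tibble(method = x$method, estimate = x$beta, std.error = x$se,
                conf.low = x$ci_low, conf.high = x$ci_high,
                p.value = x$pval, k = x$k,
                or = x$or, or.conf.low = x$or_low, or.conf.high = x$or_high)
  if (!is.null(x$intercept)) {
    out <- dplyr::bind_rows(
      dplyr::mutate(out, term = "slope", .before = 1),
      tibble(term = "intercept", method = x$method,
             estimate = x$intercept, std.error = x$intercept_se,
             conf.low = x$intercept - .z975() * x$intercept_se,
             conf.high = x$intercept + .z975() * x$intercept_se,
             p.value = x$intercept_pval, k = x$k,
             or = NA_real_, or.conf.low = NA_real_, or.conf.high = NA_real_))
  }
  out
}

#' @export
glance.mr_estimate <- function(x, ...) {
  tibble(method = x$method, k = x$k,
         Q = x$Q %||% NA_real_, Q.df = x$Q_df %||% NA_integer_,
         Q.p.value = x$Q_pval %||% NA_real_, I2 = x$I2 %||% NA_real_,
         sigma = x$sigma %||% NA_real_)
}

#' @export
tidy.mr_presso <- function(x, ...) {
  raw <- tidy(x$raw); raw$method <- "presso_raw"
  out <- raw
  if (!is.null(x$corrected)) {
    cor <- tidy(x$corrected); cor$method <- "presso_corrected"
    out <- dplyr::bind_rows(out, cor)
  }
  out
}

#' @export
glance.mr_presso <- function(x, ...) {
  tibble(rss_obs = x$rss_obs, global_p = x$global_p, n_sim = x$n_sim,
         n_outliers = length(x$outlier_rsids),
         distortion_p = x$distortion_p, seed = x$seed)
}

#' @export
tidy.mr_mvmr <- function(x, ...) {
  dplyr::rename(x$estimates, term = "exposure", estimate = "beta",
                std.error = "se", conf.low = "ci_low", conf.high = "ci_high",
                p.value = "pval", or.conf.low = "or_low",
                or.conf.high = "or_high")
}

#' @export
glance.mr_mvmr <- function(x, ...) {
  tibble(k = x$k, Q_a = x$Q_a, Q.df = x$Q_df, Q.p.value = x$Q_pval,
         sigma = x$sigma)
}

#' @export
tidy.mr_meta <- function(x, ...) {
  tibble(estimate = x$beta, std.error = x$se, p.value = x$pval, m = x$m)
}

#' @export
glance.mr_meta <- function(x, ...) {
  tibble(m = x$m, Q_between = x$Q_between, df = x$df, p.het = x$p_het,
         I2 = x$I2)
}
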