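# Multivariable MR: joint instruments for several exposures, MV-IVW
# estimation and conditional instrument-strength diagnostics.

#' Build a multivariable harmonised set
#'
#' Takes the union of the per-exposure instruments (SNPs genome-wide
#' significant in at least one exposure table), requires each SNP to be
#' present in every exposure table and in the outcome (SNPs failing this are
#' dropped with a reason), clumps across exposures at a strict threshold
#' (greedy by the best p-value across exposures) when an LD matrix is
#' supplied, and harmonises all tables onto the first exposure's
#' effect-allele orientation.
#'
#' @param exposure_tables Named list of at least two `mr_sumstats` tables;
#'   every table must cover the union of instruments (betas at any p).
#' @param outcome An `mr_sumstats` table.
#' @param ld Optional squared-correlation matrix with rsid dimnames for the
#'   cross-exposure clumping; when absent the union is assumed independent.
#' @param r2_threshold Cross-exposure clumping threshold (default 0.001).
#' @param p_threshold Instrument significance threshold applied per exposure
#'   (default 5e-8).
#' @param palindrome_eaf_window As in [harmonise()].
#' @return A tibble of class `mr_mvset` with columns `rsid`, `beta_out`,
#'   `se_out` and per-exposure `beta_<label>`, `se_<label>`; attributes
#'   `exposure_labels`, `outcome_label`, `outcome_type`, `dropped`,
#'   `provenance` (per-SNP, which exposure(s) contributed it as an
#'   instrument).
#' @export
build_mv_set <- function(exposure_tables, outcome, ld = NULL,
                         r2_threshold = 0.001, p_threshold = 5e-8,
                         palindrome_eaf_window = 0.08) {
  if (length(exposure_tables) < 2)
    abort("multivariable MR needs at least two exposures",
          class = "mrkit_config_error")
  labels <- names(exposure_tables)
  if (is.null(labels) || any(!nzchar(labels)))
    labels <- vapply(exposure_tables, function(t)
      attr(t, "trait_label") %||% "exposure", character(1))
  L <- length(exposure_tables)
  exs <- lapply(exposure_tables, function(t) as_tibble(as.data.frame(t)))
  ou <- as_tibble(as.data.frame(outcome))
  if (anyDuplicated(ou$rsid)) {
    ou <- ou |> dplyr::arrange(.data$rsid, .data$se) |>
      dplyr::distinct(.data$rsid, .keep_all = TRUE)
  }

  dropped <- tibble(rsid = character(0), reason = character(0))
  # per-exposure instruments: genome-wide significant rows of that table
  inst_sets <- lapply(exs, function(t) {
    p <- t$pval
    if (is.null(p)) p <- rep(NA_real_, nrow(t))
    p <- ifelse(is.na(p), 2 * pnorm(-abs(t$beta / t$se)), p)
    t$rsid[p < p_threshold]
  })
  all_rsids <- unique(unlist(inst_sets))
  if (length(all_rsids) == 0)
    abort("no SNP passes the instrument p-value threshold in any exposure",
          class = "mrkit_empty_set_error")
  provenance <- lapply(all_rsids, function(r)
    labels[vapply(inst_sets, function(s) r %in% s, logical(1))])
  names(provenance) <- all_rsids

  # presence in every table
  keep <- character(0)
  for (r in all_rsids) {
    in_all <- all(vapply(exs, function(t) r %in% t$rsid, logical(1)))
    if (!in_all) {
      miss <- labels[!vapply(exs, function(t) r %in% t$rsid, logical(1))]
      dropped <- dplyr::bind_rows(dropped,
        tibble(rsid = r, reason = paste0("missing_in_", miss[1])))
    } else if (!r %in% ou$rsid) {
      dropped <- dplyr::bind_rows(dropped,
        tibble(rsid = r, reason = "missing_in_outcome"))
    } else keep <- c(keep, r)
  }

  # best p across exposures, for clump ranking
  best_p <- vapply(keep, function(r) {
    min(vapply(exs, function(t) {
      row <- t[t$rsid == r, ][1, ]
      p <- row$pval
      if (is.null(p) || is.na(p)) p <- 2 * pnorm(-abs(row$beta / row$se))
      p
    }, numeric(1)))
  }, numeric(1))

  ord <- order(best_p, keep)
  keep <- keep[ord]
  if (!is.null(ld)) {
    ld <- as.matrix(ld)
    status <- rep("pending", length(keep))
    for (i in seq_along(keep)) {
      if (status[i] != "pending") next
      status[i] <- "accepted"
      for (j in seq_along(keep)) {
        if (status[j] != "pending") next
        r2 <- if (keep[i] %in% rownames(ld) && keep[j] %in% colnames(ld))
          ld[keep[i], keep[j]] else 0
        if (!is.na(r2) && r2 >= r2_threshold) status[j] <- "discarded"
      }
    }
    clumped_out <- keep[status == "discarded"]
    if (length(clumped_out) > 0)
      dropped <- dplyr::bind_rows(dropped,
        tibble(rsid = clumped_out, reason = "clumped_cross_exposure"))
    keep <- keep[status == "accepted"]
  }

  # harmonise everything to exposure 1's orientation
  ref <- exs[[1]]
  rows <- list()
  for (r in keep) {
    ref_row <- ref[ref$rsid == r, ][1, ]
    rec <- list(rsid = r)
    ok <- TRUE
    for (l in seq_len(L)) {
      t <- exs[[l]]
      row <- t[t$rsid == r, ][1, ]
      al <- .align_alleles(ref_row$effect_allele, ref_row$other_allele,
                           row$effect_allele, row$other_allele,
                           eaf_ref = ref_row$eaf %||% NA_real_,
                           eaf = row$eaf %||% NA_real_,
                           window = palindrome_eaf_window)
      if (al$status != "ok") {
        dropped <- dplyr::bind_rows(dropped, tibble(rsid = r, reason = al$status))
        ok <- FALSE; break
      }
      rec[[paste0("beta_", l)]] <- if (al$flip) -row$beta else row$beta
      rec[[paste0("se_", l)]] <- row$se
    }
    if (!ok) next
    orow <- ou[ou$rsid == r, ][1, ]
    al <- .align_alleles(ref_row$effect_allele, ref_row$other_allele,
                         orow$effect_allele, orow$other_allele,
                         eaf_ref = ref_row$eaf %||% NA_real_,
                         eaf = orow$eaf %||% NA_real_,
                         window = palindrome_eaf_window)
    if (al$status != "ok") {
      dropped <- dplyr::bind_rows(dropped, tibble(rsid = r, reason = al$status))
      next
    }
    rec$beta_out <- if (al$flip) -orow$beta else orow$beta
    rec$se_out <- orow$se
    rows[[length(rows) + 1]] <- as_tibble(rec)
  }
  m <- dplyr::bind_rows(rows)
  if (nrow(m) <= L)
    abort(paste0("only ", nrow(m), " SNPs for ", L,
                 " exposures: model under-identified"),
          class = "mrkit_underidentified_error")
  beta_cols <- paste0("beta_", seq_len(L))
  se_cols <- paste0("se_", seq_len(L))
  names(m)[match(beta_cols, names(m))] <- paste0("beta_", labels)
  names(m)[match(se_cols, names(m))] <- paste0("se_", labels)
  m <- m[c("rsid", paste0("beta_", labels), paste0("se_", labels),
           "beta_out", "se_out")]
  structure(m,
            class = c("mr_mvset", class(tibble())),
            exposure_labels = labels,
            outcome_label = attr(outcome, "trait_label") %||% "outcome",
            outcome_type = attr(outcome, "trait_type") %||% "continuous",
            dropped = dropped,
            provenance = provenance[m$rsid])
}

.mv_design <- function(m) {
  labels <- attr(m, "exposure_labels")
  X <- as.matrix(as.data.frame(m)[paste0("beta_", labels)])
  colnames(X) <- labels
  X
}

#' Multivariable IVW estimate
#'
#' Weighted least squares of the SNP-outcome betas on all SNP-exposure beta
#' columns, no intercept, weights `1/se_out^2`. Residual heterogeneity `Q_a`
#' (weighted RSS, df `k - L`) triggers multiplicative overdispersion scaling
#' of the standard errors when its chi-square p-value is at or below 0.05.
#'
#' @param m An `mr_mvset`.
#' @return An object of class `mr_mvmr`: tibble `estimates` (one row per
#'   exposure: `exposure`, `beta`, `se`, `ci_low`, `ci_high`, `pval`, `or`,
#'   `or_low`, `or_high`), plus `Q_a`, `Q_df`, `Q_pval`, `sigma`, `k`.
#' @export
mvmr_ivw <- function(m) {
  labels <- attr(m, "exposure_labels")
  X_full <- .mv_design(m)
  k <- nrow(X_full)
  y <- m$beta_out
  w <- 1 / m$se_out^2

  # an exactly-zero beta column carries no information and would make the
  # normal equations singular; exclude it (its coefficient is undefined)
  # so the remaining exposures are estimated unchanged
  nonzero <- colSums(X_full != 0) > 0
  X <- X_full[, nonzero, drop = FALSE]
  L_fit <- ncol(X)
  L <- ncol(X_full)
  if (L_fit == 0) abort("all exposure beta columns are zero",
                        class = "mrkit_degenerate_error")

  XtW <- t(X * w)
  A <- XtW %*% X
  qr_A <- qr(A)
  if (qr_A$rank < L_fit) {
    abort(paste0("collinear exposure beta columns among: ",
                 paste(labels[nonzero], collapse = ", ")),
          class = "mrkit_collinearity_error")
  }
  Ainv <- solve(A)
  coef_fit <- drop(Ainv %*% (XtW %*% y))
  resid <- y - drop(X %*% coef_fit)
  Q_a <- sum(w * resid^2)
  df <- k - L_fit
  Q_pval <- pchisq(Q_a, df, lower.tail = FALSE)
  sigma <- if (Q_pval <= 0.05) max(1, sqrt(Q_a / df)) else 1
  se_fit <- sigma * sqrt(diag(Ainv))
  coef <- rep(NA_real_, L)
  se <- rep(NA_real_, L)
  coef[nonzero] <- coef_fit
  se[nonzero] <- se_fit
  z <- coef / se
  est <- tibble(exposure = labels, beta = coef, se = se,
                ci_low = coef - .z975() * se, ci_high = coef + .z975() * se,
                pval = 2 * pnorm(-abs(z)),
                or = exp(coef), or_low = exp(coef - .z975() * se),
                or_high = exp(coef + .z975() * se))
  structure(list(estimates = est, Q_a = Q_a, Q_df = df, Q_pval = Q_pval,
                 sigma = sigma, k = k,
                 outcome_type = attr(m, "outcome_type"),
                 outcome_label = attr(m, "outcome_label")),
            class = "mr_mvmr")
}

#' Conditional instrument-strength F-statistics
#'
#' For each exposure, its SNP-beta column is regressed on the other
#' exposures' columns (weights `1/se^2` of that exposure's betas); the
#' conditional F is the weighted residual sum of squares divided by
#' `k - L + 1`. Values above 10 conventionally indicate that the instruments
#' predict the exposure well conditional on the others; strongly genetically
#' correlated exposures push the conditional F toward 0.
#'
#' @param m An `mr_mvset`.
#' @return A tibble with columns `exposure`, `conditional_F`, `df`
#'   (the divisor `k - L + 1`, stated explicitly).
#' @export
conditional_f <- function(m) {
  labels <- attr(m, "exposure_labels")
  X <- .mv_design(m)
  L <- ncol(X)
  k <- nrow(X)
  ses <- as.matrix(as.data.frame(m)[paste0("se_", labels)])
  out <- vapply(seq_len(L), function(l) {
    y <- X[, l]
    Z <- X[, -l, drop = FALSE]
    Z <- Z[, colSums(Z != 0) > 0, drop = FALSE]
    w <- 1 / ses[, l]^2
    if (ncol(Z) == 0) return(sum(w * y^2) / (k - L + 1))
    ZtW <- t(Z * w)
    A <- ZtW %*% Z
    coef <- tryCatch(solve(A, ZtW %*% y),
                     error = function(e)
                       abort("collinear columns in conditional-F regression",
                             class = "mrkit_collinearity_error"))
    resid <- y - drop(Z %*% coef)
    sum(w * resid^2) / (k - L + 1)
  }, numeric(1))
  tibble(exposure = labels, conditional_F = out, df = k - L + 1)
}

#' @export
print.mr_mvmr <- function(x, ...) {
  cat("<mr_mvmr> outcome: ", x$outcome_label, ", k = ", x$k,
      ", Q_a = ", sprintf("%.2f", x$Q_a), " (df ", x$Q_df, ", p = ",
      format(x$Q_pval, digits = 3), ")\n", sep = "")
  print(x$estimates)
  invisible(x)
}
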