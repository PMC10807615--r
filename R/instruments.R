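# Instrument selection (greedy LD clumping) and strength diagnostics.

#' Select LD-independent, genome-wide-significant instruments
#'
#' Greedy clumping: SNPs passing the p-value threshold are ranked by
#' ascending p (rsid as deterministic tie-break); the best is accepted, every
#' unaccepted SNP with squared correlation `>= r2_threshold` to an accepted
#' SNP within `window_bp` is discarded, and the process repeats. Positions
#' (column `pos`, optionally `chr`) are used for the window when present;
#' without positions all pairs are treated as within the window. When no LD
#' matrix is supplied the data are assumed pre-clumped and every passing SNP
#' is accepted (flag `preclumped_assumed`).
#'
#' @param table An `mr_sumstats` table (needs a `pval` column).
#' @param p_threshold Genome-wide significance threshold (default `5e-8`).
#' @param ld Square numeric matrix of squared correlations with rsid
#'   dimnames, covering at least the SNPs passing `p_threshold`, or `NULL`.
#' @param r2_threshold Clumping threshold on r-squared (default 0.005).
#' @param window_bp Clumping window in base pairs (default 5e6).
#' @return A tibble of class `mr_instruments` with columns `rsid`, `pval`,
#'   `f` (per-SNP F-statistic `(beta/se)^2`), and attributes `total_r2`
#'   (variance explained, when `eaf` is available), `p_threshold`,
#'   `r2_threshold`, `window_bp`, `preclumped_assumed`.
#' @export
select_instruments <- function(table, p_threshold = 5e-8, ld = NULL,
                               r2_threshold = 0.005, window_bp = 5e6) {
  tb <- as_tibble(as.data.frame(table))
  if (!"pval" %in% names(tb) || all(is.na(tb$pval)))
    tb$pval <- 2 * pnorm(-abs(tb$beta / tb$se))
  pass <- tb[!is.na(tb$pval) & tb$pval < p_threshold, , drop = FALSE]
  if (nrow(pass) == 0)
    abort("no SNP passes the p-value threshold", class = "mrkit_empty_set_error")

  pass <- pass[order(pass$pval, pass$rsid), , drop = FALSE]
  preclumped <- is.null(ld)
  if (preclumped) {
    accepted <- pass
  } else {
    ld <- as.matrix(ld)
    if (is.null(rownames(ld))) abort("ld matrix needs rsid dimnames",
                                     class = "mrkit_config_error")
    missing_ld <- setdiff(pass$rsid, rownames(ld))
    if (length(missing_ld) > 0)
      abort(paste0("ld matrix does not cover: ",
                   paste(head(missing_ld, 5), collapse = ", ")),
            class = "mrkit_config_error")
    has_pos <- "pos" %in% names(pass) && !all(is.na(pass$pos))
    in_window <- function(i, j) {
      if (!has_pos) return(TRUE)
      same_chr <- !("chr" %in% names(pass)) ||
        identical(pass$chr[i], pass$chr[j])
      same_chr && abs(pass$pos[i] - pass$pos[j]) <= window_bp
    }
    status <- rep("pending", nrow(pass))  # pending / accepted / discarded
    for (i in seq_len(nrow(pass))) {
      if (status[i] != "pending") next
      status[i] <- "accepted"
      for (j in seq_len(nrow(pass))) {
        if (status[j] != "pending") next
        r2 <- ld[pass$rsid[i], pass$rsid[j]]
        if (!is.na(r2) && r2 >= r2_threshold && in_window(i, j))
          status[j] <- "discarded"
      }
    }
    accepted <- pass[status == "accepted", , drop = FALSE]
  }

  out <- tibble(rsid = accepted$rsid,
                pval = accepted$pval,
                f = (accepted$beta / accepted$se)^2)
  total_r2 <- if ("eaf" %in% names(accepted) && !anyNA(accepted$eaf)) {
    min(1, sum(2 * accepted$eaf * (1 - accepted$eaf) * accepted$beta^2))
  } else NA_real_
  structure(out,
            class = c("mr_instruments", class(tibble())),
            total_r2 = total_r2,
            p_threshold = p_threshold,
            r2_threshold = r2_threshold,
            window_bp = window_bp,
            preclumped_assumed = preclumped)
}

#' Per-SNP instrument F-statistics
#'
#' `F_j = (beta_exp_j / se_exp_j)^2`, the squared SNP-exposure z-score; mean
#' F over 10 is the conventional indication of little weak-instrument bias.
#'
#' @param h An `mr_harmonised` set.
#' @return A list with `per_snp` (tibble `rsid`, `f`) and `mean_f`.
#' @export
f_statistics <- function(h) {
  stopifnot(nrow(h) >= 1)
  f <- (h$beta_exp / h$se_exp)^2
  list(per_snp = tibble(rsid = h$rsid, f = f), mean_f = mean(f))
}

#' Variance of the exposure explained by the instruments
#'
#' For a standardised continuous exposure, `R^2 = sum 2 f (1-f) beta^2`
#' over SNPs (effect-allele frequency `f`), capped at 1.
#'
#' @param h An `mr_harmonised` set with `eaf_exp` present for every SNP.
#' @return Total R-squared in `[0, 1]`.
#' @export
variance_explained <- function(h) {
  if (anyNA(h$eaf_exp))
    abort("eaf missing for some SNPs; supply R^2 directly instead",
          class = "mrkit_unavailable_error")
  min(1, sum(2 * h$eaf_exp * (1 - h$eaf_exp) * h$beta_exp^2))
}
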