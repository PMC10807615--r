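# Allele harmonisation of an exposure (instrument) table against an outcome
# table. Alleles are aligned onto the exposure's effect-allele orientation;
# strand complements are tried before declaring a mismatch; palindromic pairs
# (A/T, C/G) are resolved from allele frequencies or dropped.

.complement <- function(a) chartr("ACGT", "TGCA", a)
.is_palindromic <- function(ea, oa) oa == .complement(ea)

# Align one outcome record to a reference allele pair.
# Returns list(status, flip): status "ok", "palindromic_ambiguous", or
# "allele_mismatch"; flip TRUE when the outcome beta must change sign.
.align_alleles <- function(ref_ea, ref_oa, ea, oa, eaf_ref, eaf, window) {
  if (.is_palindromic(ref_ea, ref_oa)) {
    # orientation cannot be read from the alleles; use frequencies
    if (ea == ref_ea && oa == ref_oa) flip <- FALSE
    else if (ea == ref_oa && oa == ref_ea) flip <- TRUE
    else return(list(status = "allele_mismatch", flip = NA))
    if (is.na(eaf_ref) || is.na(eaf))
      return(list(status = "palindromic_ambiguous", flip = NA))
    eaf_aligned <- if (flip) 1 - eaf else eaf
    lo <- 0.5 - window
    hi <- 0.5 + window
    clear <- (eaf_ref < lo || eaf_ref > hi) && (eaf_aligned < lo || eaf_aligned > hi)
    same_side <- sign(eaf_ref - 0.5) == sign(eaf_aligned - 0.5)
    if (clear && same_side) return(list(status = "ok", flip = flip))
    return(list(status = "palindromic_ambiguous", flip = NA))
  }
  if (ea == ref_ea && oa == ref_oa) return(list(status = "ok", flip = FALSE))
  if (ea == ref_oa && oa == ref_ea) return(list(status = "ok", flip = TRUE))
  cea <- .complement(ea); coa <- .complement(oa)
  if (cea == ref_ea && coa == ref_oa) return(list(status = "ok", flip = FALSE))
  if (cea == ref_oa && coa == ref_ea) return(list(status = "ok", flip = TRUE))
  list(status = "allele_mismatch", flip = NA)
}

#' Harmonise an exposure table against an outcome table
#'
#' Aligns each instrument SNP of the exposure table with its record in the
#' outcome table onto the exposure's effect-allele orientation: identical
#' allele pairs are kept as-is, swapped pairs have the outcome beta
#' sign-flipped, strand complements (A<->T, C<->G) are tried before a pair is
#' declared mismatched, and palindromic SNPs (A/T or C/G) are kept only when
#' both allele frequencies are clearly away from 0.5 (outside
#' `0.5 +/- palindrome_eaf_window`) and on the same side after alignment.
#' Duplicate rsids in the outcome table are resolved by keeping the record
#' with the smallest standard error.
#'
#' @param exposure,outcome `mr_sumstats` tables; the exposure table is the
#'   instrument list.
#' @param palindrome_eaf_window Half-width of the ambiguity window around an
#'   allele frequency of 0.5 (default 0.08).
#' @return A tibble of class `mr_harmonised` with columns `rsid`, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `eaf_exp`, and attributes
#'   `exposure_label`, `outcome_label`, `outcome_type`, `dropped`
#'   (tibble `rsid`/`reason`).
#' @export
harmonise <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(is.data.frame(exposure), is.data.frame(outcome))
  exp_lab <- attr(exposure, "trait_label") %||% "exposure"
  out_lab <- attr(outcome, "trait_label") %||% "outcome"
  out_type <- attr(outcome, "trait_type") %||% "continuous"

  ex <- as_tibble(as.data.frame(exposure))
  ou <- as_tibble(as.data.frame(outcome))

  dropped <- tibble(rsid = character(0), reason = character(0))
  drop <- function(rsid, reason) {
    dropped <<- dplyr::bind_rows(dropped, tibble(rsid = rsid, reason = reason))
  }

  # de-duplicate: exposure duplicates dropped, outcome keeps smallest se
  dup_ex <- duplicated(ex$rsid)
  if (any(dup_ex)) {
    drop(ex$rsid[dup_ex], "duplicate")
    ex <- ex[!dup_ex, , drop = FALSE]
  }
  if (anyDuplicated(ou$rsid)) {
    ou <- ou |>
      dplyr::arrange(.data$rsid, .data$se) |>
      dplyr::distinct(.data$rsid, .keep_all = TRUE)
  }

  idx <- match(ex$rsid, ou$rsid)
  keep <- logical(nrow(ex))
  flip <- logical(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    j <- idx[i]
    if (is.na(j)) { drop(ex$rsid[i], "missing_in_outcome"); next }
    al <- .align_alleles(ex$effect_allele[i], ex$other_allele[i],
                         ou$effect_allele[j], ou$other_allele[j],
                         eaf_ref = if ("eaf" %in% names(ex)) ex$eaf[i] else NA_real_,
                         eaf = if ("eaf" %in% names(ou)) ou$eaf[j] else NA_real_,
                         window = palindrome_eaf_window)
    if (al$status != "ok") { drop(ex$rsid[i], al$status); next }
    keep[i] <- TRUE
    flip[i] <- al$flip
  }

  if (!any(keep)) {
    abort(paste0("no SNPs retained after harmonising '", exp_lab, "' vs '",
                 out_lab, "'; no analysis is possible"),
          class = "mrkit_empty_set_error")
  }

  j <- idx[keep]
  h <- tibble(
    rsid = ex$rsid[keep],
    beta_exp = ex$beta[keep],
    se_exp = ex$se[keep],
    beta_out = ifelse(flip[keep], -ou$beta[j], ou$beta[j]),
    se_out = ou$se[j],
    eaf_exp = if ("eaf" %in% names(ex)) ex$eaf[keep] else NA_real_
  )
  structure(h,
            class = c("mr_harmonised", class(tibble())),
            exposure_label = exp_lab,
            outcome_label = out_lab,
            outcome_type = out_type,
            palindrome_eaf_window = palindrome_eaf_window,
            dropped = dropped)
}

#' @export
print.mr_harmonised <- function(x, ...) {
  cat("<mr_harmonised> ", attr(x, "exposure_label"), " -> ",
      attr(x, "outcome_label"), ": ", nrow(x), " SNPs retained, ",
      nrow(attr(x, "dropped")), " dropped\n", sep = "")
  NextMethod()
}
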