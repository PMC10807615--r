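#' @importFrom rlang .data abort warn %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm qnorm pchisq pt rnorm runif rbinom approx setNames
#' @importFrom utils head
NULL

# canonical column roles; rsid/effect_allele/other_allele/beta/se are mandatory
.ss_roles <- c("rsid", "effect_allele", "other_allele", "eaf", "beta", "se",
               "pval", "n_total", "n_cases", "chr", "pos")
.ss_mandatory <- c("rsid", "effect_allele", "other_allele", "beta", "se")
.ss_numeric <- c("eaf", "beta", "se", "pval", "n_total", "n_cases", "pos")

#' Construct a validated GWAS summary-statistics table
#'
#' Builds a `mr_sumstats` tibble (one row per SNP) from any data frame holding
#' per-variant association summaries. Rows violating the record invariants
#' (non-positive standard error, allele strings outside `ACGT`, frequencies
#' outside (0, 1), p-values outside (0, 1], `n_cases > n_total`) are removed
#' and logged in the `rejected` attribute with a per-row reason.
#'
#' @param data Data frame with at least columns `rsid`, `effect_allele`,
#'   `other_allele`, `beta`, `se`; optionally `eaf`, `pval`, `n_total`,
#'   `n_cases`, `chr`, `pos`.
#' @param trait_label Short name of the trait (e.g. `"television watching"`).
#' @param trait_type `"continuous"` (beta per SD) or `"binary"` (beta on the
#'   log-odds scale).
#' @param sd_units Optional human-readable SD unit, e.g. `"1.5 h/day"`.
#' @param fail_fast If `TRUE`, the first invalid row raises an error instead
#'   of being rejected.
#' @param on_duplicate `"error"` (default) raises a validation error listing
#'   duplicated rsids; `"keep_min_se"` keeps the record with the smallest
#'   standard error and rejects the others.
#' @return A tibble of class `mr_sumstats` with attributes `trait_label`,
#'   `trait_type`, `sd_units` and `rejected` (a tibble `row`/`rsid`/`reason`).
#' @export
sumstats <- function(data, trait_label, trait_type = c("continuous", "binary"),
                     sd_units = NULL, fail_fast = FALSE,
                     on_duplicate = c("error", "keep_min_se")) {
  trait_type <- match.arg(trait_type)
  on_duplicate <- match.arg(on_duplicate)
  stopifnot(is.data.frame(data))
  data <- as_tibble(data)

  missing_cols <- setdiff(.ss_mandatory, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrkit_config_error")
  }
  keep <- intersect(.ss_roles, names(data))
  data <- data[keep]
  for (col in setdiff(.ss_roles, c(keep))) {
    if (col %in% c("eaf", "pval", "n_total", "n_cases")) data[[col]] <- NA_real_
  }

  data$rsid <- as.character(data$rsid)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))

  n <- nrow(data)
  reasons <- character(n)
  note <- function(i, msg) {
    if (fail_fast) abort(paste0("row ", i, " (", data$rsid[i], "): ", msg),
                         class = "mrkit_validation_error")
    reasons[i] <<- if (nzchar(reasons[i])) paste(reasons[i], msg, sep = "; ") else msg
  }

  # numeric coercion: unparseable values become rejections, not NAs
  for (col in intersect(.ss_numeric, names(data))) {
    raw <- data[[col]]
    if (!is.numeric(raw)) {
      chr <- trimws(as.character(raw))
      num <- suppressWarnings(as.numeric(chr))
      bad <- which(!is.na(chr) & nzchar(chr) & is.na(num))
      for (i in bad) note(i, paste0("unparseable ", col))
      data[[col]] <- num
    }
  }

  allele_ok <- function(a) !is.na(a) & grepl("^[ACGT]+$", a)
  checks <- list(
    "missing rsid" = is.na(data$rsid) | !nzchar(data$rsid),
    "invalid effect_allele" = !allele_ok(data$effect_allele),
    "invalid other_allele" = !allele_ok(data$other_allele),
    "missing beta" = is.na(data$beta),
    "missing se" = is.na(data$se),
    "nonpositive se" = !is.na(data$se) & data$se <= 0,
    "eaf outside (0,1)" = !is.na(data$eaf) & (data$eaf <= 0 | data$eaf >= 1),
    "pval outside (0,1]" = !is.na(data$pval) &
      (data$pval <= 0 | data$pval > 1),
    "nonpositive n_total" = !is.na(data$n_total) & data$n_total <= 0,
    "n_cases exceeds n_total" = !is.na(data$n_cases) & !is.na(data$n_total) &
      data$n_cases > data$n_total)
  for (msg in names(checks)) {
    for (i in which(checks[[msg]])) note(i, msg)
  }

  rejected <- tibble(row = which(nzchar(reasons)),
                     rsid = data$rsid[nzchar(reasons)],
                     reason = reasons[nzchar(reasons)])
  data <- data[!nzchar(reasons), , drop = FALSE]

  dup <- unique(data$rsid[duplicated(data$rsid)])
  if (length(dup) > 0) {
    if (on_duplicate == "error") {
      abort(paste0("duplicate rsid(s): ", paste(head(dup, 10), collapse = ", ")),
            class = "mrkit_validation_error")
    }
    drop_idx <- integer(0)
    for (d in dup) {
      idx <- which(data$rsid == d)
      keep_one <- idx[which.min(data$se[idx])]
      drop_idx <- c(drop_idx, setdiff(idx, keep_one))
    }
    rejected <- dplyr::bind_rows(rejected,
      tibble(row = drop_idx, rsid = data$rsid[drop_idx],
             reason = "duplicate (kept record with smallest se)"))
    data <- data[-drop_idx, , drop = FALSE]
  }

  structure(data,
            class = c("mr_sumstats", class(tibble())),
            trait_label = trait_label,
            trait_type = trait_type,
            sd_units = sd_units,
            rejected = rejected)
}

#' @export
print.mr_sumstats <- function(x, ...) {
  cat("<mr_sumstats> ", attr(x, "trait_label"), " (", attr(x, "trait_type"),
      if (!is.null(attr(x, "sd_units"))) paste0(", SD = ", attr(x, "sd_units")),
      "): ", nrow(x), " SNPs, ", nrow(attr(x, "rejected")), " rejected\n", sep = "")
  NextMethod()
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a TSV/CSV with one header row and one row per SNP, applies an
#' optional column mapping onto the canonical roles, and validates via
#' [sumstats()].
#'
#' @param path File path.
#' @param column_map Named character vector mapping roles to file column
#'   names, e.g. `c(rsid = "SNP", beta = "b")`. Unmapped roles use the
#'   canonical names (`rsid`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#'   `se`, `pval`, `n_total`, `n_cases`, optionally `chr`, `pos`).
#' @param delim Field delimiter; default inferred from the extension
#'   (`.csv` is comma, everything else tab).
#' @inheritParams sumstats
#' @return A validated `mr_sumstats` tibble.
#' @export
read_sumstats <- function(path, trait_label, trait_type = c("continuous", "binary"),
                          sd_units = NULL, column_map = NULL, delim = NULL,
                          fail_fast = FALSE,
                          on_duplicate = c("error", "keep_min_se")) {
  if (!file.exists(path)) abort(paste0("file not found: ", path),
                                class = "mrkit_io_error")
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(
    .default = readr::col_character()), na = c("", "NA"),
    show_col_types = FALSE, progress = FALSE)

  if (!is.null(column_map)) {
    bad_roles <- setdiff(names(column_map), .ss_roles)
    if (length(bad_roles) > 0)
      abort(paste0("unknown role(s) in column_map: ",
                   paste(bad_roles, collapse = ", ")),
            class = "mrkit_config_error")
    for (role in names(column_map)) {
      src <- column_map[[role]]
      if (!src %in% names(raw))
        abort(paste0("column_map assigns role '", role, "' to missing column '",
                     src, "'"), class = "mrkit_config_error")
      names(raw)[names(raw) == src] <- role
    }
  }
  missing_cols <- setdiff(.ss_mandatory, names(raw))
  if (length(missing_cols) > 0)
    abort(paste0("file lacks column(s) for mandatory role(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "mrkit_config_error")
  sumstats(raw, trait_label = trait_label, trait_type = trait_type,
           sd_units = sd_units, fail_fast = fail_fast,
           on_duplicate = on_duplicate)
}

#' Write a summary-statistics table to delimited text
#'
#' Emits a file re-readable by [read_sumstats()] with the default column map.
#' Numeric fields are written with 17 significant digits so the round trip is
#' value-exact; missing optional values are written as empty cells. The output
#' is byte-identical for identical inputs.
#'
#' @param table An `mr_sumstats` tibble (or plain data frame with the same
#'   columns).
#' @param path Output file path.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(table, path, delim = "\t") {
  out <- as_tibble(as.data.frame(table))
  cols <- intersect(.ss_roles, names(out))
  out <- out[cols]
  for (col in intersect(.ss_numeric, names(out))) {
    v <- out[[col]]
    out[[col]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  ok <- tryCatch({
    readr::write_delim(out, path, delim = delim, na = "", progress = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) abort(paste0("cannot write ", path, ": ",
                                conditionMessage(ok)),
                         class = "mrkit_io_error")
  invisible(path)
}
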