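# Orchestration: the full univariable sensitivity suite per exposure-outcome
# pair, multivariable adjustment reports, bidirectional analyses, subgroup
# meta-analysis, and tidy serialisation. Failures are isolated per analysis
# cell: methods that cannot run produce an explicit "not run" row and the
# run continues.

.suite_row <- function(exposure, outcome, method, est = NULL, note = NA_character_,
                       extra = list()) {
  base <- tibble(exposure = exposure, outcome = outcome, method = method,
                 beta = NA_real_, se = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, pval = NA_real_, or = NA_real_,
                 or_low = NA_real_, or_high = NA_real_, k = NA_integer_,
                 Q = NA_real_, Q_pval = NA_real_, I2 = NA_real_,
                 egger_intercept = NA_real_, egger_intercept_pval = NA_real_,
                 n_outliers = NA_integer_, seed = NA_integer_,
                 note = note)
  if (!is.null(est)) {
    base$beta <- est$beta; base$se <- est$se
    base$ci_low <- est$ci_low; base$ci_high <- est$ci_high
    base$pval <- est$pval; base$k <- as.integer(est$k)
    base$or <- est$or; base$or_low <- est$or_low; base$or_high <- est$or_high
  }
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

#' Univariable MR sensitivity suite for one harmonised pair
#'
#' Runs IVW (with Cochran's Q and I2), MR-Egger (slope and intercept test),
#' the weighted median and MR-PRESSO on one harmonised set, returning one
#' tidy row per method. Methods whose instrument-count preconditions fail
#' are reported as explicit "not run" rows rather than being silently
#' omitted.
#'
#' @param h An `mr_harmonised` set.
#' @param model IVW model (default `"auto"`).
#' @param n_boot Weighted-median bootstrap resamples.
#' @param presso_nsim,presso_sig MR-PRESSO simulation depth and outlier
#'   significance level.
#' @param seed Integer seed used for the weighted-median bootstrap and
#'   MR-PRESSO.
#' @return A tibble, one row per method, with effect, CI, p, OR view, k,
#'   heterogeneity and pleiotropy diagnostics, seed, and a `note` column.
#' @export
mr_suite <- function(h, model = "auto", n_boot = 1000,
                     presso_nsim = 1000, presso_sig = 0.05, seed = 1) {
  exl <- attr(h, "exposure_label") %||% "exposure"
  oul <- attr(h, "outcome_label") %||% "outcome"
  k <- nrow(h)
  rows <- list()

  ivw <- mr_ivw(h, model = model)
  rows$ivw <- .suite_row(exl, oul, ivw$method, ivw,
                         extra = list(Q = ivw$Q, Q_pval = ivw$Q_pval,
                                      I2 = ivw$I2))
  if (k >= 3) {
    eg <- mr_egger(h)
    rows$egger <- .suite_row(exl, oul, "egger_slope", eg,
      extra = list(egger_intercept = eg$intercept,
                   egger_intercept_pval = eg$intercept_pval))
    wm <- mr_weighted_median(h, n_boot = n_boot, seed = seed)
    rows$wm <- .suite_row(exl, oul, "weighted_median", wm,
                          extra = list(seed = as.integer(seed)))
  } else {
    rows$egger <- .suite_row(exl, oul, "egger_slope",
                             note = "not run: fewer than 3 instruments")
    rows$wm <- .suite_row(exl, oul, "weighted_median",
                          note = "not run: fewer than 3 instruments")
  }
  if (k >= 4) {
    pr <- tryCatch(mr_presso(h, n_sim = presso_nsim, sig = presso_sig,
                             seed = seed, model = model),
                   error = function(e) e)
    if (inherits(pr, "error")) {
      rows$presso <- .suite_row(exl, oul, "presso_corrected",
                                note = paste0("not run: ", conditionMessage(pr)))
    } else {
      est <- pr$corrected %||% pr$raw
      rows$presso <- .suite_row(exl, oul, "presso_corrected", est,
        extra = list(n_outliers = length(pr$outlier_rsids),
                     Q_pval = pr$global_p, seed = as.integer(seed),
                     note = if (is.null(pr$corrected))
                       "no outliers; raw IVW reported" else NA_character_))
    }
  } else {
    rows$presso <- .suite_row(exl, oul, "presso_corrected",
                              note = "not run: fewer than 4 instruments")
  }
  dplyr::bind_rows(rows)
}

.resolve_table <- function(spec, default_type = "continuous") {
  if (is.data.frame(spec$data %||% spec)) {
    tb <- spec$data %||% spec
    if (!inherits(tb, "mr_sumstats")) {
      tb <- sumstats(tb, trait_label = spec$label %||% "trait",
                     trait_type = spec$type %||% default_type,
                     sd_units = spec$sd_units)
    } else if (!is.null(spec$label)) {
      attr(tb, "trait_label") <- spec$label
    }
    return(tb)
  }
  if (!is.null(spec$path))
    return(read_sumstats(spec$path, trait_label = spec$label %||% "trait",
                         trait_type = spec$type %||% default_type,
                         sd_units = spec$sd_units,
                         column_map = spec$column_map))
  abort(paste0("trait '", spec$label %||% "?",
               "' has neither in-memory data nor a path"),
        class = "mrkit_config_error")
}

#' Read an analysis configuration
#'
#' A configuration is a list (or a YAML file holding one) with elements
#' `exposures`, `outcomes`, optionally `covariables` (each a list of
#' `label`/`path`-or-`data`/`type`/`sd_units`/`n_total`/`n_cases`/
#' `subgroup_of` entries) and `settings` (`model`, `n_boot`, `presso_nsim`,
#' `presso_sig`, `seed`).
#'
#' @param config A list or a path to a YAML file.
#' @return The validated configuration list, class `mr_config`.
#' @export
mr_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$exposures) || is.null(config$outcomes))
    abort("config needs 'exposures' and 'outcomes'",
          class = "mrkit_config_error")
  labels <- c(vapply(config$exposures, function(x) x$label %||% "", character(1)),
              vapply(config$outcomes, function(x) x$label %||% "", character(1)))
  if (any(!nzchar(labels)) || anyDuplicated(labels))
    abort("every exposure/outcome needs a unique label",
          class = "mrkit_config_error")
  config$settings <- utils::modifyList(
    list(model = "auto", n_boot = 1000, presso_nsim = 1000,
         presso_sig = 0.05, seed = 1, palindrome_eaf_window = 0.08),
    config$settings %||% list())
  structure(config, class = c("mr_config", "list"))
}

#' Run the univariable analysis grid
#'
#' For every exposure-outcome pair in the configuration: harmonise, then run
#' the full sensitivity suite ([mr_suite()]). Pair-level failures are logged
#' as rows with a `note` and the run continues. When outcomes declare
#' `subgroup_of`, a fixed-effect subgroup meta-analysis of the IVW estimates
#' is appended per parent outcome (method `subgroup_meta`, with `Q`/`I2` as
#' the between-group heterogeneity).
#'
#' @param config An [mr_config()] list or YAML path.
#' @return A tidy results tibble, one row per (exposure, outcome, method).
#' @export
run_univariable <- function(config) {
  cfg <- mr_config(config)
  st <- cfg$settings
  rows <- list()
  for (ex in cfg$exposures) {
    ext <- .resolve_table(ex, "continuous")
    for (ou in cfg$outcomes) {
      res <- tryCatch({
        out <- .resolve_table(ou, "binary")
        h <- harmonise(ext, out,
                       palindrome_eaf_window = st$palindrome_eaf_window)
        mr_suite(h, model = st$model, n_boot = st$n_boot,
                 presso_nsim = st$presso_nsim, presso_sig = st$presso_sig,
                 seed = st$seed)
      }, error = function(e)
        .suite_row(ex$label, ou$label, "ivw_fixed",
                   note = paste0("not run: ", conditionMessage(e))))
      rows[[paste(ex$label, ou$label)]] <- res
    }
  }
  res <- dplyr::bind_rows(rows)

  # subgroup heterogeneity per parent outcome
  parents <- unique(unlist(lapply(cfg$outcomes, function(o) o$subgroup_of)))
  for (p in parents) {
    members <- vapply(cfg$outcomes, function(o)
      identical(o$subgroup_of, p), logical(1))
    member_labels <- vapply(cfg$outcomes[members], `[[`, character(1), "label")
    for (ex in cfg$exposures) {
      sub <- res[res$exposure == ex$label & res$outcome %in% member_labels &
                   grepl("^ivw", res$method) & !is.na(res$beta), ]
      if (nrow(sub) < 2) next
      mt <- subgroup_meta(sub[, c("beta", "se")])
      rows_meta <- .suite_row(ex$label, paste0(p, " (subgroups)"),
                              "subgroup_meta",
                              est = list(beta = mt$beta, se = mt$se,
                                         ci_low = mt$beta - .z975() * mt$se,
                                         ci_high = mt$beta + .z975() * mt$se,
                                         pval = mt$pval, k = mt$m,
                                         or = exp(mt$beta),
                                         or_low = exp(mt$beta - .z975() * mt$se),
                                         or_high = exp(mt$beta + .z975() * mt$se)),
                              extra = list(Q = mt$Q_between, Q_pval = mt$p_het,
                                           I2 = mt$I2))
      res <- dplyr::bind_rows(res, rows_meta)
    }
  }
  res
}

#' Run the multivariable adjustment grid
#'
#' For every exposure-outcome-covariable triple: build the joint instrument
#' set, fit the multivariable IVW and the conditional F-statistics, and pair
#' the adjusted estimate with the univariable IVW on the same outcome (the
#' attenuation surface). Under-identified cells are logged and skipped.
#'
#' @param config An [mr_config()] list with a `covariables` element.
#' @param ld Optional squared-correlation matrix for cross-exposure
#'   clumping.
#' @return A tibble, one row per (exposure, outcome, adjusted_for) with
#'   `beta_univariable`, `beta_adjusted` (and ses/CIs/ORs), conditional F
#'   for both variables, `k`, and `note`.
#' @export
run_mvmr <- function(config, ld = NULL) {
  cfg <- mr_config(config)
  if (is.null(cfg$covariables))
    abort("config has no covariables", class = "mrkit_config_error")
  st <- cfg$settings
  rows <- list()
  for (ex in cfg$exposures) {
    ext <- .resolve_table(ex, "continuous")
    for (ou in cfg$outcomes) {
      out <- .resolve_table(ou, "binary")
      uni <- tryCatch(mr_ivw(harmonise(ext, out), model = st$model),
                      error = function(e) NULL)
      for (cv in cfg$covariables) {
        cvt <- .resolve_table(cv, "continuous")
        cell <- tryCatch({
          tabs <- list(ext, cvt)
          names(tabs) <- c(ex$label, cv$label)
          m <- build_mv_set(tabs, out, ld = ld,
                            p_threshold = st$p_threshold %||% 5e-8)
          fit <- mvmr_ivw(m)
          cf <- conditional_f(m)
          est <- fit$estimates[fit$estimates$exposure == ex$label, ]
          tibble(exposure = ex$label, outcome = ou$label,
                 adjusted_for = cv$label,
                 beta_univariable = uni$beta %||% NA_real_,
                 se_univariable = uni$se %||% NA_real_,
                 beta_adjusted = est$beta, se_adjusted = est$se,
                 ci_low_adjusted = est$ci_low, ci_high_adjusted = est$ci_high,
                 pval_adjusted = est$pval,
                 or_adjusted = est$or, or_low_adjusted = est$or_low,
                 or_high_adjusted = est$or_high,
                 conditional_F_exposure =
                   cf$conditional_F[cf$exposure == ex$label],
                 conditional_F_covariable =
                   cf$conditional_F[cf$exposure == cv$label],
                 Q_a = fit$Q_a, Q_a_pval = fit$Q_pval,
                 k = fit$k, note = NA_character_)
        }, error = function(e)
          tibble(exposure = ex$label, outcome = ou$label,
                 adjusted_for = cv$label,
                 beta_univariable = uni$beta %||% NA_real_,
                 se_univariable = uni$se %||% NA_real_,
                 beta_adjusted = NA_real_, se_adjusted = NA_real_,
                 ci_low_adjusted = NA_real_, ci_high_adjusted = NA_real_,
                 pval_adjusted = NA_real_, or_adjusted = NA_real_,
                 or_low_adjusted = NA_real_, or_high_adjusted = NA_real_,
                 conditional_F_exposure = NA_real_,
                 conditional_F_covariable = NA_real_,
                 Q_a = NA_real_, Q_a_pval = NA_real_, k = NA_integer_,
                 note = paste0("not run: ", conditionMessage(e))))
        rows[[paste(ex$label, ou$label, cv$label)]] <- cell
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Bidirectional MR between two traits
#'
#' Runs the full univariable suite in both directions: trait A's instruments
#' (p below `p_threshold` in A's table, cross-clumped against B's at
#' `r2_threshold` when an LD matrix is supplied) against B, and vice versa.
#'
#' @param trait_a,trait_b `mr_sumstats` tables with instrument-grade
#'   coverage (each table must contain both traits' instrument SNPs).
#' @param p_threshold Instrument significance threshold (default 5e-8).
#' @param ld Optional squared-correlation matrix over both traits'
#'   instruments.
#' @param r2_threshold Cross-trait clumping threshold (default 0.001).
#' @param ... Passed to [mr_suite()].
#' @return A tidy tibble with a `direction` column (`"A->B"`, `"B->A"`).
#' @export
run_bidirectional <- function(trait_a, trait_b, p_threshold = 5e-8,
                              ld = NULL, r2_threshold = 0.001, ...) {
  one_way <- function(from, to, tag) {
    inst <- select_instruments(from, p_threshold = p_threshold, ld = ld,
                               r2_threshold = r2_threshold)
    from_sub <- from[from$rsid %in% inst$rsid, , drop = FALSE]
    for (a in c("trait_label", "trait_type", "sd_units"))
      attr(from_sub, a) <- attr(from, a)
    h <- harmonise(from_sub, to)
    out <- mr_suite(h, ...)
    out$direction <- tag
    out
  }
  dplyr::bind_rows(
    one_way(trait_a, trait_b, "A->B"),
    one_way(trait_b, trait_a, "B->A"))
}

#' Write a tidy results table to TSV and JSON
#'
#' @param results A results tibble from [run_univariable()], [run_mvmr()] or
#'   [run_bidirectional()].
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.tsv` and `<prefix>.json`.
#' @return The two paths, invisibly.
#' @export
write_results <- function(results, path_prefix) {
  tsv <- paste0(path_prefix, ".tsv")
  js <- paste0(path_prefix, ".json")
  readr::write_tsv(results, tsv, progress = FALSE)
  jsonlite::write_json(results, js, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(c(tsv = tsv, json = js))
}

#' Re-run the published cancer analyses from supplementary SNP tables
#'
#' Runs the univariable suite for each exposure-outcome pair given a
#' directory of per-pair harmonisable SNP tables (delimited text with the
#' default column map, named `<exposure>__<outcome>.tsv` with the outcome
#' table as `<exposure>__<outcome>__outcome.tsv`, or a single pre-harmonised
#' file per pair with columns `rsid`, `beta_exp`, `se_exp`, `beta_out`,
#' `se_out`). This is the entry point for reproducing published per-SNP
#' analyses whose summary tables ship as article supplements; it performs no
#' downloads.
#'
#' @param dir Directory containing the per-pair SNP tables.
#' @param seed Seed for the stochastic sensitivity methods.
#' @return A tidy results tibble with a `pair` column.
#' @export
reproduce_published_tables <- function(dir, seed = 1) {
  if (!dir.exists(dir))
    abort(paste0("supplementary-table directory not found: ", dir),
          class = "mrkit_io_error")
  files <- list.files(dir, pattern = "\\.(tsv|csv|txt)$", full.names = TRUE)
  files <- files[!grepl("__outcome\\.", files)]
  if (length(files) == 0)
    abort("no SNP tables found", class = "mrkit_io_error")
  rows <- lapply(files, function(f) {
    pair <- sub("\\.[^.]+$", "", basename(f))
    tb <- readr::read_delim(f, show_col_types = FALSE, progress = FALSE)
    if (all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(tb))) {
      h <- structure(as_tibble(tb),
                     class = c("mr_harmonised", class(tibble())),
                     exposure_label = pair, outcome_label = pair,
                     outcome_type = "binary",
                     dropped = tibble(rsid = character(0),
                                      reason = character(0)))
    } else {
      of <- file.path(dir, paste0(pair, "__outcome.tsv"))
      ex <- sumstats(tb, trait_label = pair, trait_type = "continuous")
      ot <- read_sumstats(of, trait_label = pair, trait_type = "binary")
      h <- harmonise(ex, ot)
    }
    out <- mr_suite(h, seed = seed)
    out$pair <- pair
    out
  })
  dplyr::bind_rows(rows)
}
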