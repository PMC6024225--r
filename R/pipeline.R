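#' Flag a p-value against nominal and multiplicity-corrected thresholds
#'
#' Mirrors the reporting convention of MR studies that test several outcome
#' families: `"corrected"` when p < alpha / n_families, `"nominal"` when
#' p < alpha but not after correction, `"none"` otherwise.
#'
#' @param p p-value.
#' @param alpha nominal significance level (default 0.05).
#' @param n_families number of outcome families the correction spans
#'   (default 7).
#' @return one of `"none"`, `"nominal"`, `"corrected"`.
#' @export
flag_significance <- function(p, alpha = 0.05, n_families = 7) {
  stopifnot(p >= 0, p <= 1, n_families >= 1)
  threshold <- bonferroni_threshold(alpha, n_families)
  if (p < threshold) "corrected" else if (p < alpha) "nominal" else "none"
}

.load_dataset <- function(x, default_scale = "continuous_sd") {
  if (inherits(x, "summary_dataset")) return(x)
  if (is.character(x)) {
    return(read_summary_tsv(x, trait_scale = default_scale))
  }
  if (is.list(x)) {
    if (inherits(x$data, "summary_dataset")) {
      ds <- x$data
      # re-tag metadata if the entry overrides it
      return(summary_dataset(as.data.frame(ds),
                             trait_name = x$name %||% attr(ds, "trait_name"),
                             trait_scale = x$trait_scale %||% attr(ds, "trait_scale"),
                             sex_stratum = x$sex_stratum %||% attr(ds, "sex_stratum")))
    }
    return(read_summary_tsv(x$path,
                            trait_scale = x$trait_scale %||% default_scale,
                            sex_stratum = x$sex_stratum %||% "all",
                            trait_name = x$name))
  }
  stop("cannot interpret dataset specification", call. = FALSE)
}

.subset_dataset <- function(ds, ids) {
  summary_dataset(as.data.frame(ds)[match(ids, ds$variant_id), ],
                  trait_name = attr(ds, "trait_name"),
                  trait_scale = attr(ds, "trait_scale"),
                  sex_stratum = attr(ds, "sex_stratum"))
}

# estimate with automatic fallback: plain generalized IVW, switching to the
# principal-components estimator when the weight covariance trips the
# condition-number gate
.estimate_auto <- function(hs, estimator, pc_variance) {
  if (estimator == "ivw_correlated") return(ivw_correlated(hs))
  if (estimator == "pc_ivw") return(pc_ivw(hs, variance_kept = pc_variance))
  tryCatch(ivw_correlated(hs), error = function(e) {
    if (grepl("near-singular", conditionMessage(e)) &&
        length(hs$variant_ids) >= 2) {
      est <- pc_ivw(hs, variance_kept = pc_variance)
      message(sprintf(
        "estimator auto: weight covariance near-singular; fell back to pc_ivw (k = %d)",
        est$pc_k))
      est
    } else {
      stop(e)
    }
  })
}

#' Read an analysis configuration from YAML
#'
#' @param path YAML file whose keys mirror the `config` argument of
#'   [run_analysis()].
#' @return a configuration list.
#' @export
read_analysis_config <- function(path) {
  yaml::read_yaml(path)
}

#' Run the full correlated-instrument MR analysis
#'
#' For each outcome dataset: QC filters on the exposure side (optional),
#' harmonization against the exposure and LD matrix, instrument selection
#' (stepwise r-squared pruning or a fixed conditional list, re-selected
#' independently per outcome since the variants available differ between
#' datasets), estimation (generalized IVW with automatic fallback to the
#' principal-components estimator when the weight matrix is near-singular),
#' odds-ratio conversion for log-odds outcomes, and significance flagging
#' against both the nominal level and the multiplicity-corrected threshold.
#' Cohorts named in `combine` are additionally pooled by fixed-effect
#' meta-analysis per outcome/stratum. A failure in one outcome produces a
#' failure row and leaves the others untouched. Identical inputs give
#' identical output.
#'
#' @param config a list (or the result of [read_analysis_config()]) with
#'   elements:
#'   \describe{
#'     \item{exposure}{path, `summary_dataset`, or list with `path`/`data`,
#'       `trait_scale`, `sex_stratum`.}
#'     \item{outcomes}{list of outcome entries in the same forms, each
#'       optionally carrying `cohort` and `name` labels.}
#'     \item{ld}{path or `ld_matrix`.}
#'     \item{region}{gene-region label (default `"region"`).}
#'     \item{selection}{list with `method` (`"stepwise"` or
#'       `"conditional_list"`), `r2_max` (default 0.4), `variant_list`.}
#'     \item{qc}{optional list with `counts`, `call_rates` and threshold
#'       overrides for [apply_qc_filters()].}
#'     \item{confounders}{optional confounder p-value data frame for
#'       [confounder_filter()].}
#'     \item{pc_variance}{variance kept by [pc_ivw()] (default 0.99).}
#'     \item{estimator}{`"auto"` (default), `"ivw_correlated"`, `"pc_ivw"`.}
#'     \item{alpha}{nominal level (default 0.05).}
#'     \item{n_outcome_families}{Bonferroni family count (default 7).}
#'     \item{combine}{optional character vector of cohort labels to pool.}
#'     \item{palindromic_eaf_band}{passed to [harmonize()] (default 0.08).}
#'   }
#' @return a data frame of report rows (one per outcome, plus pooled rows),
#'   with the per-variant decision log in attribute `"log"`.
#' @export
run_analysis <- function(config) {
  exposure <- .load_dataset(config$exposure, default_scale = "log_transformed")
  ld <- if (is.character(config$ld)) read_ld_matrix(config$ld) else config$ld
  region <- config$region %||% "region"
  sel <- config$selection %||% list(method = "stepwise")
  sel$method <- sel$method %||% "stepwise"
  alpha <- config$alpha %||% 0.05
  n_fam <- config$n_outcome_families %||% 7
  pc_variance <- config$pc_variance %||% 0.99
  estimator <- config$estimator %||% "auto"
  band <- config$palindromic_eaf_band %||% 0.08
  log <- list()

  if (!is.null(config$qc)) {
    qc <- config$qc
    rep_qc <- apply_qc_filters(exposure, counts = qc$counts,
                               call_rates = qc$call_rates,
                               maf_min = qc$maf_min %||% 0.01,
                               call_rate_min = qc$call_rate_min %||% 0.95,
                               hwe_p_min = qc$hwe_p_min %||% 0.001,
                               info_min = qc$info_min %||% 0.6)
    if (nrow(rep_qc$dropped) > 0) {
      log[[length(log) + 1]] <- cbind(stage = "qc", rep_qc$dropped)
    }
    if (length(rep_qc$kept) == 0) stop("QC removed every exposure variant",
                                       call. = FALSE)
    exposure <- .subset_dataset(exposure, rep_qc$kept)
  }
  if (!is.null(config$confounders)) {
    rep_cf <- confounder_filter(exposure, config$confounders, alpha = alpha)
    if (nrow(rep_cf$dropped) > 0) {
      log[[length(log) + 1]] <- cbind(stage = "confounder", rep_cf$dropped)
    }
    if (length(rep_cf$kept) == 0) stop("confounder filter removed every variant",
                                       call. = FALSE)
    exposure <- .subset_dataset(exposure, rep_cf$kept)
  }

  rows <- list()
  ests <- list()
  for (oc in config$outcomes) {
    outcome_label <- NULL
    cohort <- if (is.list(oc)) oc$cohort %||% "cohort1" else "cohort1"
    row <- tryCatch({
      ds <- .load_dataset(oc)
      outcome_label <- attr(ds, "trait_name")
      stratum <- attr(ds, "sex_stratum")
      scale <- attr(ds, "trait_scale")
      h <- harmonize(exposure, ds, ld, palindromic_eaf_band = band)
      if (!is.null(h$log) && nrow(h$log) > 0) {
        log[[length(log) + 1]] <- cbind(stage = paste0("harmonize:", outcome_label),
                                        h$log)
      }
      ids <- switch(sel$method,
        stepwise = stepwise_select(h, sel$r2_max %||% 0.4),
        conditional_list = conditional_select(h, sel$variant_list),
        stop("unknown selection method: ", sel$method, call. = FALSE))
      hs <- subset_harmonized(h, ids)
      est <- .estimate_auto(hs, estimator, pc_variance)
      ests[[length(ests) + 1]] <- list(outcome = outcome_label,
                                       stratum = stratum, cohort = cohort,
                                       scale = scale, est = est)
      orr <- if (identical(scale, "log_odds")) to_odds_ratio(est)
             else list(or_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      data.frame(outcome = outcome_label, stratum = stratum, cohort = cohort,
                 region = region, method = est$method,
                 n_variants = est$n_variants, estimate = est$theta,
                 se = est$se_theta, pvalue = est$pvalue,
                 or = orr$or_point, ci_low = orr$ci_low, ci_high = orr$ci_high,
                 significance = flag_significance(est$pvalue, alpha, n_fam),
                 status = "ok", error = "", stringsAsFactors = FALSE)
    }, error = function(e) {
      lbl <- outcome_label %||%
        (if (is.list(oc)) oc$name %||% "outcome" else as.character(oc))
      data.frame(outcome = lbl, stratum = NA_character_, cohort = cohort,
                 region = region, method = NA_character_,
                 n_variants = NA_integer_, estimate = NA_real_, se = NA_real_,
                 pvalue = NA_real_, or = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, significance = NA_character_,
                 status = "failed", error = conditionMessage(e),
                 stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1]] <- row
  }

  if (!is.null(config$combine) && length(ests) > 0) {
    keys <- vapply(ests, function(e) paste(e$outcome, e$stratum, sep = "\r"),
                   character(1))
    in_pool <- vapply(ests, function(e) e$cohort %in% config$combine, logical(1))
    for (key in unique(keys[in_pool])) {
      grp <- ests[keys == key & in_pool]
      if (length(grp) < 2) next
      pooled <- meta_fixed_effect(lapply(grp, `[[`, "est"))
      scale <- grp[[1]]$scale
      orr <- if (identical(scale, "log_odds")) to_odds_ratio(pooled)
             else list(or_point = NA_real_, ci_low = NA_real_, ci_high = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = grp[[1]]$outcome, stratum = grp[[1]]$stratum,
        cohort = paste(vapply(grp, `[[`, character(1), "cohort"),
                       collapse = "+"),
        region = region, method = "fixed_effect",
        n_variants = pooled$n_variants, estimate = pooled$theta,
        se = pooled$se_theta, pvalue = pooled$pvalue,
        or = orr$or_point, ci_low = orr$ci_low, ci_high = orr$ci_high,
        significance = flag_significance(pooled$pvalue, alpha, n_fam),
        status = "ok", error = "", stringsAsFactors = FALSE)
    }
  }

  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  attr(report, "log") <- if (length(log) > 0) do.call(rbind, log) else
    data.frame(stage = character(0), variant_id = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  report
}

#' Write an analysis report as TSV
#'
#' Numeric columns are printed with 17 significant digits so identical
#' analyses produce byte-identical files.
#'
#' @param report the data frame returned by [run_analysis()].
#' @param path output file.
#' @export
write_report <- function(report, path) {
  out <- report
  for (col in c("estimate", "se", "pvalue", "or", "ci_low", "ci_high")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "NA", sprintf("%.17g", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
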