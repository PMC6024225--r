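#' Hardy-Weinberg equilibrium chi-square test
#'
#' One-degree-of-freedom chi-square goodness-of-fit of observed genotype
#' counts against the expectation under the estimated allele frequency
#' p-hat = (2 n_AA + n_Aa) / (2 N). When any expected genotype class is zero
#' (a monomorphic variant) the test is undefined and the p-value is 1.
#'
#' @param n_AA,n_Aa,n_aa non-negative genotype counts.
#' @return two-sided p-value.
#' @export
hwe_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (any(counts < 0)) stop("negative genotype counts", call. = FALSE)
  n <- sum(counts)
  if (n == 0) stop("no genotype observations", call. = FALSE)
  p <- (2 * n_AA + n_Aa) / (2 * n)
  expected <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  if (any(expected == 0)) return(1.0)
  chisq <- sum((counts - expected)^2 / expected)
  stats::pchisq(chisq, df = 1, lower.tail = FALSE)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate, in (0,1).
#' @param n_tests number of tests or outcome families.
#' @return `alpha / n_tests`.
#' @export
bonferroni_threshold <- function(alpha, n_tests) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0,1)", call. = FALSE)
  }
  if (n_tests < 1) stop("n_tests must be >= 1", call. = FALSE)
  alpha / n_tests
}

qc_report <- function(kept, dropped) {
  if (is.null(dropped) || nrow(dropped) == 0) {
    dropped <- data.frame(variant_id = character(0), reason = character(0),
                          stringsAsFactors = FALSE)
  }
  structure(list(kept = kept, dropped = dropped), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d kept, %d dropped\n",
              length(x$kept), nrow(x$dropped)))
  if (nrow(x$dropped) > 0) print(x$dropped)
  invisible(x)
}

#' Write a QC report as TSV
#'
#' @param report a `qc_report`.
#' @param path output file.
#' @export
write_qc_report <- function(report, path) {
  out <- rbind(
    data.frame(variant_id = report$kept, status = "kept", reason = "",
               stringsAsFactors = FALSE),
    data.frame(variant_id = report$dropped$variant_id, status = "dropped",
               reason = report$dropped$reason, stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Variant-validity filters for GWAS summary statistics
#'
#' Drops variants failing minor allele frequency, call rate, Hardy-Weinberg
#' equilibrium, or imputation quality thresholds. Each criterion is applied
#' only where its input is available: MAF needs `eaf`, the HWE test needs
#' genotype counts, the call-rate filter needs per-variant call rates, and
#' the info filter uses the dataset's `info` column — a missing info score is
#' treated as 1 (directly genotyped) with a warning, so typed variants are
#' never silently dropped by the imputation filter. Thresholds are strict
#' (`<`), so boundary values survive. When a variant fails several criteria
#' the recorded reason is the first failure in the fixed order
#' maf, call_rate, hwe, info.
#'
#' @param dataset a `summary_dataset`.
#' @param counts optional data frame (`variant_id`, `n_AA`, `n_Aa`, `n_aa`).
#' @param call_rates optional named numeric vector of per-variant call rates.
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param call_rate_min minimum call rate (default 0.95).
#' @param hwe_p_min minimum HWE p-value (default 0.001).
#' @param info_min minimum imputation info score (default 0.6).
#' @return a `qc_report`.
#' @export
apply_qc_filters <- function(dataset, counts = NULL, call_rates = NULL,
                             maf_min = 0.01, call_rate_min = 0.95,
                             hwe_p_min = 0.001, info_min = 0.6) {
  stopifnot(inherits(dataset, "summary_dataset"), nrow(dataset) > 0)
  ids <- dataset$variant_id

  hwe_p <- rep(NA_real_, length(ids))
  if (!is.null(counts)) {
    idx <- match(ids, counts$variant_id)
    ok <- !is.na(idx)
    hwe_p[ok] <- vapply(idx[ok], function(j) {
      hwe_test(counts$n_AA[j], counts$n_Aa[j], counts$n_aa[j])
    }, numeric(1))
  }
  cr <- rep(NA_real_, length(ids))
  if (!is.null(call_rates)) cr <- unname(call_rates[ids])

  info <- dataset$info
  if (any(is.na(info))) {
    warning("info score missing for ",
            sum(is.na(info)), " variant(s); treating as 1.0 (genotyped)",
            call. = FALSE)
    info[is.na(info)] <- 1.0
  }

  maf <- pmin(dataset$eaf, 1 - dataset$eaf)
  reasons <- character(length(ids))
  skipped <- character(0)
  for (i in seq_along(ids)) {
    if (is.na(maf[i])) skipped <- c(skipped, paste0(ids[i], ":maf"))
    if (!is.na(maf[i]) && maf[i] < maf_min) { reasons[i] <- "maf"; next }
    if (is.null(call_rates)) {
      # criterion not supplied at all: skip silently
    } else if (is.na(cr[i])) {
      skipped <- c(skipped, paste0(ids[i], ":call_rate"))
    } else if (cr[i] < call_rate_min) { reasons[i] <- "call_rate"; next }
    if (is.null(counts)) {
    } else if (is.na(hwe_p[i])) {
      skipped <- c(skipped, paste0(ids[i], ":hwe"))
    } else if (hwe_p[i] < hwe_p_min) { reasons[i] <- "hwe"; next }
    if (info[i] < info_min) { reasons[i] <- "info"; next }
  }
  if (length(skipped) > 0) {
    warning("criteria skipped for lack of input: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  drop <- reasons != ""
  if (all(drop)) message("apply_qc_filters: no variants pass QC")
  qc_report(ids[!drop],
            data.frame(variant_id = ids[drop], reason = reasons[drop],
                       stringsAsFactors = FALSE))
}

#' Exclude variants associated with confounder traits
#'
#' Screens instruments against a table of per-variant association p-values
#' with potential confounders (e.g. education, Townsend deprivation index,
#' alcohol, smoking) and drops any variant associated with any confounder
#' below the Bonferroni threshold alpha / (n_variants x n_confounders).
#' The comparison is strict, so a p-value exactly at the threshold survives.
#'
#' @param dataset a `summary_dataset`.
#' @param confounders data frame with a `variant_id` column and one p-value
#'   column per confounder trait.
#' @param alpha family-wise error rate (default 0.05).
#' @return a `qc_report`; drop reasons name the offending confounder.
#' @export
confounder_filter <- function(dataset, confounders, alpha = 0.05) {
  stopifnot(inherits(dataset, "summary_dataset"),
            is.data.frame(confounders), "variant_id" %in% names(confounders))
  traits <- setdiff(names(confounders), "variant_id")
  if (length(traits) == 0) stop("no confounder columns", call. = FALSE)
  ids <- dataset$variant_id
  threshold <- bonferroni_threshold(alpha, length(ids) * length(traits))
  message(sprintf("confounder_filter: Bonferroni threshold %.4g (%d variants x %d traits)",
                  threshold, length(ids), length(traits)))
  idx <- match(ids, confounders$variant_id)
  if (anyNA(idx)) {
    warning("no confounder p-values for variant(s): ",
            paste(ids[is.na(idx)], collapse = ", "), "; skipped",
            call. = FALSE)
  }
  reasons <- character(length(ids))
  for (i in seq_along(ids)) {
    if (is.na(idx[i])) next
    pvals <- as.numeric(confounders[idx[i], traits])
    hit <- which(!is.na(pvals) & pvals < threshold)
    if (length(hit) > 0) reasons[i] <- traits[hit[1]]
  }
  drop <- reasons != ""
  qc_report(ids[!drop],
            data.frame(variant_id = ids[drop], reason = reasons[drop],
                       stringsAsFactors = FALSE))
}
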