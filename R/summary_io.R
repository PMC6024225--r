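# canonical column order for summary-statistics tables
SUMMARY_COLUMNS <- c("variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pvalue", "n", "info")
MANDATORY_COLUMNS <- c("variant_id", "effect_allele", "other_allele", "beta", "se")

TRAIT_SCALES <- c("continuous_sd", "log_transformed", "log_odds")
SEX_STRATA   <- c("all", "men", "women")

VALID_ALLELES <- c("A", "C", "G", "T")
ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

#' Construct a GWAS summary-statistics dataset
#'
#' A summary dataset is a data frame with one row per variant, holding the
#' marginal association of each variant with a single trait: effect and other
#' alleles, effect size `beta` (per copy of the effect allele; a log odds
#' ratio for binary traits), standard error `se`, and optionally effect-allele
#' frequency `eaf`, p-value, sample size `n` and imputation info score.
#' Trait metadata (name, measurement scale, sex stratum) is carried as
#' attributes so downstream estimates know their scale.
#'
#' @param df data frame containing at least `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `se`; the optional columns `chrom`, `pos`,
#'   `eaf`, `pvalue`, `n`, `info` are kept when present and filled with `NA`
#'   otherwise.
#' @param trait_name label for the trait.
#' @param trait_scale one of `"continuous_sd"`, `"log_transformed"`,
#'   `"log_odds"`.
#' @param sex_stratum one of `"all"`, `"men"`, `"women"`.
#' @return a `summary_dataset` (a data frame with trait attributes).
#' @export
summary_dataset <- function(df, trait_name = "trait",
                            trait_scale = c("continuous_sd", "log_transformed", "log_odds"),
                            sex_stratum = c("all", "men", "women")) {
  trait_scale <- match.arg(trait_scale)
  sex_stratum <- match.arg(sex_stratum)
  stopifnot(is.data.frame(df))

  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in setdiff(SUMMARY_COLUMNS, names(df))) df[[col]] <- NA
  df <- df[, SUMMARY_COLUMNS]

  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("eaf", "beta", "se", "pvalue", "info")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  }
  df$n <- suppressWarnings(as.numeric(df$n))

  if (anyDuplicated(df$variant_id)) {
    stop("duplicate variant_id: ",
         paste(unique(df$variant_id[duplicated(df$variant_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_se <- is.na(df$se) | df$se <= 0
  if (any(bad_se)) {
    stop("non-positive or missing se for variant(s): ",
         paste(df$variant_id[bad_se], collapse = ", "), call. = FALSE)
  }
  bad_allele <- !(df$effect_allele %in% VALID_ALLELES) |
    !(df$other_allele %in% VALID_ALLELES) |
    df$effect_allele == df$other_allele
  if (any(bad_allele)) {
    stop("invalid allele pair for variant(s): ",
         paste(df$variant_id[bad_allele], collapse = ", "), call. = FALSE)
  }
  bad_eaf <- !is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)
  if (any(bad_eaf)) {
    stop("eaf outside (0,1) for variant(s): ",
         paste(df$variant_id[bad_eaf], collapse = ", "), call. = FALSE)
  }
  bad_p <- !is.na(df$pvalue) & (df$pvalue <= 0 | df$pvalue > 1)
  if (any(bad_p)) {
    stop("pvalue outside (0,1] for variant(s): ",
         paste(df$variant_id[bad_p], collapse = ", "), call. = FALSE)
  }

  # published tables round, so a p-value that disagrees with |beta/se| is a
  # warning, never an error
  has_p <- !is.na(df$pvalue) & !is.na(df$beta)
  if (any(has_p)) {
    p_calc <- 2 * stats::pnorm(-abs(df$beta[has_p] / df$se[has_p]))
    inconsistent <- abs(df$pvalue[has_p] - p_calc) > 0.01 &
      pmax(df$pvalue[has_p], p_calc) / pmax(pmin(df$pvalue[has_p], p_calc), 1e-300) > 2
    if (any(inconsistent)) {
      warning("pvalue inconsistent with |beta/se| for variant(s): ",
              paste(df$variant_id[has_p][inconsistent], collapse = ", "),
              call. = FALSE)
    }
  }

  rownames(df) <- NULL
  structure(df,
            trait_name = trait_name,
            trait_scale = trait_scale,
            sex_stratum = sex_stratum,
            class = c("summary_dataset", "data.frame"))
}

#' @export
print.summary_dataset <- function(x, ...) {
  cat(sprintf("GWAS summary dataset: %s (%s, %s), %d variant(s)\n",
              attr(x, "trait_name"), attr(x, "trait_scale"),
              attr(x, "sex_stratum"), nrow(x)))
  print(as.data.frame(utils::head(x, 10)))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Read a GWAS summary-statistics TSV
#'
#' The expected dialect is tab-separated with a header row; column names are
#' matched case-insensitively against `variant_id`, `chrom`, `pos`,
#' `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`,
#' `info`. Missing values are written and read as `"NA"`. Row order is
#' preserved. Unparseable entries in optional numeric columns become `NA`.
#'
#' @param path file to read.
#' @param trait_scale,sex_stratum trait metadata, see [summary_dataset()].
#' @param trait_name label; defaults to the file name without extension.
#' @return a `summary_dataset`.
#' @export
read_summary_tsv <- function(path,
                             trait_scale = c("continuous_sd", "log_transformed", "log_odds"),
                             sex_stratum = c("all", "men", "women"),
                             trait_name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(trait_name)) trait_name <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  names(raw) <- tolower(names(raw))
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols) > 0L) {
    stop("summary TSV ", path, " lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  summary_dataset(raw[, intersect(SUMMARY_COLUMNS, names(raw))],
                  trait_name = trait_name,
                  trait_scale = match.arg(trait_scale),
                  sex_stratum = match.arg(sex_stratum))
}

# format doubles so they survive a write/read round trip bit-for-bit
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, character(1))
  out
}

#' Write a GWAS summary-statistics TSV
#'
#' Emits the canonical column set (see [read_summary_tsv()]) with `"NA"` for
#' missing values. Numeric fields are printed with enough digits that
#' reading the file back reproduces the dataset exactly.
#'
#' @param dataset a `summary_dataset`.
#' @param path output file.
#' @export
write_summary_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "summary_dataset"), nrow(dataset) > 0)
  out <- data.frame(
    variant_id = dataset$variant_id,
    chrom = ifelse(is.na(dataset$chrom), "NA", dataset$chrom),
    pos = ifelse(is.na(dataset$pos), "NA", as.character(dataset$pos)),
    effect_allele = dataset$effect_allele,
    other_allele = dataset$other_allele,
    eaf = .fmt_num(dataset$eaf),
    beta = .fmt_num(dataset$beta),
    se = .fmt_num(dataset$se),
    pvalue = .fmt_num(dataset$pvalue),
    n = ifelse(is.na(dataset$n), "NA", .fmt_num(dataset$n)),
    info = .fmt_num(dataset$info),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Construct a signed LD correlation matrix
#'
#' Pairwise correlations r between variant dosages; the sign of each r refers
#' to the per-variant reference allele recorded alongside the matrix. The
#' square of r is the familiar LD r-squared.
#'
#' @param r square numeric matrix, symmetric with unit diagonal.
#' @param variant_ids variant identifiers, one per row/column.
#' @param ref_alleles optional named or positional character vector giving the
#'   allele the sign of r is anchored to for each variant.
#' @param other_alleles optional character vector of the alternative alleles.
#' @return an `ld_matrix` (a numeric matrix with attributes).
#' @export
ld_matrix <- function(r, variant_ids = rownames(r), ref_alleles = NULL,
                      other_alleles = NULL) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("LD matrix must be square", call. = FALSE)
  if (is.null(variant_ids)) stop("variant ids required", call. = FALSE)
  variant_ids <- as.character(variant_ids)
  if (length(variant_ids) != nrow(r)) {
    stop("LD matrix dimension does not match number of variant ids",
         call. = FALSE)
  }
  if (max(abs(r - t(r))) > 1e-12) {
    stop("LD matrix not symmetric", call. = FALSE)
  }
  if (max(abs(diag(r) - 1)) > 1e-6) {
    stop("LD matrix diagonal deviates from 1", call. = FALSE)
  }
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 1
  dimnames(r) <- list(variant_ids, variant_ids)
  if (!is.null(ref_alleles)) {
    ref_alleles <- toupper(as.character(ref_alleles))
    stopifnot(length(ref_alleles) == length(variant_ids))
    names(ref_alleles) <- variant_ids
  }
  if (!is.null(other_alleles)) {
    other_alleles <- toupper(as.character(other_alleles))
    stopifnot(length(other_alleles) == length(variant_ids))
    names(other_alleles) <- variant_ids
  }
  structure(r, ref_alleles = ref_alleles, other_alleles = other_alleles,
            class = c("ld_matrix", "matrix", "array"))
}

#' @export
print.ld_matrix <- function(x, ...) {
  cat(sprintf("Signed LD matrix: %d variants\n", nrow(x)))
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x))), drop = FALSE])
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}

# restrict an ld_matrix to a subset of ids, keeping attributes
subset_ld <- function(ld, ids) {
  ref <- attr(ld, "ref_alleles")
  oth <- attr(ld, "other_alleles")
  ld_matrix(unclass(ld)[ids, ids, drop = FALSE], variant_ids = ids,
            ref_alleles = if (!is.null(ref)) ref[ids],
            other_alleles = if (!is.null(oth)) oth[ids])
}

#' Read a signed LD matrix from a TSV file
#'
#' The file carries variant ids in the first row and first column; an
#' optional second header row named `ref_allele` (and optional third row
#' `other_allele`) records the allele each column's sign refers to.
#' Tab- or whitespace-delimited input is accepted. Entries with |r| slightly
#' above 1 are clipped to 1; asymmetry up to 1e-6 is symmetrized as
#' (M + t(M))/2, anything larger is an error, as is a diagonal deviating
#' from 1 by more than 1e-6.
#'
#' @param path file to read.
#' @return an `ld_matrix`.
#' @export
read_ld_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2) stop("LD file too short: ", path, call. = FALSE)
  tok <- strsplit(trimws(lines), "[\t ]+")
  header <- tok[[1]]
  # the corner cell of the header may be a label ("variant_id") or absent
  body_ncol <- length(tok[[2]])
  ids <- if (length(header) == body_ncol) header[-1] else header
  n <- length(ids)

  ref_alleles <- NULL
  other_alleles <- NULL
  row_idx <- 2
  while (row_idx <= length(tok) &&
         tolower(tok[[row_idx]][1]) %in% c("ref_allele", "other_allele")) {
    vals <- toupper(tok[[row_idx]][-1])
    if (length(vals) != n) stop("allele row length mismatch in ", path, call. = FALSE)
    if (tolower(tok[[row_idx]][1]) == "ref_allele") ref_alleles <- vals
    else other_alleles <- vals
    row_idx <- row_idx + 1
  }
  body <- tok[seq(row_idx, length(tok))]
  if (length(body) != n) {
    stop("LD matrix block is not square: ", length(body), " rows for ",
         n, " columns", call. = FALSE)
  }
  row_ids <- vapply(body, `[`, character(1), 1)
  if (!identical(row_ids, ids)) {
    stop("LD row ids do not match column ids", call. = FALSE)
  }
  vals <- lapply(body, function(x) suppressWarnings(as.numeric(x[-1])))
  if (any(lengths(vals) != n)) {
    stop("LD matrix block is not square", call. = FALSE)
  }
  m <- do.call(rbind, vals)
  if (anyNA(m)) stop("non-numeric entries in LD matrix", call. = FALSE)
  asym <- max(abs(m - t(m)))
  if (asym > 1e-6) {
    stop(sprintf("LD matrix asymmetry %.3g exceeds tolerance 1e-6", asym),
         call. = FALSE)
  }
  m <- (m + t(m)) / 2
  if (max(abs(diag(m) - 1)) > 1e-6) {
    stop("LD matrix diagonal deviates from 1 beyond tolerance 1e-6",
         call. = FALSE)
  }
  ld_matrix(m, variant_ids = ids, ref_alleles = ref_alleles,
            other_alleles = other_alleles)
}

#' Write a signed LD matrix as TSV
#'
#' @param ld an `ld_matrix`.
#' @param path output file.
#' @export
write_ld_matrix <- function(ld, path) {
  ids <- rownames(ld)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("variant_id", ids), collapse = "\t"), con)
  ref <- attr(ld, "ref_alleles")
  if (!is.null(ref)) {
    writeLines(paste(c("ref_allele", ref[ids]), collapse = "\t"), con)
  }
  oth <- attr(ld, "other_alleles")
  if (!is.null(oth)) {
    writeLines(paste(c("other_allele", oth[ids]), collapse = "\t"), con)
  }
  m <- unclass(ld)
  for (i in seq_along(ids)) {
    writeLines(paste(c(ids[i], sprintf("%.17g", m[i, ])), collapse = "\t"), con)
  }
  invisible(path)
}

#' Re-anchor the signs of an LD matrix to given effect alleles
#'
#' For each variant whose effect allele differs from the allele the matrix
#' signs are anchored to, the corresponding row and column of r are negated.
#' The diagonal is unchanged; applying the same flip twice restores the
#' original matrix.
#'
#' @param ld an `ld_matrix` with `ref_alleles` recorded.
#' @param effect_alleles named character vector (by variant id) of the
#'   alleles the signs should refer to.
#' @param other_alleles optional named character vector of the alternative
#'   allele per variant, used to reject alleles matching neither.
#' @return an `ld_matrix` anchored to `effect_alleles`.
#' @export
align_ld_to_effect_alleles <- function(ld, effect_alleles, other_alleles = NULL) {
  ids <- rownames(ld)
  ref <- attr(ld, "ref_alleles")
  if (is.null(ref)) stop("LD matrix carries no reference alleles", call. = FALSE)
  if (is.null(names(effect_alleles))) {
    stopifnot(length(effect_alleles) == length(ids))
    names(effect_alleles) <- ids
  }
  missing_ids <- setdiff(ids, names(effect_alleles))
  if (length(missing_ids) > 0L) {
    stop("no effect allele supplied for variant(s): ",
         paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  ea <- toupper(effect_alleles[ids])
  alt <- attr(ld, "other_alleles")
  if (!is.null(other_alleles)) {
    if (is.null(names(other_alleles))) names(other_alleles) <- ids
    alt <- toupper(other_alleles[ids])
    names(alt) <- ids
  }
  flip <- ea != ref[ids]
  if (!is.null(alt)) {
    bad <- flip & ea != alt[ids]
    if (any(bad)) {
      stop("effect allele matches neither LD allele for variant(s): ",
           paste(ids[bad], collapse = ", "), call. = FALSE)
    }
  }
  m <- unclass(ld)
  if (any(flip)) {
    s <- ifelse(flip, -1, 1)
    m <- m * tcrossprod(s)
    diag(m) <- 1
  }
  new_ref <- ref[ids]
  new_oth <- if (!is.null(alt)) alt[ids] else NULL
  if (any(flip)) {
    swapped_ref <- new_ref
    swapped_ref[flip] <- ea[flip]
    if (!is.null(new_oth)) new_oth[flip] <- ref[ids][flip]
    new_ref <- swapped_ref
  }
  ld_matrix(m, variant_ids = ids, ref_alleles = new_ref,
            other_alleles = new_oth)
}

#' Construct a harmonized exposure/outcome/LD set
#'
#' Low-level constructor for the object the estimators consume: aligned
#' vectors of exposure and outcome associations plus the matching LD
#' submatrix, all referring to the same effect allele per variant. Most
#' users should call [harmonize()] instead.
#'
#' @param variant_ids variant identifiers.
#' @param beta_exposure,se_exposure,p_exposure exposure association vectors.
#' @param beta_outcome,se_outcome outcome association vectors.
#' @param ld matrix of signed correlations (plain matrix or `ld_matrix`).
#' @param pos optional genomic positions (used for deterministic tie-breaks
#'   in instrument selection).
#' @param outcome_scale scale of the outcome trait.
#' @param log optional data frame of harmonization decisions.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(variant_ids, beta_exposure, se_exposure, p_exposure,
                           beta_outcome, se_outcome, ld, pos = NULL,
                           outcome_scale = "continuous_sd", log = NULL) {
  n <- length(variant_ids)
  stopifnot(length(beta_exposure) == n, length(se_exposure) == n,
            length(p_exposure) == n, length(beta_outcome) == n,
            length(se_outcome) == n, nrow(ld) == n, ncol(ld) == n,
            all(se_exposure > 0), all(se_outcome > 0))
  structure(list(
    variant_ids = as.character(variant_ids),
    beta_exposure = as.numeric(beta_exposure),
    se_exposure = as.numeric(se_exposure),
    p_exposure = as.numeric(p_exposure),
    beta_outcome = as.numeric(beta_outcome),
    se_outcome = as.numeric(se_outcome),
    ld = unname(unclass(ld)[seq_len(n), seq_len(n), drop = FALSE]),
    pos = if (is.null(pos)) rep(NA_integer_, n) else as.integer(pos),
    outcome_scale = outcome_scale,
    log = log
  ), class = "harmonized_set")
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized MR set: %d variant(s), outcome scale %s\n",
              length(x$variant_ids), x$outcome_scale))
  invisible(x)
}

#' Subset a harmonized set to selected variants
#'
#' @param h a `harmonized_set`.
#' @param ids variant ids to keep, in the order given.
#' @return a `harmonized_set` restricted to `ids`.
#' @export
subset_harmonized <- function(h, ids) {
  idx <- match(ids, h$variant_ids)
  if (anyNA(idx)) {
    stop("variant(s) not in harmonized set: ",
         paste(ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  harmonized_set(h$variant_ids[idx], h$beta_exposure[idx], h$se_exposure[idx],
                 h$p_exposure[idx], h$beta_outcome[idx], h$se_outcome[idx],
                 h$ld[idx, idx, drop = FALSE], pos = h$pos[idx],
                 outcome_scale = h$outcome_scale, log = h$log)
}

.is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize exposure and outcome summary statistics with an LD matrix
#'
#' Inner-joins the two datasets and the LD matrix on variant id and aligns
#' every effect direction to the exposure effect allele. Outcome rows whose
#' alleles are swapped (or strand-complement swapped) relative to the
#' exposure have `beta` negated and `eaf` replaced by `1 - eaf`. Palindromic
#' variants (A/T or C/G), whose strand cannot be inferred from allele labels,
#' are oriented by allele frequency when it is informative and dropped when
#' the minor allele frequency in either dataset lies within
#' `palindromic_eaf_band` of 0.5 (or is missing). Variants whose allele
#' pairs cannot be reconciled are dropped. Every drop is recorded in the
#' returned object's `log` and emitted as a message.
#'
#' @param exposure,outcome `summary_dataset` objects.
#' @param ld an `ld_matrix` covering the shared variants. If it records
#'   reference alleles the signs of r are re-anchored to the exposure effect
#'   alleles; otherwise the matrix is assumed to be already anchored to them.
#' @param palindromic_eaf_band half-width of the frequency window around 0.5
#'   within which palindromic variants are considered unresolvable.
#' @return a `harmonized_set`.
#' @export
harmonize <- function(exposure, outcome, ld, palindromic_eaf_band = 0.08) {
  stopifnot(inherits(exposure, "summary_dataset"),
            inherits(outcome, "summary_dataset"))
  shared <- exposure$variant_id[exposure$variant_id %in% outcome$variant_id &
                                exposure$variant_id %in% rownames(ld)]
  if (length(shared) == 0L) stop("no shared variants", call. = FALSE)

  ex <- exposure[match(shared, exposure$variant_id), ]
  ou <- outcome[match(shared, outcome$variant_id), ]

  action <- character(length(shared))   # "keep", "flip", or a drop reason
  for (i in seq_along(shared)) {
    ea <- ex$effect_allele[i]; oa <- ex$other_allele[i]
    ea2 <- ou$effect_allele[i]; oa2 <- ou$other_allele[i]
    cea <- ALLELE_COMPLEMENT[[ea]]; coa <- ALLELE_COMPLEMENT[[oa]]
    if (.is_palindromic(ea, oa)) {
      pair_ok <- (ea2 == ea && oa2 == oa) || (ea2 == oa && oa2 == ea)
      if (!pair_ok) { action[i] <- "allele_mismatch"; next }
      f1 <- ex$eaf[i]; f2 <- ou$eaf[i]
      if (is.na(f1) || is.na(f2)) { action[i] <- "palindromic_no_eaf"; next }
      if (abs(f1 - 0.5) <= palindromic_eaf_band ||
          abs(f2 - 0.5) <= palindromic_eaf_band) {
        action[i] <- "palindromic_ambiguous"; next
      }
      # strand labels are uninformative here: orient by frequency
      action[i] <- if (sign(f1 - 0.5) == sign(f2 - 0.5)) "keep" else "flip"
    } else {
      if (ea2 == ea && oa2 == oa) action[i] <- "keep"
      else if (ea2 == oa && oa2 == ea) action[i] <- "flip"
      else if (ea2 == cea && oa2 == coa) action[i] <- "keep"
      else if (ea2 == coa && oa2 == cea) action[i] <- "flip"
      else action[i] <- "allele_mismatch"
    }
  }

  dropped <- !(action %in% c("keep", "flip"))
  log <- data.frame(variant_id = shared[dropped],
                    reason = action[dropped],
                    stringsAsFactors = FALSE)
  for (i in which(dropped)) {
    message("harmonize: dropping ", shared[i], " (", action[i], ")")
  }
  keep <- !dropped
  if (!any(keep)) stop("all shared variants dropped during harmonization",
                       call. = FALSE)

  ids <- shared[keep]
  ex <- ex[keep, ]; ou <- ou[keep, ]
  flip <- action[keep] == "flip"
  beta_out <- ifelse(flip, -ou$beta, ou$beta)

  ld_sub <- subset_ld(ld, ids)
  if (!is.null(attr(ld_sub, "ref_alleles"))) {
    ea_vec <- stats::setNames(ex$effect_allele, ids)
    oa_vec <- stats::setNames(ex$other_allele, ids)
    ld_sub <- align_ld_to_effect_alleles(ld_sub, ea_vec, oa_vec)
  } else {
    message("harmonize: LD matrix carries no reference alleles; ",
            "assuming signs already refer to exposure effect alleles")
  }

  p_exp <- ex$pvalue
  no_p <- is.na(p_exp)
  p_exp[no_p] <- 2 * stats::pnorm(-abs(ex$beta[no_p] / ex$se[no_p]))

  harmonized_set(ids, ex$beta, ex$se, p_exp, beta_out, ou$se, ld_sub,
                 pos = ex$pos, outcome_scale = attr(outcome, "trait_scale"),
                 log = log)
}
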