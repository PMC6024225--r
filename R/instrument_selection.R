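#' Greedy stepwise instrument selection with r-squared pruning
#'
#' Visits variants in order of increasing exposure p-value and keeps a
#' candidate only if its squared LD correlation with every variant already
#' kept is below `r2_max`, yielding a set of instruments with low pairwise
#' correlations. Ties in p-value break by ascending genomic position, then
#' lexicographic variant id, so the selection is deterministic.
#'
#' @param h a `harmonized_set` with exposure p-values and LD for all variants.
#' @param r2_max pairwise r-squared ceiling, in (0,1] (default 0.4).
#' @return character vector of selected variant ids, in visit order.
#' @export
stepwise_select <- function(h, r2_max = 0.4) {
  stopifnot(inherits(h, "harmonized_set"))
  n <- length(h$variant_ids)
  if (n == 0) stop("empty harmonized set", call. = FALSE)
  if (!(r2_max > 0 && r2_max <= 1)) stop("r2_max must lie in (0,1]", call. = FALSE)
  if (anyNA(h$p_exposure)) {
    stop("exposure p-values missing for: ",
         paste(h$variant_ids[is.na(h$p_exposure)], collapse = ", "),
         call. = FALSE)
  }
  pos_key <- ifelse(is.na(h$pos), .Machine$integer.max, h$pos)
  ord <- order(h$p_exposure, pos_key, h$variant_ids)
  r2 <- h$ld^2
  selected <- integer(0)
  for (i in ord) {
    if (length(selected) > 0) {
      pair_r2 <- r2[i, selected]
      if (anyNA(pair_r2)) {
        j <- selected[which(is.na(pair_r2))[1]]
        stop("missing LD entry for pair (", h$variant_ids[i], ", ",
             h$variant_ids[j], ")", call. = FALSE)
      }
      if (any(pair_r2 >= r2_max)) next
    }
    selected <- c(selected, i)
  }
  h$variant_ids[selected]
}

#' Select instruments from a fixed conditional-score list
#'
#' Returns the sublist of `variant_list` present in the harmonized set,
#' preserving the list's order; this supports genetic scores defined by a
#' prior conditional analysis, where the variants available differ between
#' outcome datasets. Absent variants are reported by message.
#'
#' @param h a `harmonized_set`.
#' @param variant_list ordered character vector of variant ids.
#' @return character vector of the available ids, in list order.
#' @export
conditional_select <- function(h, variant_list) {
  stopifnot(inherits(h, "harmonized_set"))
  if (length(variant_list) == 0) stop("empty variant list", call. = FALSE)
  present <- variant_list %in% h$variant_ids
  if (!any(present)) {
    stop("none of the listed variants are present in the harmonized set",
         call. = FALSE)
  }
  if (any(!present)) {
    message("conditional_select: absent variant(s): ",
            paste(variant_list[!present], collapse = ", "))
  }
  variant_list[present]
}

#' Read a one-id-per-line variant list
#'
#' @param path file with one variant id per line; blank lines and lines
#'   starting with `#` are ignored.
#' @return character vector of ids.
#' @export
read_variant_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Write a selection result as TSV
#'
#' @param h the `harmonized_set` the selection was made from.
#' @param selected character vector of selected ids.
#' @param path output file; columns rank, variant_id, p_exposure.
#' @export
write_selection_tsv <- function(h, selected, path) {
  idx <- match(selected, h$variant_ids)
  out <- data.frame(rank = seq_along(selected), variant_id = selected,
                    p_exposure = sprintf("%.17g", h$p_exposure[idx]),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
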