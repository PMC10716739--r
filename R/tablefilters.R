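# ASV-table quality control and compositional transforms.

validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) stop("counts must be a numeric matrix (samples x ASVs)")
  if (nrow(counts) == 0 || ncol(counts) == 0) stop("empty count table")
  if (any(counts < 0)) stop("negative counts")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry sample ids (rownames) and ASV ids (colnames)")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate sample ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate ASV ids")
  invisible(counts)
}

record_removed <- function(counts, removed_ids, rule, value) {
  log <- attr(counts, "filter_log") %||%
    data.frame(asv_id = character(0), rule = character(0),
               value = numeric(0), action = character(0), stringsAsFactors = FALSE)
  if (length(removed_ids)) {
    log <- rbind(log, data.frame(asv_id = removed_ids, rule = rule,
                                 value = value, action = "removed",
                                 stringsAsFactors = FALSE))
  }
  attr(counts, "filter_log") <- log
  counts
}

#' Relative-abundance noise filter
#'
#' Removes ASVs whose share of the table's grand total is below `threshold`
#' (default 0.005%, the usual Bokulich-style cut for MiSeq runs). The share is
#' computed once against the input table's grand total (single pass); ASVs at
#' exactly the threshold are kept.
#'
#' @param counts sample x ASV count matrix.
#' @param threshold minimum relative abundance (fraction of grand total).
#' @return the filtered matrix; removed ASVs are recorded in the
#'   `filter_log` attribute.
#' @export
abundance_filter <- function(counts, threshold = 0.00005) {
  validate_counts(counts)
  stopifnot(threshold >= 0, threshold < 1)
  share <- colSums(counts) / sum(counts)
  keep <- share >= threshold
  out <- counts[, keep, drop = FALSE]
  attr(out, "filter_log") <- attr(counts, "filter_log")
  record_removed(out, colnames(counts)[!keep], "abundance", threshold)
}

#' Prevalence filter against structural zeros
#'
#' Drops ASVs observed (nonzero) in fewer than `min_nonzero` samples; with the
#' default of 3 this is the "at least 3 non-zero observations" rule used
#' before compositional trait assignment.
#'
#' @param counts sample x ASV count matrix.
#' @param min_nonzero minimum number of samples with a nonzero count.
#' @return filtered matrix (removals recorded in `filter_log`).
#' @export
prevalence_filter <- function(counts, min_nonzero = 3) {
  validate_counts(counts)
  stopifnot(min_nonzero >= 1)
  keep <- colSums(counts > 0) >= min_nonzero
  out <- counts[, keep, drop = FALSE]
  attr(out, "filter_log") <- attr(counts, "filter_log")
  record_removed(out, colnames(counts)[!keep], "prevalence", min_nonzero)
}

#' Library-size bias check across treatment groups
#'
#' Kruskal-Wallis rank test on per-sample library totals; a non-significant
#' result supports comparing clr values across groups without depth artifacts.
#'
#' @param counts sample x ASV count matrix.
#' @param groups group label per sample (same order as rows).
#' @return list with `H` (chi-squared statistic with tie correction) and `p`.
#' @export
library_size_bias <- function(counts, groups) {
  validate_counts(counts)
  stopifnot(length(groups) == nrow(counts))
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("at least 2 groups required")
  if (any(table(droplevels(groups)) < 2)) stop("every group needs at least 2 samples")
  totals <- rowSums(counts)
  if (length(unique(totals)) == 1) return(list(H = 0, p = 1))  # all tied
  kt <- stats::kruskal.test(totals, groups)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Centered log-ratio transform of a count table
#'
#' Per sample, `clr(x)_j = ln((x_j + offset) / g(x + offset))` with `g` the
#' geometric mean over the retained ASVs of that sample. The default offset of
#' 1 handles sampling zeros surviving the prevalence filter; rows of the
#' result sum to zero.
#'
#' @param counts sample x ASV count matrix.
#' @param count_offset pseudo-count added before taking logs; must be positive
#'   when zeros are present.
#' @return matrix of class `clr_matrix` with attributes `shifted = FALSE` and
#'   `shift_constant = 0`.
#' @export
clr_transform <- function(counts, count_offset = 1) {
  validate_counts(counts)
  if (count_offset < 0) stop("count_offset must be non-negative")
  if (count_offset == 0 && any(counts == 0)) {
    stop("zero counts present; a positive count_offset is required")
  }
  lg <- log(counts + count_offset)
  out <- lg - rowMeans(lg)
  attr(out, "shifted") <- FALSE
  attr(out, "shift_constant") <- 0
  class(out) <- c("clr_matrix", class(out))
  out
}

#' Shift a clr matrix to non-negative values
#'
#' Adds the absolute value of the global minimum to every entry, so the result
#' has minimum 0 and all pairwise differences preserved. The shifted values are
#' what the ternary carbon-preference axes are computed from.
#'
#' @param m an unshifted `clr_matrix` from [clr_transform()].
#' @return shifted `clr_matrix` (`shifted = TRUE`, `shift_constant` recorded).
#' @export
shift_nonnegative <- function(m) {
  if (!inherits(m, "clr_matrix")) stop("input must be a clr_matrix")
  if (isTRUE(attr(m, "shifted"))) stop("clr matrix is already shifted")
  shift <- abs(min(m))
  out <- m + shift
  attr(out, "shifted") <- TRUE
  attr(out, "shift_constant") <- shift
  out
}

#' Retrieve the removal log of a filtered table
#'
#' @param counts a matrix returned by [abundance_filter()] or
#'   [prevalence_filter()].
#' @return data.frame (asv_id, rule, value, action); empty if nothing was removed.
#' @export
filter_log <- function(counts) {
  attr(counts, "filter_log") %||%
    data.frame(asv_id = character(0), rule = character(0),
               value = numeric(0), action = character(0), stringsAsFactors = FALSE)
}
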