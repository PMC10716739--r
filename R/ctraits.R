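# Ternary carbon-preference trait framework: per-ASV (C-ness, St-ness,
# Su-ness) coordinates on the simplex, gated by a compositional
# differential-abundance test of the 1% amendments against the control.

.CARBON_AXES <- c("cellulose", "starch", "sucrose")

#' Carbon-preference axes of each ASV
#'
#' For each ASV, averages its shifted-clr value over the replicates of each 1%
#' carbon amendment and normalizes the three means to sum to one:
#' `C-ness = mean(cellulose) / (mean(cellulose) + mean(starch) + mean(sucrose))`,
#' and likewise St-ness (starch) and Su-ness (sucrose). Each axis lies in
#' `[0, 1]` and the three sum to exactly 1. ASVs whose three means sum to zero
#' have undefined coordinates; they are excluded and reported via the
#' `excluded` attribute.
#'
#' @param shifted_clr a shifted `clr_matrix` (see [shift_nonnegative()]),
#'   samples x ASVs.
#' @param design the experiment design mapping samples to carbons and doses.
#' @param dose amendment dose defining the trait contrast (default 1,
#'   i.e. the 1% treatments).
#' @return data.frame (asv_id, c_ness, st_ness, su_ness); attribute `excluded`
#'   lists ASVs with zero denominator.
#' @export
trait_axes <- function(shifted_clr, design, dose = 1) {
  if (!inherits(shifted_clr, "clr_matrix") || !isTRUE(attr(shifted_clr, "shifted"))) {
    stop("trait_axes() requires a shifted clr matrix")
  }
  validate_design(design)
  design <- design[match(rownames(shifted_clr), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) stop("clr matrix contains samples absent from the design")
  means <- sapply(.CARBON_AXES, function(cb) {
    rows <- design$carbon == cb & design$dose_pct == dose
    if (!any(rows)) stop("no samples for carbon '", cb, "' at dose ", dose)
    colMeans(shifted_clr[rows, , drop = FALSE])
  })  # ASVs x 3
  denom <- rowSums(means)
  ok <- denom > 0
  ax <- means[ok, , drop = FALSE] / denom[ok]
  out <- data.frame(asv_id = colnames(shifted_clr)[ok],
                    c_ness = ax[, "cellulose"],
                    st_ness = ax[, "starch"],
                    su_ness = ax[, "sucrose"],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded") <- colnames(shifted_clr)[!ok]
  out
}

#' Map simplex coordinates onto the ternary plot plane
#'
#' Barycentric-to-Cartesian mapping onto the unit-side triangle with the
#' cellulose vertex at (0, 0), starch at (1, 0) and sucrose at
#' (0.5, sqrt(3)/2).
#'
#' @param coords data.frame with columns `c_ness`, `st_ness`, `su_ness`
#'   (rows on the simplex), or a numeric length-3 vector.
#' @param tol allowed deviation from the simplex.
#' @return data.frame with columns `x`, `y` (plus `asv_id` when present).
#' @export
ternary_xy <- function(coords, tol = 1e-6) {
  if (is.numeric(coords) && length(coords) == 3) {
    coords <- data.frame(c_ness = coords[1], st_ness = coords[2], su_ness = coords[3])
  }
  b <- as.matrix(coords[, c("c_ness", "st_ness", "su_ness")])
  if (any(abs(rowSums(b) - 1) > tol) || any(b < -tol) || any(b > 1 + tol)) {
    stop("coordinates are off the simplex beyond tolerance")
  }
  out <- data.frame(x = b[, "st_ness"] + 0.5 * b[, "su_ness"],
                    y = b[, "su_ness"] * sqrt(3) / 2)
  if ("asv_id" %in% names(coords)) out <- cbind(coords["asv_id"], out)
  rownames(out) <- NULL
  out
}

# Welch two-sample test computed by hand so zero-variance replicates are
# handled deterministically rather than erroring.
welch_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  v1 <- stats::var(a); v2 <- stats::var(b)
  eff <- mean(b) - mean(a)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) return(list(effect = eff, p = if (eff == 0) 1 else 0))
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(effect = eff, p = 2 * stats::pt(-abs(eff / sqrt(se2)), df))
}

#' Differential abundance of ASVs along one carbon axis
#'
#' The significance gate of the trait framework: a compositional test of each
#' ASV's change between one 1% amendment and the unamended control. The
#' default method is a per-ASV Welch two-sample test on clr values with
#' Benjamini-Hochberg adjustment across ASVs within the axis — a self-contained
#' bias-aware gate exposed behind `da_method` so an alternative (e.g. an
#' ANCOM-BC-style estimator) can be plugged in.
#'
#' @param counts sample x ASV count matrix (after filtering).
#' @param design experiment design.
#' @param axis one of `"sucrose"`, `"starch"`, `"cellulose"`.
#' @param dose treatment dose contrasted against the control (default 1).
#' @param q_threshold adjusted-p significance cut (default 0.05).
#' @param count_offset pseudo-count for the clr step.
#' @param da_method currently `"clr_welch"`.
#' @return data.frame (asv_id, axis, effect, p, q, significant, direction);
#'   `effect` is the difference of group mean clr values (treatment minus
#'   control), `direction` its sign.
#' @export
diff_abundance <- function(counts, design, axis, dose = 1, q_threshold = 0.05,
                           count_offset = 1, da_method = "clr_welch") {
  validate_counts(counts)
  validate_design(design)
  da_method <- match.arg(da_method)
  stopifnot(axis %in% .CARBON_AXES, q_threshold > 0, q_threshold <= 1)
  design <- design[match(rownames(counts), design$sample_id), , drop = FALSE]
  if (anyNA(design$sample_id)) stop("count table contains samples absent from the design")
  trt <- which(design$carbon == axis & design$dose_pct == dose)
  ctl <- which(design$carbon == "control")
  if (length(trt) < 3 || length(ctl) < 3) {
    stop("at least 3 replicates per group required (treatment: ", length(trt),
         ", control: ", length(ctl), ")")
  }
  if (all(counts[trt, ] == 0) || all(counts[ctl, ] == 0)) {
    stop("a comparison group has zero counts for every ASV")
  }
  clr <- clr_transform(counts, count_offset = count_offset)
  res <- lapply(seq_len(ncol(clr)), function(j) welch_p(clr[ctl, j], clr[trt, j]))
  out <- data.frame(asv_id = colnames(counts),
                    axis = axis,
                    effect = vapply(res, `[[`, numeric(1), "effect"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q <= q_threshold
  out$direction <- ifelse(out$effect >= 0, "+", "-")
  out
}

#' Run the differential-abundance gate on all three carbon axes
#'
#' @inheritParams diff_abundance
#' @return row-bound [diff_abundance()] results for sucrose, starch and
#'   cellulose.
#' @export
diff_abundance_all <- function(counts, design, dose = 1, q_threshold = 0.05,
                               count_offset = 1) {
  do.call(rbind, lapply(.CARBON_AXES, function(ax) {
    diff_abundance(counts, design, ax, dose = dose, q_threshold = q_threshold,
                   count_offset = count_offset)
  }))
}

#' Combine simplex coordinates with the significance gate
#'
#' Classifies each ASV from its significant axes: none significant ->
#' `"none"`; all three significant and positive -> `"triple+"`; all three
#' negative -> `"triple-"`; exactly one significant axis -> `"single+"` or
#' `"single-"`; any other combination -> `"mixed"`.
#'
#' @param coords output of [trait_axes()].
#' @param da output of [diff_abundance_all()] (all three axes, same ASVs).
#' @return data.frame with the coordinates plus `sig_axes` (comma-separated
#'   `axis+`/`axis-` entries), `n_significant` and `class_label`.
#' @export
assign_traits <- function(coords, da) {
  stopifnot(is.data.frame(coords), is.data.frame(da))
  if (!setequal(unique(da$axis), .CARBON_AXES)) {
    stop("da must contain results for all three carbon axes")
  }
  for (ax in .CARBON_AXES) {
    ids <- da$asv_id[da$axis == ax]
    if (!all(coords$asv_id %in% ids)) {
      stop("ASV universe mismatch between coordinates and '", ax, "' results")
    }
  }
  sig <- da[da$significant, , drop = FALSE]
  lab <- vapply(coords$asv_id, function(id) {
    s <- sig[sig$asv_id == id, , drop = FALSE]
    if (nrow(s) == 0) return("none|0|")
    tags <- paste0(s$axis, s$direction)
    cls <- if (nrow(s) == 3 && all(s$direction == "+")) "triple+"
      else if (nrow(s) == 3 && all(s$direction == "-")) "triple-"
      else if (nrow(s) == 1) paste0("single", s$direction)
      else "mixed"
    paste(cls, nrow(s), paste(sort(tags), collapse = ","), sep = "|")
  }, character(1))
  parts <- strsplit(lab, "|", fixed = TRUE)
  out <- coords
  out$class_label <- vapply(parts, `[`, character(1), 1)
  out$n_significant <- as.integer(vapply(parts, `[`, character(1), 2))
  out$sig_axes <- vapply(parts, function(p) if (length(p) >= 3) p[3] else "", character(1))
  rownames(out) <- NULL
  out
}

#' Percentage of responding ASVs, rounded half-up
#'
#' @param n number of responders.
#' @param total ASV universe size.
#' @return integer percentage.
#' @export
#' @examples
#' percent_responding(173, 1503)  # 12
percent_responding <- function(n, total) {
  stopifnot(total > 0, n >= 0, n <= total)
  round_half_up(100 * n / total)
}

#' Summarize trait assignments
#'
#' Counts and integer percentages of responding ASVs overall, per axis x
#' direction, and per taxonomic group when a taxonomy is supplied.
#'
#' @param assignments output of [assign_traits()].
#' @param taxonomy optional data.frame (asv_id, group).
#' @return list with data.frames `overall`, `by_axis` and (optionally)
#'   `by_taxon`.
#' @export
summarize_traits <- function(assignments, taxonomy = NULL) {
  stopifnot(is.data.frame(assignments), nrow(assignments) > 0)
  total <- nrow(assignments)
  responding <- assignments$class_label != "none"
  n_resp <- sum(responding)
  overall <- data.frame(n_asv = total, n_responding = n_resp,
                        pct_responding = percent_responding(n_resp, total))

  tag_list <- strsplit(assignments$sig_axes[responding], ",", fixed = TRUE)
  tags <- unlist(tag_list)
  by_axis <- do.call(rbind, lapply(.CARBON_AXES, function(ax) {
    involved <- if (n_resp) sum(vapply(tag_list, function(tg) any(grepl(ax, tg, fixed = TRUE)), logical(1))) else 0L
    data.frame(axis = ax,
               n_positive = sum(tags == paste0(ax, "+")),
               n_negative = sum(tags == paste0(ax, "-")),
               n_involved = involved,
               pct_of_responders = if (n_resp) percent_responding(involved, n_resp) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(by_axis) <- NULL
  out <- list(overall = overall, by_axis = by_axis)

  if (!is.null(taxonomy)) {
    stopifnot(all(c("asv_id", "group") %in% names(taxonomy)))
    grp <- taxonomy$group[match(assignments$asv_id, taxonomy$asv_id)]
    tab <- table(group = grp, responding = factor(responding, c(FALSE, TRUE)))
    by_taxon <- data.frame(group = rownames(tab),
                           n_asv = as.integer(rowSums(tab)),
                           n_responding = as.integer(tab[, "TRUE"]),
                           stringsAsFactors = FALSE)
    by_taxon$pct_responding <- mapply(percent_responding,
                                      by_taxon$n_responding, by_taxon$n_asv)
    rownames(by_taxon) <- NULL
    out$by_taxon <- by_taxon
  }
  out
}
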