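# Community-structure statistics from first principles: Hellinger transform,
# Bray-Curtis dissimilarity, principal coordinates, and permutational
# multivariate ANOVA with sequential sums of squares.

#' Hellinger transform
#'
#' Square root of per-sample relative abundances; every output row has
#' Euclidean norm 1.
#'
#' @param counts sample x ASV count matrix with positive row sums.
#' @return numeric matrix of the same shape.
#' @export
hellinger <- function(counts) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  rs <- rowSums(counts)
  if (any(rs == 0)) {
    stop("zero-sum rows: ", paste(rownames(counts)[rs == 0], collapse = ", "))
  }
  sqrt(counts / rs)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(a, b) = sum |a_j - b_j| / sum (a_j + b_j)`, a semimetric bounded in
#' `[0, 1]` for non-negative data.
#'
#' @param m sample x feature matrix of non-negative values (counts or
#'   transformed abundances).
#' @return symmetric matrix of class `dist_matrix` with zero diagonal.
#' @export
bray_curtis <- function(m) {
  stopifnot(is.matrix(m), all(m >= 0))
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      denom <- sum(m[i, ] + m[j, ])
      if (denom == 0) {
        stop("Bray-Curtis undefined for the all-zero pair (",
             rownames(m)[i], ", ", rownames(m)[j], ")")
      }
      d[i, j] <- d[j, i] <- sum(abs(m[i, ] - m[j, ])) / denom
    }
  }
  class(d) <- c("dist_matrix", class(d))
  d
}

validate_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("distance matrix must be square")
  if (max(abs(d - t(d))) > 1e-10) stop("distance matrix is not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  invisible(d)
}

# Gower-centered inner-product matrix: G = -0.5 * C d^2 C
gower_center <- function(d) {
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  sweep(sweep(a, 1, rm), 2, rm) + mean(a)
}

#' Principal coordinates analysis
#'
#' Classical (metric) scaling: Gower double-centering of the squared
#' distances, eigendecomposition, axes ordered by eigenvalue. Negative
#' eigenvalues (possible for semimetrics such as Bray-Curtis) are reported
#' unchanged; proportions explained are taken over the positive eigenvalues.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @return list with `coordinates` (samples x positive axes), `eigenvalues`
#'   (all, decreasing) and `prop_explained`.
#' @export
pcoa <- function(d) {
  validate_dist(d)
  g <- gower_center(unclass(d))
  e <- eigen(g, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- which(e$values > tol)
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(e$values[pos]), length(pos))
  dimnames(coords) <- list(rownames(d), paste0("Axis", seq_along(pos)))
  list(coordinates = coords,
       eigenvalues = e$values,
       prop_explained = e$values[pos] / sum(e$values[pos]))
}

# orthogonal projection (hat) matrix of a design matrix
hat_matrix <- function(X) {
  qx <- qr(X)
  Q <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
  tcrossprod(Q)
}

# all permutations of 1..n (n small), as a list
all_perms <- function(n) {
  if (n > 8) stop("exhaustive permutations limited to n <= 8")
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in all_perms(n - 1)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(sub, n, after = pos - 1L)
    }
  }
  out
}

#' Permutational multivariate analysis of variance
#'
#' Partitions the total sum of squares of a distance matrix among one or two
#' categorical factors (plus their interaction for two factors) using the
#' Gower-centered inner-product matrix with sequential (order-of-entry)
#' attribution, the standard pseudo-F, and p-values from free permutation of
#' sample labels (optionally restricted within strata). With `exact = TRUE`
#' all `n!` label permutations are enumerated instead.
#'
#' @param d symmetric distance matrix.
#' @param factors a factor/character vector, or a data.frame with one or two
#'   such columns (entered in order; the interaction is entered last).
#' @param n_perm number of random permutations (ignored when `exact`).
#' @param seed integer seed for the permutation stream.
#' @param strata optional blocking vector; permutations are performed within
#'   its levels.
#' @param exact enumerate all permutations (n <= 8).
#' @return data.frame (term, df, SS, pseudo_F, R2, p_perm) with rows for each
#'   term, the residual and the total; term and residual R2 sum to 1.
#' @export
permanova <- function(d, factors, n_perm = 999, seed = NULL, strata = NULL,
                      exact = FALSE) {
  validate_dist(d)
  n <- nrow(d)
  if (is.atomic(factors)) factors <- data.frame(f = factors, stringsAsFactors = FALSE)
  stopifnot(ncol(factors) %in% c(1, 2), nrow(factors) == n)
  if (!exact && n_perm < 1) stop("n_perm must be at least 1")
  fs <- lapply(factors, function(f) droplevels(as.factor(f)))
  if (any(vapply(fs, nlevels, integer(1)) < 2)) {
    stop("every factor needs at least 2 levels")
  }
  term_names <- names(factors)
  if (length(fs) == 2) term_names <- c(term_names, paste(term_names, collapse = ":"))

  # sequential design matrices
  Xs <- list(matrix(1, n, 1))
  Xs[[2]] <- cbind(Xs[[1]], stats::model.matrix(~ fs[[1]])[, -1, drop = FALSE])
  if (length(fs) == 2) {
    Xs[[3]] <- cbind(Xs[[2]], stats::model.matrix(~ fs[[2]])[, -1, drop = FALSE])
    inter <- droplevels(interaction(fs[[1]], fs[[2]]))
    Xs[[4]] <- cbind(Xs[[3]], stats::model.matrix(~ inter)[, -1, drop = FALSE])
  }
  Hs <- lapply(Xs, hat_matrix)
  ranks <- vapply(Xs, function(X) qr(X)$rank, integer(1))
  k <- length(Hs) - 1          # number of terms
  df_terms <- diff(ranks)
  df_res <- n - ranks[k + 1]
  if (df_res < 1) stop("no residual degrees of freedom")
  Hdiff <- lapply(seq_len(k), function(i) Hs[[i + 1]] - Hs[[i]])
  Hres <- diag(n) - Hs[[k + 1]]

  G <- gower_center(unclass(d))
  ss_of <- function(Gp) {
    c(vapply(Hdiff, function(H) sum(H * Gp), numeric(1)), sum(Hres * Gp))
  }
  f_of <- function(ss) (ss[seq_len(k)] / df_terms) / (ss[k + 1] / df_res)
  ss_obs <- ss_of(G)
  f_obs <- f_of(ss_obs)
  ss_total <- sum(diag(G))

  perms <- if (exact) {
    all_perms(n)
  } else {
    with_seed(seed, replicate(n_perm, {
      if (is.null(strata)) sample.int(n) else {
        p <- seq_len(n)
        for (lv in unique(strata)) {
          idx <- which(strata == lv)
          p[idx] <- idx[sample.int(length(idx))]
        }
        p
      }
    }, simplify = FALSE))
  }
  f_perm <- vapply(perms, function(p) f_of(ss_of(G[p, p])), numeric(k))
  f_perm <- matrix(f_perm, nrow = k)
  if (exact) {
    p_perm <- rowMeans(f_perm >= f_obs - 1e-12)
  } else {
    p_perm <- (1 + rowSums(f_perm >= f_obs - 1e-12)) / (1 + length(perms))
  }

  data.frame(
    term = c(term_names, "residual", "total"),
    df = c(df_terms, df_res, n - 1),
    SS = c(ss_obs, ss_total),
    pseudo_F = c(f_obs, NA, NA),
    R2 = c(ss_obs / ss_total, 1),
    p_perm = c(p_perm, NA, NA),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Pairwise one-factor PERMANOVA with multiplicity adjustment
#'
#' One test per level pair of the factor, with p-values adjusted across pairs
#' (Benjamini-Hochberg by default).
#'
#' @param d symmetric distance matrix.
#' @param factor_ grouping vector.
#' @param n_perm,seed,strata passed to [permanova()].
#' @param adjust method for [stats::p.adjust()].
#' @return data.frame (level_a, level_b, df, pseudo_F, R2, p_perm, p_adj).
#' @export
pairwise_permanova <- function(d, factor_, n_perm = 999, seed = NULL,
                               strata = NULL, adjust = "BH") {
  validate_dist(d)
  f <- droplevels(as.factor(factor_))
  if (nlevels(f) < 2) stop("factor needs at least 2 levels")
  pairs <- utils::combn(levels(f), 2, simplify = FALSE)
  rows <- lapply(seq_along(pairs), function(i) {
    pr <- pairs[[i]]
    keep <- f %in% pr
    sub <- permanova(structure(d[keep, keep], class = class(d)),
                     data.frame(group = droplevels(f[keep])),
                     n_perm = n_perm,
                     seed = if (is.null(seed)) NULL else seed + i,
                     strata = if (is.null(strata)) NULL else strata[keep])
    data.frame(level_a = pr[1], level_b = pr[2],
               df = sub$df[1], pseudo_F = sub$pseudo_F[1],
               R2 = sub$R2[1], p_perm = sub$p_perm[1],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_perm, method = adjust)
  out
}
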