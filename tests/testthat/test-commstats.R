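# brute_permanova_p (independent all-permutations oracle) is defined in
# helper-oracles.R so the acceptance tests can reuse it.

test_that("hellinger rows have unit norm and match hand values", {
  m <- rbind(a = c(4, 0, 0), b = c(1, 1, 0))
  h <- hellinger(m)
  expect_equal(h["a", ], c(1, 0, 0))
  expect_equal(h["b", ], c(sqrt(0.5), sqrt(0.5), 0))
  expect_equal(unname(rowSums(h^2)), c(1, 1))
  expect_error(hellinger(rbind(a = c(0, 0))), "zero-sum")
})

test_that("bray_curtis matches direct arithmetic and its bounds", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0), e = c(0, 0, 1))
  d <- bray_curtis(m)
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)           # identical rows
  expect_equal(d["a", "e"], 1)           # disjoint supports
  expect_equal(unclass(d), t(unclass(d)))
  expect_true(all(d >= 0 & d <= 1))
  expect_error(bray_curtis(rbind(a = c(0, 0), b = c(0, 0))), "all-zero")
})

test_that("bray_curtis agrees with vegan::vegdist", {
  skip_if_not_installed("vegan")
  dsg <- build_design(1, c("sucrose", "starch"), c(1, 3))
  sim <- simulate_counts(dsg, community_spec(n_asv = 40), seed = 17)
  h <- hellinger(sim$counts)
  mine <- bray_curtis(h)
  ref <- as.matrix(vegan::vegdist(h, method = "bray"))
  expect_equal(unclass(mine), ref[rownames(mine), colnames(mine)], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pcoa recovers Euclidean configurations and the equidistant simplex", {
  # three equidistant points: two equal positive eigenvalues, side length 1
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  ord <- pcoa(d3)
  ev <- ord$eigenvalues
  expect_equal(ev[1], ev[2], tolerance = 1e-9)
  expect_gt(ev[1], 0)
  rec <- as.matrix(dist(ord$coordinates))
  expect_equal(unname(rec), unname(d3), tolerance = 1e-9)

  # Euclidean input distances are reproduced exactly
  pts <- withr::with_seed(5, matrix(rnorm(8 * 3), 8))
  rownames(pts) <- paste0("p", 1:8)
  de <- as.matrix(dist(pts))
  orde <- pcoa(de)
  expect_lt(max(abs(as.matrix(dist(orde$coordinates)) - de)), 1e-8)

  # duplicate points coincide
  dd <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  dimnames(dd) <- list(paste0("q", 1:4), paste0("q", 1:4))
  ordd <- pcoa(dd)
  expect_equal(ordd$coordinates[1, ], ordd$coordinates[2, ], tolerance = 1e-9)

  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("pcoa coordinates agree with stats::cmdscale", {
  pts <- withr::with_seed(8, matrix(rnorm(10 * 4), 10))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:10), paste0("s", 1:10))
  ref <- cmdscale(d, k = 4)
  ord <- pcoa(d)
  for (k in 1:4) {
    expect_equal(abs(ord$coordinates[, k]), abs(ref[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("permanova partitions match vegan::adonis2 with sequential terms", {
  skip_if_not_installed("vegan")
  d <- build_design(3, c("sucrose", "starch"), c(1, 3))
  sim <- simulate_counts(d, community_spec(n_asv = 60), seed = 23)
  dm <- bray_curtis(hellinger(sim$counts))
  keep <- d$carbon != "control"
  dmk <- structure(dm[keep, keep], class = class(dm))
  fac <- data.frame(type = d$carbon[keep], dose = factor(d$dose_pct[keep]))
  mine <- permanova(dmk, fac, n_perm = 99, seed = 1)
  ref <- vegan::adonis2(as.dist(dmk) ~ type * dose, data = fac,
                        permutations = 99, by = "terms")
  expect_equal(mine$SS, c(ref$SumOfSqs), tolerance = 1e-9)
  expect_equal(mine$df, c(ref$Df))
  expect_equal(mine$pseudo_F[1:3], c(ref$F)[1:3], tolerance = 1e-9)
  expect_equal(mine$R2, c(ref$R2), tolerance = 1e-9)
})

test_that("R2 terms close to one and strong separation reaches the minimum p", {
  for (s in 1:5) {
    pts <- withr::with_seed(s, matrix(rnorm(16 * 5), 16))
    grp <- rep(c("a", "b"), each = 8)
    pts[grp == "b", ] <- pts[grp == "b", ] + 50   # planted separation
    d <- as.matrix(dist(pts)); dimnames(d) <- list(1:16, 1:16)
    res <- permanova(d, grp, n_perm = 99, seed = s)
    expect_lt(abs(sum(res$R2[res$term != "total"]) - 1), 1e-9)
    expect_equal(res$p_perm[1], 1 / 100)
  }
})

test_that("permutation p with n = 6 equals the brute-force all-permutations oracle", {
  for (s in 1:3) {
    pts <- withr::with_seed(s, matrix(rnorm(6 * 4), 6))
    d <- as.matrix(dist(pts)); dimnames(d) <- list(1:6, 1:6)
    grp <- rep(c("x", "y"), each = 3)
    mine <- permanova(d, grp, exact = TRUE)
    expect_equal(mine$p_perm[1], brute_permanova_p(d, grp), tolerance = 1e-12)
  }
})

test_that("p-values are exchangeable under factor-label relabeling", {
  pts <- withr::with_seed(4, matrix(rnorm(9 * 3), 9))
  d <- as.matrix(dist(pts)); dimnames(d) <- list(1:9, 1:9)
  grp <- rep(c("a", "b", "c"), each = 3)
  relab <- c(a = "z", b = "x", c = "y")[grp]
  r1 <- permanova(d, grp, n_perm = 199, seed = 2)
  r2 <- permanova(d, relab, n_perm = 199, seed = 2)
  expect_equal(r1$p_perm[1], r2$p_perm[1])
  expect_equal(r1$SS, r2$SS, tolerance = 1e-12)
})

test_that("pairwise_permanova enumerates level pairs and adjusts p", {
  pts <- withr::with_seed(11, matrix(rnorm(20 * 4), 20))
  grp <- rep(c("a", "b", "c", "e"), each = 5)
  pts[grp == "e", ] <- pts[grp == "e", ] + 15   # only one level separated
  d <- as.matrix(dist(pts)); dimnames(d) <- list(1:20, 1:20)
  res <- pairwise_permanova(d, grp, n_perm = 199, seed = 3)
  expect_equal(nrow(res), choose(4, 2))
  sig <- res$p_adj < 0.05
  involves_e <- res$level_a == "e" | res$level_b == "e"
  expect_true(all(sig[involves_e]))
  expect_false(any(sig[!involves_e]))

  # two levels: single comparison equals the global one-factor test
  keep <- grp %in% c("a", "b")
  dk <- d[keep, keep]
  one <- pairwise_permanova(dk, grp[keep], n_perm = 99, seed = 5)
  glob <- permanova(dk, grp[keep], n_perm = 99, seed = 5 + 1)
  expect_equal(nrow(one), 1)
  expect_equal(one$p_perm, glob$p_perm[1])
  expect_equal(one$p_adj, one$p_perm)
})
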