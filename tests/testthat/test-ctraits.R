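# Build a shifted clr matrix with prescribed per-carbon means for 1 ASV-free
# arithmetic checks of the simplex axes.
shifted_from_means <- function(means_by_carbon) {
  d <- small_design()
  n_asv <- length(means_by_carbon[[1]])
  m <- matrix(0, nrow(d), n_asv,
              dimnames = list(d$sample_id, sprintf("ASV%02d", seq_len(n_asv))))
  for (cb in names(means_by_carbon)) {
    m[d$carbon == cb & d$dose_pct == 1, ] <-
      matrix(means_by_carbon[[cb]], 3, n_asv, byrow = TRUE)
  }
  structure(m, shifted = TRUE, shift_constant = 0,
            class = c("clr_matrix", "matrix", "array"))
}

test_that("trait axes implement the normalized mean shifted-clr arithmetic", {
  sh <- shifted_from_means(list(cellulose = c(2, 1, 3, 0),
                                starch = c(1, 1, 0, 0),
                                sucrose = c(1, 1, 0, 0)))
  co <- trait_axes(sh, small_design(), dose = 1)
  expect_equal(unlist(co[1, c("c_ness", "st_ness", "su_ness")], use.names = FALSE),
               c(0.5, 0.25, 0.25))
  expect_equal(unlist(co[2, c("c_ness", "st_ness", "su_ness")], use.names = FALSE),
               rep(1 / 3, 3))
  expect_equal(unlist(co[3, c("c_ness", "st_ness", "su_ness")], use.names = FALSE),
               c(1, 0, 0))
  # all-zero denominator: excluded with a report entry, never silently dropped
  expect_equal(nrow(co), 3)
  expect_equal(attr(co, "excluded"), "ASV04")
})

test_that("simplex closure holds exactly for every retained ASV", {
  d <- build_design()
  sim <- simulate_counts(d, community_spec(n_asv = 120), seed = 9)
  filt <- prevalence_filter(sim$counts, 3)
  sh <- shift_nonnegative(clr_transform(filt))
  co <- trait_axes(sh, d)
  sums <- co$c_ness + co$st_ness + co$su_ness
  expect_lt(max(abs(sums - 1)), 1e-9)
  expect_true(all(co$c_ness >= 0 & co$c_ness <= 1))
  expect_true(all(co$st_ness >= 0 & co$st_ness <= 1))
  expect_true(all(co$su_ness >= 0 & co$su_ness <= 1))
})

test_that("ternary mapping sends vertices, centroid and edge midpoints correctly", {
  expect_equal(unlist(ternary_xy(c(1, 0, 0))), c(x = 0, y = 0))
  expect_equal(unlist(ternary_xy(c(0, 1, 0))), c(x = 1, y = 0))
  expect_equal(unlist(ternary_xy(c(0, 0, 1))), c(x = 0.5, y = sqrt(3) / 2))
  expect_equal(unlist(ternary_xy(c(1, 1, 1) / 3)), c(x = 0.5, y = sqrt(3) / 6))
  expect_equal(unlist(ternary_xy(c(0.5, 0.5, 0))), c(x = 0.5, y = 0))
  expect_error(ternary_xy(c(0.7, 0.7, 0.1)), "simplex")
})

test_that("diff_abundance agrees with stats::t.test and flags planted responders", {
  d <- build_design()
  spec <- community_spec(n_asv = 100, responder_axes = "sucrose")
  sim <- simulate_counts(d, spec, seed = 21)
  filt <- prevalence_filter(sim$counts, 3)
  da <- diff_abundance(filt, d, "sucrose")

  # cross-check the Welch p-values against stats::t.test on the same clr values
  clr <- clr_transform(filt)
  dd <- d[match(rownames(filt), d$sample_id), ]
  trt <- dd$carbon == "sucrose" & dd$dose_pct == 1
  ctl <- dd$carbon == "control"
  for (j in sample(ncol(filt), 10)) {
    ref <- t.test(clr[trt, j], clr[ctl, j])
    expect_equal(da$p[j], ref$p.value, tolerance = 1e-10)
    expect_equal(da$effect[j], unname(diff(rev(ref$estimate))), tolerance = 1e-10)
  }

  # planted sucrose effects (responders plus structural absences) dominate
  # the significant set
  hits <- da$asv_id[da$significant]
  truth_ids <- union(sim$responders,
                     sim$structural_zeros$asv_id[sim$structural_zeros$carbon == "sucrose"])
  expect_gt(length(hits), 0)
  expect_gt(mean(hits %in% truth_ids), 0.7)
  expect_gt(mean(sim$responders %in% hits), 0.7)
})

test_that("diff_abundance makes no calls when group means are identical", {
  d <- small_design()
  m <- matrix(rep(c(5L, 9L, 14L, 21L), each = nrow(d)), nrow(d), 4,
              dimnames = list(d$sample_id, paste0("ASV", 1:4)))
  da <- diff_abundance(m, d, "starch")
  expect_false(any(da$significant))
  expect_true(all(da$p == 1))
})

test_that("null tables keep the empirical discovery fraction near the nominal level", {
  d <- build_design()
  spec <- community_spec(n_asv = 60, responder_fraction = 0, structural_zero_rate = 0)
  frac <- vapply(1:60, function(s) {
    sim <- simulate_counts(d, spec, seed = 100 + s)
    da <- diff_abundance(sim$counts, d, "sucrose")
    mean(da$q <= 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.05)
})

test_that("assign_traits applies the class taxonomy", {
  coords <- data.frame(asv_id = c("a", "b", "c", "d", "e"),
                       c_ness = 0.2, st_ness = 0.3, su_ness = 0.5,
                       stringsAsFactors = FALSE)
  mk <- function(id, axis, sig, dir) {
    data.frame(asv_id = id, axis = axis, effect = ifelse(dir == "+", 1, -1),
               p = ifelse(sig, 0.001, 0.5), q = ifelse(sig, 0.01, 0.6),
               significant = sig, direction = dir, stringsAsFactors = FALSE)
  }
  da <- rbind(
    mk("a", "sucrose", TRUE, "+"), mk("a", "starch", TRUE, "+"), mk("a", "cellulose", TRUE, "+"),
    mk("b", "sucrose", FALSE, "+"), mk("b", "starch", FALSE, "-"), mk("b", "cellulose", FALSE, "+"),
    mk("c", "sucrose", TRUE, "+"), mk("c", "starch", FALSE, "+"), mk("c", "cellulose", FALSE, "+"),
    mk("d", "sucrose", TRUE, "-"), mk("d", "starch", TRUE, "-"), mk("d", "cellulose", TRUE, "-"),
    mk("e", "sucrose", TRUE, "+"), mk("e", "starch", TRUE, "-"), mk("e", "cellulose", FALSE, "+")
  )
  out <- assign_traits(coords, da)
  expect_equal(out$class_label[match(c("a", "b", "c", "d", "e"), out$asv_id)],
               c("triple+", "none", "single+", "triple-", "mixed"))
  expect_error(assign_traits(coords[-1, ], da[da$asv_id != "b", ]), "mismatch")
})

test_that("summarize_traits reproduces reported percentage arithmetic", {
  expect_equal(percent_responding(173, 1503), 12)
  expect_equal(percent_responding(22, 293), 8)
  expect_equal(percent_responding(6, 648), 1)
  expect_equal(percent_responding(165, 173), 95)

  # zero responders: everything 0
  coords <- data.frame(asv_id = c("a", "b"), c_ness = 1 / 3, st_ness = 1 / 3,
                       su_ness = 1 / 3, stringsAsFactors = FALSE)
  da <- do.call(rbind, lapply(c("sucrose", "starch", "cellulose"), function(ax) {
    data.frame(asv_id = c("a", "b"), axis = ax, effect = 0, p = 1, q = 1,
               significant = FALSE, direction = "+", stringsAsFactors = FALSE)
  }))
  s <- summarize_traits(assign_traits(coords, da))
  expect_equal(s$overall$pct_responding, 0)
  expect_true(all(s$by_axis$n_involved == 0))
})

test_that("permuting carbon labels destroys responder recovery", {
  d <- build_design()
  spec <- community_spec(n_asv = 100, responder_axes = "sucrose")
  sens <- vapply(1:5, function(s) {
    sim <- simulate_counts(d, spec, seed = 300 + s)
    # break the sample-to-treatment link by shuffling the metadata assignment
    dp <- d
    dp$sample_id <- withr::with_seed(s, sample(d$sample_id))
    counts <- sim$counts[match(dp$sample_id, rownames(sim$counts)), ]
    da <- diff_abundance(counts, dp, "sucrose")
    mean(sim$responders %in% da$asv_id[da$significant])
  }, numeric(1))
  expect_lte(mean(sens), 0.15)
})
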