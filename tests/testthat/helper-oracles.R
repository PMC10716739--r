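# independent one-factor PERMANOVA oracle: within-group sums of squared
# distances (Anderson 2001), enumerating label permutations
brute_permanova_p <- function(d, groups) {
  n <- nrow(d)
  ss_total <- sum(d[upper.tri(d)]^2) / n
  f_of <- function(g) {
    ss_w <- sum(vapply(unique(g), function(lv) {
      idx <- which(g == lv)
      sum(d[idx, idx][upper.tri(d[idx, idx])]^2) / length(idx)
    }, numeric(1)))
    a <- length(unique(g))
    ((ss_total - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_of(groups)
  perms <- ctraitkit:::all_perms(n)
  mean(vapply(perms, function(p) f_of(groups[p]) >= f_obs - 1e-12, logical(1)))
}
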