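# Small deterministic fixtures shared across test files.

tiny_counts <- function() {
  m <- matrix(c(10, 0, 3, 7,
                12, 1, 0, 9,
                8, 0, 4, 6,
                11, 2, 5, 0,
                9, 0, 0, 8,
                10, 1, 6, 7),
              nrow = 6, byrow = TRUE,
              dimnames = list(paste0("s", 1:6), paste0("ASV", 1:4)))
  storage.mode(m) <- "integer"
  m
}

# design with 3 replicates of each carbon at 1% plus 3 controls (12 samples)
small_design <- function() build_design(n_blocks = 3, doses = 1)

noiseless_series <- function(slope = -2, c0 = 100, n = 5, window = 20) {
  t <- seq(0, window, length.out = n)
  headspace_series("fix", 0, t, c0 + slope * t)
}
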