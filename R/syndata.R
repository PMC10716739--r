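#' Build a blocked carbon-amendment experimental design
#'
#' Constructs the full factorial layout blocks x carbon sources x doses, plus
#' one unamended control microcosm per block (dose 0, carbon "control"). The
#' default arguments reproduce the 39-microcosm layout of the study system
#' this package emulates: 3 blocks x 3 carbons x 4 doses + 3 controls.
#'
#' @param n_blocks number of independent experimental blocks (labelled A, B, ...).
#' @param carbons character vector of amendment carbon sources.
#' @param doses numeric vector of amendment doses in %C-equivalent per gram of
#'   dry soil; must be positive and distinct (the 0-dose control is added
#'   automatically).
#' @return A data.frame of class `experiment_design` with columns
#'   `sample_id`, `block`, `carbon`, `dose_pct`, ordered by (block, carbon, dose).
#' @export
#' @examples
#' d <- build_design()
#' nrow(d)  # 39
build_design <- function(n_blocks = 3,
                         carbons = c("sucrose", "starch", "cellulose"),
                         doses = c(0.1, 1, 3, 5)) {
  stopifnot(length(n_blocks) == 1, n_blocks >= 1,
            length(carbons) >= 1, is.character(carbons),
            length(doses) >= 1, is.numeric(doses))
  if (anyDuplicated(doses)) {
    stop("duplicate dose values: ", paste(unique(doses[duplicated(doses)]), collapse = ", "))
  }
  if (any(doses <= 0)) {
    stop("doses must be positive; the dose-0 control is added automatically")
  }
  if ("control" %in% carbons) stop("'control' is reserved for the unamended microcosms")
  blocks <- make.unique(rep(LETTERS, length.out = n_blocks), sep = "")
  grid <- expand.grid(dose_pct = doses, carbon = carbons, block = blocks,
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  ctrl <- data.frame(dose_pct = 0, carbon = "control", block = blocks,
                     stringsAsFactors = FALSE)
  des <- rbind(grid, ctrl)
  des <- des[order(des$block, des$carbon, des$dose_pct), c("block", "carbon", "dose_pct")]
  des$sample_id <- sprintf("%s_%s_%g", des$block, des$carbon, des$dose_pct)
  des <- des[, c("sample_id", "block", "carbon", "dose_pct")]
  rownames(des) <- NULL
  class(des) <- c("experiment_design", "data.frame")
  des
}

validate_design <- function(design) {
  stopifnot(is.data.frame(design))
  need <- c("sample_id", "block", "carbon", "dose_pct")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design is missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  bad <- xor(design$carbon == "control", design$dose_pct == 0)
  if (any(bad)) {
    stop("dose_pct must be 0 exactly for control samples (offending sample_id: ",
         paste(design$sample_id[bad], collapse = ", "), ")")
  }
  invisible(design)
}

#' Specify a synthetic amplicon community
#'
#' Parameters of the negative-binomial count generator used by
#' [simulate_counts()]. Defaults describe a moderately diverse community
#' sequenced at typical MiSeq amplicon depth with the low replicate-to-replicate
#' noise of controlled laboratory microcosms.
#'
#' @param n_asv number of ASVs (>= 10).
#' @param baseline_log_abundance optional per-ASV log-scale mean relative
#'   intensity; when `NULL` it is drawn Normal(0, 0.8) from the simulation seed.
#' @param dispersion negative-binomial shape (`size`) per ASV; larger is less
#'   overdispersed. Scalar recycled to all ASVs.
#' @param library_size_mean,library_size_cv lognormal library-size model.
#' @param responder_fraction fraction of ASVs planted as treatment responders.
#' @param effect_log_fold log fold-change magnitude of responders at the 1%
#'   anchor dose; effects scale linearly in log-fold with dose.
#' @param responder_axes carbon axes a responder may react to; by default each
#'   responder is assigned one axis drawn uniformly from the three amendment
#'   carbons. Supply e.g. `"sucrose"` to plant all responders on one axis.
#' @param prob_positive probability that a planted responder is enriched
#'   (rather than depleted); default 2/3, matching the roughly 2:1
#'   enrichment:depletion ratio observed among sucrose responders in soil.
#' @param structural_zero_rate probability that a non-responder ASV is
#'   structurally absent from a given amendment carbon.
#' @return list of class `community_spec`.
#' @export
community_spec <- function(n_asv = 300,
                           baseline_log_abundance = NULL,
                           dispersion = 100,
                           library_size_mean = 1e5,
                           library_size_cv = 0.3,
                           responder_fraction = 0.1,
                           effect_log_fold = 1.5,
                           responder_axes = NULL,
                           prob_positive = 2/3,
                           structural_zero_rate = 0.05) {
  stopifnot(n_asv >= 10,
            is.null(baseline_log_abundance) || length(baseline_log_abundance) == n_asv,
            all(dispersion > 0),
            library_size_mean > 0, library_size_cv > 0,
            responder_fraction >= 0, responder_fraction <= 1,
            prob_positive >= 0, prob_positive <= 1,
            structural_zero_rate >= 0, structural_zero_rate <= 1)
  if (!is.null(responder_axes)) {
    stopifnot(all(responder_axes %in% c("sucrose", "starch", "cellulose")))
  }
  structure(list(n_asv = n_asv,
                 baseline_log_abundance = baseline_log_abundance,
                 dispersion = rep_len(dispersion, n_asv),
                 library_size_mean = library_size_mean,
                 library_size_cv = library_size_cv,
                 responder_fraction = responder_fraction,
                 effect_log_fold = effect_log_fold,
                 responder_axes = responder_axes,
                 prob_positive = prob_positive,
                 structural_zero_rate = structural_zero_rate),
            class = "community_spec")
}

#' Simulate an ASV count table with planted treatment responders
#'
#' Draws negative-binomial counts around per-ASV baselines. A planted responder
#' ASV has its expected count multiplied by `exp(direction * effect_log_fold *
#' dose_pct)` in samples of its responder carbon(s) (linear-in-dose log-fold,
#' anchored at the 1% dose). Library sizes are lognormal. Structural zeros are
#' injected per (non-responder ASV, carbon) pair. Identical
#' `(design, spec, seed)` give an identical table.
#'
#' @param design an `experiment_design` from [build_design()].
#' @param spec a [community_spec()].
#' @param seed integer seed for this draw.
#' @return list with elements
#'   \describe{
#'     \item{counts}{integer matrix samples x ASVs, dimnames set.}
#'     \item{truth}{data.frame (asv_id, axis, direction, log_fold), one row per
#'       responder x axis; the ground truth for recovery tests.}
#'     \item{responders}{character vector of responder ASV ids.}
#'     \item{structural_zeros}{data.frame (asv_id, carbon) of non-responder
#'       ASVs made structurally absent from a carbon; these are genuine
#'       treatment effects and belong to the ground truth of recovery tests.}
#'   }
#' @export
simulate_counts <- function(design, spec = community_spec(), seed = 1) {
  validate_design(design)
  stopifnot(inherits(spec, "community_spec"))
  n_asv <- spec$n_asv
  n_s <- nrow(design)
  asv_ids <- sprintf("ASV%04d", seq_len(n_asv))
  with_seed(seed, {
    base <- spec$baseline_log_abundance %||% stats::rnorm(n_asv, 0, 0.8)
    p <- exp(base) / sum(exp(base))

    n_resp <- round(spec$responder_fraction * n_asv)
    resp_idx <- if (n_resp > 0) sort(sample.int(n_asv, n_resp)) else integer(0)
    axes_pool <- spec$responder_axes %||% c("sucrose", "starch", "cellulose")
    truth <- if (n_resp > 0) {
      data.frame(
        asv_id = asv_ids[resp_idx],
        axis = sample(axes_pool, n_resp, replace = TRUE),
        direction = sample(c("+", "-"), n_resp, replace = TRUE,
                           prob = c(spec$prob_positive, 1 - spec$prob_positive)),
        stringsAsFactors = FALSE
      )
    } else {
      data.frame(asv_id = character(0), axis = character(0),
                 direction = character(0), stringsAsFactors = FALSE)
    }
    truth$log_fold <- ifelse(truth$direction == "+", 1, -1) * spec$effect_log_fold

    sdlog <- sqrt(log(1 + spec$library_size_cv^2))
    L <- stats::rlnorm(n_s, log(spec$library_size_mean) - sdlog^2 / 2, sdlog)

    # log fold effect per (sample, ASV)
    delta <- matrix(0, n_s, n_asv)
    if (n_resp > 0) {
      for (r in seq_len(nrow(truth))) {
        j <- match(truth$asv_id[r], asv_ids)
        hit <- design$carbon == truth$axis[r] & design$dose_pct > 0
        delta[hit, j] <- delta[hit, j] + truth$log_fold[r] * design$dose_pct[hit]
      }
    }

    mu <- outer(L, p) * exp(delta)
    counts <- matrix(stats::rnbinom(n_s * n_asv, mu = mu,
                                    size = rep(spec$dispersion, each = n_s)),
                     n_s, n_asv)

    # structural zeros: a non-responder ASV may be absent from a carbon entirely
    szero <- data.frame(asv_id = character(0), carbon = character(0),
                        stringsAsFactors = FALSE)
    if (spec$structural_zero_rate > 0) {
      nonresp <- setdiff(seq_len(n_asv), resp_idx)
      for (cb in setdiff(unique(design$carbon), "control")) {
        hit <- which(stats::runif(length(nonresp)) < spec$structural_zero_rate)
        if (length(hit)) {
          counts[design$carbon == cb, nonresp[hit]] <- 0L
          szero <- rbind(szero, data.frame(asv_id = asv_ids[nonresp[hit]],
                                           carbon = cb, stringsAsFactors = FALSE))
        }
      }
    }

    dimnames(counts) <- list(design$sample_id, asv_ids)
    storage.mode(counts) <- "integer"
    list(counts = counts, truth = truth, responders = truth$asv_id,
         structural_zeros = szero)
  })
}

#' Specify headspace H2 decay kinetics
#'
#' Physical and sampling parameters for [simulate_headspace()]. Defaults match
#' the microcosm assay emulated here: 125 ml bottles with 10 g dry soil
#' (117.5 ml headspace), 25 degC, 1 atm, initial H2 mixing ratio 482 ppbv,
#' 5-6 GC observations within a 20-minute window.
#'
#' @param true_rate H2 oxidation rate in nmol per g dry soil per hour
#'   (negative = net emission).
#' @param c0_ppbv initial headspace H2 mixing ratio (ppbv).
#' @param noise_sd_ppbv additive Gaussian noise on each concentration reading.
#' @param n_points number of GC observations, 5 or 6.
#' @param window_min total measurement window in minutes (<= 20).
#' @param soil_dw_g dry soil mass (g).
#' @param headspace_ml headspace volume (ml).
#' @param temp_K temperature (K).
#' @param pressure_atm pressure (atm).
#' @return list of class `kinetics_spec`.
#' @export
kinetics_spec <- function(true_rate = 0.75, c0_ppbv = 482, noise_sd_ppbv = 5,
                          n_points = 6, window_min = 15, soil_dw_g = 10,
                          headspace_ml = 117.5, temp_K = 298.15,
                          pressure_atm = 1) {
  stopifnot(n_points %in% c(5L, 6L), window_min > 0, window_min <= 20,
            c0_ppbv > 0, noise_sd_ppbv >= 0, soil_dw_g > 0, headspace_ml > 0,
            temp_K > 0, pressure_atm > 0)
  structure(list(true_rate = true_rate, c0_ppbv = c0_ppbv,
                 noise_sd_ppbv = noise_sd_ppbv, n_points = as.integer(n_points),
                 window_min = window_min, soil_dw_g = soil_dw_g,
                 headspace_ml = headspace_ml, temp_K = temp_K,
                 pressure_atm = pressure_atm),
            class = "kinetics_spec")
}

#' Simulate a headspace H2 concentration time series
#'
#' Inverts the ideal-gas flux conversion of [rate_from_slope()]: the noiseless
#' series decays linearly at the slope (ppbv per minute) whose conversion
#' equals `kin$true_rate`. Gaussian noise is added on concentration.
#' Timestamps are equally spaced on `[0, window_min]`.
#'
#' @param kin a [kinetics_spec()].
#' @param seed integer seed.
#' @param sample_id,day identifiers carried on the series.
#' @return a `headspace_series` (see [headspace_series()]).
#' @export
simulate_headspace <- function(kin = kinetics_spec(), seed = 1,
                               sample_id = "sim", day = 0L) {
  stopifnot(inherits(kin, "kinetics_spec"))
  slope <- -slope_for_rate(kin$true_rate, soil_dw_g = kin$soil_dw_g,
                           headspace_ml = kin$headspace_ml, temp_K = kin$temp_K,
                           pressure_atm = kin$pressure_atm)
  t <- seq(0, kin$window_min, length.out = kin$n_points)
  c_noiseless <- kin$c0_ppbv + slope * t
  c_obs <- with_seed(seed, c_noiseless + stats::rnorm(kin$n_points, 0, kin$noise_sd_ppbv))
  c_obs <- pmax(c_obs, 0)
  headspace_series(sample_id = sample_id, day = day, t_min = t, c_ppbv = c_obs,
                   soil_dw_g = kin$soil_dw_g, headspace_ml = kin$headspace_ml,
                   temp_K = kin$temp_K, pressure_atm = kin$pressure_atm)
}

#' Write a simulated experiment to a fixture directory
#'
#' Emits the plain-text bundle consumed by the readers in this package:
#' `counts_<gene>.tsv`, `metadata.tsv`, `truth.tsv`, and
#' `headspace/<sample>_<day>.csv` files.
#'
#' @param dir output directory (created if missing).
#' @param design experiment design.
#' @param counts list of count matrices named by gene (e.g. `list(s16 = ...)`),
#'   or a single matrix (written as `counts_asv.tsv`).
#' @param truth optional ground-truth data.frame.
#' @param headspace optional list of `headspace_series`.
#' @param seed seed recorded in output headers.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, design, counts, truth = NULL,
                             headspace = NULL, seed = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_stage(as.data.frame(design), file.path(dir, "metadata.tsv"),
                  "simulate", seed = seed)
  if (is.matrix(counts)) counts <- list(asv = counts)
  for (gene in names(counts)) {
    df <- data.frame(sample_id = rownames(counts[[gene]]),
                     counts[[gene]], check.names = FALSE)
    write_tsv_stage(df, file.path(dir, sprintf("counts_%s.tsv", gene)),
                    "simulate", seed = seed)
  }
  if (!is.null(truth)) {
    write_tsv_stage(truth, file.path(dir, "truth.tsv"), "simulate", seed = seed)
  }
  if (!is.null(headspace)) {
    hdir <- file.path(dir, "headspace")
    dir.create(hdir, showWarnings = FALSE)
    for (s in headspace) {
      utils::write.csv(data.frame(minutes = s$t_min, ppbv = s$c_ppbv),
                       file.path(hdir, sprintf("%s_%d.csv", s$sample_id, s$day)),
                       row.names = FALSE, quote = FALSE)
    }
  }
  invisible(dir)
}
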