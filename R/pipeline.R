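# End-to-end driver: simulate (or read) -> flux -> filter -> ctraits ->
# diversity -> permanova, with stage logging and a JSON run report.

# Default per-treatment median H2 oxidation rates (nmol g_dw^-1 h^-1) used by
# the synthetic headspace stage; these are the study-system medians the
# generator emulates (control 0.75; sucrose strongly dose-suppressed).
default_rate_table <- function() {
  data.frame(
    carbon = c("control",
               rep("starch", 4), rep("cellulose", 4), rep("sucrose", 4)),
    dose_pct = c(0, 0.1, 1, 3, 5, 0.1, 1, 3, 5, 0.1, 1, 3, 5),
    true_rate = c(0.75,
                  0.74, 0.74, 0.75, 0.71,
                  0.71, 0.74, 0.80, 0.52,
                  0.75, 0.36, 0.10, 0.06),
    stringsAsFactors = FALSE
  )
}

#' Configuration of an end-to-end run
#'
#' Bundles the thresholds, seeds and (optional) input paths of
#' [run_pipeline()]. When `counts_path` is `NULL` the run is synthetic: a
#' community and headspace series are generated from `seed`.
#'
#' @param out_dir output directory.
#' @param seed master seed (stage seeds are derived from it).
#' @param counts_path,metadata_path,headspace_dir optional input paths; all
#'   `NULL` for a synthetic run.
#' @param abund_threshold,prev_min_nonzero table-filter settings.
#' @param alpha significance gate of the flux estimator.
#' @param q_threshold differential-abundance significance cut.
#' @param dose trait-contrast dose (%C eq).
#' @param n_perm PERMANOVA permutations.
#' @param spec [community_spec()] for synthetic runs.
#' @param rate_table per-(carbon, dose) true rates for the synthetic headspace
#'   stage; defaults to the study-system medians.
#' @param measurement_days incubation days of the weekly GC assays.
#' @return list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1,
                       counts_path = NULL, metadata_path = NULL,
                       headspace_dir = NULL,
                       abund_threshold = 0.00005, prev_min_nonzero = 3,
                       alpha = 0.05, q_threshold = 0.05, dose = 1,
                       n_perm = 999, spec = community_spec(),
                       rate_table = default_rate_table(),
                       measurement_days = seq(0, 42, by = 6)) {
  stopifnot(abund_threshold >= 0, abund_threshold < 1, prev_min_nonzero >= 1,
            alpha > 0, alpha <= 1, q_threshold > 0, q_threshold <= 1,
            n_perm >= 1)
  if (q_threshold >= 1) warning("q_threshold = 1: every tested ASV will be called significant")
  structure(list(out_dir = out_dir, seed = seed,
                 counts_path = counts_path, metadata_path = metadata_path,
                 headspace_dir = headspace_dir,
                 abund_threshold = abund_threshold,
                 prev_min_nonzero = prev_min_nonzero,
                 alpha = alpha, q_threshold = q_threshold, dose = dose,
                 n_perm = n_perm, spec = spec, rate_table = rate_table,
                 measurement_days = measurement_days),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields of [run_config()] may be set in the file; unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @param out_dir output directory (overrides any value in the file).
#' @return `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  cfg <- yaml::read_yaml(path)
  allowed <- setdiff(names(formals(run_config)), c("spec", "rate_table"))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  if (is.null(cfg$out_dir)) stop("config must provide out_dir")
  do.call(run_config, cfg)
}

log_stage <- function(con, stage, ...) {
  msg <- sprintf("[%s] %s", stage, sprintf(...))
  message(msg)
  if (!is.null(con)) writeLines(paste(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), msg), con)
}

#' Run the full analysis pipeline
#'
#' Chains simulation (or input reading), flux estimation, table filtering,
#' carbon-preference trait assignment, Hill diversity and PERMANOVA, writing
#' every stage table plus `run.log` and `report.json` under
#' `config$out_dir`. Identical configuration and seed give identical outputs.
#'
#' @param config a [run_config()].
#' @return invisible list of the stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$out_dir, "run.log"), "w")
  on.exit(close(logf))
  seed <- config$seed

  # --- inputs ---------------------------------------------------------------
  synthetic <- is.null(config$counts_path)
  if (synthetic) {
    log_stage(logf, "simulate", "synthetic run, seed %d, %d ASVs",
              seed, config$spec$n_asv)
    design <- build_design()
    sim <- simulate_counts(design, config$spec, seed = seed)
    counts <- sim$counts
    rt <- config$rate_table
    series <- list()
    for (i in seq_len(nrow(design))) {
      key <- rt$carbon == design$carbon[i] & rt$dose_pct == design$dose_pct[i]
      if (!any(key)) stop("no true rate configured for ",
                          design$carbon[i], " at dose ", design$dose_pct[i])
      for (d in config$measurement_days) {
        kin <- kinetics_spec(true_rate = rt$true_rate[key])
        series[[length(series) + 1L]] <- simulate_headspace(
          kin, seed = seed + 7919L * i + d,
          sample_id = design$sample_id[i], day = d)
      }
    }
    write_simulation(config$out_dir, design, list(asv = counts),
                     truth = sim$truth, seed = seed)
  } else {
    design <- read_metadata(config$metadata_path)
    counts <- read_counts(config$counts_path)
    series <- if (!is.null(config$headspace_dir)) read_headspace(config$headspace_dir) else list()
    sim <- NULL
    log_stage(logf, "read", "%d samples, %d ASVs", nrow(counts), ncol(counts))
  }

  # --- flux -----------------------------------------------------------------
  rates <- NULL
  rate_summary <- NULL
  if (length(series)) {
    rates <- do.call(rbind, lapply(series, estimate_rate, alpha = config$alpha))
    rate_summary <- summarize_rates(rates)
    write_tsv_stage(rates, file.path(config$out_dir, "rates.tsv"), "flux",
                    list(alpha = config$alpha), seed)
    write_tsv_stage(rate_summary, file.path(config$out_dir, "rate_summary.tsv"),
                    "flux", list(alpha = config$alpha), seed)
    log_stage(logf, "flux", "%d series, %d gated to zero",
              nrow(rates), sum(rates$gated))
  }

  # --- filters --------------------------------------------------------------
  n0 <- ncol(counts)
  filtered <- abundance_filter(counts, config$abund_threshold)
  filtered <- prevalence_filter(filtered, config$prev_min_nonzero)
  flog <- filter_log(filtered)
  write_tsv_stage(flog, file.path(config$out_dir, "filter_log.tsv"), "filter",
                  list(abund = config$abund_threshold,
                       prev = config$prev_min_nonzero), seed)
  write_counts(filtered, file.path(config$out_dir, "counts_filtered.tsv"),
               "filter", list(abund = config$abund_threshold,
                              prev = config$prev_min_nonzero), seed)
  log_stage(logf, "filter", "ASVs in=%d removed=%d out=%d",
            n0, nrow(flog), ncol(filtered))
  stopifnot(n0 - nrow(flog) == ncol(filtered))

  bias_groups <- interaction(design$carbon[match(rownames(filtered), design$sample_id)])
  bias <- library_size_bias(filtered, bias_groups)
  log_stage(logf, "filter", "library-size bias: H=%.3f p=%.3f", bias$H, bias$p)

  # --- carbon-preference traits --------------------------------------------
  clr <- clr_transform(filtered)
  shifted <- shift_nonnegative(clr)
  coords <- trait_axes(shifted, design, dose = config$dose)
  da <- diff_abundance_all(filtered, design, dose = config$dose,
                           q_threshold = config$q_threshold)
  assignments <- assign_traits(coords, da)
  tsum <- summarize_traits(assignments)
  xy <- ternary_xy(coords)
  coords_out <- cbind(coords, xy[, c("x", "y")])
  write_tsv_stage(coords_out, file.path(config$out_dir, "trait_coords.tsv"),
                  "ctrait", list(dose = config$dose), seed)
  write_tsv_stage(da, file.path(config$out_dir, "da_results.tsv"),
                  "ctrait", list(q = config$q_threshold), seed)
  write_tsv_stage(assignments, file.path(config$out_dir, "trait_assignments.tsv"),
                  "ctrait", list(dose = config$dose, q = config$q_threshold), seed)
  write_tsv_stage(tsum$by_axis, file.path(config$out_dir, "trait_summary.tsv"),
                  "ctrait", list(dose = config$dose, q = config$q_threshold), seed)
  log_stage(logf, "ctrait", "%d/%d ASVs responding (%d%%)",
            tsum$overall$n_responding, tsum$overall$n_asv,
            tsum$overall$pct_responding)

  # --- diversity ------------------------------------------------------------
  div <- hill_diversity(filtered)
  write_tsv_stage(div, file.path(config$out_dir, "diversity.tsv"),
                  "diversity", NULL, seed)
  log_stage(logf, "diversity", "%d sample x order rows", nrow(div))

  # --- community structure --------------------------------------------------
  hel <- hellinger(filtered)
  d <- bray_curtis(hel)
  design_m <- design[match(rownames(filtered), design$sample_id), ]
  perm <- permanova(d, data.frame(carbon_type = design_m$carbon,
                                  carbon_dose = factor(design_m$dose_pct)),
                    n_perm = config$n_perm, seed = seed + 1L)
  write_tsv_stage(perm, file.path(config$out_dir, "permanova.tsv"),
                  "permanova", list(n_perm = config$n_perm), seed)
  ord <- pcoa(d)
  write_tsv_stage(data.frame(sample_id = rownames(ord$coordinates),
                             ord$coordinates, check.names = FALSE),
                  file.path(config$out_dir, "pcoa_coords.tsv"),
                  "permanova", NULL, seed)
  log_stage(logf, "permanova", "carbon_type R2=%.3f p=%.3f",
            perm$R2[1], perm$p_perm[1])

  # --- report ---------------------------------------------------------------
  report <- list(
    seed = seed,
    synthetic = synthetic,
    n_samples = nrow(counts), n_asv_in = n0, n_asv_filtered = ncol(filtered),
    library_size_bias = bias,
    trait_summary = tsum$overall,
    permanova = perm[, c("term", "df", "R2", "p_perm")],
    n_rate_series = if (is.null(rates)) 0 else nrow(rates)
  )
  write_report(report, file.path(config$out_dir, "report.json"))
  log_stage(logf, "done", "outputs in %s", config$out_dir)

  invisible(list(design = design, counts = counts, filtered = filtered,
                 truth = if (synthetic) sim$truth else NULL,
                 rates = rates, rate_summary = rate_summary,
                 coords = coords, da = da, assignments = assignments,
                 trait_summary = tsum, diversity = div,
                 permanova = perm, pcoa = ord))
}
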