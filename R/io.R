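# Readers and writers for the plain-text dialects used throughout the
# pipeline. All tables are TSV with a provenance header comment; headspace
# series are per-file CSV (minutes, ppbv).

.CARBON_LEVELS <- c("control", "sucrose", "starch", "cellulose")

#' Read an ASV count table
#'
#' Expects a TSV whose first column is `sample_id` and remaining columns are
#' ASV counts (non-negative integers). Header comment lines (`#`) are skipped.
#'
#' @param path file path.
#' @return integer matrix samples x ASVs.
#' @export
read_counts <- function(path) {
  df <- read_tsv_stage(path)
  if (names(df)[1] != "sample_id") {
    stop("first column of ", path, " must be 'sample_id', found '", names(df)[1], "'")
  }
  if (anyDuplicated(df$sample_id)) stop("duplicate sample_id in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  bad <- which(m < 0 | m != floor(m), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-integer or negative count at row %d (sample %s), column '%s' in %s",
                 bad[1, 1], df$sample_id[bad[1, 1]], colnames(m)[bad[1, 2]], path))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample_id
  validate_counts(m)
  m
}

#' Write an ASV count table
#'
#' @param counts sample x ASV matrix.
#' @param path output path.
#' @param stage,params,seed provenance recorded in the header comment.
#' @export
write_counts <- function(counts, path, stage = "filter", params = NULL, seed = NULL) {
  validate_counts(counts)
  df <- data.frame(sample_id = rownames(counts), counts, check.names = FALSE)
  write_tsv_stage(df, path, stage, params, seed)
}

#' Read a sample metadata table as an experiment design
#'
#' Validates the carbon categories and the control/dose-0 correspondence;
#' malformed values are rejected with the offending cell named.
#'
#' @param path TSV with columns sample_id, block, carbon, dose_pct.
#' @return `experiment_design` data.frame.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_stage(path)
  need <- c("sample_id", "block", "carbon", "dose_pct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, " is missing columns: ", paste(miss, collapse = ", "))
  bad <- which(!df$carbon %in% .CARBON_LEVELS)
  if (length(bad)) {
    stop(sprintf("unknown carbon '%s' at line %d of %s (allowed: %s)",
                 df$carbon[bad[1]], bad[1], path, paste(.CARBON_LEVELS, collapse = ", ")))
  }
  if (!is.numeric(df$dose_pct)) stop("dose_pct must be numeric in ", path)
  des <- df[, need]
  class(des) <- c("experiment_design", "data.frame")
  validate_design(des)
  des
}

#' Read headspace time series from a directory
#'
#' Reads every `<sample>_<day>.csv` (columns `minutes`, `ppbv`) in `dir` and
#' builds validated [headspace_series()] objects; files violating the 5-6
#' point / 20-minute assay contract are rejected with their name.
#'
#' @param dir directory of CSV files.
#' @param soil_dw_g,headspace_ml,temp_K,pressure_atm physical constants
#'   applied to every series.
#' @return list of `headspace_series`.
#' @export
read_headspace <- function(dir, soil_dw_g = 10, headspace_ml = 117.5,
                           temp_K = 298.15, pressure_atm = 1) {
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  if (!length(files)) stop("no headspace CSV files found in ", dir)
  lapply(files, function(f) {
    base <- sub("\\.csv$", "", basename(f))
    m <- regmatches(base, regexec("^(.*)_([0-9]+)$", base))[[1]]
    if (length(m) != 3) stop("headspace file name '", basename(f),
                             "' does not match <sample>_<day>.csv")
    df <- utils::read.csv(f)
    if (!all(c("minutes", "ppbv") %in% names(df))) {
      stop(f, " must have columns 'minutes' and 'ppbv'")
    }
    tryCatch(
      headspace_series(sample_id = m[2], day = as.integer(m[3]),
                       t_min = df$minutes, c_ppbv = df$ppbv,
                       soil_dw_g = soil_dw_g, headspace_ml = headspace_ml,
                       temp_K = temp_K, pressure_atm = pressure_atm),
      error = function(e) stop("invalid headspace series in ", basename(f),
                               ": ", conditionMessage(e), call. = FALSE)
    )
  })
}

#' Write a run report
#'
#' Serializes a (possibly nested) list of results as JSON.
#'
#' @param results named list.
#' @param path output path.
#' @export
write_report <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
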