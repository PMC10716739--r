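# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream (one stream per operation; no global seed state).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero (the
#' convention used when reporting responder percentages), unlike base
#' [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector.
#' @export
#' @examples
#' round_half_up(0.5)   # 1
#' round_half_up(11.51) # 12
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Write a stage table as TSV with a provenance header
#'
#' Pipeline stage outputs are tab-separated tables whose first line is a
#' comment of the form `# ctraitkit stage=<stage> [param=value ...] [seed=N]`,
#' so every file records how it was produced.
#'
#' @param df data frame to write.
#' @param path output file path.
#' @param stage short stage name recorded in the header.
#' @param params optional named list of parameters to record.
#' @param seed optional seed to record.
#' @return the path, invisibly.
#' @seealso [read_tsv_stage()]
#' @export
write_tsv_stage <- function(df, path, stage, params = NULL, seed = NULL) {
  hdr <- sprintf("# ctraitkit stage=%s%s%s",
                 stage,
                 if (length(params)) paste0(" ", paste(names(params), unlist(params),
                                                       sep = "=", collapse = " ")) else "",
                 if (!is.null(seed)) paste0(" seed=", seed) else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-headed stage TSV
#'
#' @param path file written by [write_tsv_stage()].
#' @param ... further arguments passed to [utils::read.delim()].
#' @return data frame.
#' @export
read_tsv_stage <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
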