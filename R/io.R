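#' Write analysis tables with a run manifest
#'
#' Writes each table as a tab-delimited file with a header row into `out_dir`
#' (created if needed), then a `manifest.json` recording the run (written
#' last, so a manifest implies a complete output set). Formatting: VND as
#' integers, US$ rounded to units, probabilities to 4 decimals.
#'
#' @param tables named list of data.frames; names become `<name>.tsv`.
#' @param out_dir output directory.
#' @param manifest named list of run metadata (see [run_manifest()]).
#' @return character vector of written paths, invisibly.
#' @export
write_report <- function(tables, out_dir, manifest = run_manifest()) {
  if (length(tables) == 0 || is.null(names(tables)) || any(names(tables) == "")) {
    stop("'tables' must be a non-empty named list")
  }
  for (nm in names(tables)) {
    if (!is.data.frame(tables[[nm]]) || nrow(tables[[nm]]) == 0) {
      stop("table '", nm, "' is empty; nothing written")
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  paths <- character(0)
  for (nm in names(tables)) {
    df <- tables[[nm]]
    num <- vapply(df, is.numeric, logical(1))
    for (j in which(num)) {
      x <- df[[j]]
      if (all(abs(x - round(x)) < 1e-9, na.rm = TRUE)) {
        df[[j]] <- format(round(x), scientific = FALSE, trim = TRUE)
      } else if (all(x >= 0 & x <= 1, na.rm = TRUE)) {
        df[[j]] <- formatC(x, format = "f", digits = 4)
      } else {
        df[[j]] <- formatC(x, format = "f", digits = 6)
      }
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(c(paths, mp))
}

#' Run manifest
#'
#' Metadata sufficient to reproduce a run bit-for-bit given the same inputs.
#'
#' @param subcommand analysis subcommand name.
#' @param config,lifetable input paths.
#' @param seed RNG seed.
#' @param iterations Monte-Carlo iterations.
#' @param out_dir output directory.
#' @return named list.
#' @export
run_manifest <- function(subcommand = NA, config = NA, lifetable = NA,
                         seed = NA, iterations = NA, out_dir = NA) {
  list(subcommand = subcommand, config = config, lifetable = lifetable,
       seed = seed, iterations = iterations, out_dir = out_dir,
       package_version = as.character(utils::packageVersion("her2cea")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Export / re-import a cohort trace
#'
#' Tab-delimited, full double precision; a round trip reproduces occupancies
#' exactly.
#'
#' @param trace `trace` data.frame from an `arm_result`.
#' @param path file path.
#' @return [read_trace()] returns the data.frame.
#' @export
write_trace <- function(trace, path) {
  df <- trace
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  utils::read.delim(path, header = TRUE, colClasses = "numeric")
}
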