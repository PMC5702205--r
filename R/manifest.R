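#' Write a run manifest
#'
#' Records, as JSON, everything needed to reproduce a pipeline stage: the
#' subcommand, the resolved parameters, MD5 digests of the input files,
#' any seeds, the package version and a timestamp.  Deterministic stages
#' re-run from an identical manifest produce identical outputs.
#'
#' @param path output path for the manifest JSON.
#' @param subcommand name of the pipeline stage.
#' @param params named list of resolved parameters.
#' @param inputs character vector of input file paths (digested with
#'   MD5).
#' @param seed integer seed(s), or `NULL` for deterministic stages.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, subcommand, params = list(),
                               inputs = character(0), seed = NULL) {
  digests <- if (length(inputs) > 0L) {
    as.list(tools::md5sum(inputs))
  } else {
    stats::setNames(list(), character(0))
  }
  manifest <- list(
    subcommand = subcommand,
    parameters = params,
    input_digests = digests,
    seed = seed,
    tool_version = as.character(utils::packageVersion("gcstratify")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(path)
}
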