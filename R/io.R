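#' Export simulation results
#'
#' `write_spike_events()` writes the spike raster as a tab-separated file
#' with columns `time_s`, `neuron_index`, `population`.
#' `write_readout_traces()` writes the readout trace(s) as CSV with a
#' leading time column. `write_run_manifest()` writes the run parameters
#' and seed as JSON.
#'
#' @param result A `sim_result`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_spike_events <- function(result, path) {
  df <- result$spikes
  names(df) <- c("time_s", "neuron_index", "population")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
write_readout_traces <- function(result, path) {
  utils::write.csv(result$readout, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_events
#' @export
write_run_manifest <- function(result, path) {
  cfg <- result$config
  manifest <- list(
    variant = result$variant,
    seed = result$seed,
    dt = result$dt,
    duration = result$duration,
    n = as.list(result$n),
    parameters = lapply(
      cfg[!vapply(cfg, is.object, logical(1))],
      function(v) if (length(v) > 8) c(v[1:8], "...") else v
    ),
    kernel = if (!is.null(cfg$kernel)) unclass(cfg$kernel),
    package_version = as.character(utils::packageVersion("spikecoding"))
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
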