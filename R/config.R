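#' Versioned package defaults
#'
#' Reads the shipped configuration file (\code{inst/extdata/defaults.json})
#' holding the study constants: C_m = 185 pF, C_f = 6.3 pF, G_f = 4 nS,
#' G_gap = 8 nS, the grid/stimulus geometry and the analysis thresholds.
#'
#' @return nested list of defaults.
#' @export
eadclump_defaults <- function() {
  path <- system.file("extdata", "defaults.json", package = "eadclump")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Build a scenario grid from a configuration file
#'
#' Reads a JSON scenario specification (the schema of
#' \code{\link{build_scenario}}'s arguments) and constructs the grid.
#'
#' @param path JSON file with any of the \code{build_scenario} fields.
#' @return a \code{tissue_grid}.
#' @export
read_scenario <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(build_scenario))
  unknown <- setdiff(names(spec), known)
  if (length(unknown))
    stop("unknown scenario fields: ", paste(unknown, collapse = ", "))
  do.call(build_scenario, spec)
}
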