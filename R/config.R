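# Plain-text experiment configuration files.
#
# A YAML file mirrors the experimentConfig() arguments, with nested
# blocks for the cohort, registration, protocol and plan settings, so
# every distribution parameter of the simulator is exposed without
# touching R code.

#' Read an experiment configuration from a YAML file
#'
#' Top-level keys `scale`, `seed`, `shiftSource`, `writeVolumes` and
#' optional nested blocks `cohort`, `registration`, `protocol`, `plan`
#' whose keys are passed to [cohortConfig()], [registrationSettings()],
#' [trafficLightConfig()] and [planSpec()] respectively. Margin presets
#' inside the protocol block may be given as preset names
#' (`tightMargins: tight`).
#'
#' @param path YAML file path
#' @return an [experimentConfig()]
#' @export
readExperimentConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read config files")
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("scale", "seed", "nPatients", "shiftSource",
              "largeMoverFraction", "writeVolumes"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  if (!is.null(y$cohort)) {
    cargs <- y$cohort
    if (!is.null(args$seed) && is.null(cargs$seed)) cargs$seed <- args$seed
    args$cohort <- do.call(cohortConfig, cargs)
  }
  if (!is.null(y$registration))
    args$registration <- do.call(registrationSettings, y$registration)
  if (!is.null(y$protocol)) {
    pargs <- y$protocol
    for (m in c("tightMargins", "largeMargins"))
      if (is.character(pargs[[m]])) pargs[[m]] <- marginSpec(pargs[[m]])
      else if (is.numeric(pargs[[m]]))
        pargs[[m]] <- do.call(marginSpec, as.list(pargs[[m]]))
    args$protocol <- do.call(trafficLightConfig, pargs)
  }
  if (!is.null(y$plan)) args$plan <- do.call(planSpec, y$plan)
  do.call(experimentConfig, args)
}
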