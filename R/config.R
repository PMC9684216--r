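#' Default run configuration
#'
#' The package's versioned default configuration: the network parameters
#' (see [vt_params()]), the calibrated stimulus strengths, the stimulus-noise
#' variance, and the cohort protocol.  It is stored as a YAML file under
#' \code{inst/extdata/default_config.yaml} whose fields mirror the
#' \code{vt_params} names one-to-one, and is the configuration used by the
#' worked examples and the command-line interface.
#'
#' @return A configuration list with elements \code{network},
#'   \code{stimuli}, \code{cohort}, and \code{master_seed}.
#' @export
vt_default_config <- function() {
  read_config(system.file("extdata", "default_config.yaml", package = "vtnet",
                          mustWork = TRUE))
}

#' Read / write a run configuration
#'
#' Configurations are plain YAML with sections \code{network} (fields named
#' exactly as in [vt_params()]), \code{stimuli} (\code{tactile_strength},
#' \code{visual_bright_strength}, \code{noise_variance}), \code{cohort}
#' (\code{n_subjects}, \code{reps}, \code{jitter_fraction}, \code{jitter_as})
#' and \code{master_seed}.
#'
#' @param path YAML file path.
#' @return \code{read_config}: the configuration list (network parameters
#'   validated).  \code{write_config}: \code{path}, invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (sec in c("network", "stimuli", "cohort"))
    if (is.null(cfg[[sec]])) stop("config is missing section '", sec, "'")
  cfg$params <- do.call(vt_params, cfg$network)
  if (is.null(cfg$master_seed)) cfg$master_seed <- 1L
  cfg
}

#' @rdname read_config
#' @param config A configuration list.
#' @export
write_config <- function(config, path) {
  config$params <- NULL
  yaml::write_yaml(config, path)
  invisible(path)
}

# stable hash of a configuration (md5 of its canonical YAML rendering)
config_hash <- function(config) {
  config$params <- NULL
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(config, tmp)
  unname(tools::md5sum(tmp))
}
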