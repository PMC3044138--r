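#' Default run configuration
#'
#' Returns the configuration list used by the pipeline entry points.  Every
#' key can be overridden in a YAML config file read by [load_config()].
#'
#' Keys and defaults:
#' \describe{
#'   \item{fdr}{FDR level for site and window calls, in (0,1). Default 0.05.}
#'   \item{window}{sliding-window size in sites (the focal site counts as a
#'     member). Default 50, minimum 3.}
#'   \item{n_sim}{number of null-simulation replicates for the region scan.
#'     Default 1000, minimum 100.}
#'   \item{seed}{RNG seed recorded in provenance logs. Default 1.}
#'   \item{pseudocount}{added to both channels before log ratios. Default 1.}
#'   \item{log_base}{base of methylation log ratios; \code{"e"} or a number.
#'     Default natural log.}
#'   \item{loess_span, loess_cycles}{cyclic loess parameters. Defaults 0.7, 2.}
#'   \item{promoter_upstream, promoter_downstream_infinium,
#'     promoter_downstream_msre}{promoter window sizes in bp around the TSS.
#'     Defaults 1500 / 1500 / 1000.}
#'   \item{cpg_cutoff}{promoter CpG observed/expected split point. Default 0.4.}
#'   \item{spline_df}{target trace degrees of freedom of the smoothing
#'     spline. Default 4.}
#' }
#'
#' @return A named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    fdr = 0.05,
    window = 50L,
    n_sim = 1000L,
    seed = 1L,
    pseudocount = 1,
    log_base = "e",
    loess_span = 0.7,
    loess_cycles = 3L,
    promoter_upstream = 1500L,
    promoter_downstream_infinium = 1500L,
    promoter_downstream_msre = 1000L,
    cpg_cutoff = 0.4,
    spline_df = 4
  ), class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Unspecified keys take the defaults from [default_config()].  Unknown keys
#' are an error (they are almost always typos), as are values outside their
#' documented ranges.
#'
#' @param path path to a YAML file; `NULL` returns the defaults unchanged.
#' @return A `run_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) {
    return(cfg)
  }
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  if (!is.list(user)) {
    stop("config file must contain a key: value mapping", call. = FALSE)
  }
  bad <- setdiff(names(user), names(cfg))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  for (k in names(user)) cfg[[k]] <- user[[k]]
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.numeric(cfg$fdr) || cfg$fdr <= 0 || cfg$fdr >= 1) {
    stop("fdr must lie strictly inside (0, 1)", call. = FALSE)
  }
  if (!is.numeric(cfg$window) || cfg$window < 3) {
    stop("window must be >= 3 sites", call. = FALSE)
  }
  if (!is.numeric(cfg$n_sim) || cfg$n_sim < 100) {
    stop("n_sim must be >= 100", call. = FALSE)
  }
  if (!is.numeric(cfg$pseudocount) || cfg$pseudocount <= 0) {
    stop("pseudocount must be > 0", call. = FALSE)
  }
  invisible(cfg)
}

#' Write the resolved configuration and seed next to pipeline outputs
#'
#' The region scan is simulation-based, so every output directory gets a
#' provenance record of the resolved configuration, the RNG seed and the
#' package version.
#'
#' @param cfg a `run_config` list.
#' @param dir output directory (created if missing).
#' @return Invisibly, the path of the provenance file.
#' @export
log_provenance <- function(cfg, dir) {
  validate_config(cfg)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  path <- file.path(dir, "run-config.yaml")
  rec <- c(unclass(cfg), list(
    package = "tdmrscan",
    package_version = as.character(utils::packageVersion("tdmrscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  ))
  yaml::write_yaml(rec, path)
  invisible(path)
}
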