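#' Read a forcekin YAML/JSON configuration
#'
#' Recognized blocks: `bond` (keys `k0_off`, `x_beta_nm`), `temperature`
#' (`kB_pN_nm_per_K`, `T_K`), `chamber` (`Q_ul_s` | `G_per_s` | `v_um_s`
#' plus `geometry` and `bead` sub-blocks with the [chamber_geometry()] and
#' [bead_model()] argument names). Unrecognized keys are preserved
#' untouched so configs can carry user metadata.
#'
#' @param path YAML (or JSON, a YAML subset) file.
#' @return list with any of `bond` (list k0_off, x_beta_nm), `temp`
#'   (a [temp_context()]), `geometry`, `bead`, plus the raw parsed list as
#'   attribute `"raw"`.
#' @export
read_forcekin_config <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- list()
  if (!is.null(raw$bond))
    out$bond <- list(k0_off = raw$bond$k0_off, x_beta_nm = raw$bond$x_beta_nm)
  if (!is.null(raw$temperature))
    out$temp <- temp_context(k_B = raw$temperature$kB_pN_nm_per_K %||% 0.0138,
                             T = raw$temperature$T_K %||% 310.15)
  ch <- raw$chamber
  if (!is.null(ch)) {
    if (!is.null(ch$geometry))
      out$geometry <- do.call(chamber_geometry, ch$geometry)
    if (!is.null(ch$bead))
      out$bead <- do.call(bead_model, ch$bead)
    out$flow <- ch[intersect(names(ch), c("Q_ul_s", "G_per_s", "v_um_s"))]
  }
  attr(out, "raw") <- raw
  out
}

#' Write a forcekin configuration to YAML
#'
#' Inverse of [read_forcekin_config()] for the recognized blocks.
#'
#' @param config list with any of `bond`, `temp`, `geometry`, `bead`,
#'   `flow`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_forcekin_config <- function(config, path) {
  raw <- list()
  if (!is.null(config$bond)) raw$bond <- config$bond
  if (!is.null(config$temp))
    raw$temperature <- list(kB_pN_nm_per_K = config$temp$k_B,
                            T_K = config$temp$T)
  ch <- list()
  if (!is.null(config$geometry)) ch$geometry <- unclass(config$geometry)
  if (!is.null(config$bead)) {
    b <- unclass(config$bead)
    b$torque_includes_pi <- NULL
    ch$bead <- b
  }
  if (length(config$flow)) ch <- c(ch, config$flow)
  if (length(ch)) raw$chamber <- ch
  yaml::write_yaml(raw, path)
  invisible(path)
}
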