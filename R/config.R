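# Caller configuration: every tunable threshold in one place.

#' Default caller configuration
#'
#' @return A named list:
#' \describe{
#'   \item{z_min}{Minimum per-replicate shift, in cluster spreads, for a
#'     confident vote (default 3).}
#'   \item{conflict_z}{Minimum per-replicate shift for a directional vote to
#'     participate in conflict detection (default 2; kept independent of
#'     `z_min` so that raising `z_min` can only turn calls into deferrals,
#'     never the reverse).}
#'   \item{min_votes}{Minimum number of confident, concordant votes required
#'     to name the duplicated allele (default 2).}
#'   \item{min_comparators}{Minimum two-copy heterozygous comparator samples
#'     for an assay's shift to be considered evaluable (default 3).}
#'   \item{floor_sd}{Lower bound on a cluster's robust spread in the fraction
#'     coordinate (default 0.01).}
#'   \item{zone_halfwidth}{Halfwidth of the classification zones around each
#'     cluster center (default 0.1).}
#'   \item{ambiguity_halfwidth}{Maximum distance from the nearest integer for
#'     a copy estimate to round (default 0.35; a reproducible 2.5-copy
#'     plateau always flags).}
#'   \item{validated_max}{Upper bound of the validated copy-number range
#'     (default 6).}
#'   \item{log_level}{One of `"debug"`, `"info"`, `"warn"`.}
#' }
#' @export
default_config <- function() {
  list(z_min = 3.0,
       conflict_z = 2.0,
       min_votes = 2L,
       min_comparators = 3L,
       floor_sd = 0.01,
       zone_halfwidth = 0.1,
       ambiguity_halfwidth = 0.35,
       validated_max = 6L,
       log_level = "info")
}

#' Load a configuration file
#'
#' Reads a JSON object of overrides and merges it over [default_config()];
#' unknown keys are rejected.
#'
#' @param path Path to a JSON configuration file, or `NULL` for defaults.
#' @param overrides Optional named list applied after the file.
#' @return A configuration list.
#' @export
load_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_config()
  apply_over <- function(cfg, over, src) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown) > 0L)
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    cfg[names(over)] <- over
    cfg
  }
  if (!is.null(path))
    cfg <- apply_over(cfg, jsonlite::fromJSON(path, simplifyVector = TRUE),
                      path)
  if (!is.null(overrides))
    cfg <- apply_over(cfg, overrides, "overrides")
  cfg
}

.log_levels <- c(debug = 1L, info = 2L, warn = 3L)

# Internal: leveled logging to stderr.
log_msg <- function(level, config, ...) {
  if (.log_levels[[level]] >= .log_levels[[config$log_level %||% "info"]])
    message(sprintf("[%s] %s", level, paste0(...)))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
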