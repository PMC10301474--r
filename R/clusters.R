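# Per-assay endpoint-cluster models and the signal-shift statistic.
#
# The two-axis endpoint plot is projected onto the variant-signal fraction
# FAM/(VIC+FAM); the duplication signature is purely allelic-ratio, so the
# radius (total signal) is discarded.  Cluster centers and spreads are fitted
# robustly from the two-copy control and concurrent samples of the same run,
# which absorbs per-lot channel scaling.

#' Variant-signal fraction of an endpoint point
#'
#' @param vic,fam Nonnegative endpoint intensities of the reference (VIC) and
#'   variant (FAM) channels.
#' @return `fam / (vic + fam)` in `[0, 1]`.
#' @export
fraction_coordinate <- function(vic, fam) {
  if (any(vic < 0) || any(fam < 0))
    stop("fluorescence intensities must be nonnegative")
  tot <- vic + fam
  if (any(tot == 0))
    stop("non-amplification: vic + fam must be positive")
  fam / tot
}

#' Fit per-assay two-copy cluster models
#'
#' Calibrates the classification geometry of one assay from the two-copy
#' control and concurrent points of a run: each represented genotype class
#' gets a robust center (median fraction) and spread (scaled MAD with a
#' floor), and a classification zone of `center +/- zone_halfwidth`.
#'
#' @param points Signal points (data frame with `sample_id`, `assay_id`,
#'   `vic`, `fam`, `call`, `role`); rows with `role == "query"` are excluded.
#' @param assay_id Assay to fit.
#' @param config Caller configuration, see [default_config()]; uses
#'   `floor_sd` and `zone_halfwidth`.
#' @return An object of class `cluster_model`.
#' @export
fit_clusters <- function(points, assay_id, config = default_config()) {
  pts <- points[points$assay_id == assay_id & points$role != "query" &
                  points$call %in% c("hom_ref", "het", "hom_var"), , drop = FALSE]
  if (!"het" %in% pts$call)
    stop("cannot calibrate assay ", assay_id, ": no two-copy heterozygous points")
  pts$fraction <- fraction_coordinate(pts$vic, pts$fam)
  classes <- c("hom_ref", "het", "hom_var")
  fit_one <- function(cls) {
    f <- pts$fraction[pts$call == cls]
    if (length(f) == 0L)
      return(data.frame(class = cls, center = NA_real_, spread = NA_real_,
                        n_points = 0L, n_samples = 0L))
    data.frame(class = cls,
               center = stats::median(f),
               spread = max(stats::mad(f), config$floor_sd),
               n_points = length(f),
               n_samples = length(unique(pts$sample_id[pts$call == cls])))
  }
  fit <- do.call(rbind, lapply(classes, fit_one))
  if (fit$n_points[fit$class == "het"] < 2L)
    stop("cannot calibrate assay ", assay_id,
         ": fewer than 2 heterozygous comparator points")
  present <- fit[!is.na(fit$center), , drop = FALSE]
  if (is.unsorted(present$center[match(classes[classes %in% present$class],
                                       present$class)]))
    stop("cluster centers out of order for assay ", assay_id,
         " (hom_ref < het < hom_var expected)")
  zones <- data.frame(class = fit$class,
                      lo = pmax(fit$center - config$zone_halfwidth, 0),
                      hi = pmin(fit$center + config$zone_halfwidth, 1))
  structure(list(assay_id = assay_id,
                 run_id = if ("run_id" %in% names(pts)) pts$run_id[1] else NA_character_,
                 classes = fit, zones = zones,
                 het_center = fit$center[fit$class == "het"],
                 het_spread = fit$spread[fit$class == "het"],
                 comparator_count = fit$n_samples[fit$class == "het"],
                 config = config[c("floor_sd", "zone_halfwidth")]),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat("Cluster model for assay", x$assay_id, "(run", paste0(x$run_id, ")"), "\n")
  for (i in seq_len(nrow(x$classes))) {
    cl <- x$classes[i, ]
    if (cl$n_points == 0L) {
      cat(sprintf("  %-8s (absent)\n", cl$class))
    } else {
      cat(sprintf("  %-8s center %.3f  spread %.3f  n=%d samples\n",
                  cl$class, cl$center, cl$spread, cl$n_samples))
    }
  }
  invisible(x)
}

#' Signed shift statistic of a query heterozygote
#'
#' Measures how far the duplicate query replicates sit from the two-copy
#' heterozygous cluster center, in units of the cluster's robust spread.
#' A call is confident only when both replicates deviate to the same side
#' and each by at least `z_min` spreads.
#'
#' @param fractions The two replicate fraction coordinates of the query.
#' @param model A fitted `cluster_model`.
#' @param config Caller configuration; uses `z_min`.
#' @return An object of class `shift_call` with the combined statistic `z`,
#'   per-replicate statistics, `direction` (`"toward_var"`, `"toward_ref"`,
#'   `"none"`), `confident`, `discordant` and the comparator count.
#' @export
shift_statistic <- function(fractions, model, config = default_config()) {
  stopifnot(inherits(model, "cluster_model"), length(fractions) == 2L)
  z_reps <- (fractions - model$het_center) / model$het_spread
  z <- mean(z_reps)
  direction <- if (z > 0) "toward_var" else if (z < 0) "toward_ref" else "none"
  discordant <- prod(sign(z_reps)) < 0
  confident <- !discordant && direction != "none" && min(abs(z_reps)) >= config$z_min
  structure(list(assay_id = model$assay_id, fractions = fractions,
                 z = z, z_reps = z_reps, direction = direction,
                 confident = confident, discordant = discordant,
                 comparator_count = model$comparator_count),
            class = "shift_call")
}

#' @export
print.shift_call <- function(x, ...) {
  cat(sprintf("Shift at %s: z = %+.2f (%s)%s%s\n", x$assay_id, x$z, x$direction,
              if (x$confident) ", confident" else "",
              if (x$discordant) ", replicates discordant" else ""))
  invisible(x)
}

#' Shift calls for query samples under a fitted cluster model
#'
#' @param object A `cluster_model`.
#' @param newdata Signal points of the model's assay for one or more query
#'   samples (duplicate rows per sample).
#' @param config Caller configuration.
#' @param ... Unused.
#' @return A named list of `shift_call` objects, one per query sample.
#' @export
predict.cluster_model <- function(object, newdata, config = default_config(), ...) {
  pts <- newdata[newdata$assay_id == object$assay_id, , drop = FALSE]
  out <- list()
  for (sid in unique(pts$sample_id)) {
    rows <- pts[pts$sample_id == sid, , drop = FALSE]
    if (nrow(rows) != 2L)
      stop("expected exactly 2 replicates for sample ", sid,
           " at assay ", object$assay_id)
    f <- fraction_coordinate(rows$vic, rows$fam)
    out[[sid]] <- shift_statistic(f, object, config)
  }
  out
}
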