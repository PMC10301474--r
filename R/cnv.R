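# Interpreting the three-probe copy-number result: integer rounding with
# ambiguity flags, and exhaustive enumeration of gene structures (full copies
# plus hybrid alleles) consistent with a probe triple.

#' Round three-probe copy estimates
#'
#' Averages replicate estimates per probe and rounds to the nearest integer
#' when the estimate lies within `ambiguity_halfwidth` of it; otherwise the
#' probe is left unrounded (`NA`) and flagged.  A reproducible plateau at the
#' same half-integer across all three probes is the signature of a variant
#' under the control-gene assay rather than a true copy change, and raises
#' `suspect_control_gene_variant`.  Any replicate above `validated_max`
#' raises `exceeds_validated_range`.
#'
#' @param estimates Either a named numeric vector with entries `promoter`,
#'   `intron6`, `exon9`, or a data frame with columns `probe`,
#'   `copy_estimate` (and optionally `replicate`) as read by
#'   [read_cnv_table()].
#' @param config Caller configuration; uses `ambiguity_halfwidth` and
#'   `validated_max`.
#' @param sample_id Sample label carried into the result.
#' @return An object of class `copy_number_result` with per-probe mean
#'   `estimates`, `rounded` integers (`NA` where ambiguous) and `flags`.
#' @export
round_copies <- function(estimates, config = default_config(),
                         sample_id = NA_character_) {
  probes <- c("promoter", "intron6", "exon9")
  if (is.data.frame(estimates)) {
    bad <- setdiff(unique(estimates$probe), probes)
    if (length(bad) > 0L)
      stop("unknown copy-number probe label(s): ", paste(bad, collapse = ", "))
    reps <- lapply(probes, function(p)
      estimates$copy_estimate[estimates$probe == p])
    names(reps) <- probes
  } else {
    if (!all(probes %in% names(estimates)))
      stop("estimates must be named with: ", paste(probes, collapse = ", "))
    reps <- lapply(probes, function(p) unname(estimates[[p]]))
    names(reps) <- probes
  }
  if (any(unlist(reps) < 0, na.rm = TRUE))
    stop("negative copy estimate")
  means <- vapply(reps, function(x) if (length(x) == 0L) NA_real_ else mean(x),
                  numeric(1))

  rounded <- rep(NA_integer_, 3L); names(rounded) <- probes
  flags <- character(0)
  ambiguous <- rep(FALSE, 3L)
  for (i in seq_along(probes)) {
    m <- means[i]
    if (is.na(m)) next
    nearest <- round(m)
    if (abs(m - nearest) <= config$ambiguity_halfwidth) {
      rounded[i] <- as.integer(nearest)
    } else {
      ambiguous[i] <- TRUE
    }
  }
  if (any(ambiguous)) flags <- c(flags, "ambiguous_half_copy")
  if (all(ambiguous) && length(unique(floor(means))) == 1L)
    flags <- c(flags, "suspect_control_gene_variant")
  if (any(unlist(reps) > config$validated_max, na.rm = TRUE))
    flags <- c(flags, "exceeds_validated_range")

  structure(list(sample_id = sample_id, estimates = means,
                 replicates = reps, rounded = rounded, flags = flags),
            class = "copy_number_result")
}

#' @export
print.copy_number_result <- function(x, ...) {
  cat("Copy-number result",
      if (!is.na(x$sample_id)) paste0("for ", x$sample_id) else "", "\n")
  for (p in names(x$estimates)) {
    cat(sprintf("  %-9s %.2f -> %s\n", p, x$estimates[[p]],
                ifelse(is.na(x$rounded[[p]]), "AMBIGUOUS", x$rounded[[p]])))
  }
  if (length(x$flags) > 0L) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Enumerate gene structures consistent with a probe triple
#'
#' Solves, exhaustively over nonnegative integers, the probe-contribution
#' equation
#' `(p, i, e) = n_full*(1,1,1) + n_68*(1,0,0) + n_36*(1,1,0) + n_13*(0,1,1)`
#' for the counts of full genes and the three hybrid signature classes.
#' Solutions are ordered by parsimony: fewest hybrid alleles first, then
#' more full copies.
#'
#' @param p,i,e Rounded copy numbers of the promoter, intron 6 and exon 9
#'   probes.
#' @param validated_max Upper bound of the supported probe range.
#' @return Data frame with columns `n_full`, `n_68`, `n_36`, `n_13`,
#'   `n_hybrids`; zero rows when no structure reproduces the triple.
#' @export
enumerate_structures <- function(p, i, e, validated_max = 6L) {
  stopifnot(length(p) == 1L, length(i) == 1L, length(e) == 1L)
  if (anyNA(c(p, i, e)))
    stop("cannot enumerate structures for unrounded (ambiguous) probes")
  if (any(c(p, i, e) != floor(c(p, i, e))) || any(c(p, i, e) < 0))
    stop("probe copies must be nonnegative integers")
  if (any(c(p, i, e) > validated_max))
    stop("probe copies exceed the validated range (", validated_max, ")")
  sols <- list()
  for (n13 in 0:e) {
    n_full <- e - n13
    n36 <- i - n_full - n13
    if (n36 < 0) next
    n68 <- p - n_full - n36
    if (n68 < 0) next
    sols[[length(sols) + 1L]] <- data.frame(
      n_full = n_full, n_68 = n68, n_36 = n36, n_13 = n13,
      n_hybrids = n68 + n36 + n13)
  }
  if (length(sols) == 0L)
    return(data.frame(n_full = integer(0), n_68 = integer(0),
                      n_36 = integer(0), n_13 = integer(0),
                      n_hybrids = integer(0)))
  out <- do.call(rbind, sols)
  out <- out[order(out$n_hybrids, -out$n_full), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter structural hypotheses against SNV-derived evidence
#'
#' Discards hypotheses whose full-gene copy count contradicts the copy total
#' implied by the genotype and duplication call, and recommends sequencing
#' unless exactly one hypothesis survives.
#'
#' @param hypotheses Output of [enumerate_structures()].
#' @param n_full_expected Full-gene copy total implied by the SNV data, or
#'   `NA` when unknown.
#' @return A list with the surviving `hypotheses` and `flags` (possibly
#'   containing `"recommend_sequencing"`).
#' @export
consistency_check <- function(hypotheses, n_full_expected = NA) {
  surviving <- hypotheses
  if (!is.na(n_full_expected))
    surviving <- surviving[surviving$n_full == n_full_expected, , drop = FALSE]
  flags <- if (nrow(surviving) == 1L) character(0) else "recommend_sequencing"
  list(hypotheses = surviving, flags = flags)
}
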