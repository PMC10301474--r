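# Naming the duplicated allele from per-assay shift votes.
#
# Every confident shift votes for the haplotype whose defining allele gained
# copies; the direction-to-haplotype mapping goes through the allele
# definitions rather than assuming variant = minor, so a shift toward the
# reference cluster at a *41-tagging site is evidence for duplication of the
# *1 haplotype.  Ambiguity always defers to sequencing: the caller's contract
# is that any call it does make is safe.

#' Match a heterozygosity pattern to candidate diplotypes
#'
#' Finds every unordered pair of full-gene star alleles whose combined
#' variant content reproduces the observed qualitative genotype calls at
#' all panel assays (`undetermined` rows are ignored).
#'
#' @param genotype_calls Data frame with `assay_id` and `call`
#'   (`hom_ref`/`het`/`hom_var`/`undetermined`) for one sample.
#' @param panel,defs Panel and allele definitions.
#' @return A list of character pairs, each a candidate allele pair.
#' @export
match_diplotype <- function(genotype_calls, panel, defs) {
  full <- names(defs$alleles)[vapply(defs$alleles, function(a)
    a$structure_class == "full", logical(1))]
  calls <- genotype_calls[genotype_calls$call != "undetermined", , drop = FALSE]
  calls <- calls[calls$assay_id %in% panel$assay_id, , drop = FALSE]
  has_variant <- function(allele, assay) assay %in% defs$alleles[[allele]]$defining_variants
  out <- list()
  for (i in seq_along(full)) for (j in i:length(full)) {
    a <- full[i]; b <- full[j]
    ok <- TRUE
    for (k in seq_len(nrow(calls))) {
      n_alt <- has_variant(a, calls$assay_id[k]) + has_variant(b, calls$assay_id[k])
      expected <- c("hom_ref", "het", "hom_var")[n_alt + 1L]
      if (expected != calls$call[k]) { ok <- FALSE; break }
    }
    if (ok) out[[length(out) + 1L]] <- c(a, b)
  }
  out
}

#' Call the duplicated allele of a three-copy sample
#'
#' Applies the decision procedure: the candidate two-allele diplotype is
#' identified from the qualitative genotype pattern; each evaluable
#' heterozygous assay contributes a directional vote for the haplotype that
#' gained copies; the duplicated allele is named only when the copy-number
#' total is 3, at least `min_votes` confident votes exist, and every
#' directional vote agrees.  Anything else defers to sequencing with explicit
#' reasons.
#'
#' @param genotype_calls Data frame with `assay_id` and `call` for the query
#'   sample (one row per assay).
#' @param shift_calls Named list of `shift_call` objects for the sample's
#'   heterozygous assays (names are assay ids).
#' @param panel,defs Panel and allele definitions.
#' @param cnv A `copy_number_result` for the sample (see [round_copies()]),
#'   or `NULL` when no copy-number data are available.
#' @param config Caller configuration, see [default_config()].
#' @param sample_id Sample label carried into the result.
#' @return An object of class `duplication_call`: `result` is either a star
#'   allele name or `"DEFER"`, with per-assay votes and defer reasons.
#' @export
call_duplicated_allele <- function(genotype_calls, shift_calls, panel, defs,
                                   cnv = NULL, config = default_config(),
                                   sample_id = NA_character_) {
  het_assays <- genotype_calls$assay_id[genotype_calls$call == "het"]
  if (length(het_assays) == 0L)
    stop("no informative SNV: sample is homozygous at every assay")

  pairs <- match_diplotype(genotype_calls, panel, defs)
  if (length(pairs) == 0L)
    stop("genotype pattern matches no panel diplotype")
  if (length(pairs) > 1L)
    stop("genotype pattern is ambiguous between diplotypes: ",
         paste(vapply(pairs, paste, character(1), collapse = "/"), collapse = ", "))
  pair <- pairs[[1L]]
  if (pair[1] == pair[2])
    stop("no informative SNV: both haplotypes carry the same allele")

  # Tabulate votes over heterozygous assays with shift calls.
  votes <- data.frame(assay_id = character(0), z = numeric(0),
                      direction = character(0), confident = logical(0),
                      discordant = logical(0), comparator_count = integer(0),
                      directional = logical(0), vote = character(0),
                      stringsAsFactors = FALSE)
  for (a in het_assays) {
    sc <- shift_calls[[a]]
    if (is.null(sc)) next
    alt_carrier <- if (a %in% defs$alleles[[pair[1]]]$defining_variants) pair[1] else pair[2]
    ref_carrier <- setdiff(pair, alt_carrier)
    vote <- if (sc$direction == "toward_var") alt_carrier
            else if (sc$direction == "toward_ref") ref_carrier
            else NA_character_
    votes <- rbind(votes, data.frame(
      assay_id = a, z = sc$z, direction = sc$direction,
      confident = sc$confident, discordant = sc$discordant,
      comparator_count = sc$comparator_count,
      directional = !sc$discordant && sc$direction != "none" &&
        min(abs(sc$z_reps)) >= config$conflict_z,
      vote = vote, stringsAsFactors = FALSE))
  }

  defer <- character(0)
  total_copies <- NA_integer_
  if (!is.null(cnv)) {
    r <- cnv$rounded
    if (!anyNA(r) && length(unique(r)) == 1L) total_copies <- unique(r)
  }

  if (is.na(total_copies) || total_copies != 3L)
    defer <- c(defer, "cnv_inconsistent")
  if (nrow(votes) == 0L || all(votes$comparator_count < config$min_comparators))
    defer <- c(defer, "low_comparator_count")

  directional <- votes[votes$directional, , drop = FALSE]
  confident <- votes[votes$confident, , drop = FALSE]
  if ((nrow(directional) > 0L && length(unique(directional$vote)) > 1L) ||
      (nrow(confident) > 0L && length(unique(confident$vote)) > 1L))
    defer <- c(defer, "conflicting_votes")
  if (nrow(confident) < config$min_votes) {
    if (length(het_assays) < config$min_votes)
      defer <- c(defer, "too_few_informative_snvs")
    else
      defer <- c(defer, "weak_shift")
    if (any(votes$discordant)) defer <- c(defer, "replicate_discordance")
  }

  result <- if (length(defer) == 0L) unique(confident$vote) else "DEFER"
  structure(list(sample_id = sample_id, result = result, pair = pair,
                 votes = votes, defer_reasons = defer,
                 total_copies = total_copies),
            class = "duplication_call")
}

#' @export
print.duplication_call <- function(x, ...) {
  cat("Duplication call",
      if (!is.na(x$sample_id)) paste0("for ", x$sample_id) else "", "\n")
  cat("  diplotype pair:", paste(x$pair, collapse = "/"),
      " copy-number total:", x$total_copies, "\n")
  for (i in seq_len(nrow(x$votes))) {
    v <- x$votes[i, ]
    cat(sprintf("  %-16s z=%+6.2f %-10s vote=%s%s\n", v$assay_id, v$z,
                v$direction, ifelse(is.na(v$vote), "-", v$vote),
                if (v$confident) " (confident)" else ""))
  }
  if (x$result == "DEFER") {
    cat("  result: DEFER to sequencing [",
        paste(x$defer_reasons, collapse = ", "), "]\n")
  } else {
    cat("  result: duplicated allele", x$result, "\n")
  }
  invisible(x)
}
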