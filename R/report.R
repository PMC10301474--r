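# Assembling the final clinical-style case report: diplotype string
# (including unresolvable-phasing alternatives), activity score, phenotype,
# and the evidence behind the decision.

# Internal: build a diplotype object from two haplotype term tables.
make_diplotype <- function(hap1, hap2, alternatives = character(0)) {
  structure(list(hap1 = hap1, hap2 = hap2, alternatives = alternatives),
            class = "diplotype")
}

hap_term <- function(allele, copies = 1L, unknown = FALSE) {
  data.frame(allele = allele, copies = as.integer(copies), unknown = unknown,
             stringsAsFactors = FALSE)
}

#' Resolve a case into a reportable diplotype
#'
#' Combines the duplication call, the structural hypotheses from the
#' copy-number data and the allele definitions into a case report:
#'
#' * three full copies with a named duplicated allele become `×2` on that
#'   haplotype;
#' * a surviving hybrid-containing structure attaches the hybrid in tandem
#'   (`+`) to its known partner haplotype, or to the multiplied haplotype
#'   when no partner is on board;
#' * four full copies with one unphaseable extra allele are reported as an
#'   alternatives pair with identical activity score;
#' * a deferred call becomes status `reflex_sequencing` with its reasons.
#'
#' @param dup_call A `duplication_call`.
#' @param defs Allele definitions.
#' @param structures Optional result of [consistency_check()] or
#'   [enumerate_structures()]; when absent, three full copies are assumed
#'   for a named call.
#' @param extra_allele Star allele of an additional full copy established by
#'   sequencing but unphaseable from the panel data (reported as an
#'   alternatives pair).
#' @param table Activity-value table.
#' @param config Caller configuration.
#' @return An object of class `case_report`.
#' @export
resolve <- function(dup_call, defs, structures = NULL, extra_allele = NULL,
                    table = activity_table(), config = default_config()) {
  stopifnot(inherits(dup_call, "duplication_call"))
  evidence <- list(votes = dup_call$votes,
                   total_copies = dup_call$total_copies,
                   defer_reasons = dup_call$defer_reasons)

  report <- function(status, diplotype = NULL, alternatives = character(0),
                     score = NULL, phenotype = NA_character_) {
    structure(list(sample_id = dup_call$sample_id, status = status,
                   diplotype = diplotype, alternatives = alternatives,
                   activity_score = score, phenotype = phenotype,
                   defer_reasons = dup_call$defer_reasons,
                   evidence = evidence),
              class = "case_report")
  }

  if (identical(dup_call$result, "DEFER"))
    return(report("reflex_sequencing"))

  dup <- dup_call$result
  pair <- dup_call$pair
  if (!dup %in% pair)
    stop("duplicated allele ", dup, " absent from the genotype pair ",
         paste(pair, collapse = "/"))
  other <- setdiff(pair, dup)

  hyp <- NULL
  if (!is.null(structures)) {
    h <- if (is.list(structures) && !is.data.frame(structures))
      structures$hypotheses else structures
    if (nrow(h) >= 1L) hyp <- h[1L, ]
    if (!is.null(structures$flags) &&
        "recommend_sequencing" %in% structures$flags)
      return(report("reflex_sequencing"))
  }

  hap_dup <- hap_term(dup, 2L)
  hap_other <- hap_term(other, 1L)

  # Attach hybrid alleles implied by the structural hypothesis.
  if (!is.null(hyp)) {
    hybrids <- c(rep("*68", hyp$n_68), rep("*36", hyp$n_36), rep("*13", hyp$n_13))
    for (h in hybrids) {
      partner <- if (h %in% names(defs$tandem_partners))
        defs$tandem_partners[[h]] else NULL
      if (!is.null(partner) && identical(partner, other)) {
        hap_other <- rbind(hap_term(h), hap_other)
      } else if (!is.null(partner) && identical(partner, dup)) {
        hap_dup <- rbind(hap_term(h), hap_dup)
      } else {
        hap_dup <- rbind(hap_term(h), hap_dup)   # default: ride with the dup
      }
    }
    if (hyp$n_full == 4L && !is.null(extra_allele)) {
      # one unphaseable extra full copy: report both arrangements
      alt1 <- make_diplotype(hap_dup, rbind(hap_term(extra_allele), hap_other))
      alt2 <- make_diplotype(rbind(hap_dup, hap_term(extra_allele)), hap_other)
      s1 <- format_diplotype_haps(list(alt1$hap1, alt1$hap2), sort_haps = FALSE)
      s2 <- format_diplotype_haps(list(alt2$hap1, alt2$hap2), sort_haps = FALSE)
      sc1 <- activity_score(alt1, table)
      sc2 <- activity_score(alt2, table)
      if (format(sc1) != format(sc2))
        stop("alternatives disagree on activity score: ",
             format(sc1), " vs ", format(sc2))
      return(report("reported", diplotype = s1, alternatives = s2,
                    score = sc1, phenotype = phenotype_from_score(sc1)))
    }
    if (hyp$n_full > 3L && is.null(extra_allele))
      return(report("reflex_sequencing"))
  }

  d <- make_diplotype(hap_dup, hap_other)
  sc <- activity_score(d, table)
  report("reported", diplotype = format(d), score = sc,
         phenotype = phenotype_from_score(sc))
}

#' @export
print.case_report <- function(x, ...) {
  cat(render_report(x, fmt = "text"))
  invisible(x)
}

# Internal: plain-list view of a case report (JSON-serializable).
report_as_list <- function(r) {
  list(sample_id = r$sample_id,
       status = r$status,
       diplotype = if (is.null(r$diplotype)) NA_character_ else r$diplotype,
       alternatives = as.character(r$alternatives),
       activity_score = if (is.null(r$activity_score)) NA_character_
                        else format(r$activity_score),
       phenotype = r$phenotype,
       defer_reasons = as.character(r$defer_reasons),
       evidence = list(
         total_copies = r$evidence$total_copies,
         votes = r$evidence$votes))
}

#' Render a case report
#'
#' @param r A `case_report`.
#' @param fmt `"json"` (lossless, see [parse_report()]) or `"text"` (a
#'   clinical-style summary with the evidence table and every defer reason).
#' @return A character scalar.
#' @export
render_report <- function(r, fmt = c("json", "text")) {
  if (length(fmt) != 1L || !fmt %in% c("json", "text"))
    stop("unknown report format: ", paste(fmt, collapse = ", "))
  stopifnot(inherits(r, "case_report"))
  if (fmt == "json") {
    return(as.character(jsonlite::toJSON(report_as_list(r), auto_unbox = TRUE,
                                         digits = NA, null = "null", na = "null",
                                         dataframe = "rows")))
  }
  lines <- c(
    sprintf("Sample:    %s", r$sample_id),
    sprintf("Status:    %s", r$status))
  if (identical(r$status, "reported")) {
    geno <- r$diplotype
    if (length(r$alternatives) > 0L)
      geno <- paste(c(geno, r$alternatives), collapse = " or ")
    lines <- c(lines,
               sprintf("Genotype:  %s", geno),
               sprintf("Activity:  %s", format(r$activity_score)),
               sprintf("Phenotype: %s", r$phenotype))
  }
  if (length(r$defer_reasons) > 0L)
    lines <- c(lines, sprintf("Defer reasons: %s",
                              paste(unique(r$defer_reasons), collapse = ", ")))
  v <- r$evidence$votes
  if (!is.null(v) && nrow(v) > 0L) {
    lines <- c(lines, "Evidence:")
    lines <- c(lines, sprintf("  %-16s z=%+6.2f %-10s vote=%s%s",
                              v$assay_id, v$z, v$direction,
                              ifelse(is.na(v$vote), "-", v$vote),
                              ifelse(v$confident, " (confident)", "")))
  }
  if (!is.null(r$evidence$total_copies))
    lines <- c(lines, sprintf("Copy-number total: %s", r$evidence$total_copies))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Parse a JSON case report
#'
#' Inverse of `render_report(r, "json")` at the level of the serialized
#' fields.
#'
#' @param json A JSON string.
#' @return A plain list with the report fields.
#' @export
parse_report <- function(json) {
  jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}
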