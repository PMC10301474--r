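# The packaged validation-cohort composition and its expansion into
# per-sample truth records.

#' Load the packaged cohort composition table
#'
#' One row per distinct genotype: the clinically resolved diplotype, the
#' number of cases, the reported phenotype and activity score, the number of
#' informative (heterozygous) panel SNVs available for review, the true
#' per-probe gene copy numbers, and whether the sample carries a control-gene
#' variant that interferes with the copy-number assay.  The `main` dataset
#' holds the 73 three-copy validation cases, `exploratory` the 11
#' hybrid-allele and/or multicopy cases, and `ambiguous` the 3 cases whose
#' measured copy number plateaus between 2 and 3.
#'
#' @param path Path to the composition TSV; defaults to the packaged table.
#' @return Data frame with one row per genotype group.
#' @export
load_cohort_composition <- function(path = system.file("extdata", "cohort_composition.tsv",
                                                       package = "starshift")) {
  comp <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  comp$interference <- as.logical(comp$interference)
  comp
}

# Internal: the single duplicated allele of a genotype, or NA when there is
# none or more than one multiplied haplotype.
duplicated_allele_of <- function(genotype) {
  d <- parse_diplotype(genotype)
  terms <- diplotype_terms(d)
  dup <- terms$allele[terms$unknown | (!is.na(terms$copies) & terms$copies >= 2L)]
  if (length(dup) == 1L) dup else NA_character_
}

#' Expand the packaged cohort into per-sample truth records
#'
#' Each case becomes one truth record carrying its genotype, dataset, true
#' three-probe copy numbers, interference flag, the duplicated allele (for
#' cases with exactly one multiplied haplotype), and the printed count of
#' informative SNVs.  Sample order is shuffled deterministically from the
#' seed.
#'
#' @param seed Integer seed controlling sample-id assignment order.
#' @param datasets Subset of `c("main", "exploratory", "ambiguous")`.
#' @param composition Cohort composition table, see
#'   [load_cohort_composition()].
#' @return A data frame of class `truth_cohort`, one row per sample.
#' @export
make_table1_cohort <- function(seed = 1L,
                               datasets = c("main", "exploratory", "ambiguous"),
                               composition = load_cohort_composition()) {
  comp <- composition[composition$dataset %in% datasets, , drop = FALSE]
  rows <- comp[rep(seq_len(nrow(comp)), comp$n_cases), , drop = FALSE]
  rows$n_cases <- NULL
  set.seed(as.integer(seed))
  rows <- rows[sample.int(nrow(rows)), , drop = FALSE]
  rows <- rows[order(match(rows$dataset, c("main", "exploratory", "ambiguous"))), ,
               drop = FALSE]
  prefix <- c(main = "S", exploratory = "X", ambiguous = "A")
  rows$sample_id <- paste0(prefix[rows$dataset],
                           sprintf("%03d", seq_len(nrow(rows))))
  rows$duplicated_allele <- vapply(rows$genotype, duplicated_allele_of,
                                   character(1), USE.NAMES = FALSE)
  rownames(rows) <- NULL
  rows <- rows[, c("sample_id", "dataset", "genotype", "phenotype",
                   "activity_score", "n_het_snvs", "cnv_promoter",
                   "cnv_intron6", "cnv_exon9", "interference",
                   "duplicated_allele")]
  class(rows) <- c("truth_cohort", "data.frame")
  rows
}
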