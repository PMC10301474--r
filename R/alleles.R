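# Star-allele definitions and the genotyping panel.
#
# A "panel" is the set of TaqMan allelic-discrimination assays available on the
# array; a star allele is defined here only by the panel positions at which it
# carries the variant (alt) base.  Gene-structure classes determine which
# segments of CYP2D6 an allele actually contains, and therefore which assays
# and which of the three copy-number probes (promoter, intron 6, exon 9) it
# contributes to.

# Segment coverage by structure class.  Hybrid alleles are fusions with the
# CYP2D7 pseudogene: "early" hybrids switch to CYP2D7 after exon 1, "late"
# hybrids switch in the exon 9 region, and 2D7-2D6 hybrids begin as CYP2D7.
.structure_classes <- list(
  full                 = list(regions = c("promoter", "exon1", "mid", "late"),
                              probe_vector = c(1L, 1L, 1L)),
  hybrid_2D6_2D7_early = list(regions = c("promoter", "exon1"),
                              probe_vector = c(1L, 0L, 0L)),
  hybrid_2D6_2D7_late  = list(regions = c("promoter", "exon1", "mid"),
                              probe_vector = c(1L, 1L, 0L)),
  hybrid_2D7_2D6       = list(regions = c("mid", "late"),
                              probe_vector = c(0L, 1L, 1L)),
  deletion             = list(regions = character(0),
                              probe_vector = c(0L, 0L, 0L))
)

#' Load the genotyping assay panel
#'
#' Reads the tab-separated panel description: one row per allelic
#' discrimination assay, with the cDNA-style assay id, the legacy position
#' name, the reference and variant bases, and the gene segment
#' (`promoter`, `exon1`, `mid`, `late`) the assay interrogates.  The segment
#' determines which hybrid-gene structures cover the assay.
#'
#' @param path Path to a panel TSV; defaults to the panel shipped with the
#'   package.
#' @return A data frame of class `assay_panel`.
#' @export
load_panel <- function(path = system.file("extdata", "panel.tsv", package = "starshift")) {
  panel <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  required <- c("assay_id", "legacy_name", "ref_allele", "alt_allele", "region", "panel_index")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0L)
    stop("panel file is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(panel$assay_id))
    stop("duplicated assay_id in panel: ",
         paste(unique(panel$assay_id[duplicated(panel$assay_id)]), collapse = ", "))
  if (any(panel$ref_allele == panel$alt_allele))
    stop("ref_allele must differ from alt_allele for every assay")
  bad_region <- setdiff(panel$region, c("promoter", "exon1", "mid", "late"))
  if (length(bad_region) > 0L)
    stop("unknown gene segment(s) in panel: ", paste(bad_region, collapse = ", "))
  panel <- panel[order(panel$panel_index), , drop = FALSE]
  rownames(panel) <- NULL
  class(panel) <- c("assay_panel", "data.frame")
  panel
}

#' Load star-allele definitions
#'
#' Reads the JSON allele-definition configuration: for each star allele its
#' defining panel variants, per-copy activity value, and gene-structure class
#' (full gene, CYP2D6-CYP2D7 hybrid, CYP2D7-CYP2D6 hybrid, or deletion).
#' The probe contribution vector over the (promoter, intron 6, exon 9)
#' copy-number probes is fixed by the structure class.
#'
#' @param path Path to an allele-definition JSON; defaults to the
#'   panel-resolvable definitions shipped with the package.
#' @param panel Optional `assay_panel`; when supplied, every defining variant
#'   is validated against it.
#' @return An object of class `allele_defs`: a named list of allele records
#'   plus known tandem-partner pairings.
#' @export
load_allele_defs <- function(path = system.file("extdata", "alleles.json", package = "starshift"),
                             panel = NULL) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  alleles <- list()
  for (rec in raw$alleles) {
    cls <- rec$structure_class
    if (!cls %in% names(.structure_classes))
      stop("unknown structure_class '", cls, "' for allele ", rec$name)
    info <- .structure_classes[[cls]]
    act <- if (is.null(rec$activity_value)) NA_real_ else as.numeric(rec$activity_value)
    if (!is.na(act) && act < 0)
      stop("negative activity value for allele ", rec$name)
    if (cls != "full" && !is.na(act) && act != 0)
      stop("non-full structure ", rec$name, " must have activity value 0")
    vars <- as.character(unlist(rec$defining_variants))
    if (!is.null(panel)) {
      unknown <- setdiff(vars, panel$assay_id)
      if (length(unknown) > 0L)
        stop("allele ", rec$name, " defined by assay(s) absent from panel: ",
             paste(unknown, collapse = ", "))
    }
    alleles[[rec$name]] <- list(
      name = rec$name,
      defining_variants = vars,
      activity_value = act,
      structure_class = cls,
      regions = info$regions,
      probe_vector = info$probe_vector
    )
  }
  partners <- vapply(raw$tandem_partners, as.character, character(1))
  defs <- list(alleles = alleles, tandem_partners = partners)
  class(defs) <- "allele_defs"
  defs
}

#' @export
print.allele_defs <- function(x, ...) {
  cat("Star-allele definitions:", length(x$alleles), "alleles\n")
  for (a in x$alleles) {
    cat(sprintf("  %-4s activity %-4s %-22s [%s]\n", a$name,
                ifelse(is.na(a$activity_value), "?", format(a$activity_value)),
                a$structure_class,
                paste(a$defining_variants, collapse = ", ")))
  }
  invisible(x)
}

#' Per-copy activity values as a named vector
#'
#' @param defs An `allele_defs` object.
#' @return Named numeric vector of per-copy activity values (may contain `NA`
#'   for alleles of undefined function).
#' @export
activity_table <- function(defs = load_allele_defs()) {
  vapply(defs$alleles, function(a) a$activity_value, numeric(1))
}

# Internal: fetch an allele record or fail loudly.
get_allele <- function(defs, name) {
  rec <- defs$alleles[[name]]
  if (is.null(rec)) stop("unknown star allele: ", name)
  rec
}

# Internal: does `allele` cover (contain CYP2D6 sequence at) the given assay?
allele_covers <- function(defs, allele, region) {
  region %in% get_allele(defs, allele)$regions
}

# Internal: allele carried by `allele` at an assay: "alt", "ref", or NA when
# the assay position is not CYP2D6 sequence in this structure.
allele_base <- function(defs, allele, assay_id, region) {
  rec <- get_allele(defs, allele)
  if (!region %in% rec$regions) return(NA_character_)
  if (assay_id %in% rec$defining_variants) "alt" else "ref"
}
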