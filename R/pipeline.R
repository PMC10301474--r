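# End-to-end pipeline: genotyper export + copy-number table in, case
# reports out.

#' Run the full duplicated-allele pipeline
#'
#' For every run in the genotyper export, fits per-assay two-copy cluster
#' models from the control and concurrent samples, scores the signal shift of
#' each query sample's heterozygous assays, interprets the three-probe
#' copy-number result, and resolves each query into a case report:
#'
#' * three full copies and unambiguous shift votes are reported with the
#'   duplicated allele as `×2`;
#' * two clean copies are reported as an ordinary two-copy diplotype;
#' * ambiguous copy number (half-copy plateaus, suspected control-gene
#'   variants), hybrid/multicopy structures and any conflicting or weak
#'   signal evidence defer to reflex sequencing;
#' * a duplication with no heterozygous assay is `indeterminate` (no
#'   informative SNV exists, with or without sequencing capability).
#'
#' @param genotyper Genotyper export: a path or a data frame from
#'   [read_genotyper_export()].
#' @param cnv Copy-number table: a path or a data frame from
#'   [read_cnv_table()].
#' @param panel,defs Panel and allele definitions.
#' @param config Caller configuration.
#' @return A list of class `run_reports`: `reports` (named list of
#'   `case_report`) and `summary` (one row per query sample).
#' @export
call_run <- function(genotyper, cnv, panel = load_panel(),
                     defs = load_allele_defs(), config = default_config()) {
  if (is.character(genotyper)) genotyper <- read_genotyper_export(genotyper)
  if (is.character(cnv)) cnv <- read_cnv_table(cnv)

  queries <- unique(genotyper$sample_id[genotyper$role == "query"])
  no_cnv <- setdiff(queries, unique(cnv$sample_id))
  if (length(no_cnv) > 0L)
    stop("query sample(s) absent from the copy-number table: ",
         paste(no_cnv, collapse = ", "))
  unknown_assay <- setdiff(unique(genotyper$assay_id), panel$assay_id)
  if (length(unknown_assay) > 0L)
    stop("assay(s) absent from the panel: ",
         paste(unknown_assay, collapse = ", "))

  reports <- list()
  for (rid in unique(genotyper$run_id)) {
    run <- genotyper[genotyper$run_id == rid, , drop = FALSE]
    run_queries <- unique(run$sample_id[run$role == "query"])
    # calibrate every assay with heterozygous comparators on this run
    models <- list()
    for (a in unique(run$assay_id)) {
      models[[a]] <- tryCatch(fit_clusters(run, a, config),
                              error = function(e) NULL)
    }
    for (sid in run_queries) {
      reports[[sid]] <- resolve_sample(run, cnv, sid, models, panel, defs, config)
      log_msg("debug", config, "sample ", sid, ": ", reports[[sid]]$status)
    }
  }

  summary <- do.call(rbind, lapply(reports, function(r) {
    data.frame(sample_id = r$sample_id, status = r$status,
               diplotype = if (is.null(r$diplotype)) NA_character_ else r$diplotype,
               alternatives = paste(r$alternatives, collapse = " or "),
               activity_score = if (is.null(r$activity_score)) NA_character_
                                else format(r$activity_score),
               phenotype = r$phenotype,
               defer_reasons = paste(unique(r$defer_reasons), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- NULL
  counts <- table(summary$status)
  log_msg("info", config, "resolved ", nrow(summary), " samples: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  structure(list(reports = reports, summary = summary), class = "run_reports")
}

# Internal: resolve one query sample on one run.
resolve_sample <- function(run, cnv, sid, models, panel, defs, config) {
  rows <- run[run$sample_id == sid, , drop = FALSE]
  genotype_calls <- rows[rows$replicate == 1L, c("assay_id", "call")]
  cn <- round_copies(cnv[cnv$sample_id == sid, , drop = FALSE], config,
                     sample_id = sid)

  blank_call <- structure(list(sample_id = sid, result = "DEFER",
                               pair = c(NA_character_, NA_character_),
                               votes = data.frame(), defer_reasons = character(0),
                               total_copies = NA_integer_),
                          class = "duplication_call")

  # Ambiguous copy number: a consistent half-copy plateau is evidence of a
  # control-gene variant, not of a duplication; defer with the flags.
  if (length(cn$flags) > 0L &&
      any(c("ambiguous_half_copy", "suspect_control_gene_variant",
            "exceeds_validated_range") %in% cn$flags)) {
    bc <- blank_call; bc$defer_reasons <- "cnv_inconsistent"
    rep <- resolve(bc, defs, config = config)
    rep$evidence$cnv <- cn
    return(rep)
  }

  total <- if (!anyNA(cn$rounded) && length(unique(cn$rounded)) == 1L)
    unique(cn$rounded) else NA_integer_

  het_assays <- genotype_calls$assay_id[genotype_calls$call == "het"]

  # Two clean copies: ordinary diplotype, no duplication to resolve.
  if (!is.na(total) && total == 2L) {
    pairs <- match_diplotype(genotype_calls, panel, defs)
    if (length(pairs) == 1L) {
      d <- make_diplotype(hap_term(pairs[[1]][1]), hap_term(pairs[[1]][2]))
      sc <- activity_score(d)
      rep <- structure(list(sample_id = sid, status = "reported",
                            diplotype = format(d), alternatives = character(0),
                            activity_score = sc,
                            phenotype = phenotype_from_score(sc),
                            defer_reasons = character(0),
                            evidence = list(votes = data.frame(),
                                            total_copies = total, cnv = cn)),
                       class = "case_report")
      return(rep)
    }
  }

  # A duplication with no informative SNV cannot be assessed at all.
  if (length(het_assays) == 0L && !is.na(total) && total >= 3L) {
    rep <- structure(list(sample_id = sid, status = "indeterminate",
                          diplotype = NULL, alternatives = character(0),
                          activity_score = NULL, phenotype = NA_character_,
                          defer_reasons = character(0),
                          evidence = list(votes = data.frame(),
                                          total_copies = total, cnv = cn)),
                     class = "case_report")
    return(rep)
  }

  # Hybrid and/or multicopy structures: enumerate and defer unless clean.
  if (is.na(total) || total != 3L) {
    structures <- tryCatch(
      enumerate_structures(cn$rounded[["promoter"]], cn$rounded[["intron6"]],
                           cn$rounded[["exon9"]], config$validated_max),
      error = function(e) NULL)
    bc <- blank_call; bc$defer_reasons <- "cnv_inconsistent"
    rep <- resolve(bc, defs, config = config)
    rep$evidence$cnv <- cn
    rep$evidence$structures <- structures
    return(rep)
  }

  # Main path: three copies, shift votes name the duplicated allele.
  shift_calls <- list()
  for (a in het_assays) {
    if (is.null(models[[a]])) next
    pts <- rows[rows$assay_id == a, , drop = FALSE]
    f <- fraction_coordinate(pts$vic, pts$fam)
    shift_calls[[a]] <- shift_statistic(f, models[[a]], config)
  }
  dup_call <- call_duplicated_allele(genotype_calls, shift_calls, panel, defs,
                                     cnv = cn, config = config, sample_id = sid)
  rep <- resolve(dup_call, defs, config = config)
  rep$evidence$cnv <- cn
  rep
}

#' @export
print.run_reports <- function(x, ...) {
  cat("Pipeline run:", nrow(x$summary), "query samples\n")
  print(table(x$summary$status))
  invisible(x)
}
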