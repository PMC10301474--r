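# Readers and writers for the plain-TSV dialects the pipeline consumes and
# emits.  Dialects are defined by this package (documented headers); they are
# deliberately not imitations of proprietary instrument exports.

# Internal: reject files whose rows would silently truncate.
check_rectangular <- function(path) {
  n <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(unique(n)) > 1L)
    stop("ragged file (unequal field counts across rows): ", path)
}

#' Read a genotyper-export table
#'
#' TSV dialect with header `sample_id`, `assay_id`, `replicate`, `vic`,
#' `fam`, `call`, `role`, `run_id`.  Recognized calls are `hom_ref`, `het`,
#' `hom_var`; anything else maps to `undetermined`.  Row order is preserved.
#'
#' @param path Path to the TSV.
#' @return Data frame of typed signal records.
#' @export
read_genotyper_export <- function(path) {
  check_rectangular(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "assay_id", "replicate", "vic", "fam",
                "call", "role", "run_id")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("genotyper export is missing column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("vic", "fam")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")
    if (length(bad) > 0L)
      stop("non-numeric ", col, " value at line ", bad[1] + 1L,
           " of ", path, ": '", df[[col]][bad[1]], "'")
    df[[col]] <- v
  }
  df$replicate <- as.integer(df$replicate)
  known <- c("hom_ref", "het", "hom_var")
  df$call[!df$call %in% known] <- "undetermined"
  bad_role <- setdiff(unique(df$role), c("control", "concurrent", "query"))
  if (length(bad_role) > 0L)
    stop("unknown role(s) in genotyper export: ",
         paste(bad_role, collapse = ", "))
  df
}

#' Read a copy-number table
#'
#' TSV dialect with header `sample_id`, `probe`, `replicate`,
#' `copy_estimate`; probes are `promoter`, `intron6`, `exon9`.  Replicates
#' are retained.  A sample missing a probe is kept (the probe is treated as
#' missing downstream) with a warning.
#'
#' @param path Path to the TSV.
#' @return Data frame of copy-number records.
#' @export
read_cnv_table <- function(path) {
  check_rectangular(path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("sample_id", "probe", "replicate", "copy_estimate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop("copy-number table is missing column(s): ",
         paste(missing, collapse = ", "))
  bad <- setdiff(unique(df$probe), c("promoter", "intron6", "exon9"))
  if (length(bad) > 0L)
    stop("unknown copy-number probe label(s): ", paste(bad, collapse = ", "))
  v <- suppressWarnings(as.numeric(df$copy_estimate))
  nn <- which(is.na(v) & !is.na(df$copy_estimate) & df$copy_estimate != "")
  if (length(nn) > 0L)
    stop("non-numeric copy_estimate at line ", nn[1] + 1L, " of ", path)
  if (any(v < 0, na.rm = TRUE))
    stop("negative copy estimate in ", path)
  df$copy_estimate <- v
  df$replicate <- as.integer(df$replicate)
  for (sid in unique(df$sample_id)) {
    present <- unique(df$probe[df$sample_id == sid])
    absent <- setdiff(c("promoter", "intron6", "exon9"), present)
    if (length(absent) > 0L)
      warning("sample ", sid, " is missing probe(s): ",
              paste(absent, collapse = ", "), call. = FALSE)
  }
  df
}

# Fixed-format numeric rendering so that identical simulations write
# byte-identical files.
format_num <- function(x) formatC(x, format = "g", digits = 10)

#' Write a genotyper-export table
#' @param df Signal records as produced by [simulate_run()].
#' @param path Output path.
#' @export
write_genotyper_export <- function(df, path) {
  out <- df
  out$vic <- format_num(out$vic)
  out$fam <- format_num(out$fam)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a copy-number table
#' @param df Copy-number records as produced by [simulate_run()].
#' @param path Output path.
#' @export
write_cnv_table <- function(df, path) {
  out <- df
  out$copy_estimate <- format_num(out$copy_estimate)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a truth table
#' @param df Truth records as produced by [make_table1_cohort()].
#' @param path Output path.
#' @export
write_truth_table <- function(df, path) {
  utils::write.table(as.data.frame(df), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a truth table written by [write_truth_table()]
#' @param path Path to the TSV.
#' @return Data frame of truth records.
#' @export
read_truth_table <- function(path) {
  check_rectangular(path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
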