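# Diplotype grammar, activity scores, and metabolizer phenotype translation.
#
# Diplotypes are written in star nomenclature: two haplotypes separated by
# "/", each haplotype one or more "+"-joined gene copies in their physical
# tandem arrangement, with "xK" multiplication for K identical tandem copies
# ("xN" when the multiplicity is known only to exceed a duplication).

.mult_chars <- "[×xX]"   # accepted multiplication signs; canonical is U+00D7

# Internal: parse one haplotype term such as "*41", "4", "*1×2", "*1×N".
parse_term <- function(token) {
  m <- regmatches(token, regexec(
    paste0("^\\*?([0-9]+[A-Za-z]*)(?:", .mult_chars, "([0-9]+|N))?$"), token))[[1]]
  if (length(m) == 0L)
    stop("malformed haplotype token: '", token, "'")
  copies_txt <- m[3]
  if (identical(copies_txt, "")) {
    copies <- 1L; unknown <- FALSE
  } else if (identical(copies_txt, "N")) {
    copies <- NA_integer_; unknown <- TRUE
  } else {
    copies <- as.integer(copies_txt); unknown <- FALSE
    if (copies < 1L) stop("malformed haplotype token (zero copies): '", token, "'")
  }
  list(allele = paste0("*", m[2]), copies = copies, unknown = unknown)
}

# Internal: parse one haplotype ("*68+*4", "*1×2", ...) into a data frame of
# tandem terms in physical order.
parse_haplotype <- function(text) {
  tokens <- strsplit(text, "+", fixed = TRUE)[[1]]
  tokens <- trimws(tokens)
  if (length(tokens) == 0L || any(tokens == ""))
    stop("malformed haplotype: '", text, "'")
  terms <- lapply(tokens, parse_term)
  data.frame(
    allele  = vapply(terms, `[[`, character(1), "allele"),
    copies  = vapply(terms, `[[`, integer(1), "copies"),
    unknown = vapply(terms, `[[`, logical(1), "unknown"),
    stringsAsFactors = FALSE
  )
}

#' Parse a star-nomenclature diplotype string
#'
#' Accepts strings such as `"*1×2/*41"`, `"*68+4/*41×2"` (a bare
#' `4` normalizes to `*4`), or an alternatives pair joined by `" or "` when
#' phasing cannot distinguish two arrangements.  `×N` denotes an unknown
#' multiplicity of at least 2.
#'
#' @param text A diplotype string containing exactly one `/` (per alternative).
#' @return An object of class `diplotype` with haplotype term tables and any
#'   alternative arrangements.
#' @export
parse_diplotype <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- strsplit(text, " or ", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  parse_one <- function(s) {
    halves <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(halves) != 2L)
      stop("a diplotype must contain exactly one '/': '", s, "'")
    lapply(halves, parse_haplotype)
  }
  primary <- parse_one(parts[1])
  alternatives <- character(0)
  if (length(parts) > 1L) {
    alternatives <- vapply(parts[-1], function(s) {
      format_diplotype_haps(parse_one(s), sort_haps = FALSE)
    }, character(1), USE.NAMES = FALSE)
  }
  structure(list(hap1 = primary[[1]], hap2 = primary[[2]],
                 alternatives = alternatives),
            class = "diplotype")
}

# Internal: star-number sort key for a haplotype (lowest-numbered allele in
# the tandem; letter suffix breaks ties so *2 sorts before *2A).
hap_sort_key <- function(hap) {
  nums <- as.integer(sub("^\\*([0-9]+).*$", "\\1", hap$allele))
  sufs <- sub("^\\*[0-9]+", "", hap$allele)
  i <- order(nums, sufs)[1]
  list(num = nums[i], suf = sufs[i])
}

format_term <- function(allele, copies, unknown) {
  if (unknown) return(paste0(allele, "×N"))
  if (copies >= 2L) return(paste0(allele, "×", copies))
  allele
}

format_haplotype <- function(hap) {
  paste(mapply(format_term, hap$allele, hap$copies, hap$unknown), collapse = "+")
}

format_diplotype_haps <- function(haps, sort_haps = TRUE) {
  if (sort_haps) {
    k1 <- hap_sort_key(haps[[1]]); k2 <- hap_sort_key(haps[[2]])
    if (k2$num < k1$num || (k2$num == k1$num && k2$suf < k1$suf))
      haps <- haps[c(2, 1)]
  }
  paste(vapply(haps, format_haplotype, character(1)), collapse = "/")
}

#' Canonical string form of a diplotype
#'
#' Haplotypes are ordered by their lowest star number (letter suffixes break
#' ties), tandem arrangements keep their physical order, and multiplicities
#' render as `×K`/`×N`.  Alternatives are joined by `" or "` with
#' the arrangement order preserved.
#'
#' @param x A `diplotype`.
#' @param ... Unused.
#' @export
format.diplotype <- function(x, ...) {
  # alternatives pairs keep their reported arrangement (multiplied hap first)
  s <- format_diplotype_haps(list(x$hap1, x$hap2),
                             sort_haps = length(x$alternatives) == 0L)
  if (length(x$alternatives) > 0L)
    s <- paste(c(s, x$alternatives), collapse = " or ")
  s
}

#' @export
print.diplotype <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
as.character.diplotype <- function(x, ...) format(x)

# Internal: all (allele, copies, unknown) terms of both haplotypes.
diplotype_terms <- function(d) {
  rbind(cbind(d$hap1, hap = 1L), cbind(d$hap2, hap = 2L))
}

#' Activity score of a diplotype
#'
#' Sums per-copy activity values over every gene copy on both haplotypes.
#' A term with unknown multiplicity (`×N`) and a positive per-copy value
#' yields an open lower bound, reported as `">k"` with the term evaluated at
#' three copies.  An allele with undefined activity makes the score
#' indeterminate.
#'
#' @param d A `diplotype` or a diplotype string.
#' @param table Named numeric vector of per-copy activity values; defaults to
#'   the packaged CPIC/DPWG-consistent table.
#' @return An object of class `activity_score` with fields `value`, `open`
#'   and `indeterminate`; its `format` method prints `"2.5"`, `">3"` or
#'   `"Indeterminate"`.
#' @export
activity_score <- function(d, table = activity_table()) {
  if (is.character(d)) d <- parse_diplotype(d)
  stopifnot(inherits(d, "diplotype"))
  terms <- diplotype_terms(d)
  unknown_alleles <- setdiff(terms$allele, names(table))
  if (length(unknown_alleles) > 0L)
    stop("allele(s) absent from activity table: ",
         paste(unique(unknown_alleles), collapse = ", "))
  vals <- table[terms$allele]
  if (anyNA(vals)) {
    return(structure(list(value = NA_real_, open = FALSE, indeterminate = TRUE),
                     class = "activity_score"))
  }
  copies <- terms$copies
  open <- any(terms$unknown & vals > 0)
  copies[terms$unknown] <- 3L   # open-bound evaluation point
  value <- sum(vals * copies)
  structure(list(value = value, open = open, indeterminate = FALSE),
            class = "activity_score")
}

#' @export
format.activity_score <- function(x, ...) {
  if (x$indeterminate) return("Indeterminate")
  s <- format(x$value, trim = TRUE)
  if (x$open) paste0(">", s) else s
}

#' @export
print.activity_score <- function(x, ...) {
  cat("Activity score:", format(x), "\n")
  invisible(x)
}

#' @export
as.character.activity_score <- function(x, ...) format(x)

#' Translate an activity score to a metabolizer phenotype
#'
#' Uses the CPIC/DPWG consensus cutpoints: 0 is a poor metabolizer, scores in
#' (0, 1] intermediate, (1, 2.25] normal and above 2.25 ultrarapid.  An open
#' lower bound (`">k"`) is classified just above its bound; an indeterminate
#' score returns `"Indeterminate"`.
#'
#' @param s A nonnegative number or an `activity_score`.
#' @return One of `"Poor"`, `"Intermediate"`, `"Normal"`, `"Ultrarapid"`,
#'   `"Indeterminate"`.
#' @export
phenotype_from_score <- function(s) {
  if (inherits(s, "activity_score")) {
    if (s$indeterminate) return("Indeterminate")
    v <- s$value + if (s$open) 1e-9 else 0
  } else {
    v <- as.numeric(s)
  }
  if (is.na(v)) return("Indeterminate")
  if (v < 0) stop("activity score must be nonnegative")
  if (v == 0) return("Poor")
  if (v <= 1) return("Intermediate")
  if (v <= 2.25) return("Normal")
  "Ultrarapid"
}
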