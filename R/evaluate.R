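# Accuracy and rater-agreement statistics for duplication calls.

#' Cohen's kappa for two raters
#'
#' `(p_o - p_e) / (1 - p_e)` with the observed agreement `p_o` and the
#' chance agreement `p_e` from the raters' marginal category frequencies.
#' When the raters agree on every case the table is degenerate
#' (`p_e` may equal 1); perfect observed agreement is reported as 1.
#'
#' @param x,y Category vectors of equal positive length.
#' @return Kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) == 0L) stop("cannot compute kappa on zero cases")
  x <- as.character(x); y <- as.character(y)
  po <- mean(x == y)
  if (po == 1) return(1)
  cats <- union(x, y)
  px <- vapply(cats, function(k) mean(x == k), numeric(1))
  py <- vapply(cats, function(k) mean(y == k), numeric(1))
  pe <- sum(px * py)
  (po - pe) / (1 - pe)
}

#' Evaluate duplication calls against truth
#'
#' Accuracy follows the attempted-cases convention: cases deferred to
#' sequencing are excluded from a rater's accuracy.  With two or more raters
#' the report adds the mean pairwise Cohen's kappa on correct-vs-incorrect
#' calls (computed over cases both raters attempted) and, separately, the
#' mean pairwise kappa on the called-vs-deferred decision over all cases.
#'
#' @param calls A data frame with columns `sample_id` and `result` (a star
#'   allele or `"DEFER"`), or a named list of such data frames (one per
#'   rater).
#' @param truth Data frame with `sample_id` and `duplicated_allele`.
#' @return An object of class `call_evaluation`.
#' @export
evaluate_calls <- function(calls, truth) {
  if (is.data.frame(calls)) calls <- list(rater1 = calls)
  if (length(calls) == 0L || any(!vapply(calls, is.data.frame, logical(1))))
    stop("calls must be a data frame or a nonempty list of data frames")
  if (sum(vapply(calls, nrow, integer(1))) == 0L)
    stop("empty call set")
  if (is.null(names(calls)))
    names(calls) <- paste0("rater", seq_along(calls))

  per_rater <- do.call(rbind, lapply(names(calls), function(r) {
    cl <- calls[[r]]
    idx <- match(cl$sample_id, truth$sample_id)
    if (anyNA(idx))
      stop("call(s) without a truth record: ",
           paste(cl$sample_id[is.na(idx)], collapse = ", "))
    correct <- cl$result == truth$duplicated_allele[idx]
    attempted <- cl$result != "DEFER"
    data.frame(rater = r, n_cases = nrow(cl),
               n_attempted = sum(attempted),
               n_correct = sum(correct & attempted),
               accuracy = if (sum(attempted) == 0L) NA_real_ else
                 100 * mean(correct[attempted]),
               stringsAsFactors = FALSE)
  }))

  kappa_correct <- NA_real_
  kappa_decision <- NA_real_
  if (length(calls) >= 2L) {
    # align all raters on the union of cases via the truth table order
    cat_of <- function(cl) {
      idx <- match(truth$sample_id, cl$sample_id)
      res <- cl$result[idx]
      correct <- ifelse(res == "DEFER", NA,
                        ifelse(res == truth$duplicated_allele, "correct", "incorrect"))
      list(correct = correct,
           decision = ifelse(is.na(res), NA, ifelse(res == "DEFER", "deferred", "called")))
    }
    cats <- lapply(calls, cat_of)
    prs <- utils::combn(length(calls), 2L)
    kc <- kd <- numeric(0)
    for (c2 in seq_len(ncol(prs))) {
      a <- cats[[prs[1, c2]]]; b <- cats[[prs[2, c2]]]
      both <- !is.na(a$correct) & !is.na(b$correct)
      if (any(both)) kc <- c(kc, cohens_kappa(a$correct[both], b$correct[both]))
      bothd <- !is.na(a$decision) & !is.na(b$decision)
      if (any(bothd)) kd <- c(kd, cohens_kappa(a$decision[bothd], b$decision[bothd]))
    }
    if (length(kc) > 0L) kappa_correct <- mean(kc)
    if (length(kd) > 0L) kappa_decision <- mean(kd)
  }

  structure(list(per_rater = per_rater,
                 mean_kappa_correct = kappa_correct,
                 mean_kappa_decision = kappa_decision),
            class = "call_evaluation")
}

#' @export
print.call_evaluation <- function(x, ...) {
  cat("Call evaluation\n")
  for (i in seq_len(nrow(x$per_rater))) {
    r <- x$per_rater[i, ]
    cat(sprintf("  %-8s attempted %d/%d, accuracy %s\n", r$rater,
                r$n_attempted, r$n_cases,
                ifelse(is.na(r$accuracy), "NA", sprintf("%.1f%%", r$accuracy))))
  }
  if (!is.na(x$mean_kappa_correct))
    cat(sprintf("  mean pairwise kappa (correct vs incorrect): %.3f\n",
                x$mean_kappa_correct))
  if (!is.na(x$mean_kappa_decision))
    cat(sprintf("  mean pairwise kappa (called vs deferred):   %.3f\n",
                x$mean_kappa_decision))
  invisible(x)
}
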