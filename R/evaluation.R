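# Agreement metrics between two label sequences: one-vs-rest confusion
# summaries, sensitivity/specificity/accuracy, and Cohen's kappa.

#' One-vs-rest confusion summary
#'
#' For every class, counts true/false positives and negatives of the
#' predictions against the reference, treating that class as positive
#' and all others as negative.
#'
#' @param pred,ref equal-length label vectors.
#' @param classes class universe; defaults to the union of observed
#'   labels. Labels outside the universe are an error.
#' @return A list of class `confusion_summary`: `counts` (data.frame
#'   with columns class, tp, fp, fn, tn), `n_total` and `classes`.
#' @export
confusion <- function(pred, ref, classes = NULL) {
  pred <- as.character(pred); ref <- as.character(ref)
  if (length(pred) != length(ref) || length(pred) < 1L)
    stop_leuko("pred and ref must have equal length >= 1",
               class = "invalid_labels")
  if (is.null(classes)) classes <- sort(unique(c(pred, ref)))
  bad <- setdiff(unique(c(pred, ref)), classes)
  if (length(bad))
    stop_leuko("labels outside the class set: ", paste(bad, collapse = ", "),
               class = "invalid_labels")
  n <- length(pred)
  counts <- do.call(rbind, lapply(classes, function(cl) {
    tp <- sum(pred == cl & ref == cl)
    fp <- sum(pred == cl & ref != cl)
    fn <- sum(pred != cl & ref == cl)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               tn = n - tp - fp - fn)
  }))
  structure(list(counts = counts, n_total = n, classes = classes),
            class = "confusion_summary")
}

#' Per-class and macro-averaged classification metrics
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and accuracy
#' `(tp+tn)/n` per class (one-vs-rest), plus their unweighted macro
#' averages. Ratios with a zero denominator are undefined (`NA`) and are
#' excluded from the averages with a warning. `overall_accuracy` is the
#' plain fraction of agreeing positions, i.e. the observed agreement p0.
#'
#' @param cs a `confusion_summary` from [confusion()].
#' @return A list with `per_class` (data.frame, percentages), `macro`
#'   (named vector of macro-averaged percentages) and `overall_accuracy`
#'   (percentage).
#' @export
metrics <- function(cs) {
  stopifnot(inherits(cs, "confusion_summary"))
  k <- cs$counts
  safe_div <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  per <- data.frame(
    class = k$class,
    sensitivity = 100 * safe_div(k$tp, k$tp + k$fn),
    specificity = 100 * safe_div(k$tn, k$tn + k$fp),
    accuracy = 100 * (k$tp + k$tn) / cs$n_total)
  if (anyNA(per[, -1]))
    warning("undefined metrics (zero denominator) excluded from averages")
  macro <- c(sensitivity = mean(per$sensitivity, na.rm = TRUE),
             specificity = mean(per$specificity, na.rm = TRUE),
             accuracy = mean(per$accuracy, na.rm = TRUE))
  overall <- 100 * sum(k$tp) / cs$n_total
  list(per_class = per, macro = macro, overall_accuracy = overall)
}

#' Cohen's kappa between two label sequences
#'
#' `kappa = (p0 - pe) / (1 - pe)` with observed agreement `p0` the
#' fraction of matching positions and chance agreement
#' `pe = sum_c p_a(c) p_b(c)` from the raters' marginal label
#' frequencies. When both raters assign a single identical label
#' (`pe = 1`), kappa is 1 by convention.
#'
#' @param a,b equal-length label vectors.
#' @return A list of class `kappa_result` with `p0`, `pe` and `kappa`.
#' @export
cohen_kappa <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b) || length(a) < 1L)
    stop_leuko("label vectors must have equal length >= 1",
               class = "invalid_labels")
  n <- length(a)
  p0 <- mean(a == b)
  classes <- union(a, b)
  pa <- vapply(classes, function(cl) mean(a == cl), numeric(1))
  pb <- vapply(classes, function(cl) mean(b == cl), numeric(1))
  pe <- sum(pa * pb)
  kap <- if (abs(1 - pe) < .Machine$double.eps) 1 else (p0 - pe) / (1 - pe)
  structure(list(p0 = p0, pe = pe, kappa = kap), class = "kappa_result")
}

#' Consensus labels of two raters
#'
#' Restricts two expert label sequences to the cells on which the raters
#' agree; disagreements are excluded and reported, so downstream
#' comparisons run against an unambiguous reference.
#'
#' @param e1,e2 equal-length label vectors.
#' @return List with `keep` (logical vector of agreeing positions),
#'   `labels` (the consensus labels) and `n_excluded`.
#' @export
joint_labels <- function(e1, e2) {
  e1 <- as.character(e1); e2 <- as.character(e2)
  if (length(e1) != length(e2))
    stop_leuko("expert label vectors must have equal length",
               class = "invalid_labels")
  keep <- e1 == e2
  list(keep = keep, labels = e1[keep], n_excluded = sum(!keep))
}
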