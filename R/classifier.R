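# Threshold decision tree assigning a feature vector to one of eight
# myeloid maturation classes.

#' The eight maturation classes
#'
#' Myeloblast (MB), promyelocyte (PM), myelocyte (M), metamyelocyte (MM),
#' band (B), neutrophil (N), plus two deliberate overlap classes for
#' borderline cells: `MB|PM` and `PM|M`.
#'
#' @return Character vector of the eight class labels.
#' @export
cml_classes <- function() c("MB", "PM", "M", "MM", "B", "N", "MB|PM", "PM|M")

#' Outcome label for cells that cannot be classified
#'
#' Returned when a feature required on the traversed branch is missing.
#'
#' @return The string `"unclassifiable"`.
#' @export
unclassifiable_label <- function() "unclassifiable"

#' Decision-tree thresholds
#'
#' All defaults are the tree's published operating points at the
#' reference acquisition geometry (2592 x 3872 px). Area thresholds
#' (`aon_*`) are in px^2 and the perimeter threshold `p1_band` in px;
#' use [scale_classifier_config()] for images at other resolutions.
#' ACoC thresholds are on the 8-bit-encoded b* axis (see
#' [morph_options()]).
#'
#' @param t1t2_regular T1/T2 above which a nucleus counts as regular
#'   (round/oval).
#' @param t1t2_notch_low lower edge of the T1/T2 band in which a shallow
#'   notch may be ignored based on cytoplasm colour.
#' @param acoc_notch ACoC below which the notch is ignored (basophilic
#'   cytoplasm).
#' @param t1hd_mb T1/HD above which a cell is a myeloblast.
#' @param t1hd_mid lower edge of the intermediate T1/HD band resolved by
#'   colour.
#' @param acoc_mb,acoc_pm ACoC cut points separating MB / MB|PM / PM in
#'   the intermediate band.
#' @param aon_myelocyte,aon_pm nucleus-area cut points separating M /
#'   PM|M / PM.
#' @param t1t2_mm_low lower edge of the metamyelocyte T1/T2 band.
#' @param t1t2_neutrophil T1/T2 below which a cell is a neutrophil.
#' @param p1_band post-split perimeter above which a cell is a band.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(t1t2_regular = 0.92,
                              t1t2_notch_low = 0.86,
                              acoc_notch = 30,
                              t1hd_mb = 3.7,
                              t1hd_mid = 2.1,
                              acoc_mb = 24,
                              acoc_pm = 27,
                              aon_myelocyte = 110000,
                              aon_pm = 115000,
                              t1t2_mm_low = 0.53,
                              t1t2_neutrophil = 0.1,
                              p1_band = 475) {
  cfg <- structure(list(
    t1t2_regular = t1t2_regular, t1t2_notch_low = t1t2_notch_low,
    acoc_notch = acoc_notch, t1hd_mb = t1hd_mb, t1hd_mid = t1hd_mid,
    acoc_mb = acoc_mb, acoc_pm = acoc_pm, aon_myelocyte = aon_myelocyte,
    aon_pm = aon_pm, t1t2_mm_low = t1t2_mm_low,
    t1t2_neutrophil = t1t2_neutrophil, p1_band = p1_band
  ), class = "classifier_config")
  validate_classifier_config(cfg)
  cfg
}

validate_classifier_config <- function(cfg) {
  with(cfg, {
    if (!(t1t2_neutrophil < t1t2_mm_low && t1t2_mm_low < t1t2_notch_low &&
          t1t2_notch_low < t1t2_regular))
      stop_leuko("T1/T2 thresholds must be ordered ",
                 "neutrophil < mm_low < notch_low < regular",
                 class = "invalid_config")
    if (!(acoc_mb < acoc_pm))
      stop_leuko("acoc_mb must be below acoc_pm", class = "invalid_config")
    if (!(aon_myelocyte <= aon_pm))
      stop_leuko("aon_myelocyte must not exceed aon_pm",
                 class = "invalid_config")
    if (!(t1hd_mid < t1hd_mb))
      stop_leuko("t1hd_mid must be below t1hd_mb", class = "invalid_config")
  })
  invisible(cfg)
}

#' Rescale absolute thresholds for a different image resolution
#'
#' Length thresholds scale linearly with the factor and area thresholds
#' quadratically; the dimensionless ratio and colour thresholds are
#' unchanged.
#'
#' @param cfg a [classifier_config()].
#' @param scale linear scale factor relative to the reference geometry.
#' @return A rescaled `classifier_config`.
#' @export
scale_classifier_config <- function(cfg, scale) {
  stopifnot(inherits(cfg, "classifier_config"), scale > 0)
  cfg$aon_myelocyte <- cfg$aon_myelocyte * scale^2
  cfg$aon_pm <- cfg$aon_pm * scale^2
  cfg$p1_band <- cfg$p1_band * scale
  cfg
}

#' Write / read a classifier configuration as JSON
#'
#' @param cfg a `classifier_config`.
#' @param path file path.
#' @return `write_classifier_config()` returns `path` invisibly;
#'   `read_classifier_config()` returns a validated `classifier_config`.
#'   Unknown keys in the file are an error.
#' @export
write_classifier_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "classifier_config"))
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier_config
#' @export
read_classifier_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(classifier_config))
  extra <- setdiff(names(vals), known)
  if (length(extra))
    stop_leuko("unknown configuration keys: ", paste(extra, collapse = ", "),
               class = "invalid_config")
  do.call(classifier_config, vals)
}

#' Classify one cell with the decision tree
#'
#' The tree first short-circuits multi-lobed nuclei to neutrophil, then
#' routes on nucleus regularity (T1/T2), with a colour-controlled rescue
#' of shallow notches in basophilic cells (T1 is replaced by T2 and the
#' cell continues on the regular branch); regular nuclei are staged by
#' T1/HD, colour and nucleus area into MB / MB|PM / PM / PM|M / M, and
#' irregular nuclei by T1/T2 and the post-split perimeter into MM / B /
#' N.
#'
#' Boundary convention at exact threshold equality: strict comparisons
#' send borderline cells toward the later, more ambiguous outcome (e.g.
#' T1/T2 = 0.92 goes to the irregular branch; ACoC of exactly 24 or 27
#' gives MB|PM; AoN of exactly 110000 or 115000 gives PM|M; P1 = 475
#' gives N). Cells with T1/T2 between `t1t2_notch_low` and
#' `t1t2_regular` whose cytoplasm is not basophilic fall to the
#' irregular branch, where the metamyelocyte band is treated as
#' extending up to `t1t2_regular`.
#'
#' @param fv a [feature_vector()] (or coercible named list).
#' @param cfg a [classifier_config()].
#' @return List with `label` (one of [cml_classes()] or
#'   `"unclassifiable"`) and `trace`, the ordered stage path.
#' @export
classify <- function(fv, cfg = classifier_config()) {
  if (!inherits(fv, "feature_vector")) fv <- do.call(feature_vector, as.list(fv))
  validate_classifier_config(cfg)
  trace <- character(0)
  note <- function(s) trace <<- c(trace, s)
  need <- function(x, what) {
    if (is.null(x) || length(x) == 0L || is.na(x)) {
      note(paste0("missing:", what))
      return(FALSE)
    }
    TRUE
  }
  done <- function(label) list(label = label, trace = trace)

  note("stage1:num")
  if (!need(fv$num, "num")) return(done(unclassifiable_label()))
  if (fv$num > 1L) return(done("N"))

  r <- fv$t1_over_t2
  q <- fv$t1_over_hd
  note("stage2:t1t2")
  if (!need(r, "t1_over_t2")) return(done(unclassifiable_label()))
  regular <- r > cfg$t1t2_regular
  if (!regular && r > cfg$t1t2_notch_low) {
    note("stage3:notch-band")
    if (!need(fv$acoc, "acoc")) return(done(unclassifiable_label()))
    note("stage4:acoc-notch")
    if (fv$acoc < cfg$acoc_notch) {
      # ignore the notch: T2 stands in for T1 from here on
      if (!is.null(q) && !is.na(q) && !is.na(r) && r > 0) q <- q / r
      r <- 1
      regular <- TRUE
      note("substitute:t1<-t2")
    }
  }

  if (regular) {
    note("stage5:t1hd-mb")
    if (!need(q, "t1_over_hd")) return(done(unclassifiable_label()))
    if (q > cfg$t1hd_mb) return(done("MB"))
    note("stage6:t1hd-mid")
    if (q > cfg$t1hd_mid) {
      if (!need(fv$acoc, "acoc")) return(done(unclassifiable_label()))
      note("stage7:acoc-mb")
      if (fv$acoc < cfg$acoc_mb) return(done("MB"))
      note("stage8:acoc-pm")
      if (fv$acoc > cfg$acoc_pm) return(done("PM"))
      return(done("MB|PM"))
    }
    note("stage9:aon-m")
    if (!need(fv$aon, "aon")) return(done(unclassifiable_label()))
    if (fv$aon < cfg$aon_myelocyte) return(done("M"))
    note("stage10:aon-pm")
    if (fv$aon > cfg$aon_pm) return(done("PM"))
    return(done("PM|M"))
  }

  note("stage11:t1t2-mm")
  if (r >= cfg$t1t2_mm_low) return(done("MM"))
  note("stage12:t1t2-n")
  if (r < cfg$t1t2_neutrophil) return(done("N"))
  note("stage13:p1")
  if (!need(fv$p1, "p1")) return(done(unclassifiable_label()))
  if (fv$p1 > cfg$p1_band) return(done("B"))
  done("N")
}

#' Classify a batch of feature vectors
#'
#' @param fvs a list of feature vectors, or a data.frame with columns
#'   `num`, `aon`, `acoc`, `p1`, `t1_over_t2`, `t1_over_hd` (as written
#'   by [extract_features_batch()]).
#' @param cfg a [classifier_config()].
#' @param quiet suppress the per-class count message.
#' @return Character vector of labels, in input order.
#' @export
classify_batch <- function(fvs, cfg = classifier_config(), quiet = FALSE) {
  if (is.data.frame(fvs)) {
    fvs <- lapply(seq_len(nrow(fvs)), function(i) {
      feature_vector(num = fvs$num[i], aon = fvs$aon[i], acoc = fvs$acoc[i],
                     p1 = fvs$p1[i], t1_over_t2 = fvs$t1_over_t2[i],
                     t1_over_hd = fvs$t1_over_hd[i])
    })
  }
  labels <- vapply(fvs, function(fv) {
    tryCatch(classify(fv, cfg)$label, error = function(e) unclassifiable_label())
  }, character(1))
  if (!quiet && length(labels)) {
    counts <- table(factor(labels, levels = c(cml_classes(),
                                              unclassifiable_label())))
    counts <- counts[counts > 0]
    message("classified ", length(labels), " cells: ",
            paste(names(counts), counts, sep = "=", collapse = ", "))
  }
  labels
}
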