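# Image file I/O and the end-to-end pipeline
# (segment -> features -> classify), plus helpers to score pipeline
# output against ground truth.

#' Read an RGB image file
#'
#' PNG, TIFF or JPEG. The result is the package's working representation:
#' an H x W x 3 array of 8-bit intensities indexed \[row, col, channel\].
#'
#' @param path image file.
#' @return H x W x 3 numeric array in \[0, 255\].
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path))
    stop_leuko("no such file: ", path, class = "io_error")
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e)
                    stop_leuko("cannot read image ", path, ": ",
                               conditionMessage(e), class = "io_error"))
  a <- as.array(img)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), dim = c(dim(a), 3))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  out <- aperm(a, c(2, 1, 3)) * 255
  assert_rgb_image(out)
  out
}

#' Write an RGB image array as an 8-bit image file
#'
#' @param img H x W x 3 array in \[0, 255\].
#' @param path output file; format follows the extension.
#' @return `path`, invisibly.
#' @export
write_rgb_image <- function(img, path) {
  assert_rgb_image(img)
  EBImage::writeImage(EBImage::Image(aperm(img / 255, c(2, 1, 3)),
                                     colormode = "Color"), path)
  invisible(path)
}

#' Write / read an integer label image as 16-bit TIFF
#'
#' @param labels integer matrix (values 0--65535).
#' @param path file path (use a `.tif` extension; PNG output would be
#'   quantized to 8 bits).
#' @return The path (writer, invisibly) or an integer matrix (reader).
#' @export
write_label_image <- function(labels, path) {
  stopifnot(is.matrix(labels), max(labels) <= 65535)
  EBImage::writeImage(EBImage::Image(t(labels) / 65535), path, bits = 16L)
  invisible(path)
}

#' @rdname write_label_image
#' @export
read_label_image <- function(path) {
  a <- as.array(EBImage::readImage(path))
  if (length(dim(a)) > 2L) a <- a[, , 1]
  matrix(as.integer(round(t(a) * 65535)), ncol(a), nrow(a))
}

#' Run the full pipeline on one image
#'
#' Segments the frame, extracts the morphometric features of every
#' classifiable cell and runs the decision tree.
#'
#' @param img H x W x 3 RGB array, or a file path.
#' @param scale linear scale factor relative to the reference geometry;
#'   propagated to segmentation lengths, feature thresholds and the
#'   classifier's absolute thresholds.
#' @param seg_opts,morph_opts,cfg optional overrides; by default derived
#'   from `scale`.
#' @return List with `segmentation` (output of [segment_image()]) and
#'   `features` (data.frame including a `label` column).
#' @export
process_image <- function(img, scale = 1, seg_opts = NULL, morph_opts = NULL,
                          cfg = NULL) {
  if (is.character(img)) img <- read_rgb_image(img)
  if (is.null(seg_opts)) seg_opts <- seg_options(scale = scale)
  if (is.null(morph_opts)) morph_opts <- morph_options(scale = scale)
  if (is.null(cfg)) cfg <- scale_classifier_config(classifier_config(), scale)
  seg <- segment_image(img, seg_opts)
  feats <- extract_features_batch(seg$records, img, morph_opts)
  feats$label <- if (nrow(feats)) classify_batch(feats, cfg, quiet = TRUE)
                 else character(0)
  list(segmentation = seg, features = feats)
}

# Intersection-over-union of two masks.
mask_iou <- function(a, b) {
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Score pipeline output against a synthetic scene's ground truth
#'
#' Each ground-truth cell is matched to the segmented record with the
#' highest cell-mask IoU; the match carries the predicted label and the
#' Dice coefficients of the cell and nucleus masks.
#'
#' @param result output of [process_image()].
#' @param scene a `synthetic_scene`.
#' @return data.frame with one row per ground-truth cell: `true`,
#'   `pred` (`NA` if unmatched or unclassifiable), `dice_cell`,
#'   `dice_nucleus`, `nc_achieved`.
#' @export
score_against_truth <- function(result, scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  recs <- result$segmentation$records
  feats <- result$features
  rows <- lapply(scene$truth, function(tr) {
    best <- 0; best_rec <- NULL
    for (rec in recs) {
      iou <- mask_iou(rec$cell_mask, tr$cell_mask)
      if (iou > best) { best <- iou; best_rec <- rec }
    }
    if (is.null(best_rec) || best < 0.25)
      return(data.frame(true = tr$label, pred = NA_character_,
                        dice_cell = 0, dice_nucleus = 0,
                        nc_achieved = tr$nc_achieved))
    pred <- feats$label[feats$cell_id == best_rec$cell_id]
    data.frame(
      true = tr$label,
      pred = if (length(pred)) pred else NA_character_,
      dice_cell = dice_coefficient(best_rec$cell_mask, tr$cell_mask),
      dice_nucleus = dice_coefficient(best_rec$nucleus_mask,
                                      tr$nucleus_mask),
      nc_achieved = tr$nc_achieved)
  })
  do.call(rbind, rows)
}

#' Is a predicted label the true class or its adjacent overlap class?
#'
#' The two overlap outcomes absorb borderline cells between adjacent
#' stages: `MB|PM` is compatible with true MB or PM, and `PM|M` with
#' true PM or M.
#'
#' @param true true pure-class labels.
#' @param pred predicted labels.
#' @return Logical vector.
#' @export
label_compatible <- function(true, pred) {
  ok <- !is.na(pred) & (pred == true)
  ok | (!is.na(pred) & ((true == "MB" & pred == "MB|PM") |
                          (true == "PM" & pred %in% c("MB|PM", "PM|M")) |
                          (true == "M" & pred == "PM|M")))
}

#' Run and score the pipeline over a synthetic dataset
#'
#' @param scenes list of `synthetic_scene` objects (one or more cells
#'   each).
#' @param scale the scale the scenes were rendered at.
#' @return data.frame: one row per ground-truth cell with scene index,
#'   true/predicted labels, Dice coefficients and compatibility flag.
#' @export
evaluate_pipeline <- function(scenes, scale = 1) {
  rows <- lapply(seq_along(scenes), function(i) {
    res <- process_image(scenes[[i]]$image, scale = scale)
    sc <- score_against_truth(res, scenes[[i]])
    sc$scene <- i
    sc
  })
  out <- do.call(rbind, rows)
  out$compatible <- label_compatible(out$true, out$pred)
  out
}
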