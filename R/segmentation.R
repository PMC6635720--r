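# Whole-cell and nucleus segmentation of stained smear images.
#
# The cell mask is obtained from the yellow (CMYK) channel: contrast
# enhancement, repeated 3x3 minimum filtering, Otsu thresholding (cells
# are the dark population) and morphological clean-up. Nuclei are then
# extracted inside the cell regions from the a* channel of CIELAB after
# heavy Gaussian smoothing, a second Otsu threshold and small-scale
# morphology. Touching cells are separated by a watershed on the distance
# transform.

#' Segmentation options
#'
#' All length parameters are expressed at the reference acquisition
#' geometry (2592 x 3872 px at x1000 magnification) and are multiplied by
#' `scale` so that images rendered or acquired at other resolutions can be
#' processed consistently.
#'
#' @param scale linear scale factor relative to the reference geometry.
#' @param ei_method how the enhanced image combines the linear stretch `L`
#'   and histogram equalization `H` of the yellow channel: one of
#'   `"mean"` (default, `(L + H) / 2` rescaled to \[0, 1\]),
#'   `"sum-clipped"`, `"L-only"`, `"H-only"`.
#' @param min_filter_repeats number of passes of the 3x3 minimum filter.
#' @param cell_polarity which side of the Otsu threshold is a cell in the
#'   enhanced, min-filtered image (`"dark"` by default).
#' @param opening_radius,closing_radius disc radii (px, reference scale)
#'   for the opening and closing that clean the cell mask.
#' @param nucleus_sigma standard deviation (px, reference scale) of the
#'   Gaussian filter applied to the a* channel.
#' @param nucleus_closing_diam,nucleus_opening_diam disc diameters (px,
#'   reference scale) for the nucleus mask morphology.
#' @param nucleus_polarity side of the a* Otsu threshold that is nucleus;
#'   stained nuclei have high a* (magenta), hence `"bright"`.
#' @param area_fraction components of the nucleus mask smaller than this
#'   fraction of the largest component are discarded as stain debris.
#' @param watershed_h h-maxima suppression depth (px, reference scale)
#'   used when splitting touching cells.
#' @param min_cell_area minimum area (px^2, reference scale) for a
#'   watershed region to be kept as a candidate cell.
#' @return A list of class `seg_options`.
#' @export
seg_options <- function(scale = 1,
                        ei_method = c("mean", "sum-clipped", "L-only", "H-only"),
                        min_filter_repeats = 3L,
                        cell_polarity = c("dark", "bright"),
                        opening_radius = 5,
                        closing_radius = 10,
                        nucleus_sigma = 33,
                        nucleus_closing_diam = 10,
                        nucleus_opening_diam = 2,
                        nucleus_polarity = c("bright", "dark"),
                        area_fraction = 0.25,
                        watershed_h = 5,
                        min_cell_area = 2000) {
  stopifnot(scale > 0, min_filter_repeats >= 1, area_fraction >= 0,
            area_fraction <= 1)
  structure(list(
    scale = scale,
    ei_method = match.arg(ei_method),
    min_filter_repeats = as.integer(min_filter_repeats),
    cell_polarity = match.arg(cell_polarity),
    opening_radius = opening_radius,
    closing_radius = closing_radius,
    nucleus_sigma = nucleus_sigma,
    nucleus_closing_diam = nucleus_closing_diam,
    nucleus_opening_diam = nucleus_opening_diam,
    nucleus_polarity = match.arg(nucleus_polarity),
    area_fraction = area_fraction,
    watershed_h = watershed_h,
    min_cell_area = min_cell_area
  ), class = "seg_options")
}

#' Contrast enhancement of the yellow channel
#'
#' Combines a linear contrast stretch `L` and a 256-level histogram
#' equalization `H` of the input. The default combination is the
#' arithmetic mean of the two, rescaled to span \[0, 1\].
#'
#' A constant image has no defined stretch; it is returned unchanged with
#' a warning.
#'
#' @param y numeric matrix in \[0, 1\].
#' @param method see [seg_options()].
#' @return Enhanced image, numeric matrix in \[0, 1\].
#' @export
enhance_contrast <- function(y, method = "mean") {
  assert_gray(y)
  rng <- range(y)
  if (diff(rng) <= .Machine$double.eps) {
    warning("constant image: contrast enhancement is undefined, returning input")
    return(y)
  }
  L <- (y - rng[1]) / diff(rng)
  H <- equalize_hist(y)
  ei <- switch(method,
    "mean" = (L + H) / 2,
    "sum-clipped" = pmin(L + H, 1),
    "L-only" = L,
    "H-only" = H,
    stop_leuko("unknown ei_method: ", method, class = "invalid_option"))
  r <- range(ei)
  if (diff(r) > .Machine$double.eps) ei <- (ei - r[1]) / diff(r)
  ei
}

#' Histogram equalization over 256 bins
#'
#' Classic cumulative-histogram remapping: every pixel is replaced by the
#' empirical CDF of its intensity bin, rescaled so the occupied range
#' spans \[0, 1\]. Ties (pixels in the same bin) map to the same value.
#'
#' @param y numeric matrix in \[0, 1\].
#' @param levels number of histogram bins.
#' @return Equalized matrix in \[0, 1\].
#' @export
equalize_hist <- function(y, levels = 256L) {
  assert_gray(y)
  breaks <- seq(0, 1, length.out = levels + 1L)
  bin <- pmin(pmax(findInterval(y, breaks, rightmost.closed = TRUE), 1L),
              levels)
  counts <- tabulate(bin, nbins = levels)
  cdf <- cumsum(counts) / length(y)
  cdf_min <- min(cdf[counts > 0])
  val <- if (cdf_min >= 1) rep(0, levels) else
    (cdf - cdf_min) / (1 - cdf_min)
  out <- val[bin]
  dim(out) <- dim(y)
  out
}

#' Repeated 3x3 minimum filter
#'
#' Grayscale erosion with a 3x3 square window applied `repeats` times;
#' image borders are handled by edge replication.
#'
#' @param img numeric matrix in \[0, 1\].
#' @param repeats number of passes (>= 1).
#' @return Filtered matrix.
#' @export
min_filter_3x3 <- function(img, repeats = 3L) {
  assert_gray(img)
  stopifnot(repeats >= 1)
  out <- img
  for (i in seq_len(repeats)) {
    m <- out
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      m <- pmin(m, shift_replicate(out, dr, dc))
    }
    out <- m
  }
  out
}

#' Otsu threshold of a sample of intensities
#'
#' Exhaustive maximisation of the between-class variance over a 256-bin
#' histogram of values in \[0, 1\]. Operating on a plain vector lets the
#' same thresholder run on full frames and on region-restricted samples
#' (e.g. only the pixels inside a cell).
#'
#' @param values numeric vector in \[0, 1\] with at least two distinct
#'   values.
#' @param levels number of histogram bins.
#' @return The threshold, the upper edge of the optimal cut bin.
#' @export
otsu_threshold <- function(values, levels = 256L) {
  values <- values[is.finite(values)]
  if (length(values) == 0L || diff(range(values)) <= .Machine$double.eps)
    stop_leuko("cannot threshold a constant sample", class = "no_threshold")
  breaks <- seq(0, 1, length.out = levels + 1L)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L),
              levels)
  n <- tabulate(bin, nbins = levels)
  p <- n / sum(n)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  w0 <- cumsum(p)[-levels]
  w1 <- 1 - w0
  mu0 <- cumsum(p * mids)[-levels]
  muT <- sum(p * mids)
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, levels - 1L)
  sigma_b[valid] <- (muT * w0[valid] - mu0[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b)
  breaks[k + 1L]
}

#' Otsu binarisation of a grayscale image
#'
#' @param img numeric matrix in \[0, 1\], not constant.
#' @param polarity `"dark"` makes pixels strictly below the threshold
#'   foreground, `"bright"` pixels at or above it.
#' @return Logical mask.
#' @export
otsu_mask <- function(img, polarity = c("dark", "bright")) {
  assert_gray(img)
  polarity <- match.arg(polarity)
  thr <- otsu_threshold(as.numeric(img))
  if (polarity == "dark") img < thr else img >= thr
}

#' Morphological clean-up of the cell mask
#'
#' Opening followed by closing (disc structuring elements) and hole
#' filling, so that each remaining component is simply connected.
#'
#' @param mask logical matrix.
#' @param opts [seg_options()].
#' @return Cleaned logical mask.
#' @export
clean_cell_mask <- function(mask, opts = seg_options()) {
  assert_mask(mask)
  if (!any(mask)) {
    warning("empty mask: nothing to clean")
    return(mask)
  }
  m <- EBImage::Image(mask)
  bo <- disc_brush(2 * opts$opening_radius * opts$scale + 1)
  bc <- disc_brush(2 * opts$closing_radius * opts$scale + 1)
  if (!is.null(bo)) m <- EBImage::opening(m, bo)
  if (!is.null(bc)) m <- EBImage::closing(m, bc)
  m <- EBImage::fillHull(m)
  matrix(as.logical(as.matrix(m)), nrow(mask), ncol(mask))
}

#' Nucleus extraction inside the cell regions
#'
#' The RGB frame is restricted to the cell mask (background set to
#' black), converted to CIELAB, and the a* channel -- on which the
#' magenta-stained nucleus stands out from the cytoplasm -- is smoothed
#' with a Gaussian filter, min-max normalised over the cell region and
#' Otsu-thresholded there. The resulting mask is regularised by a closing
#' and an opening, holes are filled and components much smaller than the
#' largest one (stain debris) are discarded.
#'
#' @param img H x W x 3 RGB array in \[0, 255\].
#' @param cell_mask logical matrix of cell foreground, non-empty.
#' @param opts [seg_options()].
#' @return Logical nucleus mask, a subset of `cell_mask`.
#' @export
extract_nucleus_mask <- function(img, cell_mask, opts = seg_options()) {
  assert_rgb_image(img); assert_mask(cell_mask, "cell_mask")
  if (!any(cell_mask))
    stop_leuko("cell mask is empty", class = "empty_nucleus")
  masked <- img
  for (ch in 1:3) {
    sl <- masked[, , ch]; sl[!cell_mask] <- 0; masked[, , ch] <- sl
  }
  a_star <- rgb_to_lab(masked)[, , 2]
  sigma <- max(opts$nucleus_sigma * opts$scale, 0.5)
  blurred <- as.matrix(EBImage::gblur(EBImage::Image(a_star), sigma = sigma))
  vals <- blurred[cell_mask]
  rng <- range(vals)
  if (diff(rng) <= .Machine$double.eps)
    stop_leuko("no nucleus contrast inside the cell region",
               class = "empty_nucleus")
  norm <- (blurred - rng[1]) / diff(rng)
  norm[norm < 0] <- 0; norm[norm > 1] <- 1
  thr <- otsu_threshold(norm[cell_mask])
  nuc <- if (opts$nucleus_polarity == "bright") norm >= thr else norm < thr
  nuc <- nuc & cell_mask
  m <- EBImage::Image(nuc)
  bc <- disc_brush(opts$nucleus_closing_diam * opts$scale)
  bo <- disc_brush(opts$nucleus_opening_diam * opts$scale)
  if (!is.null(bc)) m <- EBImage::closing(m, bc)
  if (!is.null(bo)) m <- EBImage::opening(m, bo)
  m <- EBImage::fillHull(m)
  nuc <- matrix(as.logical(as.matrix(m)), nrow(cell_mask), ncol(cell_mask)) &
    cell_mask
  if (!any(nuc))
    stop_leuko("no nucleus component survived morphology",
               class = "empty_nucleus")
  lab <- label8(nuc)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= opts$area_fraction * max(areas))
  nuc <- lab %in% keep & nuc
  dim(nuc) <- dim(cell_mask)
  if (!any(nuc))
    stop_leuko("no nucleus component survived the area filter",
               class = "empty_nucleus")
  nuc
}

#' Split touching cells by a distance-transform watershed
#'
#' Markers are the regional maxima of the Euclidean distance transform
#' after h-maxima suppression (depth `watershed_h`), and regions are grown
#' by flooding, which cuts touching cells near their waist. Regions
#' smaller than `min_cell_area` (scaled) are dropped.
#'
#' @param cell_mask logical matrix.
#' @param opts [seg_options()].
#' @return Integer label matrix; `0` is background and labels `1..n`
#'   partition the foreground (minus dropped fragments).
#' @export
split_touching_cells <- function(cell_mask, opts = seg_options()) {
  assert_mask(cell_mask, "cell_mask")
  out <- matrix(0L, nrow(cell_mask), ncol(cell_mask))
  if (!any(cell_mask)) return(out)
  d <- EBImage::distmap(EBImage::Image(cell_mask))
  w <- EBImage::watershed(d, tolerance = max(opts$watershed_h * opts$scale, 1),
                          ext = 1)
  lab <- matrix(as.integer(w), nrow(cell_mask), ncol(cell_mask))
  if (max(lab) > 0L) {
    areas <- tabulate(lab[lab > 0L])
    keep <- which(areas >= opts$min_cell_area * opts$scale^2)
    lab[!(lab %in% keep)] <- 0L
    lab[lab > 0L] <- match(lab[lab > 0L], sort(unique(lab[lab > 0L])))
  }
  lab
}

#' Assemble per-cell records from a label image and the nucleus mask
#'
#' For each label, the cell mask is the labelled region, the nucleus mask
#' is its intersection with the global nucleus mask and the cytoplasm is
#' their set difference. Records whose nucleus is empty are flagged as
#' not classifiable (they are typically debris or cut cells) but are
#' still returned.
#'
#' @param labels integer label matrix from [split_touching_cells()].
#' @param nucleus_mask logical matrix, same geometry.
#' @return List of `cell_record` objects with fields `cell_id`,
#'   `cell_mask`, `nucleus_mask`, `cytoplasm_mask`, `bbox` (0-based
#'   half-open `c(r0, r1, c0, c1)`), `classifiable` and
#'   `cytoplasm_empty` (degenerate records whose nucleus fills the whole
#'   cell).
#' @export
make_cell_records <- function(labels, nucleus_mask) {
  stopifnot(is.matrix(labels))
  assert_mask(nucleus_mask, "nucleus_mask")
  stopifnot(all(dim(labels) == dim(nucleus_mask)))
  n <- max(labels)
  records <- vector("list", n)
  for (id in seq_len(n)) {
    cell <- labels == id
    nuc <- cell & nucleus_mask
    records[[id]] <- structure(list(
      cell_id = id,
      cell_mask = cell,
      nucleus_mask = nuc,
      cytoplasm_mask = cell & !nuc,
      bbox = mask_bbox(cell),
      classifiable = any(nuc),
      cytoplasm_empty = !any(cell & !nuc)
    ), class = "cell_record")
  }
  records
}

#' Full segmentation of a smear image
#'
#' Runs the whole chain: CMYK yellow channel, contrast enhancement,
#' repeated minimum filtering, Otsu cell mask, morphological clean-up,
#' a*-channel nucleus extraction, watershed separation of touching cells
#' and per-cell record assembly.
#'
#' @param img H x W x 3 RGB array in \[0, 255\].
#' @param opts [seg_options()].
#' @return List with `records` (list of `cell_record`), `labels`,
#'   `cell_mask`, `nucleus_mask` and the intermediate `enhanced` image.
#' @export
segment_image <- function(img, opts = seg_options()) {
  assert_rgb_image(img)
  y <- rgb_to_cmyk_y(img)
  ei <- tryCatch(enhance_contrast(y, opts$ei_method),
                 warning = function(w) y)
  f <- min_filter_3x3(ei, opts$min_filter_repeats)
  empty <- function() list(records = list(),
                           labels = matrix(0L, nrow(f), ncol(f)),
                           cell_mask = matrix(FALSE, nrow(f), ncol(f)),
                           nucleus_mask = matrix(FALSE, nrow(f), ncol(f)),
                           enhanced = ei)
  cm <- tryCatch(otsu_mask(f, opts$cell_polarity),
                 leukotree_error = function(e) NULL)
  if (is.null(cm) || !any(cm)) return(empty())
  cm <- suppressWarnings(clean_cell_mask(cm, opts))
  if (!any(cm)) return(empty())
  nm <- tryCatch(extract_nucleus_mask(img, cm, opts),
                 leukotree_error = function(e)
                   matrix(FALSE, nrow(cm), ncol(cm)))
  labels <- split_touching_cells(cm, opts)
  records <- make_cell_records(labels, nm)
  list(records = records, labels = labels, cell_mask = cm,
       nucleus_mask = nm, enhanced = ei)
}
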