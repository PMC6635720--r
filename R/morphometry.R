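# Morphometric features of a segmented cell.
#
# The classifier consumes six quantities per cell: the lobe count (Num),
# the nucleus area (AoN), the mean cytoplasm colour on the CIELAB b* axis
# (ACoC), the minimum nucleus thickness T1 found by a modified bottleneck
# algorithm, the minimum convex thickness T2 of the nucleus (rotating
# calipers on the convex hull), the Hausdorff distance HD between nucleus
# and cell borders, and the perimeter P1 of the smaller nucleus part
# after a validated bottleneck split.
#
# Thickness convention: distances between boundary pixel centres are
# converted to material thickness by adding one pixel (a w-pixel-wide
# rectangle has centre span w - 1). The perimeter convention is the count
# of foreground pixels having at least one 4-neighbour in the background.

#' Morphometry options
#'
#' @param scale linear scale factor relative to the reference geometry
#'   (2592 x 3872 px); absolute area thresholds scale with `scale^2` and
#'   length thresholds with `scale`.
#' @param min_contour_sep minimum separation, in contour steps, between
#'   candidate bottleneck points.
#' @param pinch_ratio a boundary point pair is a pinch candidate when its
#'   Euclidean distance is below `pinch_ratio` times the shorter contour
#'   arc between the points; convex outlines (chord/arc >= 2/pi for a
#'   circle) generate no candidates.
#' @param split_ratio,split_min_total acceptance rule for a bottleneck
#'   split: the bigger part must exceed `split_ratio` times the smaller
#'   and the summed area must exceed `split_min_total` px^2 (reference
#'   scale).
#' @param split_comparator direction of the ratio clause;
#'   `"big_over_small"` is the printed rule.
#' @param acoc_offset offset added to the mean cytoplasm b* so that the
#'   ACoC feature lives on the 8-bit-encoded b* axis (neutral at 128)
#'   used by common imaging toolchains; the classifier thresholds are
#'   expressed on that axis.
#' @param hd_directed if `TRUE`, the Hausdorff distance is the directed
#'   distance from nucleus border to cell border only.
#' @param max_contour_points contours longer than this are subsampled
#'   before the all-pairs bottleneck search.
#' @return A list of class `morph_options`.
#' @export
morph_options <- function(scale = 1,
                          min_contour_sep = 10L,
                          pinch_ratio = 0.55,
                          split_ratio = 3.8,
                          split_min_total = 74000,
                          split_comparator = c("big_over_small", "small_over_big"),
                          acoc_offset = 128,
                          hd_directed = FALSE,
                          max_contour_points = 2600L) {
  stopifnot(scale > 0, min_contour_sep >= 1, pinch_ratio > 0)
  structure(list(
    scale = scale,
    min_contour_sep = as.integer(min_contour_sep),
    pinch_ratio = pinch_ratio,
    split_ratio = split_ratio,
    split_min_total = split_min_total,
    split_comparator = match.arg(split_comparator),
    acoc_offset = acoc_offset,
    hd_directed = hd_directed,
    max_contour_points = as.integer(max_contour_points)
  ), class = "morph_options")
}

#' Ordered boundary contour of a mask
#'
#' @param mask logical matrix with at least one foreground pixel.
#' @return A list with one ordered `n x 2` matrix of 1-based (row, col)
#'   boundary coordinates per 8-connected component, largest first.
#' @export
mask_contour <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop_leuko("empty mask has no contour", class = "empty_mask")
  lab <- label8(mask)
  oc <- EBImage::ocontour(lab)
  areas <- tabulate(lab[lab > 0L])
  ord <- order(areas, decreasing = TRUE)
  lapply(oc[ord], function(m) {
    m <- m + 1L
    colnames(m) <- c("row", "col")
    m
  })
}

#' Number of nucleus lobes
#'
#' Lobes are the 8-connected components of the nucleus mask.
#'
#' @param nucleus logical matrix, non-empty.
#' @return Integer component count.
#' @export
count_lobes <- function(nucleus) {
  assert_mask(nucleus, "nucleus")
  if (!any(nucleus)) stop_leuko("empty nucleus mask", class = "empty_mask")
  n_components8(nucleus)
}

#' Nucleus area
#'
#' @param nucleus logical matrix.
#' @return Foreground pixel count.
#' @export
nucleus_area <- function(nucleus) {
  assert_mask(nucleus, "nucleus")
  sum(nucleus)
}

#' Average cytoplasm colour on the CIELAB b* axis
#'
#' @param img H x W x 3 RGB array in \[0, 255\].
#' @param cytoplasm logical matrix selecting the cytoplasm pixels.
#' @return Mean b* over the cytoplasm on the standard CIELAB scale, or
#'   `NA` (with a warning) when the cytoplasm is empty.
#' @export
avg_cytoplasm_b <- function(img, cytoplasm) {
  assert_rgb_image(img); assert_mask(cytoplasm, "cytoplasm")
  if (!any(cytoplasm)) {
    warning("empty cytoplasm: ACoC is undefined for this cell")
    return(NA_real_)
  }
  mean(lab_of_pixels(img, cytoplasm)[, 3])
}

#' Minimum convex thickness of a mask
#'
#' Width of the convex hull of the foreground pixels: the smallest
#' distance between two parallel supporting lines, computed by rotating
#' calipers over the hull edges, plus one pixel for the pixel extent.
#'
#' @param mask logical matrix with at least 3 foreground pixels.
#' @return Minimum hull width in pixels.
#' @export
min_convex_thickness <- function(mask) {
  assert_mask(mask)
  pts <- which(mask, arr.ind = TRUE)
  if (nrow(pts) < 3L)
    stop_leuko("mask too small for a convex width", class = "degenerate_shape")
  hull <- pts[grDevices::chull(pts[, 2], pts[, 1]), , drop = FALSE]
  h <- nrow(hull)
  if (h < 3L) {
    # collinear points: width across the line is a single pixel
    return(1)
  }
  widths <- numeric(h)
  for (i in seq_len(h)) {
    j <- if (i == h) 1L else i + 1L
    e <- hull[j, ] - hull[i, ]
    len <- sqrt(sum(e^2))
    if (len < .Machine$double.eps) { widths[i] <- Inf; next }
    nrm <- c(-e[2], e[1]) / len
    proj <- (hull[, 1] - hull[i, 1]) * nrm[1] + (hull[, 2] - hull[i, 2]) * nrm[2]
    widths[i] <- max(abs(proj))
  }
  min(widths) + 1
}

#' Hausdorff distance between two boundary point sets
#'
#' `h(U, V) = max_u min_v ||u - v||`; the symmetric distance is
#' `max(h(U, V), h(V, U))`.
#'
#' @param u,v `n x 2` numeric matrices of (row, col) coordinates.
#' @param directed if `TRUE` return the directed distance `h(U, V)` only.
#' @return Distance in pixels.
#' @export
hausdorff_distance <- function(u, v, directed = FALSE) {
  if (!is.matrix(u) || !is.matrix(v) || ncol(u) != 2L || ncol(v) != 2L ||
      nrow(u) == 0L || nrow(v) == 0L)
    stop_leuko("contours must be non-empty n x 2 matrices",
               class = "empty_contour")
  directed_h <- function(a, b) {
    worst <- 0
    chunk <- max(1L, floor(4e6 / nrow(b)))
    for (s in seq(1L, nrow(a), by = chunk)) {
      idx <- s:min(s + chunk - 1L, nrow(a))
      d2 <- outer(a[idx, 1], b[, 1], "-")^2 + outer(a[idx, 2], b[, 2], "-")^2
      worst <- max(worst, max(apply(d2, 1, min)))
    }
    sqrt(worst)
  }
  if (directed) directed_h(u, v) else max(directed_h(u, v), directed_h(v, u))
}

# Thicken a rasterised line by one pixel in every direction (the cut used
# to actually disconnect the two sides under 8-connectivity).
thicken_line <- function(px, dims) {
  out <- matrix(FALSE, dims[1], dims[2])
  for (dr in -1:1) for (dc in -1:1) {
    r <- px[, 1] + dr; c <- px[, 2] + dc
    ok <- r >= 1 & r <= dims[1] & c >= 1 & c <= dims[2]
    out[cbind(r[ok], c[ok])] <- TRUE
  }
  out
}

# Partition a mask by removing a thickened cut line and labelling what is
# left; slivers beyond the two largest pieces are attached to the nearer
# large piece.
split_mask_by_segment <- function(mask, a, b) {
  line <- bresenham_line(a[1], a[2], b[1], b[2])
  cut <- thicken_line(line, dim(mask))
  remainder <- mask & !cut
  lab <- label8(remainder)
  n <- max(lab)
  if (n < 2L) return(NULL)
  areas <- tabulate(lab[lab > 0L])
  big2 <- order(areas, decreasing = TRUE)[1:2]
  if (n > 2L) {
    cent <- function(id) {
      idx <- which(lab == id, arr.ind = TRUE)
      colMeans(idx)
    }
    c1 <- cent(big2[1]); c2 <- cent(big2[2])
    for (id in setdiff(seq_len(n), big2)) {
      ci <- cent(id)
      tgt <- if (sum((ci - c1)^2) <= sum((ci - c2)^2)) big2[1] else big2[2]
      lab[lab == id] <- tgt
    }
  }
  m1 <- lab == big2[1]; m2 <- lab == big2[2]
  if (sum(m1) >= sum(m2)) list(part_big = m1, part_small = m2)
  else list(part_big = m2, part_small = m1)
}

#' Bottleneck point pair of a shape
#'
#' Searches the ordered boundary of the (largest component of the) mask
#' for the closest pair of non-adjacent contour points that pinches the
#' shape: the Euclidean distance between the points must be smaller than
#' `pinch_ratio` times the shorter boundary arc connecting them, and --
#' the modification that makes the pair usable for splitting -- the
#' straight segment between them must contain no background pixel.
#' Candidates are visited in order of increasing distance and the first
#' valid pair is accepted; T1 is its distance (plus one pixel extent).
#'
#' Convex shapes have no pinching pair; for them T1 falls back to the
#' minimum convex thickness so that T1/T2 = 1, and no split is performed.
#'
#' @param nucleus logical matrix (a single shape; for multi-lobed masks
#'   the largest 8-connected component is used).
#' @param opts [morph_options()].
#' @return A list of class `split_result` with fields `point_a`,
#'   `point_b`, `t1`, `part_small`, `part_big`, `split_performed` and
#'   `pinch_found`.
#' @export
bottleneck_pair <- function(nucleus, opts = morph_options()) {
  assert_mask(nucleus, "nucleus")
  if (!any(nucleus)) stop_leuko("empty nucleus mask", class = "empty_mask")
  comp <- largest_component(nucleus)
  t2 <- min_convex_thickness(comp)
  if (t2 < 2)
    stop_leuko("shape is thinner than 2 px everywhere",
               class = "degenerate_shape")
  no_split <- function() structure(list(
    point_a = NULL, point_b = NULL, t1 = t2,
    part_small = NULL, part_big = NULL,
    split_performed = FALSE, pinch_found = FALSE), class = "split_result")
  ct <- mask_contour(comp)[[1]]
  n <- nrow(ct)
  if (n < 2L * opts$min_contour_sep + 2L) return(no_split())
  if (n > opts$max_contour_points) {
    step <- ceiling(n / opts$max_contour_points)
    ct <- ct[seq(1L, n, by = step), , drop = FALSE]
    n <- nrow(ct)
  }
  # arc length along the closed contour
  nxt <- c(2:n, 1L)
  steps <- sqrt(rowSums((ct[nxt, , drop = FALSE] - ct)^2))
  cum <- c(0, cumsum(steps))
  total <- cum[n + 1L]
  D2 <- outer(ct[, 1], ct[, 1], "-")^2 + outer(ct[, 2], ct[, 2], "-")^2
  arc <- abs(outer(cum[1:n], cum[1:n], "-"))
  arc <- pmin(arc, total - arc)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  sep <- pmin(sep, n - sep)
  cand <- which(upper.tri(D2) & sep >= opts$min_contour_sep &
                  D2 < (opts$pinch_ratio * arc)^2 & D2 > 0)
  if (length(cand) == 0L) return(no_split())
  cand <- cand[order(D2[cand])]
  # cap the number of interior-segment tests; beyond this the shape is a
  # pathological tangle rather than a pinched nucleus
  if (length(cand) > 600L) cand <- cand[1:600L]
  rows <- (cand - 1L) %% n + 1L
  cols <- (cand - 1L) %/% n + 1L
  for (k in seq_along(cand)) {
    a <- ct[rows[k], ]; b <- ct[cols[k], ]
    line <- bresenham_line(a[1], a[2], b[1], b[2])
    if (all(comp[line])) {
      t1 <- sqrt(D2[cand[k]]) + 1
      parts <- split_mask_by_segment(comp, a, b)
      return(structure(list(
        point_a = unname(a), point_b = unname(b), t1 = t1,
        part_small = if (is.null(parts)) NULL else parts$part_small,
        part_big = if (is.null(parts)) NULL else parts$part_big,
        split_performed = !is.null(parts), pinch_found = TRUE),
        class = "split_result"))
    }
  }
  no_split()
}

#' Acceptance rule for a bottleneck split
#'
#' A split is acceptable when the bigger part's area exceeds
#' `split_ratio` (default 3.8) times the smaller part's and the summed
#' area exceeds `split_min_total` (default 74000 px^2 at reference
#' scale). Otherwise the smaller part should be removed by an area filter
#' and the bottleneck search repeated on the remainder.
#'
#' @param part_big,part_small logical masks or scalar areas (px^2).
#' @param opts [morph_options()]; `split_min_total` is multiplied by
#'   `scale^2`.
#' @return `"accept"` or `"remove_small_and_retry"`.
#' @export
validate_split <- function(part_big, part_small, opts = morph_options()) {
  area_of <- function(x) if (is.matrix(x)) sum(x) else as.numeric(x)
  a_big <- area_of(part_big); a_small <- area_of(part_small)
  if (a_big < a_small) { tmp <- a_big; a_big <- a_small; a_small <- tmp }
  if (a_small <= 0)
    stop_leuko("both parts must be nonempty", class = "invalid_split")
  ratio_ok <- switch(opts$split_comparator,
    big_over_small = a_big > opts$split_ratio * a_small,
    small_over_big = a_big <= opts$split_ratio * a_small)
  total_ok <- (a_big + a_small) > opts$split_min_total * opts$scale^2
  if (ratio_ok && total_ok) "accept" else "remove_small_and_retry"
}

#' Perimeter of the smaller part of a split
#'
#' Counts the border pixels (foreground pixels with a background
#' 4-neighbour) of the smaller part. When no split was performed the
#' feature is 0.
#'
#' @param split a `split_result` from [bottleneck_pair()].
#' @return Perimeter in pixels, or 0 when `split_performed` is `FALSE`.
#' @export
perimeter_smaller_part <- function(split) {
  stopifnot(inherits(split, "split_result"))
  if (!isTRUE(split$split_performed)) return(0)
  mask_perimeter(split$part_small)
}

# Validated-split loop: run the bottleneck split, test the acceptance
# rule; on rejection strip the smaller part (area filter) and retry on
# the remainder. Terminates because every retry removes a part.
validated_split <- function(nucleus, opts = morph_options(), max_iter = 12L) {
  cur <- largest_component(nucleus)
  removed <- 0
  for (i in seq_len(max_iter)) {
    sp <- bottleneck_pair(cur, opts)
    if (!sp$split_performed)
      return(list(split = sp, p1 = 0, iterations = i, removed_area = removed))
    if (validate_split(sp$part_big, sp$part_small, opts) == "accept")
      return(list(split = sp, p1 = perimeter_smaller_part(sp),
                  iterations = i, removed_area = removed))
    removed <- removed + sum(sp$part_small)
    cur <- sp$part_big
  }
  list(split = NULL, p1 = 0, iterations = max_iter, removed_area = removed)
}

#' Construct a feature vector by hand
#'
#' Builds the classifier input from raw measurements or directly from the
#' derived ratios (useful for tests and for classifying externally
#' computed feature tables).
#'
#' @param num lobe count.
#' @param aon nucleus area (px^2).
#' @param acoc average cytoplasm colour (encoded b* axis; see
#'   [morph_options()]).
#' @param t1,t2,hd,p1 raw measurements in pixels.
#' @param t1_over_t2,t1_over_hd ratios; computed from the raw values when
#'   omitted.
#' @return A named list of class `feature_vector`.
#' @export
feature_vector <- function(num = 1L, aon = NA_real_, acoc = NA_real_,
                           t1 = NA_real_, t2 = NA_real_, hd = NA_real_,
                           p1 = NA_real_, t1_over_t2 = NULL,
                           t1_over_hd = NULL) {
  if (is.null(t1_over_t2))
    t1_over_t2 <- if (is.finite(t1) && is.finite(t2) && t2 > 0) t1 / t2 else NA_real_
  if (is.null(t1_over_hd))
    t1_over_hd <- if (is.finite(t1) && is.finite(hd) && hd > 0) t1 / hd else NA_real_
  structure(list(num = as.integer(num), aon = aon, acoc = acoc, t1 = t1,
                 t2 = t2, hd = hd, p1 = p1, t1_over_t2 = t1_over_t2,
                 t1_over_hd = t1_over_hd), class = "feature_vector")
}

#' Extract the classifier features from a segmented cell
#'
#' Orchestrates the morphometric measurements for one `cell_record`: lobe
#' count, nucleus area, mean cytoplasm b*, bottleneck thickness T1,
#' minimum convex thickness T2, nucleus-to-cell Hausdorff distance, and
#' the validated-split perimeter P1. Multi-lobed nuclei have their
#' geometry computed on the largest lobe (the classifier short-circuits
#' on the lobe count anyway). Masks are cropped to the cell bounding box
#' before the geometric work.
#'
#' @param rec a `cell_record` with a non-empty nucleus.
#' @param img the RGB frame the record was segmented from.
#' @param opts [morph_options()].
#' @return A `feature_vector`; fields that could not be measured are `NA`
#'   and listed in `attr(, "flags")`.
#' @export
extract_features <- function(rec, img, opts = morph_options()) {
  stopifnot(inherits(rec, "cell_record"))
  assert_rgb_image(img)
  if (!any(rec$nucleus_mask))
    stop_leuko("record has an empty nucleus", class = "empty_mask")
  flags <- character(0)
  win <- crop_window(rec$bbox, dim(rec$cell_mask), pad = 3L)
  cell <- rec$cell_mask[win$rows, win$cols, drop = FALSE]
  nuc <- rec$nucleus_mask[win$rows, win$cols, drop = FALSE]
  num <- count_lobes(nuc)
  aon <- nucleus_area(nuc)
  acoc_raw <- suppressWarnings(avg_cytoplasm_b(img, rec$cytoplasm_mask))
  if (is.na(acoc_raw)) flags <- c(flags, "acoc_missing")
  acoc <- if (is.na(acoc_raw)) NA_real_ else acoc_raw + opts$acoc_offset
  comp <- largest_component(nuc)
  t2 <- tryCatch(min_convex_thickness(comp), leukotree_error = function(e) NA_real_)
  sp <- tryCatch(bottleneck_pair(comp, opts), leukotree_error = function(e) NULL)
  t1 <- if (is.null(sp)) NA_real_ else sp$t1
  if (is.null(sp)) flags <- c(flags, "t1_missing")
  hd <- tryCatch(
    hausdorff_distance(mask_contour(comp)[[1]], mask_contour(cell)[[1]],
                       directed = opts$hd_directed),
    leukotree_error = function(e) NA_real_)
  if (is.na(hd)) flags <- c(flags, "hd_missing")
  vs <- tryCatch(validated_split(nuc, opts), leukotree_error = function(e) NULL)
  p1 <- if (is.null(vs)) 0 else vs$p1
  fv <- feature_vector(num = num, aon = aon, acoc = acoc, t1 = t1, t2 = t2,
                       hd = hd, p1 = p1)
  attr(fv, "flags") <- flags
  fv
}

#' Feature table for a list of cell records
#'
#' @param records list of `cell_record` objects; records flagged as not
#'   classifiable (empty nucleus) are skipped.
#' @param img the RGB frame.
#' @param opts [morph_options()].
#' @return A data.frame with one row per classifiable cell.
#' @export
extract_features_batch <- function(records, img, opts = morph_options()) {
  rows <- lapply(records, function(rec) {
    if (!isTRUE(rec$classifiable)) return(NULL)
    fv <- extract_features(rec, img, opts)
    data.frame(cell_id = rec$cell_id, num = fv$num, aon = fv$aon,
               acoc = fv$acoc, t1 = fv$t1, t2 = fv$t2, hd = fv$hd,
               p1 = fv$p1, t1_over_t2 = fv$t1_over_t2,
               t1_over_hd = fv$t1_over_hd,
               flags = paste(attr(fv, "flags"), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), num = integer(0),
                      aon = numeric(0), acoc = numeric(0), t1 = numeric(0),
                      t2 = numeric(0), hd = numeric(0), p1 = numeric(0),
                      t1_over_t2 = numeric(0), t1_over_hd = numeric(0),
                      flags = character(0))
  out
}
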