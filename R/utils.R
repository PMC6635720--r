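# Internal raster helpers shared across the package. Masks are logical
# matrices indexed [row, col]; grayscale images are numeric matrices in
# [0, 1]; RGB images are H x W x 3 arrays with 8-bit intensities.

stop_leuko <- function(..., class) {
  stop(structure(class = c(class, "leukotree_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

is_binary_mask <- function(m) is.matrix(m) && is.logical(m)

assert_mask <- function(m, arg = "mask") {
  if (!is_binary_mask(m))
    stop_leuko(arg, " must be a logical matrix", class = "invalid_mask")
  invisible(m)
}

assert_gray <- function(x, arg = "image") {
  if (!is.matrix(x) || !is.numeric(x))
    stop_leuko(arg, " must be a numeric matrix", class = "invalid_image")
  rng <- range(x, finite = TRUE)
  if (rng[1] < -1e-8 || rng[2] > 1 + 1e-8)
    stop_leuko(arg, " must have values in [0, 1]", class = "invalid_image")
  invisible(x)
}

#' Validate an RGB raster
#'
#' Checks that `img` is an H x W x 3 numeric array with 8-bit intensities
#' (values in \[0, 255\]) and at least 32 pixels along each side.
#'
#' @param img array to validate.
#' @return The input, invisibly.
#' @export
assert_rgb_image <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop_leuko("expected an H x W x 3 RGB array", class = "invalid_image")
  if (dim(img)[1] < 32L || dim(img)[2] < 32L)
    stop_leuko("image must be at least 32 x 32 pixels", class = "invalid_image")
  rng <- range(img, finite = TRUE)
  if (rng[1] < 0 || rng[2] > 255)
    stop_leuko("RGB values must lie in [0, 255]", class = "invalid_image")
  invisible(img)
}

# Shift a matrix by (dr, dc) with edge replication.
shift_replicate <- function(m, dr, dc) {
  h <- nrow(m); w <- ncol(m)
  ri <- pmin(pmax(seq_len(h) - dr, 1L), h)
  ci <- pmin(pmax(seq_len(w) - dc, 1L), w)
  m[ri, ci, drop = FALSE]
}

# 8-connected labelling. EBImage::bwlabel() uses 4-connectivity, so labels
# touching only diagonally are merged with a union-find pass.
label8 <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union2 <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb) }
  h <- nrow(lab); w <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(h - 1L), , drop = FALSE]
    if (sh[2] == 1L) {
      a <- a[, seq_len(w - 1L), drop = FALSE]
      b <- lab[2:h, 2:w, drop = FALSE]
    } else {
      a <- a[, 2:w, drop = FALSE]
      b <- lab[2:h, seq_len(w - 1L), drop = FALSE]
    }
    touch <- which(a > 0L & b > 0L & a != b)
    if (length(touch)) {
      pairs <- unique(cbind(a[touch], b[touch]))
      for (k in seq_len(nrow(pairs))) union2(pairs[k, 1], pairs[k, 2])
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- relab[lab[lab > 0L]]
  out
}

n_components8 <- function(mask) max(label8(mask))

largest_component <- function(mask) {
  lab <- label8(mask)
  if (max(lab) == 0L) return(mask & FALSE)
  areas <- tabulate(lab[lab > 0L])
  lab == which.max(areas)
}

# Border pixels: foreground with at least one 4-neighbour that is background
# (pixels on the image edge count as bordering the outside).
mask_border <- function(mask) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2L, w + 2L)
  pad[2:(h + 1L), 2:(w + 1L)] <- mask
  inner <- pad[2:(h + 1L), 2:(w + 1L)]
  nb <- pad[1:h, 2:(w + 1L)] & pad[3:(h + 2L), 2:(w + 1L)] &
    pad[2:(h + 1L), 1:w] & pad[2:(h + 1L), 3:(w + 2L)]
  inner & !nb
}

# Perimeter as the count of border pixels (4-neighbour convention).
mask_perimeter <- function(mask) sum(mask_border(mask))

#' Dice similarity between two binary masks
#'
#' @param a,b logical matrices of identical dimensions.
#' @return `2|A n B| / (|A| + |B|)`, or `NA` if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  assert_mask(a, "a"); assert_mask(b, "b")
  stopifnot(all(dim(a) == dim(b)))
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  2 * sum(a & b) / s
}

# Bresenham line rasterisation between two pixel centres (inclusive).
bresenham_line <- function(r0, c0, r1, c1) {
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dr - dc
  n <- dr + dc + 1L
  rows <- integer(n); cols <- integer(n)
  r <- r0; c <- c0; k <- 0L
  repeat {
    k <- k + 1L
    rows[k] <- r; cols[k] <- c
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dc) { err <- err - dc; r <- r + sr }
    if (e2 < dr) { err <- err + dr; c <- c + sc }
  }
  cbind(row = rows[seq_len(k)], col = cols[seq_len(k)])
}

# Odd-sized disc brush with diameter approximately d pixels (d >= 3);
# returns NULL for diameters too small to matter.
disc_brush <- function(d) {
  d <- round(d)
  if (d < 2) return(NULL)
  size <- if (d %% 2 == 1) d else d + 1
  EBImage::makeBrush(max(size, 3), shape = "disc")
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Crop helpers: bounding box of a mask as a 0-based half-open interval
# c(r0, r1, c0, c1); crop with symmetric padding clipped to the image.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(c(0L, 0L, 0L, 0L))
  c(min(idx[, 1]) - 1L, max(idx[, 1]), min(idx[, 2]) - 1L, max(idx[, 2]))
}

crop_window <- function(bbox, dims, pad = 2L) {
  r <- max(bbox[1] + 1L - pad, 1L):min(bbox[2] + pad, dims[1])
  c <- max(bbox[3] + 1L - pad, 1L):min(bbox[4] + pad, dims[2])
  list(rows = r, cols = c)
}
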