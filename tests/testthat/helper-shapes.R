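# Shape fixtures and independent brute-force oracles used across tests.

disk_mask <- function(h, w, cy, cx, r) {
  rr <- matrix(seq_len(h), h, w)
  cc <- matrix(seq_len(w), h, w, byrow = TRUE)
  (rr - cy)^2 + (cc - cx)^2 <= r^2
}

rect_mask <- function(h, w, r0, r1, c0, c1) {
  m <- matrix(FALSE, h, w)
  m[r0:r1, c0:c1] <- TRUE
  m
}

# two disks bridged by a thin rectangular neck
dumbbell_mask <- function(r = 40, neck_w = 10, neck_len = 60) {
  h <- 2 * r + 21
  w <- 4 * r + neck_len + 21
  cy <- (h + 1) / 2
  m <- disk_mask(h, w, cy, r + 10, r) |
    disk_mask(h, w, cy, w - r - 10, r)
  c0 <- ceiling(r + 10)
  c1 <- floor(w - r - 10)
  m[(cy - neck_w / 2 + 1):(cy + neck_w / 2), c0:c1] <- TRUE
  m
}

# horseshoe with a narrow mouth: the closest boundary pairs sit across
# the mouth gap (background), closer than the true cross-arm thickness
horseshoe_mask <- function(r_out = 60, r_in = 40, mouth = 0.14) {
  side <- 2 * r_out + 21
  cy <- cx <- (side + 1) / 2
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  rad <- sqrt((rr - cy)^2 + (cc - cx)^2)
  ang <- atan2(rr - cy, cc - cx)
  rad <= r_out & rad >= r_in & abs(ang) > mouth
}

# random single-component blob: union of a few disks, lightly smoothed
random_blob <- function(seed, base_r = 30) {
  set.seed(seed)
  n <- sample(3:6, 1)
  side <- 6 * base_r
  cy <- cx <- side / 2
  m <- matrix(FALSE, side, side)
  for (i in seq_len(n)) {
    th <- runif(1, 0, 2 * pi)
    d <- runif(1, 0, base_r)
    r <- runif(1, 0.4, 1) * base_r
    m <- m | disk_mask(side, side, cy + d * sin(th), cx + d * cos(th), r)
  }
  lab <- EBImage::bwlabel(m)
  areas <- tabulate(lab[lab > 0])
  matrix(lab == which.max(areas), side, side)
}

rotate_mask <- function(mask, angle_deg) {
  idx <- which(mask, arr.ind = TRUE)
  th <- angle_deg * pi / 180
  cy <- mean(idx[, 1]); cx <- mean(idx[, 2])
  side <- max(dim(mask)) * 2
  r2 <- round(cy + (idx[, 1] - cy) * cos(th) - (idx[, 2] - cx) * sin(th)) +
    side / 4
  c2 <- round(cx + (idx[, 1] - cy) * sin(th) + (idx[, 2] - cx) * cos(th)) +
    side / 4
  out <- matrix(FALSE, side, side)
  out[cbind(r2, c2)] <- TRUE
  # close single-pixel rotation holes
  m <- EBImage::closing(EBImage::Image(out), EBImage::makeBrush(3, "box"))
  matrix(as.logical(as.matrix(m)), side, side)
}

# O(n * m) double-loop Hausdorff oracle
oracle_hausdorff <- function(u, v, directed = FALSE) {
  h <- function(a, b) {
    worst <- 0
    for (i in seq_len(nrow(a))) {
      best <- Inf
      for (j in seq_len(nrow(b)))
        best <- min(best, sqrt(sum((a[i, ] - b[j, ])^2)))
      worst <- max(worst, best)
    }
    worst
  }
  if (directed) h(u, v) else max(h(u, v), h(v, u))
}

# projection-width oracle: min over 0.1 degree direction steps of the
# foreground's projected extent (plus the 1 px pixel-extent convention)
oracle_projection_width <- function(mask, step_deg = 0.1) {
  pts <- which(mask, arr.ind = TRUE)
  angles <- seq(0, pi, by = step_deg * pi / 180)
  dirs <- rbind(cos(angles), sin(angles))
  proj <- pts %*% dirs
  min(apply(proj, 2, max) - apply(proj, 2, min)) + 1
}

# brute-force repeated 3x3 minimum filter with edge replication
oracle_min_filter <- function(img, repeats) {
  h <- nrow(img); w <- ncol(img)
  out <- img
  for (k in seq_len(repeats)) {
    res <- out
    for (i in seq_len(h)) for (j in seq_len(w)) {
      ri <- max(1, i - 1):min(h, i + 1)
      ci <- max(1, j - 1):min(w, j + 1)
      block <- out[ri, ci]
      # edge replication: out-of-image neighbours repeat the edge value,
      # which never changes the minimum of the clipped block
      res[i, j] <- min(block)
    }
    out <- res
  }
  out
}

# exhaustive Otsu oracle: direct between-class variance from group means
# over every one of the 255 possible cuts of a 256-bin histogram
oracle_otsu <- function(values, levels = 256L) {
  breaks <- seq(0, 1, length.out = levels + 1L)
  bin <- pmin(pmax(findInterval(values, breaks, rightmost.closed = TRUE), 1L),
              levels)
  mids <- (breaks[-1] + breaks[-(levels + 1L)]) / 2
  best <- -Inf; best_t <- NA
  for (t in seq_len(levels - 1L)) {
    lo <- bin <= t
    w0 <- mean(lo)
    if (w0 == 0 || w0 == 1) next
    mu0 <- mean(mids[bin[lo]])
    mu1 <- mean(mids[bin[!lo]])
    sb <- w0 * (1 - w0) * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_t <- breaks[t + 1L] }
  }
  best_t
}

# independent sRGB (D65) -> XYZ -> CIELAB conversion, written from the
# textbook formulas
oracle_srgb_to_lab <- function(rgb) {
  v <- rgb / 255
  lin <- ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
  M <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                0.2126729, 0.7151522, 0.0721750,
                0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
  xyz <- as.numeric(M %*% lin)
  wp <- c(0.95047, 1.0, 1.08883)
  f <- function(t) ifelse(t > (6 / 29)^3, t^(1 / 3),
                          t / (3 * (6 / 29)^2) + 4 / 29)
  fx <- f(xyz[1] / wp[1]); fy <- f(xyz[2] / wp[2]); fz <- f(xyz[3] / wp[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# the eight worked feature vectors of the decision tree and their labels
worked_examples <- function() {
  list(
    list(fv = feature_vector(num = 3), label = "N"),
    list(fv = feature_vector(num = 1, t1_over_t2 = 0.95, t1_over_hd = 4.0),
         label = "MB"),
    list(fv = feature_vector(num = 1, t1_over_t2 = 0.95, t1_over_hd = 3.0,
                             acoc = 25), label = "MB|PM"),
    list(fv = feature_vector(num = 1, t1_over_t2 = 0.95, t1_over_hd = 1.5,
                             aon = 100000), label = "M"),
    list(fv = feature_vector(num = 1, t1_over_t2 = 0.95, t1_over_hd = 1.5,
                             aon = 112000), label = "PM|M"),
    list(fv = feature_vector(num = 1, t1_over_t2 = 0.70), label = "MM"),
    list(fv = feature_vector(num = 1, t1_over_t2 = 0.05), label = "N"),
    list(fv = feature_vector(num = 1, t1_over_t2 = 0.30, p1 = 500),
         label = "B"))
}

# random feature vectors (including threshold boundary values) for
# totality fuzzing
fuzz_feature_vectors <- function(n, seed) {
  set.seed(seed)
  r_bound <- c(0.1, 0.53, 0.86, 0.92)
  q_bound <- c(2.1, 3.7)
  acoc_bound <- c(24, 27, 30)
  aon_bound <- c(110000, 115000)
  p1_bound <- 475
  lapply(seq_len(n), function(i) {
    pickr <- function(cont, bounds)
      if (runif(1) < 0.25) sample(bounds, 1) else cont
    feature_vector(
      num = sample(1:4, 1, prob = c(0.7, 0.1, 0.1, 0.1)),
      aon = pickr(runif(1, 0, 300000), aon_bound),
      acoc = pickr(runif(1, 0, 255), acoc_bound),
      p1 = pickr(runif(1, 0, 2000), p1_bound),
      t1_over_t2 = pickr(runif(1, 0, 1), r_bound),
      t1_over_hd = pickr(runif(1, 0, 6), q_bound))
  })
}
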