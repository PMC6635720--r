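# Seeded generator of synthetic smear scenes with ground-truth masks.
#
# Each scene holds one white blood cell drawn according to the
# phenomenology of its maturation stage -- nucleus shape (round/oval,
# kidney, band, lobed), nucleus-to-cell area ratio band, cytoplasm colour
# shifting from basophilic blue to pink -- over a slightly warm
# background with red-cell-like distractor disks and Gaussian pixel
# noise. Geometry is calibrated to the reference acquisition scale
# (2592 x 3872 px at x1000) so the classifier's absolute pixel
# thresholds apply; `scale` shrinks everything linearly.

#' Generator colour palette
#'
#' RGB constants used by the renderer. Cytoplasm colours step from deep
#' blue (myeloblast) through lighter blue (promyelocyte, myelocyte) to
#' pinkish lavender (metamyelocyte, band, neutrophil); nuclei are dark
#' magenta-purple and red-cell distractors warm pink. Saturation of the
#' blues is kept moderate so that the nucleus remains the strongest
#' a*-channel structure inside every cell.
#'
#' @return Named list of RGB triples (0--255).
#' @export
synth_palette <- function() {
  list(background = c(248, 242, 190),
       rbc = c(226, 150, 160),
       nucleus = c(135, 5, 140),
       cytoplasm = list(MB = c(70, 90, 215),
                        PM = c(95, 125, 225),
                        M = c(150, 180, 235),
                        MM = c(205, 175, 225),
                        B = c(205, 175, 225),
                        N = c(205, 175, 225)))
}

# Nucleus-to-cell area bands per maturation stage (lower, upper) and the
# narrower bands the sampler actually draws from.
nc_band <- function(class) {
  switch(class,
    MB = c(0.80, 0.95), PM = c(0.70, 0.80), M = c(0.60, 0.70),
    MM = c(0.40, 0.60), B = c(0.30, 0.40), N = c(0.20, 0.30),
    stop_leuko("unknown class: ", class, class = "invalid_spec"))
}

nc_sample_band <- function(class) {
  switch(class,
    MB = c(0.82, 0.88), PM = c(0.72, 0.78), M = c(0.62, 0.68),
    MM = c(0.45, 0.52), B = c(0.31, 0.37), N = c(0.22, 0.28))
}

#' Specification of one synthetic cell
#'
#' Samples (deterministically from `seed`) the free geometric parameters
#' of one cell of the requested maturation stage: cell radius, target
#' nucleus-to-cell area ratio inside the stage's band, nucleus shape
#' parameters, and distractor layout. All lengths are in reference-scale
#' pixels.
#'
#' @param target_class one of the six pure classes `MB`, `PM`, `M`,
#'   `MM`, `B`, `N`.
#' @param seed integer seed controlling every random choice.
#' @param scale linear rendering scale (1 = reference geometry).
#' @param noise_sigma standard deviation of the additive Gaussian pixel
#'   noise, 8-bit intensity units.
#' @param nc_ratio optional override of the target nucleus:cell area
#'   ratio; must lie in the stage's band.
#' @param lobes optional lobe count for class `N` (2--5).
#' @return A list of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(target_class, seed, scale = 1,
                                noise_sigma = 2, nc_ratio = NULL,
                                lobes = NULL) {
  if (!target_class %in% c("MB", "PM", "M", "MM", "B", "N"))
    stop_leuko("target_class must be one of the six pure stages",
               class = "invalid_spec")
  band <- nc_band(target_class)
  with_seed(seed, {
    nc <- if (is.null(nc_ratio)) stats::runif(1, nc_sample_band(target_class)[1],
                                              nc_sample_band(target_class)[2])
          else nc_ratio
    if (nc < band[1] - 1e-9 || nc > band[2] + 1e-9)
      stop_leuko("nc_ratio ", nc, " outside the ", target_class, " band [",
                 band[1], ", ", band[2], "]", class = "invalid_spec")
    r0 <- switch(target_class,
      MB = stats::runif(1, 210, 240), PM = stats::runif(1, 215, 245),
      M = stats::runif(1, 185, 210), MM = stats::runif(1, 200, 230),
      B = stats::runif(1, 330, 355), N = stats::runif(1, 245, 275))
    shape <- switch(target_class,
      MB = "round", PM = "round", M = "round",
      MM = "kidney", B = "band", N = "lobed")
    k <- NULL
    geo <- list()
    if (shape == "round") {
      tail <- switch(target_class,
        MB = NULL,
        PM = list(len = 0.40, base = 0.34, tip = 0.10),
        M = list(len = 0.78, base = 0.36, tip = 0.08))
      geo <- list(tail = tail,
                  tail_angle = stats::runif(1, 0, 2 * pi),
                  offset = switch(target_class, MB = 0.015, PM = 0.02,
                                  M = 0.03))
    } else if (shape == "kidney") {
      geo <- list(rn_frac = 0.865, bite_frac = 0.75,
                  bite_dist = stats::runif(1, 0.95, 1.05),
                  bite_angle = stats::runif(1, 0, 2 * pi),
                  smooth_frac = 0.12)
    } else if (shape == "band") {
      # a band nucleus: a curved tube with a thinner head segment, a
      # distinct waist at the head/body junction (the bottleneck the
      # splitter should find) and rounded ends
      geo <- list(arc_frac = 0.66, sweep = stats::runif(1, 3.5, 3.9),
                  theta0 = stats::runif(1, 0, 2 * pi),
                  waist_u = 0.25, taper = 0.55, dip_amp = 0.355,
                  ramp_width = 0.04, dip_width = 0.05)
    } else {
      k <- if (is.null(lobes)) sample(2:4, 1) else as.integer(lobes)
      if (k < 2L || k > 5L)
        stop_leuko("lobed nuclei support 2-5 lobes", class = "invalid_spec")
      geo <- list(k = k,
                  lobe_jitter = stats::runif(k, 0.92, 1.08),
                  angle0 = stats::runif(1, 0, 2 * pi),
                  angle_jitter = stats::runif(k, -0.12, 0.12))
    }
    n_rbc <- sample(2:3, 1)
    structure(list(
      target_class = target_class, seed = as.integer(seed), scale = scale,
      noise_sigma = noise_sigma, nc_ratio_target = nc, cell_radius = r0,
      nucleus_shape = shape, lobes = k, geometry = geo, n_rbc = n_rbc,
      rbc_radius_frac = stats::runif(n_rbc, 0.22, 0.30),
      cytoplasm_rgb = synth_palette()$cytoplasm[[target_class]],
      nucleus_rgb = synth_palette()$nucleus
    ), class = "synthetic_cell_spec")
  })
}

# -- rasterisation helpers (continuous coordinates, origin at canvas
#    centre, lengths already multiplied by scale) --------------------------

raster_disk <- function(rr, cc, cy, cx, r) (rr - cy)^2 + (cc - cx)^2 <= r^2

raster_quad <- function(rr, cc, quad) {
  inside <- rep(TRUE, length(rr))
  for (i in 1:4) {
    j <- if (i == 4) 1L else i + 1L
    ex <- quad[j, 1] - quad[i, 1]; ey <- quad[j, 2] - quad[i, 2]
    inside <- inside & ((rr - quad[i, 1]) * ey - (cc - quad[i, 2]) * ex <= 0)
  }
  inside
}

open_mask <- function(mask, radius) {
  br <- disc_brush(2 * radius + 1)
  if (is.null(br)) return(mask)
  m <- EBImage::opening(EBImage::Image(mask), br)
  matrix(as.logical(as.matrix(m)), nrow(mask), ncol(mask))
}

#' Render one synthetic cell scene
#'
#' Deterministically draws the cell described by a
#' [synthetic_cell_spec()]: cytoplasm body (with a tapering pseudopod
#' tail for promyelocytes and myelocytes, which stretches the
#' cell border away from the nucleus), the stage-specific nucleus, red
#' -cell-like distractors and Gaussian noise. The achieved
#' nucleus-to-cell area ratio is enforced by construction: for round
#' nuclei the nucleus radius is derived from the rasterised cell area,
#' for irregular nuclei the cell radius is derived from the rasterised
#' nucleus area.
#'
#' @param spec a `synthetic_cell_spec`.
#' @return A list of class `synthetic_scene` with `image` (H x W x 3,
#'   0--255), `truth` (list of one element with `cell_mask`,
#'   `nucleus_mask`, `label`, `nc_achieved`), `seed` and `scale`.
#' @export
render_cell <- function(spec) {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  s <- spec$scale
  r0 <- spec$cell_radius * s
  tail_len <- if (spec$nucleus_shape == "round" && !is.null(spec$geometry$tail))
    spec$geometry$tail$len * r0 else 0
  half <- ceiling(1.35 * (r0 + tail_len)) + 8L
  side <- 2L * half + 1L
  cy <- cx <- half + 1
  rr <- matrix(seq_len(side), side, side)
  cc <- matrix(seq_len(side), side, side, byrow = TRUE)
  rv <- as.numeric(rr); cv <- as.numeric(cc)

  nuc <- cell <- NULL
  if (spec$nucleus_shape == "round") {
    cellv <- raster_disk(rv, cv, cy, cx, r0)
    th <- spec$geometry$tail_angle
    u <- c(sin(th), cos(th)); v <- c(-cos(th), sin(th))
    if (!is.null(spec$geometry$tail)) {
      tl <- spec$geometry$tail
      quad <- rbind(
        c(cy, cx) + (r0 - 5 * s) * u + (tl$base * r0 / 2) * v,
        c(cy, cx) + (r0 - 5 * s) * u - (tl$base * r0 / 2) * v,
        c(cy, cx) + (r0 + tl$len * r0) * u - (tl$tip * r0 / 2) * v,
        c(cy, cx) + (r0 + tl$len * r0) * u + (tl$tip * r0 / 2) * v)
      cellv <- cellv | raster_quad(rv, cv, quad)
    }
    a_cell <- sum(cellv)
    rn <- sqrt(spec$nc_ratio_target * a_cell / pi)
    off <- spec$geometry$offset * r0
    nc_centre <- c(cy, cx) - (off * u)
    if (rn + off > r0 - 2 * s)
      stop_leuko("nucleus does not fit inside the cell",
                 class = "impossible_spec")
    nucv <- raster_disk(rv, cv, nc_centre[1], nc_centre[2], rn)
    cell <- matrix(cellv, side, side); nuc <- matrix(nucv, side, side)
  } else if (spec$nucleus_shape == "kidney") {
    rn <- spec$geometry$rn_frac * r0
    rb <- spec$geometry$bite_frac * rn
    d <- spec$geometry$bite_dist * rn
    th <- spec$geometry$bite_angle
    u <- c(sin(th), cos(th))
    ncentre <- c(cy, cx) + 0.15 * r0 * u
    bcentre <- ncentre + d * u
    nucv <- raster_disk(rv, cv, ncentre[1], ncentre[2], rn) &
      !raster_disk(rv, cv, bcentre[1], bcentre[2], rb)
    nuc <- open_mask(matrix(nucv, side, side),
                     round(spec$geometry$smooth_frac * rn))
    r_cell <- cell_radius_for_nucleus(nuc, spec$nc_ratio_target, cy, cx, s)
    cell <- matrix(raster_disk(rv, cv, cy, cx, r_cell), side, side)
  } else if (spec$nucleus_shape == "band") {
    g <- spec$geometry
    rc <- g$arc_frac * r0
    sweep <- g$sweep
    profile <- function(u) {
      base <- g$taper + (1 - g$taper) * stats::plogis((u - g$waist_u) /
                                                        g$ramp_width)
      base - g$dip_amp * exp(-((u - g$waist_u) / g$dip_width)^2)
    }
    mean_prof <- mean(profile(seq(0, 1, length.out = 400)))
    t0 <- spec$nc_ratio_target * pi * r0^2 / (rc * sweep * mean_prof)
    th0 <- g$theta0
    ang <- atan2(rv - cy, cv - cx) - th0
    uu <- (ang %% (2 * pi)) / sweep
    radial <- sqrt((rv - cy)^2 + (cv - cx)^2)
    inband <- uu <= 1 & abs(radial - rc) <= t0 * profile(uu) / 2
    for (uend in c(0, 1)) {
      ec <- c(cy + rc * sin(th0 + uend * sweep),
              cx + rc * cos(th0 + uend * sweep))
      inband <- inband | raster_disk(rv, cv, ec[1], ec[2],
                                     t0 * profile(uend) / 2)
    }
    nuc <- matrix(inband, side, side)
    r_cell <- cell_radius_for_nucleus(nuc, spec$nc_ratio_target, cy, cx, s)
    cell <- matrix(raster_disk(rv, cv, cy, cx, r_cell), side, side)
  } else { # lobed
    k <- spec$geometry$k
    nc <- spec$nc_ratio_target
    rl0 <- r0 * sqrt(nc / k)
    rl <- rl0 * spec$geometry$lobe_jitter
    rho <- (2 * max(rl) + 85 * s) / (2 * sin(pi / k))
    rho <- min(rho, 0.85 * r0 - max(rl))
    angles <- spec$geometry$angle0 + 2 * pi * (seq_len(k) - 1) / k +
      spec$geometry$angle_jitter
    nucv <- rep(FALSE, length(rv))
    for (i in seq_len(k)) {
      lc <- c(cy + rho * sin(angles[i]), cx + rho * cos(angles[i]))
      nucv <- nucv | raster_disk(rv, cv, lc[1], lc[2], rl[i])
    }
    nuc <- matrix(nucv, side, side)
    r_cell <- cell_radius_for_nucleus(nuc, spec$nc_ratio_target, cy, cx, s)
    cell <- matrix(raster_disk(rv, cv, cy, cx, r_cell), side, side)
  }
  if (!all(cell[nuc]))
    stop_leuko("nucleus does not fit inside the cell",
               class = "impossible_spec")

  pal <- synth_palette()
  img <- array(0, dim = c(side, side, 3))
  for (ch in 1:3) img[, , ch] <- pal$background[ch]
  with_seed(spec$seed + 1L, {
    extent <- max(r0 + tail_len, suppressWarnings(max(
      sqrt((which(cell, arr.ind = TRUE)[, 1] - cy)^2 +
             (which(cell, arr.ind = TRUE)[, 2] - cx)^2))))
    for (i in seq_len(spec$n_rbc)) {
      rr_r <- spec$rbc_radius_frac[i] * r0
      thr <- stats::runif(1, 0, 2 * pi)
      dr <- extent + rr_r + stats::runif(1, 10 * s, 60 * s)
      ctr <- c(cy + dr * sin(thr), cx + dr * cos(thr))
      rbc <- matrix(raster_disk(rv, cv, ctr[1], ctr[2], rr_r), side, side)
      for (ch in 1:3) {
        sl <- img[, , ch]; sl[rbc] <- pal$rbc[ch]; img[, , ch] <- sl
      }
    }
    for (ch in 1:3) {
      sl <- img[, , ch]
      sl[cell] <- spec$cytoplasm_rgb[ch]
      sl[nuc] <- spec$nucleus_rgb[ch]
      img[, , ch] <- sl
    }
    if (spec$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, spec$noise_sigma),
                         dim = dim(img))
  })
  img <- round(pmin(pmax(img, 0), 255))
  nc_achieved <- sum(nuc) / sum(cell)
  if (abs(nc_achieved - spec$nc_ratio_target) > 0.05)
    warning("achieved N:C ", round(nc_achieved, 3),
            " deviates from target ", round(spec$nc_ratio_target, 3))
  structure(list(
    image = img,
    truth = list(list(cell_mask = cell, nucleus_mask = nuc,
                      label = spec$target_class, nc_achieved = nc_achieved)),
    seed = spec$seed, scale = spec$scale
  ), class = "synthetic_scene")
}

# Cell radius realising the target N:C for an already rasterised nucleus,
# clamped so the nucleus stays strictly inside the cell disk.
cell_radius_for_nucleus <- function(nuc, nc_target, cy, cx, s) {
  a_n <- sum(nuc)
  idx <- which(nuc, arr.ind = TRUE)
  reach <- sqrt(max((idx[, 1] - cy)^2 + (idx[, 2] - cx)^2))
  max(sqrt(a_n / (pi * nc_target)), reach + 4 * s)
}

#' Generate a balanced synthetic dataset
#'
#' Renders `n_per_class` cells for each of the six pure maturation
#' stages, with per-cell parameter jitter driven by seeds derived from
#' the master seed.
#'
#' @param n_per_class cells per class (>= 1).
#' @param seed master seed.
#' @param scale,noise_sigma forwarded to [synthetic_cell_spec()].
#' @param classes classes to generate (default all six).
#' @param out_dir optional directory; when given, per-scene PNG images,
#'   16-bit mask PNGs and a `truth.csv` are written there.
#' @return List of `synthetic_scene` objects (invisibly when writing).
#' @export
generate_dataset <- function(n_per_class, seed, scale = 1, noise_sigma = 2,
                             classes = c("MB", "PM", "M", "MM", "B", "N"),
                             out_dir = NULL) {
  stopifnot(n_per_class >= 1)
  combos <- expand.grid(idx = seq_len(n_per_class), class = classes,
                        stringsAsFactors = FALSE)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                      nrow(combos)))
  scenes <- lapply(seq_len(nrow(combos)), function(i) {
    sp <- synthetic_cell_spec(combos$class[i], seed = seeds[i], scale = scale,
                              noise_sigma = noise_sigma)
    render_cell(sp)
  })
  if (!is.null(out_dir)) {
    write_dataset(scenes, out_dir)
    return(invisible(scenes))
  }
  scenes
}

#' Write a synthetic dataset to disk
#'
#' Layout: `images/scene_###.png` (8-bit RGB), `masks/scene_###_cell.png`
#' and `masks/scene_###_nucleus.png` (16-bit label images) and
#' `truth.csv` (scene, file, label, nc_achieved).
#'
#' @param scenes list of `synthetic_scene` objects.
#' @param out_dir target directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(scenes, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  rows <- lapply(seq_along(scenes), function(i) {
    sc <- scenes[[i]]
    stem <- sprintf("scene_%03d", i)
    write_rgb_image(sc$image, file.path(out_dir, "images",
                                        paste0(stem, ".png")))
    write_label_image(sc$truth[[1]]$cell_mask * 1L,
                      file.path(out_dir, "masks", paste0(stem, "_cell.tif")))
    write_label_image(sc$truth[[1]]$nucleus_mask * 1L,
                      file.path(out_dir, "masks",
                                paste0(stem, "_nucleus.tif")))
    data.frame(scene = i, file = paste0("images/", stem, ".png"),
               label = sc$truth[[1]]$label,
               nc_achieved = sc$truth[[1]]$nc_achieved)
  })
  utils::write.csv(do.call(rbind, rows), file.path(out_dir, "truth.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
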