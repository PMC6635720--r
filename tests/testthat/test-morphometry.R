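test_that("lobe counting uses 8-connectivity", {
  one <- disk_mask(60, 60, 30, 30, 15)
  expect_equal(count_lobes(one), 1)
  three <- disk_mask(60, 180, 30, 30, 15) | disk_mask(60, 180, 30, 90, 15) |
    disk_mask(60, 180, 30, 150, 15)
  expect_equal(count_lobes(three), 3)
  diag2 <- matrix(FALSE, 10, 10)
  diag2[4, 4] <- TRUE; diag2[5, 5] <- TRUE
  expect_equal(count_lobes(diag2), 1)
  expect_error(count_lobes(matrix(FALSE, 5, 5)), class = "empty_mask")
})

test_that("nucleus area is the foreground pixel count", {
  sq <- rect_mask(20, 20, 5, 9, 5, 9)
  expect_equal(nucleus_area(sq), 25)
  d <- disk_mask(140, 140, 70, 70, 50)
  expect_lt(abs(nucleus_area(d) - pi * 50^2) / (pi * 50^2), 0.02)
  parts <- disk_mask(80, 160, 40, 40, 20) | disk_mask(80, 160, 40, 120, 15)
  expect_equal(nucleus_area(parts),
               nucleus_area(disk_mask(80, 160, 40, 40, 20)) +
                 nucleus_area(disk_mask(80, 160, 40, 120, 15)))
})

test_that("average cytoplasm b* sits on the standard CIELAB scale", {
  img <- array(0, c(40, 40, 3))
  mask <- rect_mask(40, 40, 10, 30, 10, 30)
  for (ch in 1:3) img[, , ch] <- 128
  expect_lt(abs(avg_cytoplasm_b(img, mask)), 1)
  img[, , 1] <- 0; img[, , 2] <- 0; img[, , 3] <- 255
  expect_lt(avg_cytoplasm_b(img, mask), 0)
  for (ch in 1:3) img[, , ch] <- c(200, 180, 140)[ch]
  expect_lt(abs(avg_cytoplasm_b(img, mask) -
                  unname(oracle_srgb_to_lab(c(200, 180, 140))["b"])), 0.2)
  expect_warning(v <- avg_cytoplasm_b(img, matrix(FALSE, 40, 40)))
  expect_true(is.na(v))
})

test_that("minimum convex thickness matches simple shapes and the projection oracle", {
  rect <- rect_mask(60, 60, 20, 39, 10, 50)   # 20 x 41 rectangle
  expect_equal(min_convex_thickness(rect), 20)
  d <- disk_mask(140, 140, 70, 70, 55)
  expect_lt(abs(min_convex_thickness(d) - 110) / 110, 0.02)
  for (seed in c(3, 14, 25)) {
    blob <- random_blob(seed)
    expect_lt(abs(min_convex_thickness(blob) - oracle_projection_width(blob)) /
                oracle_projection_width(blob), 0.005)
  }
  expect_error(min_convex_thickness(matrix(FALSE, 5, 5)),
               class = "degenerate_shape")
})

test_that("minimum convex thickness is rotation invariant", {
  blob <- random_blob(8)
  w0 <- min_convex_thickness(blob)
  for (ang in c(17, 45, 78, 123)) {
    wr <- min_convex_thickness(rotate_mask(blob, ang))
    expect_lt(abs(wr - w0) / w0, 0.03)
  }
})

test_that("Hausdorff distance is exact on known pairs and symmetric", {
  u <- cbind(c(1, 5, 9), c(2, 4, 8))
  expect_equal(hausdorff_distance(u, u), 0)
  expect_equal(hausdorff_distance(cbind(0, 0), cbind(3, 4)), 5)
  set.seed(2)
  a <- cbind(runif(50, 0, 100), runif(50, 0, 100))
  b <- cbind(runif(40, 0, 100), runif(40, 0, 100))
  expect_equal(hausdorff_distance(a, b), oracle_hausdorff(a, b))
  expect_equal(hausdorff_distance(a, b), hausdorff_distance(b, a))
  expect_equal(hausdorff_distance(a, b, directed = TRUE),
               oracle_hausdorff(a, b, directed = TRUE))
  expect_error(hausdorff_distance(a[0, ], b), class = "empty_contour")
})

test_that("bottleneck pair finds the dumbbell neck and splits it", {
  m <- dumbbell_mask(r = 40, neck_w = 10, neck_len = 60)
  sp <- bottleneck_pair(m)
  expect_true(sp$pinch_found)
  expect_true(sp$split_performed)
  expect_gte(sp$t1, 9); expect_lte(sp$t1, 12)
  # both parts close to a single disk's area
  a_disk <- pi * 40^2
  expect_lt(abs(sum(sp$part_small) - a_disk) / a_disk, 0.25)
  expect_lt(abs(sum(sp$part_big) - a_disk) / a_disk, 0.25)
  # the accepted segment never crosses background (Bresenham re-check)
  line <- leukotree:::bresenham_line(sp$point_a[1], sp$point_a[2],
                                     sp$point_b[1], sp$point_b[2])
  expect_true(all(m[line]))
})

test_that("convex shapes yield no bottleneck and T1/T2 = 1", {
  d <- disk_mask(140, 140, 70, 70, 50)
  sp <- bottleneck_pair(d)
  expect_false(sp$pinch_found)
  expect_false(sp$split_performed)
  expect_equal(sp$t1, min_convex_thickness(d))
})

test_that("pairs whose segment crosses background are rejected", {
  m <- horseshoe_mask()
  sp <- bottleneck_pair(m)
  expect_true(sp$pinch_found)
  # accepted pair spans an arm (thickness ~ 20), not the narrower mouth
  expect_gte(sp$t1, 15)
  line <- leukotree:::bresenham_line(sp$point_a[1], sp$point_a[2],
                                     sp$point_b[1], sp$point_b[2])
  expect_true(all(m[line]))
  # there exist boundary pairs closer than the accepted one whose segment
  # crosses the opening; verify at least one such pair was skipped
  ct <- mask_contour(m)[[1]]
  d_acc <- sqrt(sum((sp$point_a - sp$point_b)^2))
  closer_invalid <- FALSE
  for (i in seq(1, nrow(ct) - 11, by = 7)) {
    for (j in seq(i + 10, nrow(ct), by = 7)) {
      d <- sqrt(sum((ct[i, ] - ct[j, ])^2))
      if (d < d_acc) {
        ln <- leukotree:::bresenham_line(ct[i, 1], ct[i, 2],
                                         ct[j, 1], ct[j, 2])
        if (!all(m[ln])) { closer_invalid <- TRUE; break }
      }
    }
    if (closer_invalid) break
  }
  expect_true(closer_invalid)
})

test_that("split validation implements the area rule", {
  opts <- morph_options()
  expect_equal(validate_split(76000, 19000, opts), "accept")
  expect_equal(validate_split(40000, 30000, opts), "remove_small_and_retry")
  expect_equal(validate_split(50000, 10000, opts), "remove_small_and_retry")
  # thresholds scale quadratically with image scale
  half <- morph_options(scale = 0.5)
  expect_equal(validate_split(76000 / 4, 19000 / 4, half), "accept")
  # mask inputs are measured by area
  big <- rect_mask(400, 400, 1, 380, 1, 200)    # 76000 px
  small <- rect_mask(400, 400, 1, 95, 250, 449 - 250)  # 19000 px
  expect_equal(validate_split(big, small, opts), "accept")
  flipped <- morph_options(split_comparator = "small_over_big")
  expect_equal(validate_split(76000, 19000, flipped),
               "remove_small_and_retry")
})

test_that("perimeter follows the border-pixel convention", {
  sq <- rect_mask(20, 20, 6, 15, 6, 15)
  sp <- structure(list(split_performed = TRUE, part_small = sq),
                  class = "split_result")
  expect_equal(perimeter_smaller_part(sp), 36)
  d <- disk_mask(200, 200, 100, 100, 80)
  spd <- structure(list(split_performed = TRUE, part_small = d),
                   class = "split_result")
  # independent border-pixel count: foreground with a background
  # 4-neighbour, computed by explicit shifts
  pad <- matrix(FALSE, 202, 202); pad[2:201, 2:201] <- d
  nb4 <- pad[1:200, 2:201] & pad[3:202, 2:201] &
    pad[2:201, 1:200] & pad[2:201, 3:202]
  expect_equal(perimeter_smaller_part(spd), sum(d & !nb4))
  # the pixel-count convention slightly exceeds the Euclidean circumference
  expect_lt(abs(perimeter_smaller_part(spd) - 2 * pi * 80) / (2 * pi * 80),
            0.15)
  none <- structure(list(split_performed = FALSE), class = "split_result")
  expect_equal(perimeter_smaller_part(none), 0)
})

test_that("T2 >= T1 and the convex fallback hold on random blobs", {
  for (seed in 1:30) {
    blob <- random_blob(seed)
    sp <- bottleneck_pair(blob)
    t2 <- min_convex_thickness(blob)
    expect_lte(sp$t1, t2 * 1.02)
  }
})

test_that("feature extraction lands fixtures in their class regions", {
  mo <- morph_options(scale = 0.35)
  run <- function(cl, seed, ...) {
    sc <- render_cell(synthetic_cell_spec(cl, seed = seed, scale = 0.35, ...))
    seg <- segment_image(sc$image, seg_options(scale = 0.35))
    recs <- Filter(function(r) r$classifiable, seg$records)
    extract_features(recs[[1]], sc$image, mo)
  }
  fv_mb <- run("MB", 21)
  expect_equal(fv_mb$num, 1L)
  expect_gt(fv_mb$t1_over_t2, 0.92)
  fv_b <- run("B", 22)
  expect_gt(fv_b$t1_over_t2, 0.1)
  expect_lt(fv_b$t1_over_t2, 0.53)
  expect_gt(fv_b$p1, 0)
  fv_n <- run("N", 23, lobes = 3)
  expect_equal(fv_n$num, 3L)
})
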