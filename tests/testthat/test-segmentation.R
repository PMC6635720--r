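test_that("contrast enhancement combines stretch and equalization", {
  y <- matrix(c(0.2, 0.2, 0.8, 0.8), 2, 2)
  ei <- enhance_contrast(y)
  # two-valued image: L maps to {0,1}, H to cumulative ranks; the mean,
  # rescaled, is again {0,1}
  expect_equal(sort(unique(as.numeric(ei))), c(0, 1))
  # range contract for arbitrary non-constant input
  set.seed(1)
  ei2 <- enhance_contrast(matrix(runif(400), 20, 20))
  expect_equal(min(ei2), 0)
  expect_equal(max(ei2), 1)
  # degenerate input: constant image returned unchanged with a warning
  cst <- matrix(0.5, 8, 8)
  expect_warning(out <- enhance_contrast(cst), "constant")
  expect_equal(out, cst)
})

test_that("repeated 3x3 minimum filter matches the sliding-window oracle", {
  cst <- matrix(0.3, 10, 10)
  expect_equal(min_filter_3x3(cst, 3), cst)
  spike <- matrix(0, 9, 9); spike[5, 5] <- 1
  expect_true(all(min_filter_3x3(spike, 1) == 0))
  set.seed(7)
  img <- matrix(runif(64), 8, 8)
  for (rep in 1:3)
    expect_equal(min_filter_3x3(img, rep), oracle_min_filter(img, rep))
})

test_that("Otsu threshold equals the exhaustive between-class search", {
  bimodal <- matrix(rep(c(0, 1), each = 50), 10, 10)
  m <- otsu_mask(bimodal, "bright")
  expect_equal(m, bimodal == 1)
  set.seed(11)
  for (i in 1:5) {
    vals <- c(runif(30, 0, 0.4), runif(20, 0.6, 1))[sample(50)]
    expect_equal(otsu_threshold(vals), oracle_otsu(vals))
  }
  expect_error(otsu_threshold(rep(0.5, 16)), class = "no_threshold")
  expect_error(otsu_mask(matrix(0.5, 8, 8)), class = "no_threshold")
})

test_that("cell-mask clean-up fills holes, removes specks and is idempotent", {
  opts <- seg_options(scale = 0.25)
  m <- disk_mask(80, 80, 40, 40, 25)
  holey <- m; holey[40, 40] <- FALSE
  expect_equal(clean_cell_mask(holey, opts), clean_cell_mask(m, opts))
  salted <- m
  salted[5, 5] <- TRUE; salted[70, 8] <- TRUE
  cleaned <- clean_cell_mask(salted, opts)
  expect_false(cleaned[5, 5])
  expect_false(cleaned[70, 8])
  expect_equal(clean_cell_mask(cleaned, opts), cleaned)
  # no enclosed background in any component
  expect_equal(matrix(as.logical(as.matrix(
    EBImage::fillHull(EBImage::Image(cleaned)))), 80, 80), cleaned)
  expect_warning(clean_cell_mask(matrix(FALSE, 8, 8), opts), "empty")
})

test_that("nucleus extraction finds the stained nucleus and drops specks", {
  # toy cell: pale cytoplasm disk with a magenta nucleus and a small
  # distant magenta speck
  side <- 200
  cell <- disk_mask(side, side, 100, 100, 90)
  nuc_true <- disk_mask(side, side, 100, 90, 45)
  speck <- disk_mask(side, side, 100, 178, 5)
  img <- array(0, c(side, side, 3))
  pal <- synth_palette()
  for (ch in 1:3) {
    sl <- matrix(pal$background[ch], side, side)
    sl[cell] <- pal$cytoplasm$MM[ch]
    sl[nuc_true | speck] <- pal$nucleus[ch]
    img[, , ch] <- sl
  }
  opts <- seg_options(scale = 0.25)
  nm <- extract_nucleus_mask(img, cell, opts)
  expect_true(all(nm[!cell] == FALSE))
  expect_gte(dice_coefficient(nm, nuc_true), 0.9)
  # the 5-px speck is far below the 25 % area cut
  expect_false(any(nm & speck))
  expect_error(extract_nucleus_mask(img, matrix(FALSE, side, side), opts),
               class = "empty_nucleus")
})

test_that("watershed splits touching cells and partitions the foreground", {
  opts <- seg_options(scale = 1, min_cell_area = 200)
  single <- disk_mask(120, 120, 60, 60, 40)
  lab1 <- split_touching_cells(single, opts)
  expect_equal(max(lab1), 1)
  expect_equal(lab1 > 0, single)
  # two disks with centres 1.5 radii apart
  two <- disk_mask(200, 260, 100, 90, 40) | disk_mask(200, 260, 100, 150, 40)
  lab2 <- split_touching_cells(two, opts)
  expect_equal(max(lab2), 2)
  areas <- tabulate(lab2[lab2 > 0])
  expect_true(all(abs(areas - pi * 40^2) / (pi * 40^2) < 0.2))
  expect_equal(lab2 > 0, two)           # labels partition the foreground
  empty <- split_touching_cells(matrix(FALSE, 50, 50), opts)
  expect_equal(max(empty), 0)
})

test_that("cell records obey the mask algebra", {
  labels <- matrix(0L, 60, 150)
  labels[disk_mask(60, 150, 30, 25, 20)] <- 1L
  labels[disk_mask(60, 150, 30, 75, 20)] <- 2L
  labels[disk_mask(60, 150, 30, 125, 20)] <- 3L
  nuc <- disk_mask(60, 150, 30, 25, 10) | disk_mask(60, 150, 30, 75, 20)
  recs <- make_cell_records(labels, nuc)
  expect_length(recs, 3)
  expect_equal(sum(vapply(recs, function(r) r$classifiable, logical(1))), 2)
  r1 <- recs[[1]]
  expect_equal(r1$cytoplasm_mask, r1$cell_mask & !r1$nucleus_mask)
  expect_false(any(r1$cytoplasm_mask & r1$nucleus_mask))
  expect_equal(r1$cytoplasm_mask | r1$nucleus_mask, r1$cell_mask)
  expect_true(all(r1$nucleus_mask[r1$cell_mask] | TRUE))
  # nucleus covering the whole cell: degenerate record is flagged
  r2 <- recs[[2]]
  expect_true(r2$cytoplasm_empty)
  expect_equal(sum(r2$cytoplasm_mask), 0)
  expect_false(recs[[3]]$classifiable)
})

test_that("every stage preserves geometry and the masks nest correctly", {
  sc <- render_cell(synthetic_cell_spec("PM", seed = 5, scale = 0.3))
  seg <- segment_image(sc$image, seg_options(scale = 0.3))
  expect_equal(dim(seg$cell_mask), dim(sc$image)[1:2])
  expect_equal(dim(seg$nucleus_mask), dim(sc$image)[1:2])
  expect_true(all(seg$nucleus_mask[!seg$cell_mask] == FALSE))
  expect_gte(length(seg$records), 1)
  rec <- seg$records[[1]]
  expect_true(all(rec$nucleus_mask[!rec$cell_mask] == FALSE))
  expect_equal(rec$nucleus_mask | rec$cytoplasm_mask, rec$cell_mask)
})
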