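test_that("the worked stage examples reach their mandated leaves", {
  for (ex in worked_examples())
    expect_equal(classify(ex$fv)$label, ex$label)
})

test_that("boundary values follow the documented tie-breaking", {
  cl <- function(...) classify(feature_vector(...))$label
  # T1/T2 exactly at the regular cut falls to the irregular branch
  expect_equal(cl(num = 1, t1_over_t2 = 0.92, acoc = 200), "MM")
  # the metamyelocyte band includes its lower edge
  expect_equal(cl(num = 1, t1_over_t2 = 0.53), "MM")
  # colour exactly at either cut point gives the overlap class
  expect_equal(cl(num = 1, t1_over_t2 = 0.95, t1_over_hd = 3.0, acoc = 24),
               "MB|PM")
  expect_equal(cl(num = 1, t1_over_t2 = 0.95, t1_over_hd = 3.0, acoc = 27),
               "MB|PM")
  # nucleus area exactly at either cut point gives the overlap class
  expect_equal(cl(num = 1, t1_over_t2 = 0.95, t1_over_hd = 1.5,
                  aon = 110000), "PM|M")
  expect_equal(cl(num = 1, t1_over_t2 = 0.95, t1_over_hd = 1.5,
                  aon = 115000), "PM|M")
  # P1 exactly at the band cut stays neutrophil
  expect_equal(cl(num = 1, t1_over_t2 = 0.30, p1 = 475), "N")
  # T1/HD exactly at the myeloblast cut continues to the colour stages
  expect_equal(cl(num = 1, t1_over_t2 = 0.95, t1_over_hd = 3.7, acoc = 20),
               "MB")
  # non-basophilic cells in the notch band fall to the irregular branch
  expect_equal(cl(num = 1, t1_over_t2 = 0.90, acoc = 30), "MM")
})

test_that("the notch substitution rewrites T1 and is traced", {
  fv <- feature_vector(num = 1, t1_over_t2 = 0.90, t1_over_hd = 3.4,
                       acoc = 20)
  res <- classify(fv)
  expect_true("substitute:t1<-t2" %in% res$trace)
  # effective T1/HD becomes 3.4 / 0.90 = 3.78 > 3.7
  expect_equal(res$label, "MB")
})

test_that("missing features give the unclassifiable outcome only when needed", {
  expect_equal(classify(feature_vector(num = 1))$label, "unclassifiable")
  expect_equal(classify(feature_vector(num = 1, t1_over_t2 = 0.95))$label,
               "unclassifiable")
  # ACoC missing is tolerated on branches that never read it
  expect_equal(classify(feature_vector(num = 1, t1_over_t2 = 0.95,
                                       t1_over_hd = 4.0))$label, "MB")
  expect_equal(classify(feature_vector(num = 1, t1_over_t2 = 0.90,
                                       t1_over_hd = 4.0))$label,
               "unclassifiable")
})

test_that("increasing nucleus regularity walks N -> B -> MM -> regular", {
  path <- vapply(c(0.05, 0.30, 0.70, 0.99), function(r)
    classify(feature_vector(num = 1, t1_over_t2 = r, t1_over_hd = 4.0,
                            p1 = 600))$label, character(1))
  expect_equal(path, c("N", "B", "MM", "MB"))
})

test_that("classification is total over fuzzed feature space", {
  outcomes <- c(cml_classes(), unclassifiable_label())
  labels <- classify_batch(fuzz_feature_vectors(1000, seed = 99),
                           quiet = TRUE)
  expect_length(labels, 1000)
  expect_true(all(labels %in% outcomes))
  expect_false(unclassifiable_label() %in% labels)  # all features present
})

test_that("configs validate, scale and round-trip through JSON", {
  expect_error(classifier_config(t1t2_regular = 0.5), class = "invalid_config")
  expect_error(classifier_config(acoc_mb = 30, acoc_pm = 24),
               class = "invalid_config")
  cfg <- classifier_config()
  half <- scale_classifier_config(cfg, 0.5)
  expect_equal(half$aon_myelocyte, 110000 * 0.25)
  expect_equal(half$p1_band, 475 * 0.5)
  expect_equal(half$t1t2_regular, 0.92)
  path <- tempfile(fileext = ".json")
  write_classifier_config(cfg, path)
  cfg2 <- read_classifier_config(path)
  expect_equal(cfg2, cfg)
  fvs <- fuzz_feature_vectors(200, seed = 5)
  expect_equal(classify_batch(fvs, cfg2, quiet = TRUE),
               classify_batch(fvs, cfg, quiet = TRUE))
  bad <- path
  writeLines('{"t1t2_regular": 0.92, "bogus_key": 1}', bad)
  expect_error(read_classifier_config(bad), class = "invalid_config")
})

test_that("batch classification preserves order and handles empties", {
  expect_equal(classify_batch(list(), quiet = TRUE), character(0))
  exs <- worked_examples()
  labels <- classify_batch(lapply(exs, `[[`, "fv"), quiet = TRUE)
  expect_equal(labels, vapply(exs, `[[`, character(1), "label"))
  df <- data.frame(num = c(3, 1), aon = c(NA, 100000), acoc = NA,
                   p1 = NA, t1_over_t2 = c(NA, 0.95),
                   t1_over_hd = c(NA, 1.5))
  expect_equal(classify_batch(df, quiet = TRUE), c("N", "M"))
})
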