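test_that("scene_params validates counts, probabilities and scales", {
  expect_error(scene_params(n_nuclei = -1), "non-negative")
  expect_error(scene_params(n_nuclei = 2.5), "non-negative integer")
  expect_error(scene_params(pixel_size_um = 0), "positive")
  expect_error(scene_params(p_green = 1.2), "\\[0, 1\\]")
  expect_error(scene_params(p_green = 0.2, p_red = 0.5, p_double = 0.3),
               "p_double")
  expect_error(scene_params(p_green = 0.9, p_red = 0.9, p_double = 0.1),
               "not exceed 1")
  expect_error(scene_params(nuclei_per_myotube = 1), "at least 2")
})

test_that("an empty scene renders no foreground and empty ground truth", {
  fg <- generate_field(tiny_params(n_nuclei = 0, noise_sd = 0,
                                   blur_sigma_px = 0))
  expect_equal(nrow(fg$truth$nuclei), 0L)
  expect_true(all(fg$stack$channels$dapi == fg$stack$channels$dapi[1, 1]))
  expect_true(is.na(fg$truth$true_indices$proliferation_pct))
  expect_true(is.na(fg$truth$true_indices$fusion_pct))
  bm <- isodata_threshold(fg$stack$channels$dapi)
  expect_false(any(bm$mask))
})

test_that("identical parameters and seed give bit-identical fields", {
  p <- tiny_params(n_myotubes = 2, seed = 77)
  a <- generate_field(p)
  b <- generate_field(p)
  expect_identical(a$stack$channels, b$stack$channels)
  expect_identical(a$truth$nuclei, b$truth$nuclei)
  expect_identical(a$truth$true_counts, b$truth$true_counts)
})

test_that("noise-free non-touching render is recovered exactly (CC oracle)", {
  fg <- generate_field(clean_params(n_nuclei = 40, seed = 8))
  bm <- isodata_threshold(fg$stack$channels$dapi)
  expect_equal(igraph_cc_count(bm$mask), 40L)  # oracle on the binary render
  seg <- segment_nuclei(fg$stack$channels$dapi)
  expect_equal(sum(seg$segments$retained), 40L)
})

test_that("rendered nucleus areas fall inside the 15-230 px window", {
  for (s in 1:3) {
    fg <- generate_field(clean_params(n_nuclei = 60, seed = s))
    seg <- segment_nuclei(fg$stack$channels$dapi)
    areas <- seg$segments$area_px[seg$segments$retained]
    expect_equal(length(areas), 60L)
    expect_true(all(areas >= 15 & areas <= 230))
    # and the generating truth stays in the window too
    expect_true(all(fg$truth$nuclei$area_px >= 15 &
                      fg$truth$nuclei$area_px <= 230))
  }
})

test_that("true double count never exceeds either marginal; green count is monotone in p_green", {
  counts <- lapply(c(0.3, 0.5, 0.7), function(pg) {
    fg <- generate_field(tiny_params(p_green = pg, p_red = 0.3,
                                     p_double = 0.15, seed = 99))
    fg$truth$true_counts
  })
  for (tc in counts)
    expect_lte(tc$n_double, min(tc$n_green, tc$n_red))
  greens <- vapply(counts, function(tc) tc$n_green, integer(1))
  expect_true(all(diff(greens) >= 0))
})

test_that("every generated myotube has at least two member nuclei", {
  fg <- generate_field(tiny_params(n_nuclei = 60, n_myotubes = 6,
                                   nuclei_per_myotube = 3, seed = 12))
  members <- table(fg$truth$nuclei$myotube_id)
  expect_equal(length(members), 6L)
  expect_true(all(members >= 2))
  expect_identical(as.integer(members[as.character(fg$truth$myotubes$id)]),
                   fg$truth$myotubes$n_members)
})

test_that("true indices are exactly the index formulas applied to true states", {
  fg <- generate_field(tiny_params(n_nuclei = 50, n_myotubes = 4,
                                   nuclei_per_myotube = 3, seed = 21))
  nuc <- fg$truth$nuclei
  ti <- fg$truth$true_indices
  expect_equal(ti$proliferation_pct,
               100 * sum(nuc$green & nuc$red) / sum(nuc$green))
  expect_equal(ti$differentiation_pct,
               100 * sum(nuc$green & nuc$red) / sum(nuc$red))
  expect_equal(ti$fusion_pct, 100 * sum(!is.na(nuc$myotube_id)) / nrow(nuc))
})

test_that("generate_study writes the full grid, manifest and truth tables", {
  d <- tempfile()
  design <- list(coatings = c("matrigel", "fibrin"), days = c(1, 5),
                 wells = 1, fields = 2)
  man <- generate_study(design, d, base_params = tiny_params(n_nuclei = 10),
                        channels = c("dapi", "green", "red"), seed = 5)
  expect_equal(nrow(man), 2 * 2 * 1 * 2)
  expect_true(file.exists(file.path(d, "manifest.csv")))
  expect_equal(length(list.files(file.path(d, "images"))), 8 * 3)
  expect_equal(length(list.files(file.path(d, "truth"))), 8)
  # deterministic regeneration
  d2 <- tempfile()
  man2 <- generate_study(design, d2, base_params = tiny_params(n_nuclei = 10),
                         channels = c("dapi", "green", "red"), seed = 5)
  expect_identical(man$n_nuclei, man2$n_nuclei)
  f1 <- file.path(d, "images", "matrigel_1_w1_f1_dapi.tif")
  f2 <- file.path(d2, "images", "matrigel_1_w1_f1_dapi.tif")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # refuses to clobber an existing study
  expect_error(generate_study(design, d,
                              base_params = tiny_params(n_nuclei = 10)),
               "overwrite")
})

test_that("per-condition overrides reach the right fields", {
  d <- tempfile()
  man <- generate_study(list(coatings = c("matrigel", "fibrin"), days = 1,
                             wells = 1, fields = 2),
                        d, base_params = tiny_params(n_nuclei = 12),
                        condition_params = list(fibrin = list(n_nuclei = 4)),
                        channels = "dapi", seed = 2)
  expect_true(all(man$n_nuclei[man$coating == "matrigel"] == 12))
  expect_true(all(man$n_nuclei[man$coating == "fibrin"] == 4))
})
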