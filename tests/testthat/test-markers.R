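test_that("detect_marker_segments applies the 15-230 px window without border exclusion", {
  img <- matrix(5L, 64, 64)
  img <- draw_disk(img, 10, 10, 2, 200)    # 13 px: below window
  img <- draw_disk(img, 30, 30, 5, 200)    # 81 px: kept
  img[1:10, 50:59] <- 200L                 # 100 px touching the border: kept
  ms <- detect_marker_segments(img)
  expect_equal(sum(ms$segments$retained), 2L)
  expect_true(any(ms$segments$touches_border[ms$segments$retained]))
  # blank channel
  blank <- detect_marker_segments(matrix(5L, 32, 32))
  expect_equal(sum(blank$segments$retained), 0L)
  # sizes 14 and 231 are both rejected
  img2 <- matrix(0L, 64, 64)
  img2[5:11, 5:6] <- 200L      # 14 px
  img2[20:40, 20:30] <- 200L   # 231 px
  ms2 <- detect_marker_segments(img2)
  expect_equal(sum(ms2$segments$retained), 0L)
})

make_nuclei <- function(lab) {
  # wrap a hand-built nucleus label image the way segment_nuclei returns it
  filter_segments(lab, min_area = 1, max_area = 1e6, exclude_border = FALSE)
}

test_that("assign_markers: intersection vs containment rules", {
  nl <- matrix(0L, 40, 40)
  nl[10:16, 10:16] <- 1L
  nl[10:16, 25:31] <- 2L
  nuclei <- make_nuclei(nl)
  g <- matrix(0L, 40, 40)
  g[12:14, 12:14] <- 1L        # fully inside nucleus 1
  g[14:16, 29:35] <- 2L        # straddles nucleus 2's edge
  r <- matrix(0L, 40, 40)
  r[11:13, 11:13] <- 1L        # inside nucleus 1 -> double with green
  ph <- assign_markers(nuclei, g, r, rule = "intersection")
  expect_equal(ph$green_positive, c(TRUE, TRUE))
  expect_equal(ph$red_positive, c(TRUE, FALSE))
  expect_equal(ph$double_positive, ph$green_positive & ph$red_positive)
  ph_c <- assign_markers(nuclei, g, r, rule = "containment")
  expect_equal(ph_c$green_positive, c(TRUE, FALSE))  # straddler not contained
  expect_equal(ph_c$red_positive, c(TRUE, FALSE))
})

test_that("assign_markers with no marker segments yields all-negative phenotypes", {
  fg <- generate_field(clean_params(n_nuclei = 15, seed = 31))
  nuc <- segment_nuclei(fg$stack$channels$dapi)
  ph <- assign_markers(nuc, NULL, NULL)
  expect_equal(nrow(ph), 15L)
  expect_false(any(ph$green_positive | ph$red_positive | ph$double_positive))
})

test_that("detect_myotubes requires >= 2 nucleus centroids per MyHC object", {
  myhc <- matrix(0L, 80, 80)
  myhc[20:35, 10:70] <- 180L   # one large component
  nl <- matrix(0L, 80, 80)
  nl[25:29, 20:24] <- 1L
  nl[25:29, 40:44] <- 2L
  nl[25:29, 60:64] <- 3L
  nuclei <- make_nuclei(nl)
  mt <- detect_myotubes(myhc, nuclei)
  expect_equal(nrow(mt$myotubes), 1L)
  expect_equal(mt$myotubes$n_nuclei, 3L)
  expect_equal(mt$n_nuclei_in_myotubes, 3L)
  # with a single nucleus inside, the object is not a myotube
  nl1 <- matrix(0L, 80, 80)
  nl1[25:29, 40:44] <- 1L
  mt1 <- detect_myotubes(myhc, make_nuclei(nl1))
  expect_equal(nrow(mt1$myotubes), 0L)
  # blank channel
  mt0 <- detect_myotubes(matrix(0L, 80, 80), nuclei)
  expect_equal(nrow(mt0$myotubes), 0L)
  expect_equal(mt0$n_nuclei_in_myotubes, 0L)
})

test_that("small MyHC speckle is suppressed by min_myotube_area", {
  myhc <- matrix(0L, 60, 60)
  myhc <- draw_disk(myhc, 30, 30, 5, 180)  # 81 px < 300
  nl <- matrix(0L, 60, 60)
  nl[28:32, 27:31] <- 1L
  nl[28:32, 33:37] <- 2L
  mt <- detect_myotubes(myhc, make_nuclei(nl))
  expect_equal(nrow(mt$myotubes), 0L)
  mt2 <- detect_myotubes(myhc, make_nuclei(nl), min_myotube_area = 50)
  expect_equal(nrow(mt2$myotubes), 1L)
})

test_that("quantify_field equals ground truth on a clean field (oracle equivalence)", {
  fg <- generate_field(clean_params(n_nuclei = 50, n_myotubes = 3,
                                    nuclei_per_myotube = 3, seed = 17))
  q <- quantify_field(fg$stack, mode = "auto")
  tc <- fg$truth$true_counts
  expect_equal(q$n_nuclei, tc$n_nuclei)
  expect_equal(q$n_green, tc$n_green)
  expect_equal(q$n_red, tc$n_red)
  expect_equal(q$n_double, tc$n_double)
  expect_equal(q$n_myotubes, tc$n_myotubes)
  expect_equal(q$n_nuclei_in_myotubes, tc$n_nuclei_in_myotubes)
})

test_that("counts are independent of channel processing order and nucleus labels", {
  fg <- generate_field(tiny_params(seed = 23))
  chans <- fg$stack$channels
  nuc <- segment_nuclei(chans$dapi)
  gl <- detect_marker_segments(chans$green)$labels
  rl <- detect_marker_segments(chans$red)$labels
  a <- assign_markers(nuc, gl, rl)
  b <- assign_markers(nuc, rl, gl)  # swapped roles
  expect_equal(a$green_positive, b$red_positive)
  expect_equal(a$red_positive, b$green_positive)
  expect_equal(a$double_positive, b$double_positive)
  # relabeling nuclei permutes rows but not the counts
  perm_lab <- nuc$labels
  ids <- sort(unique(perm_lab[perm_lab > 0]))
  remap <- setNames(rev(ids), ids)
  perm_lab[perm_lab > 0] <- remap[as.character(perm_lab[perm_lab > 0])]
  nuc_perm <- list(segments = within(nuc$segments, {
    label <- unname(remap[as.character(label)])
  }), labels = perm_lab)
  p <- assign_markers(nuc_perm, gl, rl)
  expect_equal(sum(p$green_positive), sum(a$green_positive))
  expect_equal(sum(p$red_positive), sum(a$red_positive))
  expect_equal(sum(p$double_positive), sum(a$double_positive))
})

test_that("quantify_field validates required channels per mode", {
  fg <- generate_field(tiny_params(seed = 2), channels = c("dapi", "green"))
  expect_error(quantify_field(fg$stack, mode = "myhc"), "myhc")
  expect_error(quantify_field(fg$stack, mode = "pax7-myod"), "red")
  q <- quantify_field(fg$stack, mode = "auto")
  expect_true(is.na(q$n_myotubes))
  expect_false(is.na(q$n_green))
})
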