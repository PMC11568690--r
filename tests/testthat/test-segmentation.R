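test_that("detect_rois boxes nuclei and keeps per-ROI masks exclusive", {
  binned <- matrix(5, 64, 64)
  binned <- binned + disk_image(64, 64, cbind(c(20, 20), c(15, 45)),
                                c(4, 4), c(200, 200))
  rois <- detect_rois(binned, bin_factor = 8, margin = 16)
  expect_length(rois, 2L)
  # each ROI mask covers its own nucleus and excludes the neighbour's
  for (i in 1:2) {
    b <- rois[[i]]$bounds
    expect_true(b[1] >= 0 && b[2] >= 0)
    expect_true(b[3] <= 512 && b[4] <= 512)
    expect_equal(dim(rois[[i]]$roi_mask),
                 c(b[3] - b[1], b[4] - b[2]))
  }
  own <- function(i, cx) {
    b <- rois[[i]]$bounds
    # nucleus center (binned 20, cx) in full-res coordinates
    r <- 20 * 8 - b[1]; c <- cx * 8 - b[2]
    r >= 1 && r <= nrow(rois[[i]]$roi_mask) &&
      c >= 1 && c <= ncol(rois[[i]]$roi_mask) && rois[[i]]$roi_mask[r, c]
  }
  centers_x <- c(15, 45)
  covering <- vapply(1:2, function(i) own(i, centers_x[i]), logical(1))
  expect_true(all(covering))
  # blank image -> no ROIs
  expect_length(detect_rois(matrix(3, 32, 32), 8), 0L)
  # one blob -> one ROI
  one <- matrix(5, 64, 64) + disk_image(64, 64, cbind(30, 30), 5, 300)
  expect_length(detect_rois(one, 8), 1L)
})

test_that("two-pass nucleus detection finds bright and 5x-dimmer nuclei", {
  set.seed(8)
  img <- disk_image(140, 140, cbind(c(40, 100), c(40, 100)), c(16, 16),
                    c(2500, 500), bg = 100) +
    matrix(rnorm(140 * 140, 0, 5), 140)
  p <- nucleus_params(lower_bound_high = 1000, lower_bound_low = 200,
                      min_diameter = 10, declump_min_distance = 20)
  seg <- segment_nuclei(img, p)
  expect_identical(max(seg$labels), 2L)
  expect_setequal(seg$tier, c("high", "low"))
  # a single global pass at the bright-pass floor finds only the bright one
  one_pass <- coduco:::one_pass_nuclei(img, matrix(TRUE, 140, 140),
                                       1.0, 1000, p)
  expect_identical(length(setdiff(unique(as.integer(one_pass)), 0L)), 1L)
  # centroid accuracy
  o <- order(seg$centroid_y)
  expect_lt(abs(seg$centroid_y[o[1]] - 39), 2.5)
  expect_lt(abs(seg$centroid_x[o[2]] - 99), 2.5)
  # diameter filter removes a tiny speck (smoothing spreads a radius-2
  # speck to an equivalent diameter of ~11 px, still below the floor)
  speck <- disk_image(60, 60, cbind(30, 30), 2, 2500, bg = 100)
  seg2 <- segment_nuclei(speck, nucleus_params(min_diameter = 14,
                                               lower_bound_high = 1000,
                                               lower_bound_low = 200))
  expect_identical(max(seg2$labels), 0L)
})

test_that("touching nuclei are declumped by the seeded watershed", {
  img <- disk_image(100, 160, cbind(c(50, 50), c(55, 95)), c(20, 20),
                    c(2500, 2400), bg = 100)
  seg <- segment_nuclei(img, nucleus_params(lower_bound_high = 500,
                                            min_diameter = 20,
                                            declump_min_distance = 25))
  expect_identical(max(seg$labels), 2L)
  # the two labels split near the midline between the seeds
  left <- seg$labels[50, 55]; right <- seg$labels[50, 95]
  expect_true(left > 0 && right > 0 && left != right)
})

test_that("expand_cells applies the area-conditional budget and stays
           disjoint", {
  # isolated nucleus below the cutoff: budget 12 px
  lab <- matrix(0L, 120, 120)
  d <- sqrt(outer((1:120 - 60)^2, (1:120 - 60)^2, `+`))
  lab[d <= 25] <- 1L                      # area ~1963 < 2800
  cm <- expand_cells(lab)
  expect_equal(unname(cm$expansion), 12)
  grown <- cm$labels == 1L
  expect_true(all(grown[lab == 1L]))       # nucleus subset of cell
  expect_true(all(d[grown] <= 25 + 12 + 1.5))
  expect_gt(sum(grown), sum(lab == 1L))
  # at/above the cutoff: budget 32 (area exactly >= 2800 takes 32)
  lab2 <- matrix(0L, 160, 160)
  d2 <- sqrt(outer((1:160 - 80)^2, (1:160 - 80)^2, `+`))
  lab2[d2 <= 30] <- 1L                     # area ~2827 >= 2800
  cm2 <- expand_cells(lab2)
  expect_equal(unname(cm2$expansion), 32)
  # two nuclei 10 px apart: expansion halts at the equidistant frontier
  lab3 <- matrix(0L, 80, 140)
  da <- sqrt(outer((1:80 - 40)^2, (1:140 - 50)^2, `+`))
  db <- sqrt(outer((1:80 - 40)^2, (1:140 - 90)^2, `+`))
  lab3[da <= 15] <- 1L; lab3[db <= 15] <- 2L
  cm3 <- expand_cells(lab3)
  expect_identical(sum(cm3$labels == 1L & cm3$labels == 2L), 0L)
  expect_true(all(cm3$labels[lab3 == 1L] == 1L))
  expect_true(all(cm3$labels[lab3 == 2L] == 2L))
  # pixels on nucleus-1 side of the frontier never belong to cell 2
  expect_true(all(cm3$labels[da < db - 1 & cm3$labels > 0] %in% c(1L, 0L) |
                    lab3[da < db - 1 & cm3$labels > 0] > 0))
  # empty input passes through
  empty <- expand_cells(matrix(0L, 10, 10))
  expect_identical(max(empty$labels), 0L)
})
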