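test_that("simulation is deterministic and conserves signals", {
  cfg <- sim_config(image_shape = c(512L, 512L),
                    n_cells_per_class = c(CTC = 1L, PBMC = 3L, artefact = 1L,
                                          false_positive = 1L, negative = 1L),
                    autofluor_rate = 1, seed = 9L)
  s1 <- simulate_sample(cfg)
  s2 <- simulate_sample(cfg)
  expect_identical(s1$pair$original, s2$pair$original)
  expect_identical(s1$pair$background, s2$pair$background)
  expect_identical(s1$truth, s2$truth)
  # per-marker conservation: cell count sums equal signal table tallies
  mk <- marker_names(build_default_panel())
  for (m in mk) {
    expect_identical(sum(s1$truth$cells[[m]]),
                     sum(s1$truth$signals$marker == m))
  }
  # signals lie within their owner's extent
  for (i in seq_len(nrow(s1$truth$signals))) {
    sg <- s1$truth$signals[i, ]
    cell <- s1$truth$cells[sg$cell, ]
    expect_lte(sqrt((sg$y - cell$y)^2 + (sg$x - cell$x)^2),
               cell$radius + 15 + 1e-9)
  }
})

test_that("all-zero configuration yields blank channels and empty truth", {
  cfg <- sim_config(image_shape = c(256L, 256L),
                    n_cells_per_class = c(CTC = 0L, PBMC = 0L, artefact = 0L,
                                          false_positive = 0L, negative = 0L),
                    autofluor_rate = 0, noise_sd = 0, seed = 1L)
  s <- simulate_sample(cfg)
  expect_identical(nrow(s$truth$cells), 0L)
  expect_identical(nrow(s$truth$signals), 0L)
  for (ch in SIGNAL_CHANNELS)
    expect_true(all(s$pair$original[[ch]] == cfg$background_level))
})

test_that("spots render at amplitude in both code channels; bleed-through
           leaks Cy5 into TexasRed", {
  cfg <- sim_config(image_shape = c(384L, 384L),
                    n_cells_per_class = c(CTC = 1L, PBMC = 0L, artefact = 0L,
                                          false_positive = 0L, negative = 0L),
                    autofluor_rate = 0, noise_sd = 0, seed = 21L)
  s <- simulate_sample(cfg)
  sig <- s$truth$signals
  cbk <- build_default_panel()
  for (i in seq_len(nrow(sig))) {
    code <- marker_code(cbk, sig$marker[i])
    for (ch in code) {
      v <- s$pair$original[[ch]][round(sig$y[i]) + 1L, round(sig$x[i]) + 1L]
      expect_gte(v, cfg$background_level + 0.5 * cfg$spot_amplitude)
    }
  }
  # Cy5 content leaks into TexasRed at beta
  cy5_sig <- sig[vapply(sig$marker, function(m)
    "Cy5" %in% marker_code(cbk, m), logical(1)), ]
  if (nrow(cy5_sig)) {
    i <- 1L
    r <- round(cy5_sig$y[i]) + 1L; c <- round(cy5_sig$x[i]) + 1L
    tr <- s$pair$original$TexasRed[r, c] - cfg$background_level
    cy5 <- s$pair$original$Cy5[r, c] - cfg$background_level
    expect_gt(tr, 0.8 * cfg$bleedthrough_beta * cy5)
  }
  # noise-free background scan, inverse-transformed, equals the original
  # minus coding spots (integer-translation misalignment)
  cfg2 <- sim_config(image_shape = c(256L, 256L),
                     n_cells_per_class = c(CTC = 0L, PBMC = 2L,
                                           artefact = 1L,
                                           false_positive = 0L,
                                           negative = 0L),
                     noise_sd = 0, autofluor_rate = 1,
                     misalignment = c(dx = 4, dy = -3, theta = 0),
                     seed = 33L)
  s2 <- simulate_sample(cfg2)
  inv <- invert_transform(rigid_transform(4, -3, 0))
  back <- apply_rigid(s2$pair$background$DAPI, inv)
  orig <- s2$pair$original$DAPI
  expect_lt(max(abs(back$image - orig)[back$valid]), 1e-6)
  # a signal channel differs from its background only at coding spots
  backc <- apply_rigid(s2$pair$background$Cy3, inv)
  diffc <- (s2$pair$original$Cy3 - backc$image)[backc$valid]
  expect_gte(min(diffc), -1e-6)
})

test_that("feature tables follow the class-conditional models", {
  cfg <- sim_config(n_cells_per_class = c(CTC = 100L, PBMC = 100L,
                                          artefact = 100L,
                                          false_positive = 100L,
                                          negative = 100L), seed = 4L)
  tab <- simulate_feature_table(cfg)
  expect_identical(nrow(tab), 500L)
  expect_true(all(table(tab$class) == 100L))
  expect_setequal(unique(tab$class), CLASS_LEVELS)
  expect_true(all(tab$total == rowSums(tab[, marker_names(build_default_panel())])))
  # PBMC hem positivity within +-5 points of the published 86%
  big <- sim_config(n_cells_per_class = c(CTC = 0L, PBMC = 4000L,
                                          artefact = 0L,
                                          false_positive = 0L,
                                          negative = 0L), seed = 10L)
  tb <- simulate_feature_table(big)
  expect_lt(abs(mean(tb$hem >= 1) - 0.86), 0.05)
  # CTC-like (VCaP) AR-FL median ~34
  bigc <- sim_config(n_cells_per_class = c(CTC = 4000L, PBMC = 0L,
                                           artefact = 0L,
                                           false_positive = 0L,
                                           negative = 0L), seed = 11L)
  tc <- simulate_feature_table(bigc)
  expect_lte(abs(stats::median(tc$`AR-FL`) - 34), 2)
  expect_lt(abs(mean(tc$`AR-FL` >= 1) - 0.99), 0.03)
  # degenerate constant model reproduces the mean vector exactly
  cm <- default_count_models()
  for (m in names(cm$negative)) cm$negative[[m]] <- list(type = "constant",
                                                         value = 3L)
  cfg3 <- sim_config(n_cells_per_class = c(CTC = 0L, PBMC = 0L,
                                           artefact = 0L,
                                           false_positive = 0L,
                                           negative = 5L),
                     count_model = cm, seed = 2L)
  t3 <- simulate_feature_table(cfg3)
  expect_true(all(t3[, marker_names(build_default_panel())] == 3L))
  # missing model entry errors with the pair named
  cm2 <- default_count_models()
  cm2$PBMC$hem <- NULL
  cfg4 <- sim_config(n_cells_per_class = c(CTC = 0L, PBMC = 2L,
                                           artefact = 0L,
                                           false_positive = 0L,
                                           negative = 0L),
                     count_model = cm2, seed = 2L)
  expect_error(simulate_feature_table(cfg4), "PBMC.*hem")
})

test_that("fixtures round-trip losslessly through the readers", {
  sim <- small_sim()
  dir <- withr::local_tempdir()
  manifest <- write_fixture(sim, dir)
  expect_identical(sum(grepl("\\.tif$", manifest)), 14L)  # 7 channels x 2
  fx <- read_fixture(dir)
  # pixel-identical after the 16-bit quantization applied at write time
  for (ch in names(sim$pair$original)) {
    q <- round(pmin(pmax(sim$pair$original[[ch]], 0), 65535))
    expect_identical(fx$pair$original[[ch]], q)
  }
  expect_identical(nrow(fx$truth$cells) + nrow(fx$truth$signals),
                   nrow(sim$truth$cells) + nrow(sim$truth$signals))
  expect_identical(fx$config$seed, 42L)
})
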