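mk_spots <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(channel = r[[1]], x = as.numeric(r[[2]]),
               y = as.numeric(r[[3]]), peak_intensity = 500, area = 9)))
  df
}

cb <- build_default_panel()

test_that("colocalize_code pairs within the radius, one-to-one by distance", {
  sp <- mk_spots(list("Cy3", 10, 10), list("TexasRed", 10.8, 10.6))
  pr <- colocalize_code(sp, c("TexasRed", "Cy3"), radius = 2.5)
  expect_identical(nrow(pr), 1L)
  expect_equal(pr$x, 10.4); expect_equal(pr$y, 10.3)
  # farther than the radius: no pair
  sp2 <- mk_spots(list("Cy3", 10, 10), list("TexasRed", 15, 10))
  expect_identical(nrow(colocalize_code(sp2, c("TexasRed", "Cy3"), 2.5)), 0L)
  # one A between two Bs pairs with the nearer B
  sp3 <- mk_spots(list("Cy3", 10, 10), list("TexasRed", 11, 10),
                  list("TexasRed", 8.5, 10))
  pr3 <- colocalize_code(sp3, c("TexasRed", "Cy3"), 2.5)
  expect_identical(nrow(pr3), 1L)
  expect_identical(sp3$x[pr3$j], 11)   # nearer at distance 1 vs 1.5
  expect_error(colocalize_code(sp3, c("TexasRed", "Cy3"), 0), "radius")
})

test_that("greedy matching agrees with brute-force minimum matching on
           small random instances", {
  # oracle: exhaustive assignment minimizing total distance, same radius
  brute_pairs <- function(sp, code, radius) {
    ia <- which(sp$channel == code[1]); ib <- which(sp$channel == code[2])
    best <- NULL; best_n <- -1L; best_d <- Inf
    perms <- function(v) if (length(v) <= 1) list(v) else
      do.call(c, lapply(seq_along(v), function(i)
        lapply(perms(v[-i]), function(p) c(v[i], p))))
    for (p in perms(ib)) {
      n <- min(length(ia), length(p))
      d <- sqrt((sp$y[ia[seq_len(n)]] - sp$y[p[seq_len(n)]])^2 +
                  (sp$x[ia[seq_len(n)]] - sp$x[p[seq_len(n)]])^2)
      ok <- d <= radius
      if (sum(ok) > best_n || (sum(ok) == best_n && sum(d[ok]) < best_d)) {
        best_n <- sum(ok); best_d <- sum(d[ok])
      }
    }
    best_n
  }
  set.seed(55)
  agree <- 0L
  for (trial in 1:50) {
    na <- sample(1:3, 1); nb <- sample(1:3, 1)
    sp <- rbind(
      data.frame(channel = "Cy3", x = runif(na, 0, 12), y = runif(na, 0, 12),
                 peak_intensity = 500, area = 9),
      data.frame(channel = "Cy5", x = runif(nb, 0, 12), y = runif(nb, 0, 12),
                 peak_intensity = 500, area = 9))
    mine <- nrow(colocalize_code(sp, c("Cy3", "Cy5"), 2.5))
    if (mine == brute_pairs(sp, c("Cy3", "Cy5"), 2.5)) agree <- agree + 1L
  }
  expect_gte(agree, 49L)  # >= 99% size agreement with the optimal matching
})

test_that("decode_signals applies the three false-positive filters", {
  # clean hem call: Cy3 + TexasRed at one location
  sp <- mk_spots(list("Cy3", 20, 20), list("TexasRed", 20.5, 20))
  dec <- decode_signals(sp, cb)
  expect_identical(dec$status, "accepted")
  expect_identical(dec$marker, "hem")
  # lone spot -> rejected_single_channel
  dec2 <- decode_signals(mk_spots(list("Cy5", 5, 5)), cb)
  expect_identical(dec2$status, "rejected_single_channel")
  # off-code pair: TexasRed + Cy5 is excluded by the channel restriction
  dec3 <- decode_signals(mk_spots(list("TexasRed", 8, 8),
                                  list("Cy5", 8.5, 8)), cb)
  expect_identical(dec3$status, "rejected_off_code")
  # five coincident channels -> all unspecific
  sp5 <- mk_spots(list("Atto425", 30, 30), list("Atto488", 30.4, 30),
                  list("Cy3", 30, 30.4), list("Cy5", 30.4, 30.4),
                  list("AF750", 29.6, 30))
  dec5 <- decode_signals(sp5, cb)
  expect_true(all(dec5$status == "unspecific_multichannel"))
  # partition: every candidate has exactly one status, counts conserved
  all_sp <- rbind(sp, mk_spots(list("Cy5", 5, 5)), sp5)
  decA <- decode_signals(all_sp, cb)
  expect_identical(sum(table(decA$status)), nrow(decA))
  # a 3-channel group containing valid codes decodes per constituent code
  sp3 <- mk_spots(list("Atto488", 50, 50), list("Cy3", 50.5, 50),
                  list("Cy5", 50, 50.5))
  dec6 <- decode_signals(sp3, cb)
  acc <- dec6[dec6$status == "accepted", ]
  expect_setequal(acc$marker, c("VIM", "AR-FL", "PSMA"))
})

test_that("masking hierarchy levels, idempotence and monotonicity", {
  # AR-FL coincident with accepted VIM -> masked_by:VIM
  sp <- mk_spots(list("Atto488", 10, 10), list("Cy5", 10.5, 10),  # AR-FL
                 list("Atto488", 11, 10.5), list("Cy3", 10.2, 10.8)) # VIM
  dec <- apply_masks(decode_signals(sp, cb))
  arfl <- dec[!is.na(dec$marker) & dec$marker == "AR-FL", ]
  expect_true(all(startsWith(arfl$status, "masked_by:")))
  vim <- dec[!is.na(dec$marker) & dec$marker == "VIM", ]
  expect_identical(vim$status, "accepted")
  # EPCAM coincident with accepted PSA -> masked (level 2)
  sp2 <- mk_spots(list("Atto488", 20, 60), list("AF750", 20.4, 60),  # EPCAM
                  list("Atto425", 20.8, 60.2), list("AF750", 20.2, 60.9)) # PSA
  dec2 <- apply_masks(decode_signals(sp2, cb))
  ep <- dec2[!is.na(dec2$marker) & dec2$marker == "EPCAM", ]
  expect_identical(ep$status, "masked_by:PSA")
  # KRT coincident with VIM: both stay accepted (KRT is never a target)
  sp3 <- mk_spots(list("Atto425", 40, 40), list("Cy5", 40.4, 40),   # KRT
                  list("Atto488", 40.2, 40.6), list("Cy3", 40.7, 40.2)) # VIM
  dec3 <- apply_masks(decode_signals(sp3, cb))
  expect_true(all(dec3$status[!is.na(dec3$marker) &
                                dec3$marker %in% c("KRT", "VIM")] ==
                    "accepted"))
  # a level-1-masked AR-FL still masks level-2 targets
  sp4 <- mk_spots(list("Atto488", 70, 70), list("Cy5", 70.5, 70),   # AR-FL
                  list("Atto488", 70.9, 70.4), list("Cy3", 70.1, 70.8), # VIM
                  list("Cy3", 71.0, 69.8), list("AF750", 70.3, 69.5))   # AR-V7
  dec4 <- apply_masks(decode_signals(sp4, cb))
  arv7 <- dec4[!is.na(dec4$marker) & dec4$marker == "AR-V7", ]
  expect_true(all(startsWith(arv7$status, "masked_by:")))
  # idempotence and monotonicity over random decoded sets
  set.seed(77)
  for (trial in 1:5) {
    n <- 40
    sp_r <- data.frame(
      channel = sample(SIGNAL_CHANNELS, n, replace = TRUE),
      x = runif(n, 0, 60), y = runif(n, 0, 60),
      peak_intensity = 500, area = 9)
    d0 <- decode_signals(sp_r, cb)
    d1 <- apply_masks(d0)
    d2 <- apply_masks(d1)
    expect_identical(d1, d2)
    expect_lte(sum(d1$status == "accepted"), sum(d0$status == "accepted"))
    expect_identical(nrow(d1), nrow(d0))
  }
})

test_that("autofluorescence and border masking", {
  bg_a <- matrix(10, 80, 80); bg_b <- matrix(10, 80, 80)
  bg_a[30:40, 30:40] <- 800           # bright in A only
  bg_a[60:70, 60:70] <- 800; bg_b[60:70, 60:70] <- 700  # bright in both
  af <- autofluorescence_objects(bg_a, bg_b,
                                 spot_params(lower_bound = 100, min_area = 3),
                                 margin = 2)
  expect_true(af[65, 65])
  expect_false(af[35, 35])
  expect_error(autofluorescence_objects(bg_a, matrix(0, 10, 10)), "shape")
  # border voids mask accepted signals; autofluor mask masks the rest
  sig <- data.frame(marker = c("hem", "hem", "hem"),
                    x = c(65, 35, 2), y = c(65, 35, 40),
                    status = "accepted", spot1 = NA, spot2 = NA,
                    cell = NA_integer_)
  valid <- matrix(TRUE, 80, 80); valid[, 1:5] <- FALSE
  out <- mask_artifacts(sig, autofluor = af, valid = valid)
  expect_identical(out$status, c("masked_autofluor", "accepted",
                                 "masked_border"))
})

test_that("assign_to_cells counts accepted signals per containing cell", {
  cells <- matrix(0L, 40, 40)
  cells[5:15, 5:15] <- 1L; cells[25:35, 25:35] <- 2L
  sig <- data.frame(
    marker = c("hem", "hem", "KRT", "VIM"),
    x = c(10, 30, 30, 20), y = c(10, 30, 31, 2),
    status = c("accepted", "accepted", "accepted", "rejected_single_channel"),
    spot1 = NA, spot2 = NA, cell = NA_integer_)
  out <- assign_to_cells(sig, cells, markers = c("hem", "KRT", "VIM"))
  expect_identical(out$counts$hem, c(1L, 1L))
  expect_identical(out$counts$KRT, c(0L, 1L))
  expect_identical(out$counts$VIM, c(0L, 0L))   # rejected not counted
  expect_identical(out$counts$total, c(1L, 2L))
  # background signal stays unassigned
  sig2 <- data.frame(marker = "hem", x = 20, y = 20, status = "accepted",
                     spot1 = NA, spot2 = NA, cell = NA_integer_)
  out2 <- assign_to_cells(sig2, cells, markers = "hem")
  expect_true(is.na(out2$signals$cell))
  expect_identical(sum(out2$counts$hem), 0L)
  # conservation: column sums equal assigned accepted signals
  expect_identical(sum(out$counts$hem + out$counts$KRT + out$counts$VIM),
                   sum(!is.na(out$signals$cell)))
})

test_that("the TexasRed restriction suppresses bleed-through mis-decoding", {
  # one tumor-like cell expressing only the {Atto488, Cy5} code, with
  # bleed-through raised above the spot detection threshold: Cy5 spots
  # ghost into TexasRed at the same coordinates
  cm <- default_count_models()
  for (cl in names(cm)) for (m in names(cm[[cl]]))
    cm[[cl]][[m]] <- list(type = "zero")
  cm$CTC$`AR-FL` <- list(type = "constant", value = 30L)
  cfg <- sim_config(image_shape = c(384L, 384L),
                    n_cells_per_class = c(CTC = 1L, PBMC = 0L, artefact = 0L,
                                          false_positive = 0L, negative = 0L),
                    count_model = cm, autofluor_rate = 0, noise_sd = 0,
                    bleedthrough_beta = 0.6,
                    misalignment = c(dx = 0, dy = 0, theta = 0), seed = 61L)
  sim <- simulate_sample(cfg)
  corr <- subtract_background(sim$pair, rigid_transform(0, 0, 0))
  spots <- detect_spots_all(corr$channels, build_default_panel(),
                            spot_params(lower_bound = 150))
  expect_true("TexasRed" %in% spots$channel)   # ghosts are detected
  # unrestricted 15-code book: every channel pair is a marker
  all_codes <- enumerate_codes(SIGNAL_CHANNELS, 2)
  cb15 <- build_default_panel()
  cb15$markers <- lapply(all_codes, function(cd)
    list(name = paste(cd, collapse = "+"), genes = "synthetic", code = cd))
  cb15$restrictions <- list()
  expect_identical(validate_codebook(cb15), character(0))
  tr_calls <- function(dec) {
    acc <- dec[dec$status == "accepted" & !is.na(dec$marker), ]
    sum(grepl("TexasRed", acc$marker) | acc$marker == "hem")
  }
  dec15 <- decode_signals(spots, cb15)
  dec11 <- decode_signals(spots, build_default_panel())
  expect_gt(tr_calls(dec15), 0)          # spurious TexasRed-code calls
  expect_lt(tr_calls(dec11), tr_calls(dec15))
  expect_identical(tr_calls(dec11), 0L)  # no Cy3 present -> no hem calls
})
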