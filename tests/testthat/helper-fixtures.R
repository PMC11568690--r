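# Shared fixtures, built in code. Kept deliberately small: unit tests use
# tiny constructed images; only the end-to-end acceptance test simulates a
# full field of view.

# a small simulated sample (few cells, small field) for pipeline-level
# unit tests; memoised per test run
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_sample(sim_config(
        image_shape = c(640L, 640L),
        n_cells_per_class = c(CTC = 2L, PBMC = 6L, artefact = 1L,
                              false_positive = 1L, negative = 2L),
        autofluor_rate = 2, seed = 42L))
    cache
  }
})

# independent cross-entropy oracle: brute force over every integer
# threshold, computing the criterion by direct pixel sums (no histogram)
li_oracle_8bit <- function(img) {
  vals <- sort(unique(as.integer(img)))
  if (length(vals) == 1L) return(vals)
  # shift to strict positivity for the log terms, as the implementation does
  shift <- if (min(vals) <= 0) -min(vals) + 1 else 0
  x <- as.numeric(img) + shift
  best_t <- NA; best_ce <- Inf
  for (t in vals[-length(vals)]) {
    bg <- x[x <= t + shift]; fg <- x[x > t + shift]
    ce <- -(sum(bg) * log(mean(bg)) + sum(fg) * log(mean(fg)))
    if (ce < best_ce) { best_ce <- ce; best_t <- t }
  }
  list(threshold = best_t, ce = best_ce)
}

# cross entropy of a binarization at threshold t (same shift convention)
ce_at <- function(img, t) {
  vals <- as.numeric(img)
  shift <- if (min(vals) <= 0) -min(vals) + 1 else 0
  x <- vals + shift
  bg <- x[vals <= t]; fg <- x[vals > t]
  if (length(bg) == 0 || length(fg) == 0) return(Inf)
  -(sum(bg) * log(mean(bg)) + sum(fg) * log(mean(fg)))
}

# render a disk for segmentation fixtures
disk_image <- function(nr, nc, centers, radii, peaks, bg = 0) {
  img <- matrix(bg, nr, nc)
  for (i in seq_len(nrow(centers))) {
    d <- sqrt(outer((seq_len(nr) - centers[i, 1])^2,
                    (seq_len(nc) - centers[i, 2])^2, `+`))
    img <- img + peaks[i] / (1 + exp((d - radii[i]) / 1.2))
  }
  img
}

expect_transform_close <- function(est, dx, dy, theta, tol_t = 0.5,
                                   tol_r = 0.2) {
  expect_lt(abs(est$dx - dx), tol_t)
  expect_lt(abs(est$dy - dy), tol_t)
  expect_lt(abs(est$theta - theta), tol_r)
}
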