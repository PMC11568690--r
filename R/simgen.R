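# Synthetic sample generator with full ground truth. Emulates: DAPI nuclei
# in two intensity tiers, diffraction-limited dual-color spots placed per
# the codebook, autofluorescent multi-channel objects, Cy5 -> TexasRed
# bleed-through, a small rigid misalignment between original and post-strip
# background scans, and class-conditional per-cell count distributions
# parameterized from the published cell-line/PBMC expression table.

CLASS_LEVELS <- c("CTC", "PBMC", "artefact", "false_positive", "negative")

# published per-class marker statistics used to parameterize count models:
# positivity [%], median, Q1, Q3 [RCPs/cell]. CTC uses the VCaP profile,
# PBMC the healthy-donor PBMC profile.
count_targets <- function() {
  m <- c("hem", "VIM", "KRT", "EPCAM", "PSA", "PSMA", "AR-FL", "AR-V7",
         "NE", "SLFN11", "DLL3")
  vcap <- data.frame(marker = m,
    pos = c(2, 75, 94, 79, 44, 93, 99, 90, 12, 16, 14) / 100,
    med = c(0, 1, 5, 2, 0, 4, 34, 4, 0, 0, 0),
    q1  = c(0, 1, 3, 1, 0, 2, 25, 2, 0, 0, 0),
    q3  = c(0, 3, 8, 3, 1, 7, 43, 7, 0, 0, 0))
  pbmc <- data.frame(marker = m,
    pos = c(86, 32, 4, 0, 0, 1, 1, 1, 4, 7, 1) / 100,
    med = c(3, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    q1  = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),
    q3  = c(5, 1, 0, 0, 0, 0, 0, 0, 0, 0, 0))
  list(CTC = vcap, PBMC = pbmc)
}

# hurdle negative binomial: count = Bernoulli(pos) * (1 + NB(mu, size)).
# mu/size are fitted so mixture quantiles match the published median/IQR.
fit_hurdle_nb <- function(pos, med, q1, q3) {
  if (pos <= 0) return(list(type = "hurdle_nb", pos = 0, mu = 0, size = 1))
  qmix <- function(p, mu, size) {
    # quantile of the mixture at probability p
    if (p <= 1 - pos) return(0)
    1 + stats::qnbinom((p - (1 - pos)) / pos, mu = mu, size = size)
  }
  target <- c(q1, med, q3)
  best <- NULL; best_err <- Inf
  for (size in c(0.5, 1, 2, 4, 8, 16, 32)) {
    for (mu in c(seq(0.05, 5, by = 0.05), seq(5.2, 60, by = 0.2))) {
      got <- c(qmix(0.25, mu, size), qmix(0.5, mu, size), qmix(0.75, mu, size))
      err <- sum((got - target)^2) + 1e-4 * mu  # mild parsimony tie-break
      if (err < best_err) { best_err <- err; best <- c(mu, size) }
    }
  }
  list(type = "hurdle_nb", pos = pos, mu = best[1], size = best[2])
}

draw_count <- function(model, n) {
  switch(model$type,
    hurdle_nb = {
      z <- stats::rbinom(n, 1L, model$pos)
      k <- 1L + stats::rnbinom(n, mu = model$mu, size = model$size)
      as.integer(z * k)
    },
    poisson = as.integer(stats::rpois(n, model$lambda)),
    zero = integer(n),
    constant = rep(as.integer(model$value), n),
    stop("unknown count model type: ", model$type))
}

#' Default class-conditional count models
#'
#' CTC and PBMC models are hurdle negative binomials fitted to the
#' published VCaP and PBMC positivity/median/IQR values. Artefacts draw
#' low multi-marker Poisson counts (dust autofluorescent in many
#' channels), in situ false-positive cells low Poisson counts concentrated
#' on sporadic markers, and negative cells are all-zero.
#'
#' @return nested list `model[[class]][[marker]]`.
#' @export
default_count_models <- function() {
  tg <- count_targets()
  mk <- tg$CTC$marker
  fit_class <- function(df) {
    out <- lapply(seq_len(nrow(df)), function(i)
      fit_hurdle_nb(df$pos[i], df$med[i], df$q1[i], df$q3[i]))
    stats::setNames(out, df$marker)
  }
  list(
    CTC = fit_class(tg$CTC),
    PBMC = fit_class(tg$PBMC),
    artefact = stats::setNames(
      rep(list(list(type = "poisson", lambda = 0.8)), length(mk)), mk),
    false_positive = stats::setNames(
      rep(list(list(type = "poisson", lambda = 0.35)), length(mk)), mk),
    negative = stats::setNames(
      rep(list(list(type = "zero")), length(mk)), mk)
  )
}

#' Simulation configuration
#'
#' Defaults state the emulated world: a 1280 x 1280 px field of view
#' (1 px = 1/6.2 um, the scale at which a 2800 px^2 nucleus is 73.6 um^2),
#' 16-bit intensity semantics, spots of sigma 1.2 px so
#' thresholded spots land in the 3-5 px diameter regime, spot peak
#' amplitude 600 over a background of 100 with Gaussian read noise sd 8
#' (SNR well above 10), 6 autofluorescent objects per field, 15% Cy5 ->
#' TexasRed bleed-through (below spot-detection threshold at these
#' amplitudes), and a sub-cell rigid misalignment of the background scan.
#'
#' @param image_shape `c(H, W)` in px.
#' @param bin_factor integer scanner bin factor (8 for cell samples).
#' @param n_cells_per_class named integer vector over the 5 classes.
#' @param count_model nested list `[[class]][[marker]]`, see
#'   [default_count_models()].
#' @param spot_sigma Gaussian spot sigma in px.
#' @param spot_amplitude spot peak amplitude (intensity units).
#' @param background_level additive background (intensity units).
#' @param noise_sd Gaussian noise sd per scan.
#' @param autofluor_rate autofluorescent objects per image.
#' @param bleedthrough_beta fraction of Cy5 intensity added to TexasRed.
#' @param misalignment `c(dx, dy, theta)` of the background scan (px, px,
#'   degrees).
#' @param seed integer driving all randomness.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(image_shape = c(1280L, 1280L),
                       bin_factor = 8L,
                       n_cells_per_class = c(CTC = 8L, PBMC = 24L,
                                             artefact = 4L,
                                             false_positive = 5L,
                                             negative = 10L),
                       count_model = default_count_models(),
                       spot_sigma = 1.2,
                       spot_amplitude = 600,
                       background_level = 100,
                       noise_sd = 8,
                       autofluor_rate = 6,
                       bleedthrough_beta = 0.15,
                       misalignment = c(dx = 3.5, dy = -2.5, theta = 0.4),
                       seed = 1L) {
  stopifnot(all(n_cells_per_class >= 0), spot_sigma > 0,
            bleedthrough_beta >= 0, bleedthrough_beta < 1)
  cfg <- list(image_shape = as.integer(image_shape),
              bin_factor = as.integer(bin_factor),
              n_cells_per_class = n_cells_per_class,
              count_model = count_model,
              spot_sigma = spot_sigma, spot_amplitude = spot_amplitude,
              background_level = background_level, noise_sd = noise_sd,
              autofluor_rate = autofluor_rate,
              bleedthrough_beta = bleedthrough_beta,
              misalignment = misalignment, seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# add a Gaussian spot (amplitude at the exact continuous center) to an image
add_spot <- function(img, y, x, amplitude, sigma) {
  half <- ceiling(4 * sigma)
  r0 <- max(1L, floor(y) - half + 1L); r1 <- min(nrow(img), floor(y) + half + 1L)
  c0 <- max(1L, floor(x) - half + 1L); c1 <- min(ncol(img), floor(x) + half + 1L)
  if (r0 > r1 || c0 > c1) return(img)
  rr <- r0:r1; cc <- c0:c1
  dy2 <- ((rr - 1) - y)^2
  dx2 <- ((cc - 1) - x)^2
  img[rr, cc] <- img[rr, cc] +
    amplitude * exp(-outer(dy2, dx2, `+`) / (2 * sigma^2))
  img
}

# nucleus as a radial-falloff disk with a soft logistic edge
add_nucleus <- function(img, y, x, radius, peak) {
  half <- ceiling(radius + 6)
  r0 <- max(1L, floor(y) - half); r1 <- min(nrow(img), floor(y) + half)
  c0 <- max(1L, floor(x) - half); c1 <- min(ncol(img), floor(x) + half)
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer(((rr - 1) - y)^2, ((cc - 1) - x)^2, `+`))
  prof <- peak * (0.75 + 0.25 * pmax(0, 1 - (d / radius)^2)) /
    (1 + exp((d - radius) / 1.2))
  img[rr, cc] <- img[rr, cc] + prof
  img
}

add_blob <- function(img, y, x, radius, amplitude) {
  half <- ceiling(radius + 5)
  r0 <- max(1L, floor(y) - half); r1 <- min(nrow(img), floor(y) + half)
  c0 <- max(1L, floor(x) - half); c1 <- min(ncol(img), floor(x) + half)
  rr <- r0:r1; cc <- c0:c1
  d <- sqrt(outer(((rr - 1) - y)^2, ((cc - 1) - x)^2, `+`))
  img[rr, cc] <- img[rr, cc] + amplitude / (1 + exp((d - radius) / 1.5))
  img
}

# dart-throwing placement of object centers; object i keeps a clearance of
# spacing[i] around itself, so a pair (i, j) must be spacing[i] + spacing[j]
# apart. Objects are placed in the order given (place large objects first).
place_centers <- function(spacing, H, W, margin, label) {
  n <- length(spacing)
  ys <- numeric(0); xs <- numeric(0); sp <- numeric(0)
  attempts <- 0L
  for (i in seq_len(n)) {
    repeat {
      if (attempts > 6000L * max(n, 1L))
        stop("simulate_sample: cannot place all objects of class ", label,
             " without overlap; enlarge image_shape or reduce counts")
      attempts <- attempts + 1L
      y <- stats::runif(1, margin, H - 1 - margin)
      x <- stats::runif(1, margin, W - 1 - margin)
      if (length(ys) == 0 ||
          all((ys - y)^2 + (xs - x)^2 >= (sp + spacing[i])^2)) {
        ys <- c(ys, y); xs <- c(xs, x); sp <- c(sp, spacing[i])
        break
      }
    }
  }
  cbind(y = ys, x = xs)
}

#' Simulate a matched original/background sample pair with ground truth
#'
#' @param config a [sim_config()].
#' @param cb codebook (default panel if omitted).
#' @return list with `pair` (a `sample_pair`), `truth` (list of `cells`,
#'   `signals`, `autofluor` data.frames) and `config`.
#' @export
simulate_sample <- function(config = sim_config(), cb = build_default_panel()) {
  set.seed(config$seed)
  H <- config$image_shape[1]; W <- config$image_shape[2]
  chans <- setdiff(cb$channels, cb$nuclear)
  blank <- function() matrix(0, H, W)
  spots_img <- stats::setNames(lapply(chans, function(.) blank()), chans)
  base_img <- stats::setNames(lapply(chans, function(.) blank()), chans)
  dapi <- blank()

  ncl <- config$n_cells_per_class
  classes <- rep(names(ncl), ncl)
  n_total <- length(classes)
  cells <- NULL; signals <- NULL; af <- NULL
  if (n_total > 0) {
    # radius by class: CTC nuclei large (some above the 2800 px^2 cutoff),
    # blood/negative nuclei small; artefact rows are nucleus-free blobs
    radius <- numeric(n_total)
    # 1 px = 1/6.2 um: tumor-line nuclei ~11-15 um across (area straddles
    # the 2800 px^2 budget cutoff), blood-cell nuclei ~6.5-9 um
    radius[classes == "CTC"] <- stats::runif(sum(classes == "CTC"), 34, 48)
    radius[classes != "CTC"] <- stats::runif(sum(classes != "CTC"), 20, 28)
    # clearance: nucleus + expansion budget + spot rim; large cells first
    ord <- order(-radius)
    classes <- classes[ord]; radius <- radius[ord]
    spacing <- radius + ifelse(pi * radius^2 >= 2800, 32, 12) + 12
    ctr <- place_centers(spacing, H, W, margin = max(radius) + 38,
                         label = "all")
    perm <- seq_len(n_total)
    tier <- ifelse(stats::runif(n_total) < 0.3, "low", "high")
    peak <- ifelse(tier == "high", stats::runif(n_total, 2200, 3200),
                   stats::runif(n_total, 450, 700))
    mk <- marker_names(cb)
    counts <- matrix(0L, n_total, length(mk), dimnames = list(NULL, mk))
    sig_rows <- list()
    for (i in seq_len(n_total)) {
      cl <- classes[i]
      if (cl != "artefact") dapi <- add_nucleus(dapi, ctr[i, 1], ctr[i, 2],
                                                radius[i], peak[i])
      if (cl %in% c("CTC", "PBMC")) {
        kk <- vapply(mk, function(m)
          draw_count(config$count_model[[cl]][[m]], 1L), integer(1))
        counts[i, ] <- kk
        k_tot <- sum(kk)
        if (k_tot > 0L) {
          # RCPs are ~0.5-1 um amplified DNA balls; they exclude each
          # other physically, so spot centers keep a 4 px minimum
          # separation inside the cell disk (nucleus + cytoplasm rim)
          rmax <- radius[i] + 15
          sy <- numeric(0); sx <- numeric(0)
          tries <- 0L
          while (length(sy) < k_tot && tries < 400L * k_tot) {
            tries <- tries + 1L
            rs <- rmax * sqrt(stats::runif(1)); th <- stats::runif(1, 0, 2 * pi)
            y <- min(max(ctr[i, 1] + rs * sin(th), 1), H - 2)
            x <- min(max(ctr[i, 2] + rs * cos(th), 1), W - 2)
            if (length(sy) && any((sy - y)^2 + (sx - x)^2 < 16)) next
            sy <- c(sy, y); sx <- c(sx, x)
          }
          if (length(sy) < k_tot)
            stop("simulate_sample: cell ", i, " too crowded for ", k_tot,
                 " signals")
          mvec <- rep(mk, kk)
          for (j in seq_len(k_tot)) {
            code <- marker_code(cb, mvec[j])
            for (ch in code)
              spots_img[[ch]] <- add_spot(spots_img[[ch]], sy[j], sx[j],
                                          config$spot_amplitude,
                                          config$spot_sigma)
            sig_rows[[length(sig_rows) + 1L]] <-
              data.frame(marker = mvec[j], y = sy[j], x = sx[j], cell = i)
          }
        }
      }
      if (cl %in% c("artefact", "false_positive")) {
        # autofluorescent blob (bright in Cy5 + TexasRed + one more channel)
        b_r <- stats::runif(1, 5, 9)
        amp <- stats::runif(1, 500, 900)
        af_ch <- c("Cy5", "TexasRed", sample(setdiff(chans, c("Cy5", "TexasRed")), 1))
        for (ch in af_ch)
          base_img[[ch]] <- add_blob(base_img[[ch]], ctr[i, 1], ctr[i, 2],
                                     b_r, amp)
        af <- rbind(af, data.frame(y = ctr[i, 1], x = ctr[i, 2], radius = b_r,
                                   channels = paste(af_ch, collapse = "+")))
      }
    }
    cells <- data.frame(cell = seq_len(n_total), class = classes,
                        y = ctr[, 1], x = ctr[, 2], radius = radius,
                        tier = tier, counts, check.names = FALSE)
    signals <- if (length(sig_rows)) do.call(rbind, sig_rows) else
      data.frame(marker = character(), y = numeric(), x = numeric(),
                 cell = integer())
  } else {
    cells <- data.frame(cell = integer(), class = character(), y = numeric(),
                        x = numeric(), radius = numeric(), tier = character())
    signals <- data.frame(marker = character(), y = numeric(), x = numeric(),
                          cell = integer())
  }
  # free-floating autofluorescent debris
  n_af <- stats::rpois(1, config$autofluor_rate)
  for (k in seq_len(n_af)) {
    y <- stats::runif(1, 20, H - 21); x <- stats::runif(1, 20, W - 21)
    b_r <- stats::runif(1, 4, 8); amp <- stats::runif(1, 400, 800)
    for (ch in c("Cy5", "TexasRed"))
      base_img[[ch]] <- add_blob(base_img[[ch]], y, x, b_r, amp)
    af <- rbind(af, data.frame(y = y, x = x, radius = b_r,
                               channels = "Cy5+TexasRed"))
  }
  if (is.null(af)) af <- data.frame(y = numeric(), x = numeric(),
                                    radius = numeric(), channels = character())

  mis <- rigid_transform(config$misalignment[["dx"]],
                         config$misalignment[["dy"]],
                         config$misalignment[["theta"]])
  noise <- function() if (config$noise_sd > 0)
    matrix(stats::rnorm(H * W, 0, config$noise_sd), H, W) else 0
  compose_scan <- function(extra_spots, transform) {
    out <- list()
    for (ch in chans) {
      img <- base_img[[ch]] + config$background_level
      if (extra_spots) img <- img + spots_img[[ch]]
      out[[ch]] <- img
    }
    # Cy5 emission leaks into the TexasRed detection band
    out[["TexasRed"]] <- out[["TexasRed"]] +
      config$bleedthrough_beta * (out[["Cy5"]] - config$background_level)
    out[[cb$nuclear]] <- dapi + config$background_level
    if (!is.null(transform))
      out <- lapply(out, function(im) apply_rigid(im, transform)$image)
    lapply(out, function(im) { im <- im + noise(); im[im < 0] <- 0; im })
  }
  original <- compose_scan(TRUE, NULL)
  background <- compose_scan(FALSE, mis)
  pair <- sample_pair(original, background, nuclear = cb$nuclear)
  list(pair = pair,
       truth = list(cells = cells, signals = signals, autofluor = af),
       config = config)
}

#' Simulate per-cell count feature tables with class labels
#'
#' @param config a [sim_config()] (only `n_cells_per_class`, `count_model`
#'   and `seed` are used).
#' @param markers marker names (default: the default panel's).
#' @return data.frame of per-marker counts plus `total` and `class`.
#' @export
simulate_feature_table <- function(config = sim_config(),
                                   markers = marker_names(build_default_panel())) {
  set.seed(config$seed)
  ncl <- config$n_cells_per_class
  for (cl in names(ncl)) {
    if (ncl[[cl]] == 0L) next
    missing <- setdiff(markers, names(config$count_model[[cl]]))
    if (is.null(config$count_model[[cl]]) || length(missing))
      stop("simulate_feature_table: no count model for (", cl, ", ",
           paste(missing, collapse = ", "), ")")
  }
  rows <- lapply(names(ncl), function(cl) {
    n <- ncl[[cl]]
    if (n == 0L) return(NULL)
    cnt <- vapply(markers, function(m)
      draw_count(config$count_model[[cl]][[m]], n), integer(n))
    if (n == 1L) cnt <- matrix(cnt, nrow = 1L, dimnames = list(NULL, markers))
    df <- data.frame(cnt, check.names = FALSE)
    df$total <- as.integer(rowSums(cnt))
    df$class <- cl
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a simulated sample to disk as a pipeline-readable fixture
#'
#' Layout: `<dir>/original/<channel>.tif`, `<dir>/background/<channel>.tif`,
#' `truth_cells.csv`, `truth_signals.csv`, `config.json`.
#'
#' @param sim result of [simulate_sample()].
#' @param directory output directory (created if needed).
#' @return character vector of written paths (the manifest).
#' @export
write_fixture <- function(sim, directory) {
  dir.create(file.path(directory, "original"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(directory, "background"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- character()
  for (scan in c("original", "background")) {
    for (ch in names(sim$pair[[scan]])) {
      p <- file.path(directory, scan, paste0(ch, ".tif"))
      write_tiff(sim$pair[[scan]][[ch]], p)
      manifest <- c(manifest, p)
    }
  }
  p <- file.path(directory, "truth_cells.csv")
  utils::write.csv(sim$truth$cells, p, row.names = FALSE); manifest <- c(manifest, p)
  p <- file.path(directory, "truth_signals.csv")
  utils::write.csv(sim$truth$signals, p, row.names = FALSE); manifest <- c(manifest, p)
  p <- file.path(directory, "config.json")
  cfg <- sim$config
  cfg$count_model <- NULL  # refitted from defaults on read
  jsonlite::write_json(unclass(cfg), p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  manifest <- c(manifest, p)
  manifest
}

#' Read a fixture directory back into a sample pair
#'
#' @param directory fixture directory written by [write_fixture()].
#' @return list with `pair`, `truth` (NULL if truth tables absent) and
#'   `config` (NULL if absent).
#' @export
read_fixture <- function(directory) {
  read_scan <- function(scan) {
    files <- list.files(file.path(directory, scan), pattern = "\\.tif$",
                        full.names = TRUE)
    if (length(files) == 0L) stop("read_fixture: no TIFFs under ",
                                  file.path(directory, scan))
    ims <- lapply(files, read_tiff)
    stats::setNames(ims, sub("\\.tif$", "", basename(files)))
  }
  original <- read_scan("original")
  background <- read_scan("background")
  truth <- NULL
  tc <- file.path(directory, "truth_cells.csv")
  if (file.exists(tc))
    truth <- list(cells = utils::read.csv(tc, check.names = FALSE),
                  signals = utils::read.csv(file.path(directory,
                                                      "truth_signals.csv")))
  cfg <- NULL
  cj <- file.path(directory, "config.json")
  if (file.exists(cj)) cfg <- jsonlite::read_json(cj, simplifyVector = TRUE)
  list(pair = sample_pair(original, background), truth = truth, config = cfg)
}
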