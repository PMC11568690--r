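# Shared image primitives: minimum cross-entropy (Li) thresholding, its
# tiled/adaptive variant, Gaussian smoothing, block binning, connected
# components, and local maxima. Images are plain numeric matrices with
# (row, col) = (y, x), 0-based coordinates at the API surface.

#' Minimum cross-entropy (Li) threshold
#'
#' Selects the threshold minimizing the cross entropy between the image and
#' its binarized version, by testing every candidate threshold on a 256-bin
#' histogram (exhaustive search, as in the classical formulation). Pixels
#' strictly above the returned value are foreground.
#'
#' @param image numeric matrix (non-negative intensities).
#' @param bins number of histogram bins for continuous data (default 256).
#' @return scalar threshold. For a constant image the constant itself is
#'   returned, so the foreground is empty by convention.
#' @export
li_threshold <- function(image, bins = 256L) {
  x <- as.numeric(image)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("li_threshold: empty image")
  lo <- min(x); hi <- max(x)
  if (hi == lo) return(lo)
  # weighted unique values if few (exact, e.g. 8/16-bit data), otherwise a
  # histogram of `bins` bins; values shifted so all are strictly positive
  # (the criterion needs log of class means)
  uv <- sort(unique(x))
  if (length(uv) <= bins) {
    g0 <- uv
    w <- as.numeric(table(factor(x, levels = uv)))
    # candidate thresholds: midpoints between adjacent values (split
    # after value i; the midpoint induces the same partition and lies
    # strictly between the two populations)
    t_cand <- (uv[-length(uv)] + uv[-1]) / 2
  } else {
    h <- hist(x, breaks = seq(lo, hi, length.out = bins + 1L), plot = FALSE)
    g0 <- h$mids
    w <- h$counts
    t_cand <- h$breaks[-c(1L, bins + 1L)]
  }
  shift <- if (lo <= 0) 1 - lo else 0
  g <- g0 + shift
  nb <- length(g)
  cum_w <- cumsum(w)
  cum_gw <- cumsum(g * w)
  tot_w <- cum_w[nb]; tot_gw <- cum_gw[nb]
  i <- seq_len(nb - 1L)
  wb <- cum_w[i]; wf <- tot_w - wb
  gb <- cum_gw[i]; gf <- tot_gw - gb
  ok <- wb > 0 & wf > 0
  mu_b <- gb / wb; mu_f <- gf / wf
  ce <- rep(Inf, nb - 1L)
  ce[ok] <- -(gb[ok] * log(mu_b[ok]) + gf[ok] * log(mu_f[ok]))
  best <- which.min(ce)
  t_cand[best]
}

#' Adaptive (tiled) minimum cross-entropy mask
#'
#' Computes Li thresholds on overlapping square tiles, bilinearly
#' interpolates tile thresholds to a per-pixel threshold surface, multiplies
#' by a correction factor and floors at a lower bound, then thresholds the
#' image. Mirrors CellProfiler-style adaptive thresholding with manually
#' tuned correction factor and lower bound.
#'
#' @param image numeric matrix.
#' @param window tile size in px (>= 8). If larger than the image, a global
#'   threshold is used (with a message).
#' @param correction multiplicative threshold correction factor.
#' @param lower_bound absolute floor on the per-pixel threshold.
#' @return logical matrix, `TRUE` where `image > threshold`.
#' @export
adaptive_mask <- function(image, window = 64L, correction = 1.0,
                          lower_bound = 0) {
  stopifnot(is.matrix(image))
  if (window < 8L) stop("adaptive_mask: window must be >= 8 px")
  nr <- nrow(image); nc <- ncol(image)
  if (window > nr || window > nc) {
    message("adaptive_mask: window exceeds image; falling back to global threshold")
    thr <- pmax(li_threshold(image) * correction, lower_bound)
    return(image > thr)
  }
  nt_r <- max(1L, ceiling(nr / window)); nt_c <- max(1L, ceiling(nc / window))
  centers_r <- (seq_len(nt_r) - 0.5) * (nr / nt_r)
  centers_c <- (seq_len(nt_c) - 0.5) * (nc / nt_c)
  tile_thr <- matrix(NA_real_, nt_r, nt_c)
  for (i in seq_len(nt_r)) {
    r0 <- floor((i - 1) * nr / nt_r) + 1L; r1 <- floor(i * nr / nt_r)
    for (j in seq_len(nt_c)) {
      c0 <- floor((j - 1) * nc / nt_c) + 1L; c1 <- floor(j * nc / nt_c)
      tile_thr[i, j] <- li_threshold(image[r0:r1, c0:c1])
    }
  }
  # bilinear interpolation of the tile-center threshold grid to pixels,
  # clamped at the borders
  ri <- seq_len(nr) - 0.5; ci <- seq_len(nc) - 0.5
  interp1 <- function(centers, q) {
    # returns (index of left center, fraction) for each query
    k <- findInterval(q, centers)
    k0 <- pmax(1L, pmin(k, length(centers) - 1L))
    if (length(centers) == 1L) return(list(i0 = rep(1L, length(q)),
                                           i1 = rep(1L, length(q)),
                                           f = rep(0, length(q))))
    f <- (q - centers[k0]) / (centers[k0 + 1L] - centers[k0])
    f <- pmin(1, pmax(0, f))
    list(i0 = k0, i1 = k0 + 1L, f = f)
  }
  ar <- interp1(centers_r, ri); ac <- interp1(centers_c, ci)
  t00 <- tile_thr[ar$i0, ac$i0, drop = FALSE]
  t10 <- tile_thr[ar$i1, ac$i0, drop = FALSE]
  t01 <- tile_thr[ar$i0, ac$i1, drop = FALSE]
  t11 <- tile_thr[ar$i1, ac$i1, drop = FALSE]
  fr <- matrix(ar$f, nr, nc); fc <- matrix(ac$f, nr, nc, byrow = TRUE)
  thr <- (1 - fr) * (1 - fc) * t00 + fr * (1 - fc) * t10 +
    (1 - fr) * fc * t01 + fr * fc * t11
  thr <- pmax(thr * correction, lower_bound)
  image > thr
}

#' Gaussian smoothing (separable, replicate padding)
#' @param image numeric matrix.
#' @param sigma standard deviation in px; `0` returns the input.
#' @return smoothed matrix.
#' @export
gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  .sep_conv(image, k)
}

#' Block-bin an image by an integer factor (mean pooling)
#'
#' Emulates the reduced-resolution scans exported by the slide scanner.
#' Trailing rows/columns that do not fill a block are dropped.
#'
#' @param image numeric matrix.
#' @param factor integer bin factor (e.g. 8 for cell samples, 2 for tissue).
#' @return binned matrix.
#' @export
bin_image <- function(image, factor) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  if (factor == 1L) return(image)
  nr <- (nrow(image) %/% factor) * factor
  nc <- (ncol(image) %/% factor) * factor
  x <- image[seq_len(nr), seq_len(nc), drop = FALSE]
  # average factor x factor blocks
  x <- rowsum(x, gl(nr %/% factor, factor, nr)) / factor
  x <- t(rowsum(t(x), gl(nc %/% factor, factor, nc)) / factor)
  unname(x)
}

#' Label connected foreground components (8-connectivity)
#' @param mask logical matrix.
#' @return integer label matrix, 0 = background.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  .cc_label(mask)
}

#' Local maxima of an image within an optional mask
#'
#' A pixel is a local maximum if it is >= all 8 neighbours and > at least
#' one of them (plateaus keep their lexicographically smallest (y, x)
#' member). Maxima closer than `min_distance` are merged, keeping the
#' brightest (ties again by (y, x)).
#'
#' @param image numeric matrix.
#' @param mask optional logical matrix restricting the search.
#' @param min_distance minimum separation in px.
#' @return data.frame with 0-based `y`, `x` and `value`.
#' @export
local_maxima <- function(image, mask = NULL, min_distance = 1) {
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(mask)) mask <- matrix(TRUE, nr, nc)
  pad <- matrix(-Inf, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- ifelse(mask, image, -Inf)
  ctr <- pad[2:(nr + 1L), 2:(nc + 1L)]
  is_max <- is.finite(ctr)
  # a maximum must dominate all neighbours and strictly exceed at least
  # one finite neighbour (isolated pixels with no finite neighbour count)
  strictly_greater <- matrix(FALSE, nr, nc)
  has_finite_nb <- matrix(FALSE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    nb <- pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    fin <- is.finite(nb)
    is_max <- is_max & (ctr >= nb)
    strictly_greater <- strictly_greater | (fin & (ctr > nb))
    has_finite_nb <- has_finite_nb | fin
  }
  is_max <- is_max & (strictly_greater | !has_finite_nb)
  idx <- which(is_max)
  if (length(idx) == 0L)
    return(data.frame(y = integer(), x = integer(), value = numeric()))
  rr <- (idx - 1L) %% nr; cc <- (idx - 1L) %/% nr
  df <- data.frame(y = rr, x = cc, value = ctr[idx])
  df <- df[order(df$y, df$x), , drop = FALSE]
  # plateau handling: collapse maxima belonging to one connected plateau of
  # equal value; then enforce min_distance keeping the brightest
  keep <- rep(TRUE, nrow(df))
  if (nrow(df) > 1L && min_distance > 0) {
    ord <- order(-df$value, df$y, df$x)
    taken_y <- numeric(0); taken_x <- numeric(0)
    sel <- logical(nrow(df))
    for (i in ord) {
      if (length(taken_y) > 0 &&
          any((df$y[i] - taken_y)^2 + (df$x[i] - taken_x)^2 <= min_distance^2)) next
      sel[i] <- TRUE
      taken_y <- c(taken_y, df$y[i]); taken_x <- c(taken_x, df$x[i])
    }
    keep <- sel
  }
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
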