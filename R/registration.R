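# Rigid-body registration of the post-strip background scan onto the
# original scan, and background subtraction. The workflow is: estimate the
# transform on binned DAPI, multiply the translation by the bin factor,
# apply it to the full-resolution background channels, then (per ROI)
# refine with a second small-range registration.

#' Construct a rigid transform
#'
#' `dx`/`dy` translate content along columns/rows (px); `theta` rotates
#' counter-clockwise (degrees) about the image center. Applying the
#' transform to an image moves its content by (+dx, +dy) after rotation.
#'
#' @param dx,dy translation in px.
#' @param theta rotation in degrees.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(dx = 0, dy = 0, theta = 0) {
  stopifnot(is.finite(dx), is.finite(dy), is.finite(theta))
  structure(list(dx = dx, dy = dy, theta = theta), class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("rigid transform: dx=%.3f px, dy=%.3f px, theta=%.3f deg\n",
              x$dx, x$dy, x$theta))
  invisible(x)
}

#' Invert a rigid transform
#' @param t a `rigid_transform`.
#' @return the inverse `rigid_transform` (about the same image center).
#' @export
invert_transform <- function(t) {
  # forward map: p = R(theta) (q - c) + c + (dy, dx); the inverse is a
  # rotation by -theta with translation -R(-theta) (dy, dx)
  th <- t$theta * pi / 180
  ct <- cos(th); st <- sin(th)
  rigid_transform(dx = -(ct * t$dx - st * t$dy),
                  dy = -(ct * t$dy + st * t$dx),
                  theta = -t$theta)
}

#' Scale a rigid transform to a finer resolution
#'
#' Translation components are multiplied by `factor`; the rotation angle is
#' scale-invariant. This is the "multiply the matrix by the bin factor"
#' upscaling step, interpreted so that rigidity is preserved.
#'
#' @param t a `rigid_transform`.
#' @param factor integer >= 1 (the bin factor).
#' @return scaled `rigid_transform`.
#' @export
scale_transform <- function(t, factor) {
  if (factor < 1) stop("scale_transform: factor must be >= 1")
  rigid_transform(t$dx * factor, t$dy * factor, t$theta)
}

#' Apply a rigid transform to an image
#'
#' Bilinear interpolation; pixels whose source sample falls outside the
#' input are 0 with `valid = FALSE` (the "empty border areas" that later
#' mask decoded signals).
#'
#' @param image numeric matrix.
#' @param t a `rigid_transform`.
#' @return list with `image` and logical `valid` mask.
#' @export
apply_rigid <- function(image, t) {
  out <- .warp_rigid(image, t$dx, t$dy, t$theta)
  list(image = out$image, valid = out$valid)
}

mse_at <- function(reference, moving, t) {
  w <- .warp_rigid(moving, t[1], t[2], t[3])
  d <- (reference - w$image)[w$valid]
  if (length(d) < 16) return(Inf)
  mean(d * d)
}

#' Estimate the rigid transform aligning `moving` onto `reference`
#'
#' Two stages: integer translation by FFT cross-correlation over a coarse
#' rotation grid, then Nelder-Mead refinement of (dx, dy, theta) minimizing
#' the mean squared difference over the overlap. Handles translations up to
#' `max_shift` (default 15% of the image) and rotations up to `max_theta`.
#'
#' @param reference,moving numeric matrices of identical shape.
#' @param max_shift translation search bound in px (default 0.15 * min dim).
#' @param max_theta rotation search bound in degrees (default 5).
#' @param theta_step coarse rotation grid step (default 1 degree).
#' @return a `rigid_transform` such that `apply_rigid(moving, t)` matches
#'   `reference`.
#' @export
estimate_rigid <- function(reference, moving,
                           max_shift = NULL, max_theta = 5,
                           theta_step = 1) {
  stopifnot(identical(dim(reference), dim(moving)))
  if (stats::sd(reference) == 0)
    stop("estimate_rigid: reference image is constant")
  nr <- nrow(reference); nc <- ncol(reference)
  if (is.null(max_shift)) max_shift <- ceiling(0.15 * min(nr, nc))
  rz <- reference - mean(reference)
  fr <- stats::fft(rz)
  thetas <- if (max_theta > 0) seq(-max_theta, max_theta, by = theta_step) else 0
  best <- NULL; best_score <- Inf
  for (th in thetas) {
    m <- if (th == 0) moving else .warp_rigid(moving, 0, 0, th)$image
    mz <- m - mean(m)
    xc <- Re(stats::fft(fr * Conj(stats::fft(mz)), inverse = TRUE))
    # shift (dy, dx) with wrap-around; restrict to the allowed range
    sy <- c(0:(nr - 1)); sy[sy > nr / 2] <- sy[sy > nr / 2] - nr
    sx <- c(0:(nc - 1)); sx[sx > nc / 2] <- sx[sx > nc / 2] - nc
    ok <- outer(abs(sy) <= max_shift, abs(sx) <= max_shift, `&`)
    xc[!ok] <- -Inf
    i <- which.max(xc)
    dy <- sy[(i - 1) %% nr + 1]; dx <- sx[(i - 1) %/% nr + 1]
    sc <- mse_at(reference, moving, c(dx, dy, th))
    if (sc < best_score) { best_score <- sc; best <- c(dx, dy, th) }
  }
  fit <- stats::optim(best, function(p) mse_at(reference, moving, p),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-10, maxit = 400))
  # polish: restart once from the optimum (Nelder-Mead can stall)
  fit <- stats::optim(fit$par, function(p) mse_at(reference, moving, p),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 400))
  rigid_transform(fit$par[1], fit$par[2], fit$par[3])
}

#' Assemble a sample pair
#'
#' @param original named list of channel matrices (original scan).
#' @param background named list of channel matrices (post-strip scan).
#' @param nuclear nuclear channel name (default "DAPI").
#' @return object of class `sample_pair`.
#' @export
sample_pair <- function(original, background, nuclear = NUCLEAR_CHANNEL) {
  stopifnot(nuclear %in% names(original), nuclear %in% names(background))
  dims <- unique(lapply(original, dim))
  if (length(dims) != 1L) stop("sample_pair: original channels differ in shape")
  dims_b <- unique(lapply(background, dim))
  if (length(dims_b) != 1L) stop("sample_pair: background channels differ in shape")
  structure(list(original = original, background = background,
                 nuclear = nuclear), class = "sample_pair")
}

#' Register the background scan and subtract it from the original
#'
#' Every signal channel becomes `max(original - registered background, 0)`;
#' the nuclear channel passes through unmodified. The returned validity
#' mask is `FALSE` where registration sampled outside the background scan.
#'
#' @param pair a `sample_pair`.
#' @param t the `rigid_transform` aligning background onto original (at
#'   full resolution).
#' @return list with `channels` (corrected named list, nuclear included
#'   untouched) and `valid` (logical matrix).
#' @export
subtract_background <- function(pair, t) {
  sig <- setdiff(names(pair$original), pair$nuclear)
  missing_bg <- setdiff(sig, names(pair$background))
  if (length(missing_bg))
    stop("subtract_background: channel missing in background scan: ",
         paste(missing_bg, collapse = ", "))
  valid <- NULL
  out <- list()
  for (ch in sig) {
    w <- apply_rigid(pair$background[[ch]], t)
    if (is.null(valid)) valid <- w$valid
    corr <- pair$original[[ch]] - w$image
    corr[corr < 0] <- 0
    out[[ch]] <- corr
  }
  out[[pair$nuclear]] <- pair$original[[pair$nuclear]]
  list(channels = out, valid = valid)
}

#' Serialize / deserialize a rigid transform as JSON
#' @param t a `rigid_transform`.
#' @param path file path.
#' @export
write_transform <- function(t, path) {
  jsonlite::write_json(list(dx = t$dx, dy = t$dy, theta = t$theta), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(x$dx, x$dy, x$theta)
}
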