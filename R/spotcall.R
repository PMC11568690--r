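# Per-channel spot calling on background-subtracted signal channels:
# adaptive minimum cross-entropy threshold, connected components, area
# filter, and reduction of each component to its local intensity maximum
# (the "shrink to a point" step). Components holding two well-separated
# maxima are split.

#' Default spot detection parameters
#'
#' @param window adaptive threshold tile size in px.
#' @param correction per-channel threshold correction factor.
#' @param lower_bound per-channel absolute threshold floor.
#' @param min_area,max_area accepted component area range (px^2, pre-shrink).
#' @param max_diameter maximum spot diameter in px; components with two
#'   maxima farther apart than this are split at their maxima.
#' @return named list of parameters.
#' @export
spot_params <- function(window = 64L, correction = 1.0, lower_bound = 0,
                        min_area = 3L, max_area = 200L, max_diameter = 5) {
  as.list(environment())
}

#' Detect spots in one background-subtracted channel
#'
#' @param channel_image numeric matrix (background-subtracted).
#' @param params see [spot_params()].
#' @param channel channel name stored in the output (default "").
#' @return data.frame (`channel`, `x`, `y`, `peak_intensity`, `area`);
#'   coordinates are 0-based full-resolution px.
#' @export
detect_spots <- function(channel_image, params = spot_params(),
                         channel = "") {
  empty <- data.frame(channel = character(), x = integer(), y = integer(),
                      peak_intensity = numeric(), area = integer())
  if (max(channel_image) == min(channel_image)) return(empty)
  mask <- adaptive_mask(channel_image, params$window, params$correction,
                        params$lower_bound)
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= params$min_area & areas <= params$max_area)
  if (length(keep) == 0L) return(empty)
  idx <- which(lab > 0L)
  l <- lab[idx]
  sel <- l %in% keep
  idx <- idx[sel]; l <- l[sel]
  nr <- nrow(channel_image)
  ys <- (idx - 1L) %% nr; xs <- (idx - 1L) %/% nr
  vals <- channel_image[idx]
  rows <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    k <- keep[j]
    i <- which(l == k)
    cy <- ys[i]; cx <- xs[i]; cv <- vals[i]
    # component-restricted local maxima on the component's bounding box;
    # split if two maxima are farther apart than the maximum spot diameter
    y0 <- min(cy); x0 <- min(cx)
    crop <- channel_image[(y0 + 1L):(max(cy) + 1L),
                          (x0 + 1L):(max(cx) + 1L), drop = FALSE]
    sub_mask <- matrix(FALSE, nrow(crop), ncol(crop))
    sub_mask[cbind(cy - y0 + 1L, cx - x0 + 1L)] <- TRUE
    mx <- local_maxima(crop, sub_mask, min_distance = params$max_diameter)
    if (nrow(mx) > 0L) { mx$y <- mx$y + y0; mx$x <- mx$x + x0 }
    if (nrow(mx) <= 1L) {
      o <- order(-cv, cy, cx)[1]
      rows[[j]] <- data.frame(channel = channel, x = cx[o], y = cy[o],
                              peak_intensity = cv[o], area = length(i))
    } else {
      # assign component pixels to the nearest retained maximum
      d2 <- outer(cy, mx$y, `-`)^2 + outer(cx, mx$x, `-`)^2
      grp <- max.col(-d2, ties.method = "first")
      area_g <- tabulate(grp, nbins = nrow(mx))
      rows[[j]] <- data.frame(channel = channel, x = mx$x, y = mx$y,
                              peak_intensity = mx$value, area = area_g)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spots in all signal channels of a corrected sample
#'
#' @param channels named list of background-subtracted channel matrices.
#' @param cb codebook (defines which channels carry signals).
#' @param params a single [spot_params()] list, or a named list of per-
#'   channel parameter lists (per-channel correction factors and lower
#'   bounds mirror the per-sample manual tuning of the original pipeline).
#' @return combined spot data.frame.
#' @export
detect_spots_all <- function(channels, cb, params = spot_params()) {
  sig <- intersect(setdiff(cb$channels, cb$nuclear), names(channels))
  per_channel <- !is.null(names(params)) && all(sig %in% names(params))
  out <- lapply(sig, function(ch) {
    p <- if (per_channel) params[[ch]] else params
    detect_spots(channels[[ch]], p, channel = ch)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}
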