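# Nucleus-driven segmentation: ROI detection on the binned DAPI image,
# two-pass nucleus detection at full resolution (bright nuclei first, dim
# nuclei on the remainder), watershed declumping, and area-conditional
# expansion of nuclei to cell borders.

#' Detect regions of interest on a binned DAPI image
#'
#' Thresholds the binned nuclear image (Li), labels connected nucleus
#' regions, and returns one ROI per region: a full-resolution bounding box
#' (padded by `margin` px and clamped to the image) plus the ROI's own
#' binary nucleus mask upscaled to full resolution. The per-ROI mask
#' excludes nuclei of neighbouring ROIs whose padded boxes overlap.
#'
#' @param binned_dapi binned nuclear channel (matrix).
#' @param bin_factor integer bin factor relating binned to full resolution.
#' @param margin padding in full-resolution px (default 40, so that the
#'   largest 32 px cell expansion fits inside the box).
#' @param full_dim full-resolution image dimension `c(nr, nc)`; default
#'   `dim(binned_dapi) * bin_factor`.
#' @param min_area minimum region area on the binned image (px, default 4).
#' @param correction,lower_bound threshold correction factor and absolute
#'   floor applied to the Li threshold (the usual per-sample tuning knobs;
#'   a correction below 1 with a sensible floor keeps dim nuclei that a
#'   bright-nucleus-dominated global threshold would drop).
#' @return list of ROIs, each a list with `bounds` (row0, col0, row1, col1;
#'   0-based, half-open, full resolution) and `roi_mask` (logical matrix of
#'   the box extent).
#' @export
detect_rois <- function(binned_dapi, bin_factor, margin = 40L,
                        full_dim = dim(binned_dapi) * bin_factor,
                        min_area = 4L, correction = 1.0, lower_bound = 0) {
  thr <- max(li_threshold(binned_dapi) * correction, lower_bound)
  mask <- binned_dapi > thr
  lab <- label_components(mask)
  n <- max(lab)
  if (n == 0L) return(list())
  out <- list()
  for (k in seq_len(n)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    # binned (1-based) -> full-resolution (0-based, half-open)
    r0 <- (min(idx[, 1]) - 1L) * bin_factor - margin
    r1 <- max(idx[, 1]) * bin_factor + margin
    c0 <- (min(idx[, 2]) - 1L) * bin_factor - margin
    c1 <- max(idx[, 2]) * bin_factor + margin
    r0 <- max(0L, r0); c0 <- max(0L, c0)
    r1 <- min(full_dim[1], r1); c1 <- min(full_dim[2], c1)
    # upscale this component's binned mask into the box
    box_mask <- matrix(FALSE, r1 - r0, c1 - c0)
    for (i in seq_len(nrow(idx))) {
      rr <- ((idx[i, 1] - 1L) * bin_factor):(idx[i, 1] * bin_factor - 1L)
      cc <- ((idx[i, 2] - 1L) * bin_factor):(idx[i, 2] * bin_factor - 1L)
      rr <- rr[rr >= r0 & rr < r1] - r0 + 1L
      cc <- cc[cc >= c0 & cc < c1] - c0 + 1L
      box_mask[rr, cc] <- TRUE
    }
    # pad the mask so slightly mis-binned nucleus borders survive masking
    box_mask <- dilate_mask(box_mask, bin_factor)
    out[[length(out) + 1L]] <- list(bounds = c(r0, c0, r1, c1),
                                    roi_mask = box_mask)
  }
  out
}

# binary dilation by Euclidean radius r (via the distance transform)
dilate_mask <- function(mask, r) {
  if (r <= 0 || !any(mask)) return(mask)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- 1L
  .edt_nearest(lab)$dist <= r
}

#' Default nucleus segmentation parameters
#'
#' @param min_diameter,max_diameter accepted nucleus diameter range in px.
#' @param correction_high,lower_bound_high threshold controls of the first
#'   (bright-nucleus) pass.
#' @param correction_low,lower_bound_low threshold controls of the second
#'   (dim-nucleus) pass run on the remaining area.
#' @param smooth_sigma Gaussian sigma (px) applied before thresholding.
#' @param declump_min_distance minimum peak separation (px) used to seed
#'   the watershed that splits touching nuclei.
#' @param halo_margin px around pass-1 nuclei excluded from the dim pass
#'   (suppresses the soft skirt of bright nuclei re-detecting as rings).
#' @return named list of parameters.
#' @export
nucleus_params <- function(min_diameter = 8, max_diameter = 80,
                           correction_high = 1.0, lower_bound_high = 0,
                           correction_low = 1.0, lower_bound_low = 0,
                           smooth_sigma = 2, declump_min_distance = 12,
                           halo_margin = 8) {
  as.list(environment())
}

one_pass_nuclei <- function(img, available, correction, lower_bound, params) {
  sm <- gaussian_blur(img, params$smooth_sigma)
  sm[!available] <- 0
  vals <- sm[available]
  if (length(vals) == 0L || max(vals) == min(vals))
    return(matrix(0L, nrow(img), ncol(img)))
  thr <- max(li_threshold(sm[available]) * correction, lower_bound)
  mask <- sm > thr & available
  if (!any(mask)) return(matrix(0L, nrow(img), ncol(img)))
  # declump: intensity peaks as seeds, watershed within the mask
  peaks <- local_maxima(sm, mask, min_distance = params$declump_min_distance)
  seeds <- matrix(0L, nrow(img), ncol(img))
  if (nrow(peaks) > 0L)
    seeds[cbind(peaks$y + 1L, peaks$x + 1L)] <- seq_len(nrow(peaks))
  lab <- .watershed_seeded(sm, seeds, mask)
  # components never reached by a seed (plateau corner cases): label them
  left <- mask & lab == 0L
  if (any(left)) {
    extra <- label_components(left)
    extra[extra > 0L] <- extra[extra > 0L] + max(lab)
    lab <- lab + extra
  }
  lab
}

#' Segment nuclei with two intensity passes
#'
#' Pass 1 detects bright nuclei (its threshold floor `lower_bound_high` is
#' set above the dim-nucleus intensity); pass 2 re-thresholds the remaining
#' area to pick up dim nuclei. Pass-2 objects overlapping pass-1 objects
#' are discarded, the union is relabelled, and objects outside the
#' configured diameter range are removed.
#'
#' @param dapi full-resolution nuclear channel, background-masked by the
#'   ROI mask where applicable.
#' @param params see [nucleus_params()].
#' @return list with `labels` (integer matrix), and per-nucleus vectors
#'   `area`, `centroid_y`, `centroid_x`, `tier` ("high"/"low").
#' @export
segment_nuclei <- function(dapi, params = nucleus_params()) {
  lab1 <- one_pass_nuclei(dapi, matrix(TRUE, nrow(dapi), ncol(dapi)),
                          params$correction_high, params$lower_bound_high,
                          params)
  lab1 <- filter_labels_by_diameter(lab1, params)
  # pass 2 on the area not claimed by pass 1, excluding a halo margin so
  # the soft skirt of bright nuclei cannot re-detect as a ring
  avail <- !dilate_mask(lab1 > 0L, params$halo_margin)
  lab2 <- one_pass_nuclei(dapi, avail, params$correction_low,
                          params$lower_bound_low, params)
  # drop pass-2 objects overlapping pass-1 objects
  if (max(lab2) > 0L) {
    overlap <- unique(lab2[lab2 > 0L & lab1 > 0L])
    lab2[lab2 %in% overlap] <- 0L
  }
  lab2 <- filter_labels_by_diameter(lab2, params)
  n1 <- max(lab1)
  lab <- lab1
  lab[lab2 > 0L] <- lab2[lab2 > 0L] + n1
  lab <- relabel_sequential(lab)
  stats <- label_stats(lab)
  # tier by provenance: ids <= number of pass-1 labels kept are "high"
  n_high <- length(setdiff(unique(as.integer(lab1)), 0L))
  tier <- ifelse(seq_along(stats$id) <= n_high, "high", "low")
  list(labels = lab, area = stats$area, centroid_y = stats$cy,
       centroid_x = stats$cx, tier = tier)
}

filter_labels_by_diameter <- function(lab, params) {
  if (max(lab) == 0L) return(lab)
  areas <- tabulate(lab[lab > 0L])
  eq_d <- 2 * sqrt(areas / pi)
  bad <- which(eq_d < params$min_diameter | eq_d > params$max_diameter)
  lab[lab %in% bad] <- 0L
  lab
}

relabel_sequential <- function(lab) {
  ids <- sort(setdiff(unique(as.integer(lab)), 0L))
  if (length(ids) == 0L) return(lab)
  map <- integer(max(ids)); map[ids] <- seq_along(ids)
  lab[lab > 0L] <- map[lab[lab > 0L]]
  lab
}

label_stats <- function(lab) {
  ids <- sort(setdiff(unique(as.integer(lab)), 0L))
  if (length(ids) == 0L)
    return(list(id = integer(), area = integer(), cy = numeric(),
                cx = numeric()))
  idx <- which(lab > 0L, arr.ind = TRUE)
  l <- lab[lab > 0L]
  area <- as.integer(table(factor(l, levels = ids)))
  cy <- tapply(idx[, 1] - 1L, factor(l, levels = ids), mean)
  cx <- tapply(idx[, 2] - 1L, factor(l, levels = ids), mean)
  list(id = ids, area = area, cy = as.numeric(cy), cx = as.numeric(cx))
}

#' Expand nuclei to cell borders
#'
#' Each nucleus is expanded by a distance budget that depends on its area:
#' 12 px (2 um) for areas below 2800 px^2, 32 px (5 um) for areas of
#' 2800 px^2 and above (ties take the larger budget). Contested pixels go
#' to the nearest nucleus; cell regions stay disjoint and contain their
#' nucleus.
#'
#' @param nuclei integer nucleus label matrix.
#' @param small_expand,large_expand expansion budgets in px.
#' @param area_cutoff nucleus area (px^2) switching the budget.
#' @return list with `labels` (cell label matrix) and `expansion`
#'   (named vector of budgets used per cell id).
#' @export
expand_cells <- function(nuclei, small_expand = 12, large_expand = 32,
                         area_cutoff = 2800) {
  n <- max(nuclei)
  if (n == 0L)
    return(list(labels = nuclei, expansion = numeric()))
  areas <- tabulate(nuclei[nuclei > 0L], nbins = n)
  budget <- ifelse(areas < area_cutoff, small_expand, large_expand)
  ft <- .edt_nearest(nuclei)
  cells <- ft$label
  cells[ft$dist > budget[pmax(ft$label, 1L)]] <- 0L
  cells[nuclei > 0L] <- nuclei[nuclei > 0L]
  list(labels = cells, expansion = stats::setNames(budget, seq_len(n)))
}
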