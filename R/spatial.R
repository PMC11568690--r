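# Tissue-mode spatial analyses: grid-binned region clustering of decoded
# signals (a Points2Regions-style procedure: bin, smooth, k-means) and
# hierarchical clustering of per-cell count profiles for heatmap display.

#' Cluster decoded signals into coarse spatial regions
#'
#' Bins accepted signals per marker onto a square grid, Gaussian-smooths
#' each marker layer, and k-means-clusters the per-grid-cell composition
#' vectors. Defaults for `pixel_size` and `smoothing` are 20 px, the
#' values used for the published tissue analysis.
#'
#' @param signals data.frame with `marker`, `x`, `y` (accepted signals).
#' @param pixel_size grid cell size in px.
#' @param smoothing Gaussian smoothing scale in px (sigma =
#'   `smoothing / pixel_size` grid units).
#' @param k number of regions.
#' @param seed RNG seed for k-means.
#' @return object of class `region_map`: list with `labels` (matrix of
#'   region ids, 0 = empty grid cell), `grid` (per-cell marker count
#'   matrix before smoothing), `pixel_size`, `smoothing`, `k`.
#' @export
points_to_regions <- function(signals, pixel_size = 20, smoothing = 20,
                              k = 2L, seed = 1L) {
  stopifnot(nrow(signals) > 0)
  markers <- sort(unique(signals$marker))
  gy <- floor(signals$y / pixel_size); gx <- floor(signals$x / pixel_size)
  nr <- max(gy) + 1L; nc <- max(gx) + 1L
  layers <- lapply(markers, function(m) {
    sel <- signals$marker == m
    mtx <- matrix(0, nr, nc)
    if (any(sel)) {
      tab <- table(factor(gy[sel], levels = 0:(nr - 1)),
                   factor(gx[sel], levels = 0:(nc - 1)))
      mtx <- mtx + unclass(tab)
    }
    mtx
  })
  raw <- layers
  sigma <- smoothing / pixel_size
  layers <- lapply(layers, gaussian_blur, sigma = sigma)
  nonempty <- which(Reduce(`+`, raw) > 0)
  if (length(nonempty) < k)
    stop("points_to_regions: only ", length(nonempty),
         " non-empty grid cells for k = ", k)
  feat <- vapply(layers, function(l) l[nonempty], numeric(length(nonempty)))
  feat <- matrix(feat, nrow = length(nonempty))
  set.seed(seed)
  km <- stats::kmeans(feat, centers = k, nstart = 10, iter.max = 100)
  lab <- matrix(0L, nr, nc)
  lab[nonempty] <- km$cluster
  structure(list(labels = lab,
                 grid = Reduce(`+`, raw),
                 markers = markers, pixel_size = pixel_size,
                 smoothing = smoothing, k = k),
            class = "region_map")
}

#' Hierarchically cluster per-cell profiles
#'
#' Subsamples at most `max_n` profiles (uniformly, seeded), then runs
#' agglomerative clustering (average linkage, Euclidean distance) on the
#' marker-count vectors. Returns the linkage and the leaf order used to
#' arrange heatmap rows.
#'
#' @param profiles data.frame of per-cell counts (numeric columns are the
#'   features; `cell_id`/`total` excluded).
#' @param max_n subsample ceiling (default 10000).
#' @param seed RNG seed for the subsample.
#' @return list with `hclust` (the `stats::hclust` object), `order`
#'   (leaf order), `ids` (row indices of the profiles clustered).
#' @export
cluster_cells <- function(profiles, max_n = 10000L, seed = 1L) {
  if (nrow(profiles) < 2L)
    stop("cluster_cells: need at least 2 profiles")
  num <- vapply(profiles, is.numeric, logical(1))
  feats <- setdiff(names(profiles)[num], c("cell_id", "total"))
  ids <- seq_len(nrow(profiles))
  if (nrow(profiles) > max_n) {
    set.seed(seed)
    ids <- sort(sample(ids, max_n))
  }
  X <- as.matrix(profiles[ids, feats, drop = FALSE])
  hc <- stats::hclust(stats::dist(X, method = "euclidean"),
                      method = "average")
  list(hclust = hc, order = hc$order, ids = ids)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b equal-length label vectors.
#' @return ARI in [-1, 1] (1 = identical partitions).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

#' Write a region map as label TIFF + per-grid-cell CSV
#' @param rm a `region_map`.
#' @param tiff_path,csv_path output paths.
#' @export
write_region_map <- function(rm, tiff_path, csv_path) {
  write_tiff(rm$labels, tiff_path, bits = 16L)
  idx <- which(rm$grid > 0, arr.ind = TRUE)
  utils::write.csv(data.frame(row = idx[, 1] - 1L, col = idx[, 2] - 1L,
                              region = rm$labels[idx],
                              n_signals = rm$grid[idx]),
                   csv_path, row.names = FALSE)
  invisible(NULL)
}
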