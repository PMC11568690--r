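# Dual-color decoding: per-code colocalization of channel spots, the three
# false-positive filters (single-channel, off-code, >4-channel unspecific),
# the two-level expression-based masking hierarchy, artifact/border
# masking, and assignment of accepted signals to cells.
#
# Statuses partition every candidate signal:
#   accepted                  colocalized pair matching a code
#   rejected_single_channel   spot with no partner in any code channel
#   rejected_off_code         colocalization group matching no code
#   unspecific_multichannel   group spanning > 4 channels
#   masked_by:<marker>        accepted call masked by a high-expression call
#   masked_autofluor          inside a multi-channel autofluorescent object
#   masked_border             inside a registration void

#' Colocalize spots of one dual-color code
#'
#' One-to-one greedy matching by ascending centroid distance between the
#' spots of the two code channels; ties broken by (y, x) of the first, then
#' second, spot.
#'
#' @param spots spot data.frame (see [detect_spots()]).
#' @param code character vector of the 2 code channels.
#' @param radius colocalization radius in px.
#' @return data.frame of pairs: `i`, `j` (row indices into `spots` for the
#'   two code channels in sorted order), `x`, `y` (pair midpoint), `dist`.
#' @export
colocalize_code <- function(spots, code, radius = 2.5) {
  if (radius <= 0) stop("colocalize_code: radius must be > 0")
  code <- sort(code)
  ia <- which(spots$channel == code[1])
  ib <- which(spots$channel == code[2])
  empty <- data.frame(i = integer(), j = integer(), x = numeric(),
                      y = numeric(), dist = numeric())
  if (length(ia) == 0L || length(ib) == 0L) return(empty)
  sub <- c(ia, ib)
  pr <- neighbor_pairs(spots$y[sub], spots$x[sub], radius)
  if (nrow(pr) == 0L) return(empty)
  gi <- sub[pr[, 1]]; gj <- sub[pr[, 2]]
  cross <- (gi %in% ia & gj %in% ib) | (gi %in% ib & gj %in% ia)
  gi2 <- ifelse(gi %in% ia, gi, gj)[cross]
  gj2 <- ifelse(gi %in% ia, gj, gi)[cross]
  if (length(gi2) == 0L) return(empty)
  dd <- sqrt((spots$y[gi2] - spots$y[gj2])^2 + (spots$x[gi2] - spots$x[gj2])^2)
  ord <- order(dd, spots$y[gi2], spots$x[gi2], spots$y[gj2], spots$x[gj2])
  used <- logical(nrow(spots))
  out_i <- integer(); out_j <- integer(); out_d <- numeric()
  for (k in ord) {
    if (used[gi2[k]] || used[gj2[k]]) next
    used[gi2[k]] <- TRUE; used[gj2[k]] <- TRUE
    out_i <- c(out_i, gi2[k]); out_j <- c(out_j, gj2[k])
    out_d <- c(out_d, dd[k])
  }
  data.frame(i = out_i, j = out_j,
             x = (spots$x[out_i] + spots$x[out_j]) / 2,
             y = (spots$y[out_i] + spots$y[out_j]) / 2,
             dist = out_d)
}

# all index pairs (i < j) with distance <= radius, via grid buckets so the
# cost stays near-linear in the number of points
neighbor_pairs <- function(y, x, radius) {
  n <- length(y)
  if (n < 2L) return(cbind(i = integer(), j = integer()))
  gy <- floor(y / radius); gx <- floor(x / radius)
  key <- paste(gy, gx)
  buckets <- split(seq_len(n), key)
  bk <- do.call(rbind, strsplit(names(buckets), " "))
  bgy <- as.numeric(bk[, 1]); bgx <- as.numeric(bk[, 2])
  bucket_of <- stats::setNames(seq_along(buckets), names(buckets))
  out_i <- integer(0); out_j <- integer(0)
  for (b in seq_along(buckets)) {
    pts <- buckets[[b]]
    # neighbours: this bucket and the 8 surrounding cells (dedup by order)
    nb <- pts
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      kk <- paste(bgy[b] + dy, bgx[b] + dx)
      ob <- bucket_of[kk]
      if (!is.na(ob)) nb <- c(nb, buckets[[ob]])
    }
    d2 <- outer(y[pts], y[nb], `-`)^2 + outer(x[pts], x[nb], `-`)^2
    hit <- which(d2 <= radius^2, arr.ind = TRUE)
    ii <- pts[hit[, 1]]; jj <- nb[hit[, 2]]
    sel <- ii < jj
    out_i <- c(out_i, ii[sel]); out_j <- c(out_j, jj[sel])
  }
  dup <- duplicated(paste(out_i, out_j))
  cbind(i = out_i[!dup], j = out_j[!dup])
}

# single-linkage colocalization groups: spots within `radius` of each other
# are chained into one group
coloc_groups <- function(spots, radius) {
  n <- nrow(spots)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  pr <- neighbor_pairs(spots$y, spots$x, radius)
  for (k in seq_len(nrow(pr))) {
    a <- find(pr[k, 1]); b <- find(pr[k, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(n), find, integer(1))
}

#' Decode spots into marker signals
#'
#' Runs [colocalize_code()] for every marker of the codebook, then applies
#' the three false-positive filters. Colocalization groups spanning more
#' than 4 channels are unspecific; groups whose channel span contains no
#' code are off-code; unpaired spots are single-channel rejections. Groups
#' spanning 3-4 channels that do contain codes are decoded per constituent
#' code (the masking hierarchy arbitrates afterwards).
#'
#' @param spots spot data.frame.
#' @param cb codebook.
#' @param radius colocalization radius in px (default 2.5, half the
#'   maximum post-shrink spot diameter).
#' @return data.frame of decoded signals: `marker`, `x`, `y`, `status`,
#'   `spot1`, `spot2` (row indices into `spots`, NA for group/singleton
#'   records), `cell` (NA until assignment).
#' @export
decode_signals <- function(spots, cb, radius = 2.5) {
  empty <- data.frame(marker = character(), x = numeric(), y = numeric(),
                      status = character(), spot1 = integer(),
                      spot2 = integer(), cell = integer())
  if (nrow(spots) == 0L) return(empty)
  grp <- coloc_groups(spots, radius)
  span <- tapply(spots$channel, grp, function(ch) sort(unique(ch)))
  grp_span_n <- vapply(span, length, integer(1))[as.character(grp)]
  unspecific_grp <- names(span)[vapply(span, length, integer(1)) > 4L]
  codes <- lapply(cb$markers, `[[`, "code")
  has_code <- vapply(span, function(s)
    any(vapply(codes, function(cd) all(cd %in% s), logical(1))), logical(1))
  off_grp <- names(span)[!has_code & vapply(span, length, integer(1)) >= 2L &
                           vapply(span, length, integer(1)) <= 4L]

  rows <- list()
  paired <- logical(nrow(spots))
  for (m in cb$markers) {
    pr <- colocalize_code(spots, m$code, radius)
    if (nrow(pr) == 0L) next
    ok <- !(as.character(grp[pr$i]) %in% unspecific_grp)
    paired[pr$i[ok]] <- TRUE; paired[pr$j[ok]] <- TRUE
    if (any(ok))
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m$name, x = pr$x[ok], y = pr$y[ok], status = "accepted",
        spot1 = pr$i[ok], spot2 = pr$j[ok], cell = NA_integer_)
    if (any(!ok))
      rows[[length(rows) + 1L]] <- data.frame(
        marker = m$name, x = pr$x[!ok], y = pr$y[!ok],
        status = "unspecific_multichannel",
        spot1 = pr$i[!ok], spot2 = pr$j[!ok], cell = NA_integer_)
  }
  # group-level rejections: one record per off-code group; leftover spots
  # (no pair, group not off-code/unspecific) are single-channel rejections
  for (g in off_grp) {
    members <- which(as.character(grp) == g & !paired)
    if (length(members) == 0L) next
    paired[members] <- TRUE
    rows[[length(rows) + 1L]] <- data.frame(
      marker = NA_character_, x = mean(spots$x[members]),
      y = mean(spots$y[members]), status = "rejected_off_code",
      spot1 = members[1], spot2 = NA_integer_, cell = NA_integer_)
  }
  lone <- which(!paired & !(as.character(grp) %in% unspecific_grp))
  if (length(lone))
    rows[[length(rows) + 1L]] <- data.frame(
      marker = NA_character_, x = spots$x[lone], y = spots$y[lone],
      status = "rejected_single_channel", spot1 = lone,
      spot2 = NA_integer_, cell = NA_integer_)
  # unpaired members of unspecific groups are unspecific too
  lone_u <- which(!paired & (as.character(grp) %in% unspecific_grp))
  if (length(lone_u))
    rows[[length(rows) + 1L]] <- data.frame(
      marker = NA_character_, x = spots$x[lone_u], y = spots$y[lone_u],
      status = "unspecific_multichannel", spot1 = lone_u,
      spot2 = NA_integer_, cell = NA_integer_)
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$y, out$x, out$marker, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply the expression-based masking hierarchy
#'
#' Level 1: accepted AR-FL within `radius` of an accepted VIM or KRT is
#' masked. Level 2: accepted EPCAM, PSMA, AR-V7, NE, SLFN11 or DLL3 within
#' `radius` of an accepted (or level-1-masked) VIM, KRT, AR-FL or PSA is
#' masked. A level-1-masked AR-FL still masks at level 2 because its spots
#' are physically real high-expression transcripts.
#'
#' @param signals decoded signal data.frame (from [decode_signals()]).
#' @param radius masking radius in px (same default as colocalization).
#' @return the data.frame with `status` updated to `masked_by:<marker>`
#'   where applicable. Idempotent.
#' @export
apply_masks <- function(signals, radius = 2.5) {
  if (nrow(signals) == 0L) return(signals)
  near_any <- function(targets, sources) {
    # for each target row index, the first source (by distance) within radius
    if (length(targets) == 0L || length(sources) == 0L)
      return(rep(NA_integer_, length(targets)))
    d2 <- outer(signals$y[targets], signals$y[sources], `-`)^2 +
      outer(signals$x[targets], signals$x[sources], `-`)^2
    hit <- d2 <= radius^2
    apply_idx <- apply(hit, 1L, function(h) if (any(h)) which(h)[1] else NA_integer_)
    sources[apply_idx]
  }
  is_masked_by <- startsWith(signals$status, "masked_by:")
  # level 1: VIM/KRT mask AR-FL
  src1 <- which(signals$status == "accepted" & signals$marker %in% c("VIM", "KRT"))
  tgt1 <- which(signals$status == "accepted" & signals$marker == "AR-FL")
  hit1 <- near_any(tgt1, src1)
  if (length(tgt1))
    signals$status[tgt1[!is.na(hit1)]] <-
      paste0("masked_by:", signals$marker[hit1[!is.na(hit1)]])
  # level 2: VIM/KRT/AR-FL/PSA mask the low-expression markers; AR-FL
  # masked at level 1 remains a mask source
  src2 <- which(signals$marker %in% c("VIM", "KRT", "AR-FL", "PSA") &
                  (signals$status == "accepted" |
                     startsWith(signals$status, "masked_by:")))
  tgt2 <- which(signals$status == "accepted" &
                  signals$marker %in% c("EPCAM", "PSMA", "AR-V7", "NE",
                                        "SLFN11", "DLL3"))
  hit2 <- near_any(tgt2, src2)
  if (length(tgt2))
    signals$status[tgt2[!is.na(hit2)]] <-
      paste0("masked_by:", signals$marker[hit2[!is.na(hit2)]])
  signals
}

#' Multi-channel autofluorescent object mask from two background channels
#'
#' Objects detectable in both background channels (Cy5 and TexasRed for
#' cell samples; Atto425 and Atto488 for tissue) are autofluorescent
#' artifacts; the returned mask is the intersection of the per-channel
#' adaptive-threshold masks, dilated by `margin`.
#'
#' @param bg_a,bg_b two background-scan channel matrices (same shape).
#' @param params [spot_params()] controlling the per-channel thresholds.
#' @param margin dilation radius in px (default 3).
#' @return logical matrix.
#' @export
autofluorescence_objects <- function(bg_a, bg_b, params = spot_params(),
                                     margin = 3) {
  if (!identical(dim(bg_a), dim(bg_b)))
    stop("autofluorescence_objects: images differ in shape")
  m <- adaptive_mask(bg_a, params$window, params$correction, params$lower_bound) &
    adaptive_mask(bg_b, params$window, params$correction, params$lower_bound)
  dilate_mask(m, margin)
}

#' Mask signals inside artifacts or registration voids
#'
#' @param signals decoded signal data.frame.
#' @param autofluor logical artifact mask (or NULL).
#' @param valid logical validity mask from registration (or NULL); signals
#'   on `FALSE` pixels become `masked_border`.
#' @return updated data.frame. Only `accepted` signals change status.
#' @export
mask_artifacts <- function(signals, autofluor = NULL, valid = NULL) {
  if (nrow(signals) == 0L) return(signals)
  acc <- which(signals$status == "accepted")
  if (length(acc) == 0L) return(signals)
  ri <- pmin(pmax(round(signals$y[acc]), 0), nrow(autofluor %||% valid) - 1L) + 1L
  ci <- pmin(pmax(round(signals$x[acc]), 0), ncol(autofluor %||% valid) - 1L) + 1L
  if (!is.null(valid)) {
    off <- !valid[cbind(ri, ci)]
    signals$status[acc[off]] <- "masked_border"
  }
  if (!is.null(autofluor)) {
    still <- signals$status[acc] == "accepted"
    af <- autofluor[cbind(ri, ci)] & still
    signals$status[acc[af]] <- "masked_autofluor"
  }
  signals
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign accepted signals to cells and tabulate per-cell counts
#'
#' @param signals decoded signal data.frame.
#' @param cells integer cell label matrix (see [expand_cells()]).
#' @param markers marker names defining the table columns (default: the
#'   markers present).
#' @return list with `signals` (cell column filled for accepted signals)
#'   and `counts`: one row per cell that received >= 1 signal or exists in
#'   `cells`, one column per marker plus `total`.
#' @export
assign_to_cells <- function(signals, cells,
                            markers = sort(unique(stats::na.omit(signals$marker)))) {
  n_cells <- max(cells)
  ids <- seq_len(n_cells)
  counts <- matrix(0L, nrow = n_cells, ncol = length(markers),
                   dimnames = list(NULL, markers))
  acc <- which(signals$status == "accepted")
  if (length(acc)) {
    ri <- pmin(pmax(round(signals$y[acc]), 0), nrow(cells) - 1L) + 1L
    ci <- pmin(pmax(round(signals$x[acc]), 0), ncol(cells) - 1L) + 1L
    cid <- cells[cbind(ri, ci)]
    signals$cell[acc] <- ifelse(cid > 0L, cid, NA_integer_)
    tab <- table(factor(signals$cell[acc], levels = ids),
                 factor(signals$marker[acc], levels = markers))
    counts <- counts + unclass(tab)
  }
  df <- data.frame(cell_id = ids, counts, check.names = FALSE)
  df$total <- as.integer(rowSums(counts))
  list(signals = signals, counts = df)
}
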