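# Pipeline orchestration: ROI detection on binned DAPI, global rigid
# pre-alignment with transform upscaling, per-ROI registration refinement,
# background subtraction, two-pass nucleus segmentation, area-conditional
# cell expansion, spot detection, dual-color decoding with masking, cell
# assignment, and optional classification. One code path serves both the
# cell mode (bin 8, background subtraction, Cy5/TexasRed artifact scans)
# and the tissue mode (bin 2, no subtraction, Atto425/Atto488 artifact
# scans) via configuration.

#' Build a pipeline configuration
#'
#' @param input fixture directory (see [write_fixture()]) or a list with
#'   `pair` (a `sample_pair`) for in-memory runs.
#' @param output output directory (created; NULL = no files written).
#' @param mode "cells" or "tissue".
#' @param bin_factor scanner bin factor (8 for cells, 2 for tissue).
#' @param codebook a codebook (default panel if NULL).
#' @param roi_margin ROI bounding-box padding at full resolution (px).
#' @param roi_correction,roi_lower_bound threshold tuning for ROI
#'   detection on the binned nuclear image (see [detect_rois()]).
#' @param nucleus [nucleus_params()] list.
#' @param spots [spot_params()] list (or named per-channel list).
#' @param coloc_radius colocalization/masking radius in px.
#' @param subtract_background logical; FALSE for tissue mode.
#' @param artifact_channels the two background channels defining
#'   multi-channel autofluorescent objects.
#' @param autofluor_margin dilation of the artifact mask in px.
#' @param classifier optional `coduco_forest` applied to per-cell counts.
#' @param seed seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, output = NULL, mode = c("cells", "tissue"),
                            bin_factor = NULL, codebook = NULL,
                            roi_margin = 40L,
                            roi_correction = 0.25, roi_lower_bound = 200,
                            nucleus = nucleus_params(lower_bound_high = 1000,
                                                     lower_bound_low = 250,
                                                     min_diameter = 24,
                                                     max_diameter = 140,
                                                     declump_min_distance = 30),
                            spots = spot_params(lower_bound = 150),
                            coloc_radius = 2.5,
                            subtract_background = NULL,
                            artifact_channels = NULL,
                            autofluor_margin = 3,
                            classifier = NULL, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(bin_factor)) bin_factor <- if (mode == "cells") 8L else 2L
  if (is.null(subtract_background)) subtract_background <- mode == "cells"
  if (is.null(artifact_channels))
    artifact_channels <- if (mode == "cells") c("Cy5", "TexasRed") else
      c("Atto425", "Atto488")
  if (is.null(codebook)) codebook <- build_default_panel()
  structure(list(input = input, output = output, mode = mode,
                 bin_factor = as.integer(bin_factor), codebook = codebook,
                 roi_margin = roi_margin,
                 roi_correction = roi_correction,
                 roi_lower_bound = roi_lower_bound,
                 nucleus = nucleus, spots = spots,
                 coloc_radius = coloc_radius,
                 subtract_background = subtract_background,
                 artifact_channels = artifact_channels,
                 autofluor_margin = autofluor_margin,
                 classifier = classifier, seed = as.integer(seed)),
            class = "pipeline_config")
}

crop <- function(img, b) img[(b[1] + 1L):b[3], (b[2] + 1L):b[4], drop = FALSE]

#' Run the full decoding pipeline
#'
#' @param config a [pipeline_config()].
#' @return list (the run manifest) with `counts` (per-cell count table
#'   over all ROIs), `signals` (decoded signals in global coordinates),
#'   `cells` (per-cell geometry: ROI, centroid, area, tier), `transform`
#'   (global rigid transform), `rois` (bounding boxes), `predicted`
#'   (classifier output or NULL) and `parameters`.
#' @export
run_pipeline <- function(config) {
  cb <- config$codebook
  fx <- if (is.character(config$input)) read_fixture(config$input) else
    config$input
  pair <- fx$pair
  required <- cb$channels
  for (scan in c("original", "background")) {
    missing <- setdiff(required, names(pair[[scan]]))
    if (length(missing))
      stop("run_pipeline: channel ", paste(missing, collapse = ", "),
           " missing from the ", scan, " scan")
  }
  nuc <- cb$nuclear
  # global pre-alignment on binned DAPI, upscaled to full resolution
  b_orig <- bin_image(pair$original[[nuc]], config$bin_factor)
  b_bg <- bin_image(pair$background[[nuc]], config$bin_factor)
  t_binned <- estimate_rigid(b_orig, b_bg)
  t_full <- scale_transform(t_binned, config$bin_factor)
  # ROI detection on the binned original DAPI
  rois <- detect_rois(b_orig, config$bin_factor, margin = config$roi_margin,
                      full_dim = dim(pair$original[[nuc]]),
                      correction = config$roi_correction,
                      lower_bound = config$roi_lower_bound)
  sig_ch <- setdiff(cb$channels, nuc)
  # apply the upscaled global transform to the whole background scan once;
  # each ROI then refines the small residual on its own crop
  bg_warp <- lapply(pair$background[required], function(im)
    apply_rigid(im, t_full))
  all_signals <- NULL; all_counts <- NULL; all_cells <- NULL
  cell_offset <- 0L
  for (ri in seq_along(rois)) {
    roi <- rois[[ri]]
    b <- roi$bounds
    orig_crop <- lapply(pair$original[required], crop, b = b)
    bg_crop <- lapply(bg_warp, function(w) crop(w$image, b))
    valid0 <- crop(bg_warp[[nuc]]$valid, b)
    t_ref <- tryCatch(
      estimate_rigid(orig_crop[[nuc]], bg_crop[[nuc]],
                     max_shift = 5, max_theta = 1, theta_step = 0.5),
      error = function(e) rigid_transform(0, 0, 0))
    roi_pair <- sample_pair(orig_crop, bg_crop, nuclear = nuc)
    if (config$subtract_background) {
      sb <- subtract_background(roi_pair, t_ref)
      channels <- sb$channels
      valid <- sb$valid & apply_rigid(valid0 * 1, t_ref)$image > 0.5
    } else {
      channels <- orig_crop
      valid <- matrix(TRUE, nrow(orig_crop[[nuc]]), ncol(orig_crop[[nuc]]))
    }
    bg_reg <- lapply(bg_crop[config$artifact_channels], function(im)
      apply_rigid(im, t_ref)$image)
    # nuclei: DAPI restricted to this ROI's own mask
    dapi_roi <- orig_crop[[nuc]]
    dapi_roi[!roi$roi_mask] <- 0
    seg <- segment_nuclei(dapi_roi, config$nucleus)
    if (max(seg$labels) == 0L) next
    cellmap <- expand_cells(seg$labels)
    spots <- detect_spots_all(channels, cb, config$spots)
    signals <- decode_signals(spots, cb, config$coloc_radius)
    signals <- apply_masks(signals, config$coloc_radius)
    af <- autofluorescence_objects(bg_reg[[1]], bg_reg[[2]],
                                   if (is.null(names(config$spots)) ||
                                       !is.list(config$spots[[1]]))
                                     config$spots else config$spots[[1]],
                                   margin = config$autofluor_margin)
    signals <- mask_artifacts(signals, autofluor = af, valid = valid)
    asg <- assign_to_cells(signals, cellmap$labels, markers = marker_names(cb))
    signals <- asg$signals; counts <- asg$counts
    # lift to global coordinates / ids
    if (nrow(signals)) {
      signals$x <- signals$x + b[2]; signals$y <- signals$y + b[1]
      signals$cell <- signals$cell + cell_offset
      signals$roi <- ri
    }
    if (nrow(counts)) {
      counts$cell_id <- counts$cell_id + cell_offset
      counts$roi <- ri
    }
    cells <- data.frame(cell_id = seq_along(seg$area) + cell_offset,
                        roi = ri,
                        y = seg$centroid_y + b[1], x = seg$centroid_x + b[2],
                        nucleus_area = seg$area, tier = seg$tier,
                        expansion = as.numeric(cellmap$expansion))
    cell_offset <- cell_offset + max(cellmap$labels)
    if (nrow(signals)) all_signals <- rbind(all_signals, signals)
    if (nrow(counts)) all_counts <- rbind(all_counts, counts)
    all_cells <- rbind(all_cells, cells)
  }
  predicted <- NULL
  if (!is.null(config$classifier) && !is.null(all_counts))
    predicted <- predict(config$classifier, all_counts)
  manifest <- list(counts = all_counts, signals = all_signals,
                   cells = all_cells, transform = t_full,
                   rois = lapply(rois, `[[`, "bounds"),
                   predicted = predicted,
                   parameters = config[setdiff(names(config),
                                               c("classifier", "input"))])
  if (!is.null(config$output)) {
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(all_counts))
      utils::write.csv(all_counts, file.path(config$output, "cell_counts.csv"),
                       row.names = FALSE)
    if (!is.null(all_signals))
      utils::write.csv(all_signals, file.path(config$output,
                                              "decoded_signals.csv"),
                       row.names = FALSE)
    if (!is.null(all_cells))
      utils::write.csv(all_cells, file.path(config$output, "cells.csv"),
                       row.names = FALSE)
    write_transform(t_full, file.path(config$output, "transform.json"))
    if (!is.null(predicted))
      utils::write.csv(data.frame(cell_id = all_counts$cell_id,
                                  predicted = as.character(predicted)),
                       file.path(config$output, "predicted.csv"),
                       row.names = FALSE)
    log <- list(package_version = as.character(utils::packageVersion("coduco")),
                r_version = R.version.string, seed = config$seed,
                mode = config$mode, bin_factor = config$bin_factor,
                coloc_radius = config$coloc_radius,
                n_rois = length(rois),
                n_cells = if (is.null(all_cells)) 0L else nrow(all_cells))
    jsonlite::write_json(log, file.path(config$output, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  manifest
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write a synthetic fixture), `decode` (run the
#' pipeline on a fixture), `evaluate` (compare predicted vs truth CSVs).
#' Invoke from Rscript, e.g.
#' `Rscript -e 'coduco::coduco_cli()' simulate --out fix --seed 1`.
#'
#' @param args character vector (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
coduco_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: coduco_cli <simulate|decode|evaluate> [options]",
    "  simulate --out DIR [--seed N]",
    "  decode   --in DIR --out DIR [--mode cells|tissue] [--seed N]",
    "  evaluate --pred CSV --truth CSV [--positive CLASS]", sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  opt <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i) == 0L) return(default)
    args[i[1] + 1L]
  }
  cmd <- args[1]
  if (cmd == "simulate") {
    out <- opt("--out"); if (is.null(out)) stop("simulate: --out required")
    seed <- as.integer(opt("--seed", "1"))
    sim <- simulate_sample(sim_config(seed = seed))
    manifest <- write_fixture(sim, out)
    message("wrote ", length(manifest), " files under ", out)
  } else if (cmd == "decode") {
    ind <- opt("--in"); if (is.null(ind)) stop("decode: --in required")
    out <- opt("--out"); if (is.null(out)) stop("decode: --out required")
    cfg <- pipeline_config(ind, out, mode = opt("--mode", "cells"),
                           seed = as.integer(opt("--seed", "1")))
    mf <- run_pipeline(cfg)
    message("decoded ", if (is.null(mf$counts)) 0L else nrow(mf$counts),
            " cells across ", length(mf$rois), " ROIs -> ", out)
  } else if (cmd == "evaluate") {
    pred <- utils::read.csv(opt("--pred"))
    truth <- utils::read.csv(opt("--truth"))
    rep <- evaluate(pred[[ncol(pred)]], truth[[ncol(truth)]],
                    positive_class = opt("--positive", "CTC"))
    print(rep)
  } else {
    message(usage); return(invisible(1L))
  }
  invisible(0L)
}
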