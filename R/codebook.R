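# Dual-color combinatorial codebook: six signal channels plus a nuclear
# channel; every marker is identified by an unordered pair of signal
# channels. One channel (TexasRed) is restricted to a single partner (Cy3)
# because Cy5 emission bleeds into the TexasRed detection band: any
# TexasRed code other than {TexasRed, Cy3} would risk mis-decoding bright
# Cy5-containing signals.

#' Canonical channel names
#'
#' The nuclear stain plus the six signal fluorophores, in canonical order.
#' Internal keys are always these strings; configuration files may alias
#' but aliases are resolved at the boundary.
#' @export
CODUCO_CHANNELS <- c("DAPI", "Atto425", "Atto488", "Cy3", "TexasRed",
                     "Cy5", "AF750")

#' Signal channels (canonical order)
#' @export
SIGNAL_CHANNELS <- setdiff(CODUCO_CHANNELS, "DAPI")

#' @rdname CODUCO_CHANNELS
#' @export
NUCLEAR_CHANNEL <- "DAPI"

canon_code <- function(pair) sort(as.character(pair))

code_key <- function(pair) paste(canon_code(pair), collapse = "+")

#' Enumerate all size-k channel combinations
#'
#' With six signal channels and a two-color code there are choose(6, 2) =
#' 15 distinct combinations, the assay's theoretical multiplexing capacity.
#'
#' @param channels character vector of signal-channel names.
#' @param k code size (the assay uses k = 2).
#' @return list of sorted character vectors, one per code.
#' @export
enumerate_codes <- function(channels = SIGNAL_CHANNELS, k = 2L) {
  channels <- unique(as.character(channels))
  k <- as.integer(k)
  if (k < 1L || k > length(channels))
    stop("enumerate_codes: k must be in [1, ", length(channels), "], got ", k)
  cmb <- utils::combn(sort(channels), k, simplify = FALSE)
  lapply(cmb, canon_code)
}

#' Restrict a channel to a single partner
#'
#' Removes every code containing `channel` except `{channel, partner}`.
#' Applying (TexasRed, Cy3) to the 15 two-color codes leaves 11.
#'
#' @param codes list of codes (character vectors).
#' @param channel the restricted channel.
#' @param partner the only channel it may pair with.
#' @return filtered list of codes.
#' @export
restrict_channel <- function(codes, channel, partner) {
  if (identical(channel, partner))
    stop("restrict_channel: partner must differ from channel")
  allowed <- code_key(c(channel, partner))
  keep <- vapply(codes, function(cd) {
    !(channel %in% cd) || code_key(cd) == allowed
  }, logical(1))
  codes[keep]
}

#' Build the default 11-marker panel
#'
#' Markers, pooled genes and color codes of the prostate-cancer CTC panel:
#' pooled hematopoietic markers (hem), VIM, pooled keratins (KRT), EPCAM,
#' PSA, PSMA, AR-FL, AR-V7, pooled neuroendocrine markers (NE), SLFN11 and
#' DLL3, with the TexasRed -> Cy3 restriction.
#'
#' @return object of class `coduco_codebook`: list with `channels`,
#'   `markers` (each with `name`, `genes`, `code`) and `restrictions`.
#' @export
build_default_panel <- function() {
  marker <- function(name, genes, code)
    list(name = name, genes = genes, code = canon_code(code))
  markers <- list(
    marker("hem", c("PTPRC", "ITGAM", "FCGR3A", "FCGR3B", "CD4", "ITGB2"),
           c("TexasRed", "Cy3")),
    marker("VIM", "VIM", c("Atto488", "Cy3")),
    marker("KRT", c("KRT8", "KRT18", "KRT19"), c("Atto425", "Cy5")),
    marker("EPCAM", "EPCAM", c("Atto488", "AF750")),
    marker("PSA", "KLK3", c("Atto425", "AF750")),
    marker("PSMA", "FOLH1", c("Cy3", "Cy5")),
    marker("AR-FL", "AR-FL", c("Atto488", "Cy5")),
    marker("AR-V7", "AR-V7", c("Cy3", "AF750")),
    marker("NE", c("SYP", "CHGA", "NCAM1"), c("Cy5", "AF750")),
    marker("SLFN11", "SLFN11", c("Atto425", "Atto488")),
    marker("DLL3", "DLL3", c("Atto425", "Cy3"))
  )
  cb <- structure(list(
    channels = CODUCO_CHANNELS,
    nuclear = NUCLEAR_CHANNEL,
    markers = markers,
    restrictions = list(c(channel = "TexasRed", partner = "Cy3"))
  ), class = "coduco_codebook")
  cb
}

#' Marker names of a codebook
#' @param cb a `coduco_codebook`.
#' @return character vector.
#' @export
marker_names <- function(cb) vapply(cb$markers, `[[`, character(1), "name")

#' Look up the code of a marker
#' @param cb a `coduco_codebook`.
#' @param name marker name.
#' @return sorted 2-element character vector.
#' @export
marker_code <- function(cb, name) {
  i <- match(name, marker_names(cb))
  if (is.na(i)) stop("unknown marker: ", name)
  cb$markers[[i]]$code
}

#' Validate a codebook
#'
#' Violations are returned as data, not thrown: duplicate codes, unknown
#' channels, empty gene lists and restriction breaches are each one entry.
#'
#' @param cb a `coduco_codebook`.
#' @return character vector of violation descriptions (empty if valid).
#' @export
validate_codebook <- function(cb) {
  v <- character()
  sig <- setdiff(cb$channels, cb$nuclear)
  keys <- vapply(cb$markers, function(m) code_key(m$code), character(1))
  dup <- keys[duplicated(keys)]
  for (d in unique(dup))
    v <- c(v, paste0("code ", d, " assigned to more than one marker"))
  for (m in cb$markers) {
    if (length(m$genes) == 0L)
      v <- c(v, paste0("marker ", m$name, " has no genes"))
    if (length(m$code) != 2L || anyDuplicated(m$code))
      v <- c(v, paste0("marker ", m$name, " code is not 2 distinct channels"))
    bad <- setdiff(m$code, sig)
    if (length(bad))
      v <- c(v, paste0("marker ", m$name, " uses unknown channel ",
                       paste(bad, collapse = ", ")))
    for (rs in cb$restrictions) {
      if (rs[["channel"]] %in% m$code &&
          code_key(m$code) != code_key(c(rs[["channel"]], rs[["partner"]])))
        v <- c(v, paste0("marker ", m$name, " violates restriction ",
                         rs[["channel"]], " -> ", rs[["partner"]]))
    }
  }
  nm <- marker_names(cb)
  if (anyDuplicated(nm))
    v <- c(v, paste0("duplicate marker name ", nm[duplicated(nm)][1]))
  v
}

#' Serialize / deserialize a codebook as JSON
#' @param cb a `coduco_codebook`.
#' @param path file path.
#' @return `read_codebook` returns a `coduco_codebook`; `write_codebook`
#'   returns `path` invisibly.
#' @export
write_codebook <- function(cb, path) {
  x <- unclass(cb)
  x$restrictions <- lapply(x$restrictions, as.list)  # keep JSON keys
  jsonlite::write_json(x, path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  markers <- lapply(x$markers, function(m)
    list(name = m$name[[1]], genes = unlist(m$genes),
         code = canon_code(unlist(m$code))))
  restrictions <- lapply(x$restrictions, function(r) {
    r <- unlist(r)
    if (is.null(names(r)) || !all(c("channel", "partner") %in% names(r)))
      names(r) <- c("channel", "partner")
    r
  })
  structure(list(channels = unlist(x$channels), nuclear = unlist(x$nuclear),
                 markers = markers, restrictions = restrictions),
            class = "coduco_codebook")
}

#' @export
print.coduco_codebook <- function(x, ...) {
  cat("CoDuCo codebook:", length(x$markers), "markers,",
      length(setdiff(x$channels, x$nuclear)), "signal channels\n")
  for (m in x$markers)
    cat(sprintf("  %-7s {%s}  [%s]\n", m$name, paste(m$code, collapse = ", "),
                paste(m$genes, collapse = ", ")))
  invisible(x)
}
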