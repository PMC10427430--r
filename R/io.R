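# Sidecar path convention: <image>.json next to the image file.
sidecar_path <- function(path) paste0(path, ".json")

read_sidecar <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop(sprintf("missing sidecar '%s' describing '%s'", sc, basename(path)))
  jsonlite::read_json(sc, simplifyVector = TRUE)
}

write_sidecar <- function(path, meta) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Read and write mosaic frames, maps and stacks
#'
#' Images travel as TIFF with a JSON sidecar (`<file>.tif` + `<file>.tif.json`)
#' carrying bit depth, layout and kind, so a file round trip is lossless for
#' integer mosaics and within float32 representation for maps and stacks.
#' Rendered overlays are written as PNG.
#'
#' @param path file path (`.tif`; the sidecar name is derived from it).
#' @param frame,map,stack,img object to write.
#' @return readers return the reconstructed object; writers return the path
#'   invisibly.
#' @name endopol_io
NULL

#' @rdname endopol_io
#' @export
write_mosaic <- function(path, frame) {
  bitdepth <- attr(frame, "bitdepth")
  layout <- attr(frame, "layout")
  bits <- if (bitdepth <= 8) 8L else 16L
  tiff::writeTIFF(unclass(frame) / (2^bits - 1), path,
                  bits.per.sample = bits)
  write_sidecar(path, list(type = "mosaic", bitdepth = bitdepth,
                           storage_bits = bits,
                           layout = attr(layout, "angles_deg"),
                           phase = attr(layout, "phase"),
                           mode = attr(frame, "mode")))
  invisible(path)
}

#' @rdname endopol_io
#' @export
read_mosaic <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "mosaic")) stop("sidecar does not describe a mosaic")
  x <- tiff::readTIFF(path)
  counts <- round(x * (2^meta$storage_bits - 1))
  structure(counts, class = c("mosaic_frame", "matrix", "array"),
            bitdepth = as.integer(meta$bitdepth),
            layout = dofp_layout(meta$layout, meta$phase),
            mode = meta$mode)
}

# float32 multi-page TIFF helper.  TIFF float storage is only defined on
# [0, 1], so pages are stored affinely rescaled; the range goes into the
# sidecar and read_float_pages() inverts it.
write_float_pages <- function(path, pages) {
  lo <- min(vapply(pages, min, 0)); hi <- max(vapply(pages, max, 0))
  if (hi <= lo) hi <- lo + 1
  tiff::writeTIFF(lapply(pages, function(p) (p - lo) / (hi - lo)),
                  path, bits.per.sample = 32L, reduce = FALSE)
  c(lo, hi)
}

read_float_pages <- function(path, range = c(0, 1)) {
  x <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(x)) x <- list(x)
  lapply(x, function(p) range[1] + p * (range[2] - range[1]))
}

#' @rdname endopol_io
#' @export
write_map <- function(path, map) {
  rg <- write_float_pages(path, list(map$values, map$valid * 1))
  write_sidecar(path, list(type = "parameter_map", kind = map$kind,
                           pages = c("values", "valid"), range = rg))
  invisible(path)
}

#' @rdname endopol_io
#' @export
read_map <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "parameter_map"))
    stop("sidecar does not describe a parameter map")
  pg <- read_float_pages(path, meta$range)
  parameter_map(pg[[1]], pg[[2]] > 0.5, meta$kind)
}

#' @rdname endopol_io
#' @export
write_stack <- function(path, stack) {
  d <- dim(stack)
  pages <- lapply(seq_len(d[3]), function(p) stack[, , p])
  rg <- write_float_pages(path, pages)
  write_sidecar(path, list(type = "intensity_stack", pages = d[3],
                           page_order = "analyser-fastest ((k-1)*6 + j)",
                           range = rg))
  invisible(path)
}

#' @rdname endopol_io
#' @export
read_stack <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "intensity_stack"))
    stop("sidecar does not describe an intensity stack")
  pg <- read_float_pages(path, meta$range)
  out <- array(0, c(dim(pg[[1]]), length(pg)))
  for (p in seq_along(pg)) out[, , p] <- pg[[p]]
  structure(out, class = "intensity_stack")
}

#' @rdname endopol_io
#' @export
write_mueller_image <- function(path, img) {
  pages <- list()
  for (r in 1:4) for (cc in 1:4) {
    pages[[length(pages) + 1L]] <- img$M[, , r, cc]
  }
  rg <- write_float_pages(path, pages)
  write_sidecar(path, list(type = "mueller_image",
                           page_order = "row-major m00..m33", range = rg))
  invisible(path)
}

#' @rdname endopol_io
#' @export
read_mueller_image <- function(path) {
  meta <- read_sidecar(path)
  if (!identical(meta$type, "mueller_image"))
    stop("sidecar does not describe a Mueller image")
  pg <- read_float_pages(path, meta$range)
  H <- nrow(pg[[1]]); W <- ncol(pg[[1]])
  M <- array(0, c(H, W, 4, 4))
  p <- 0L
  for (r in 1:4) for (cc in 1:4) {
    p <- p + 1L
    M[, , r, cc] <- pg[[p]]
  }
  mueller_image(M)
}

#' @rdname endopol_io
#' @export
write_render <- function(path, img) {
  png::writePNG(img, path)
  invisible(path)
}
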