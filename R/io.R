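#' Write a multichannel stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are ordered channel-major (all z of channel 1, then channel 2,
#' ...); the sidecar (`<path>.json`) records the channel order, slice
#' count, bit depth and voxel size so the stack can be reassembled.
#'
#' @param stack A [channel_stack()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$voxels)
  ord <- names(sort(stack$channel_map))
  pages <- list()
  for (ch in ord) {
    v <- stack$voxels[, , , stack$channel_map[[ch]], drop = TRUE]
    dim(v) <- c(d[1], d[2], d[3])
    for (z in seq_len(d[3]))
      pages[[length(pages) + 1L]] <- v[, , z] / 65535
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  meta <- list(channels = ord, n_z = d[3], bit_depth = stack$bit_depth,
               pixel_size = stack$pixel_size, z_step = stack$z_step,
               page_order = "channel_major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a stack written by [write_stack_tiff()]
#'
#' @param path TIFF path (the `<path>.json` sidecar must exist).
#' @return A [channel_stack()].
#' @export
read_stack_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- meta$n_z
  nch <- length(meta$channels)
  stopifnot(length(pages) == nz * nch)
  d <- dim(pages[[1]])
  vox <- array(0, dim = c(d[1], d[2], nz, nch))
  k <- 0L
  for (ch in seq_len(nch)) {
    for (z in seq_len(nz)) {
      k <- k + 1L
      vox[, , z, ch] <- round(pages[[k]] * 65535)
    }
  }
  channel_stack(vox, stats::setNames(seq_len(nch), meta$channels),
                meta$bit_depth, meta$pixel_size, meta$z_step)
}

#' Write an RGB section as PNG
#'
#' @param section An [rgb_section()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_section_png <- function(section, path) {
  stopifnot(inherits(section, "rgb_section"))
  png::writePNG(section$pixels / 255, path)
  invisible(path)
}

#' Read an RGB section from PNG or TIFF
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @param pixel_size um per pixel to attach.
#' @return An [rgb_section()].
#' @export
read_section <- function(path, pixel_size) {
  px <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else {
    tiff::readTIFF(path)
  }
  if (length(dim(px)) == 3 && dim(px)[3] >= 3) px <- px[, , 1:3]
  rgb_section(round(px * 255), pixel_size, provenance = path)
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member gene ids, tab-separated.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Read a genes x samples count table (TSV/CSV)
#'
#' First column = gene ids; remaining columns = integer counts per sample.
#'
#' @param path File path; the delimiter is inferred from the extension.
#' @return Integer matrix with gene-id rownames.
#' @export
read_counts_table <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Read an ROI polygon from JSON
#'
#' Expects `{"coordinates": [[row, col], ...]}` in pixel coordinates.
#'
#' @param path JSON path.
#' @return A 2-column matrix of vertices.
#' @export
read_roi_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- obj$coordinates
  stopifnot(is.matrix(m) || is.data.frame(m))
  as.matrix(m)
}
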