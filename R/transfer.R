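#' Soma mask from a marker channel
#'
#' Floods the soma interior with a large averaging (box mean) filter, then
#' thresholds. The default threshold is Otsu's, computed on the filtered
#' intensities of the whole input with a noise-floor guard
#' (`median + 6 * mad`) so that a channel containing no signal yields an
#' empty mask rather than thresholding inside the noise distribution.
#'
#' @param channel 2-D matrix or 3-D array (`H x W x Z`) of a 12-bit channel.
#' @param filter_size Side of the square averaging kernel in pixels; the
#'   default 31 px spans roughly one soma diameter at 0.4 um/pixel.
#' @param threshold Fixed threshold overriding the automatic one.
#' @return Logical mask with the same dimensions as `channel`.
#' @export
soma_mask <- function(channel, filter_size = 31L, threshold = NULL) {
  is3d <- length(dim(channel)) == 3
  k <- matrix(1 / filter_size^2, filter_size, filter_size)
  filt <- function(m) EBImage::filter2(m, k, boundary = "replicate")
  if (is3d) {
    f <- channel
    for (z in seq_len(dim(channel)[3])) f[, , z] <- filt(channel[, , z])
  } else {
    f <- filt(channel)
  }
  if (max(f) == 0) return(array(FALSE, dim(channel)))
  if (is.null(threshold)) {
    thr <- otsu_split(as.numeric(f))
    floor_thr <- stats::median(f) + 6 * stats::mad(as.numeric(f))
    threshold <- max(thr, floor_thr, na.rm = TRUE)
  }
  f > threshold
}

#' Threshold mask for a single channel
#'
#' Pixels strictly above the threshold. The threshold must lie inside the
#' representable range of the channel's bit depth.
#'
#' @param channel Numeric matrix or array.
#' @param threshold Intensity threshold.
#' @param bit_depth Bit depth defining the valid range `[0, 2^bit_depth - 1]`.
#' @return Logical mask, same dimensions as `channel`.
#' @export
channel_mask <- function(channel, threshold, bit_depth = 12L) {
  if (threshold < 0 || threshold > 2^bit_depth - 1)
    stop("threshold outside the channel range [0, ", 2^bit_depth - 1, "]")
  channel > threshold
}

#' Composite positivity mask
#'
#' Logical AND of the cell-body, marker and alpha-synuclein masks: the
#' "white pixels" where the marker and synuclein channels exceed their
#' thresholds inside the cell body.
#'
#' @param body_mask,marker_mask,syn_mask Logical masks of identical shape.
#' @return Logical mask.
#' @export
composite_positive <- function(body_mask, marker_mask, syn_mask) {
  if (!identical(dim(body_mask), dim(marker_mask)) ||
      !identical(dim(body_mask), dim(syn_mask)))
    stop("mask shape mismatch")
  body_mask & marker_mask & syn_mask
}

# Otsu with noise-floor guard on a numeric vector (12-bit scale)
guarded_otsu <- function(v) {
  thr <- otsu_split(v)
  floor_thr <- stats::median(v) + 6 * stats::mad(v)
  max(thr, floor_thr, na.rm = TRUE)
}

#' Classify cells of one marker in a confocal stack
#'
#' Identifies somata of the requested marker from the mean-filtered maximum
#' projection of the marker channel, then scores every cell per z-slice: a
#' cell is called alpha-synuclein-positive when, in at least one slice, a
#' 4-connected component of the composite mask (body AND marker AND syn)
#' inside the cell reaches `min_punctum_px` pixels.
#'
#' @param stack A [channel_stack()].
#' @param marker `"TH"` (neurons) or `"Iba1"` (microglia).
#' @param marker_channels Named map from marker to channel name; by default
#'   TH is imaged in the red channel and Iba-1 in the green channel. The
#'   synuclein channel is named by `syn_channel`.
#' @param syn_channel Channel carrying the human alpha-synuclein signal.
#' @param min_punctum_px Minimum contiguous composite pixel count in a
#'   single slice for a positive call (default 4; single-pixel positives
#'   would be noise-dominated).
#' @param min_soma_px Minimum projected soma area (pixels) for a region to
#'   count as a cell.
#' @param filter_size Averaging-filter side for [soma_mask()] (pixels);
#'   roughly one soma diameter.
#' @param split_touching Split merged somata by a distance-map watershed
#'   (default `TRUE`).
#' @param thresholds Optional list with fixed `marker` and `syn` thresholds;
#'   by default each channel gets a guarded Otsu threshold.
#' @param animal_id,group Annotations copied into the output rows.
#' @return A `cell_call_table` data frame: `cell_id`, `marker`, `positive`,
#'   `positive_pixels`, `max_punctum_px`, `centroid_x`, `centroid_y`,
#'   `animal_id`, `group`.
#' @export
classify_cells <- function(stack, marker = c("TH", "Iba1"),
                           marker_channels = c(TH = "red", Iba1 = "green"),
                           syn_channel = "syn", min_punctum_px = 4L,
                           min_soma_px = 120L, filter_size = 31L,
                           split_touching = TRUE, thresholds = NULL,
                           animal_id = NA_character_, group = NA_character_) {
  marker <- match.arg(marker)
  stopifnot(inherits(stack, "channel_stack"))
  mk_name <- marker_channels[[marker]]
  mk <- get_channel(stack, mk_name)     # errors if missing
  syn <- get_channel(stack, syn_channel)
  if (length(dim(mk)) == 2) {
    dim(mk) <- c(dim(mk), 1L)
    dim(syn) <- c(dim(syn), 1L)
  }
  nz <- dim(mk)[3]

  # cell identity from the max projection of the marker channel
  proj <- apply(mk, c(1, 2), max)
  body2d <- soma_mask(proj, filter_size = filter_size)
  cells <- if (split_touching && any(body2d)) {
    matrix(as.integer(EBImage::watershed(EBImage::distmap(body2d + 0),
                                         tolerance = 1)),
           nrow(body2d), ncol(body2d))
  } else {
    EBImage::bwlabel(body2d)
  }
  ncell <- max(cells)
  if (ncell > 0) {
    keep <- tabulate(cells[cells > 0], nbins = ncell) >= min_soma_px
    pos <- which(cells > 0)
    cells[pos[!keep[cells[pos]]]] <- 0L
    cells <- matrix(as.integer(factor(cells, levels = c(0, which(keep)))) - 1L,
                    nrow(cells), ncol(cells))
    ncell <- max(cells)
  }
  empty <- data.frame(cell_id = integer(0), marker = character(0),
                      positive = logical(0), positive_pixels = integer(0),
                      max_punctum_px = integer(0), centroid_x = numeric(0),
                      centroid_y = numeric(0), animal_id = character(0),
                      group = character(0), stringsAsFactors = FALSE)
  if (ncell == 0) return(structure(empty, class = c("cell_call_table",
                                                    "data.frame")))

  thr_mk <- if (!is.null(thresholds$marker)) thresholds$marker else
    guarded_otsu(as.numeric(mk))
  thr_syn <- if (!is.null(thresholds$syn)) thresholds$syn else
    guarded_otsu(as.numeric(syn))

  pos_px <- integer(ncell)
  max_comp <- integer(ncell)
  for (z in seq_len(nz)) {
    comp <- composite_positive(cells > 0,
                               channel_mask(mk[, , z], thr_mk),
                               channel_mask(syn[, , z], thr_syn))
    if (!any(comp)) next
    clab <- EBImage::bwlabel(comp)
    nc <- max(clab)
    sizes <- tabulate(clab[clab > 0], nbins = nc)
    # assign each composite component to the cell that owns its pixels
    idx <- which(clab > 0)
    owner <- cells[idx]
    compid <- clab[idx]
    per <- tapply(owner, compid, function(o) o[1])
    for (ci in seq_len(nc)) {
      cell <- per[[as.character(ci)]]
      if (is.na(cell) || cell == 0) next
      pos_px[cell] <- pos_px[cell] + sizes[ci]
      max_comp[cell] <- max(max_comp[cell], sizes[ci])
    }
  }
  idx <- which(cells > 0, arr.ind = TRUE)
  lab <- cells[cells > 0]
  out <- data.frame(
    cell_id = seq_len(ncell), marker = marker,
    positive = max_comp >= min_punctum_px,
    positive_pixels = pos_px, max_punctum_px = max_comp,
    centroid_x = as.numeric(tapply(idx[, 1], lab, mean)),
    centroid_y = as.numeric(tapply(idx[, 2], lab, mean)),
    animal_id = animal_id, group = group, stringsAsFactors = FALSE)
  structure(out, class = c("cell_call_table", "data.frame"))
}

#' Classify a single-cell stack
#'
#' Convenience wrapper for stacks imaged around one cell of interest: runs
#' [classify_cells()] and returns the row of the largest detected soma.
#'
#' @inheritParams classify_cells
#' @param ... Passed to [classify_cells()].
#' @return A one-row `cell_call_table` (zero rows if no soma was found).
#' @export
classify_cell <- function(stack, marker = c("TH", "Iba1"), ...) {
  tab <- classify_cells(stack, marker, ...)
  if (nrow(tab) <= 1) return(tab)
  # keep the cell with the largest projected soma: approximate by the one
  # closest to the frame centre, the imaging convention for single cells
  d <- dim(stack$voxels)
  dist2 <- (tab$centroid_x - d[1] / 2)^2 + (tab$centroid_y - d[2] / 2)^2
  tab[which.min(dist2), , drop = FALSE]
}

#' Percent of cells positive for transferred alpha-synuclein
#'
#' Per-animal percentage `100 * n_positive / n_cells`, then a per-group
#' summary (mean +/- SEM over animals). Rows with missing `animal_id` are
#' pooled as a single unit.
#'
#' @param table A `cell_call_table` (rows from [classify_cells()]).
#' @param marker Optional marker filter (`"TH"` or `"Iba1"`).
#' @return A list with data frames `per_animal` (`animal_id`, `group`,
#'   `n_cells`, `n_positive`, `percent_positive`) and `per_group`
#'   (`group`, `n_animals`, `mean_percent`, `sem`).
#' @export
percent_positive <- function(table, marker = NULL) {
  df <- as.data.frame(table)
  if (!is.null(marker)) df <- df[df$marker == marker, , drop = FALSE]
  if (nrow(df) == 0) stop("zero cells; cannot compute a percentage")
  df$animal_id[is.na(df$animal_id)] <- "(pooled)"
  key <- interaction(df$animal_id, df$group, drop = TRUE)
  per_animal <- do.call(rbind, lapply(levels(key), function(k) {
    sub <- df[key == k, , drop = FALSE]
    data.frame(animal_id = sub$animal_id[1], group = sub$group[1],
               n_cells = nrow(sub), n_positive = sum(sub$positive),
               percent_positive = 100 * sum(sub$positive) / nrow(sub),
               stringsAsFactors = FALSE)
  }))
  groups <- unique(per_animal$group)
  per_group <- do.call(rbind, lapply(groups, function(g) {
    v <- per_animal$percent_positive[per_animal$group %in% g]
    data.frame(group = g, n_animals = length(v), mean_percent = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(per_animal = per_animal, per_group = per_group)
}
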