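#' Saturation channel of an RGB section
#'
#' HSV saturation `(max - min) / max` per pixel, scaled to 0-255 (0 where
#' the pixel is black). DAB-brown stain has high saturation against the
#' near-neutral bright-field background, which the segmentation exploits.
#'
#' @param section An [rgb_section()] or `H x W x 3` array (0-255).
#' @return A numeric matrix in 0-255.
#' @export
saturation_channel <- function(section) {
  px <- if (inherits(section, "rgb_section")) section$pixels else section
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  s <- ifelse(mx > 0, (mx - mn) / mx, 0)
  s * 255
}

#' Dynamic FWHM intensity band
#'
#' Fits a single Gaussian to the 256-bin intensity histogram of the supplied
#' pixels (nonlinear least squares) and returns the band
#' `[peak - FWHM/2, peak + FWHM/2]`, where FWHM is the full width at half
#' maximum of the fitted curve (`2.3548 * sigma` for a Gaussian). When the
#' fit fails, the half-maximum crossings of the smoothed raw histogram are
#' used instead. Band end points are clamped to the observed intensity range.
#'
#' @param x Numeric matrix or vector of pixel intensities.
#' @param bins Number of histogram bins.
#' @param channel Optional label stored on the result (e.g. `"blue"`,
#'   `"saturation"`).
#' @return A `threshold_pair`: list with `low`, `high`, `channel`, `method`.
#' @export
dynamic_threshold <- function(x, bins = 256L, channel = NA_character_) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("no finite pixel values")
  rng <- range(v)
  if (diff(rng) == 0)
    stop("degenerate histogram: constant image, no dynamic threshold exists")
  breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
  h <- graphics::hist(v, breaks = breaks, plot = FALSE)
  xs <- h$mids
  ys <- h$counts
  mu0 <- xs[which.max(ys)]
  sd0 <- max(stats::sd(v) / 2, diff(rng) / bins)
  fit <- tryCatch(
    stats::nls(ys ~ A * exp(-(xs - mu)^2 / (2 * s^2)),
               start = list(A = max(ys), mu = mu0, s = sd0),
               algorithm = "port",
               lower = list(A = 0, mu = rng[1], s = diff(rng) / (2 * bins)),
               upper = list(A = Inf, mu = rng[2], s = diff(rng)),
               control = stats::nls.control(warnOnly = TRUE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    fwhm <- 2 * sqrt(2 * log(2)) * cf[["s"]]
    low <- cf[["mu"]] - fwhm / 2
    high <- cf[["mu"]] + fwhm / 2
    method <- "gaussian_fit"
  } else {
    # fallback: half-max crossings of the smoothed histogram
    k <- 5L
    ysm <- stats::filter(ys, rep(1 / k, k), sides = 2)
    ysm[is.na(ysm)] <- ys[is.na(ysm)]
    pk <- which.max(ysm)
    half <- ysm[pk] / 2
    li <- pk
    while (li > 1 && ysm[li] > half) li <- li - 1L
    ri <- pk
    while (ri < length(ysm) && ysm[ri] > half) ri <- ri + 1L
    low <- xs[li]
    high <- xs[ri]
    method <- "halfmax_crossing"
  }
  low <- max(low, rng[1])
  high <- min(high, rng[2])
  structure(list(low = low, high = high, channel = channel, method = method),
            class = "threshold_pair")
}

# labeled_regions constructor from an integer label matrix
label_regions <- function(labels) {
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  ids <- sort(setdiff(unique(as.vector(labels)), 0L))
  # relabel to consecutive positive integers
  if (length(ids) > 0 && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids))
    remap[ids] <- seq_along(ids)
    pos <- labels > 0L
    labels[pos] <- remap[labels[pos]]
    ids <- seq_along(ids)
  }
  H <- nrow(labels)
  W <- ncol(labels)
  if (length(ids) == 0) {
    regions <- data.frame(region_id = integer(0), area = integer(0),
                          centroid_x = numeric(0), centroid_y = numeric(0),
                          touches_border = logical(0))
  } else {
    idx <- which(labels > 0L, arr.ind = TRUE)
    lab <- labels[labels > 0L]
    area <- tabulate(lab, nbins = length(ids))
    cx <- tapply(idx[, 1], lab, mean)
    cy <- tapply(idx[, 2], lab, mean)
    border <- idx[, 1] == 1L | idx[, 1] == H | idx[, 2] == 1L | idx[, 2] == W
    tb <- tapply(border, lab, any)
    regions <- data.frame(region_id = ids, area = area,
                          centroid_x = as.numeric(cx),
                          centroid_y = as.numeric(cy),
                          touches_border = as.logical(tb))
  }
  structure(list(labels = labels, regions = regions,
                 n_regions = length(ids)),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("labeled_regions: %d region(s) on a %d x %d label image\n",
              x$n_regions, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

# internal: Otsu threshold on arbitrary-range data
otsu_split <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(NA_real_)
  EBImage::otsu(matrix((v - rng[1]) / diff(rng), nrow = 1L), levels = 256L) *
    diff(rng) + rng[1]
}

# band mask for one channel: Gaussian FWHM band fit to the stain-side
# sub-histogram of an Otsu split (stain is dark in blue, bright in saturation)
stain_band_mask <- function(channel_img, stain_side = c("low", "high"),
                            label = NA_character_) {
  stain_side <- match.arg(stain_side)
  thr <- otsu_split(as.numeric(channel_img))
  if (is.na(thr)) return(matrix(FALSE, nrow(channel_img), ncol(channel_img)))
  sel <- if (stain_side == "low") channel_img < thr else channel_img > thr
  if (sum(sel) < 50) return(matrix(FALSE, nrow(channel_img), ncol(channel_img)))
  vals <- channel_img[sel]
  if (diff(range(vals)) == 0) {
    # noise-free stain: the band collapses to the single stain intensity
    band <- list(low = vals[1], high = vals[1])
  } else {
    band <- tryCatch(dynamic_threshold(vals, channel = label),
                     error = function(e) NULL)
    if (is.null(band)) return(matrix(FALSE, nrow(channel_img), ncol(channel_img)))
  }
  channel_img >= band$low & channel_img <= band$high
}

# drop small and border-touching components, given a binary mask
filter_components <- function(mask, area_min_px) {
  lab <- EBImage::bwlabel(mask)
  nlab <- max(lab)
  if (nlab == 0) return(mask & FALSE)
  keep <- tabulate(lab[lab > 0], nbins = nlab) >= area_min_px
  border_ids <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep[border_ids[border_ids > 0]] <- FALSE
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  pos <- lab > 0
  out[pos] <- keep[lab[pos]]
  out
}

#' Segment cell bodies in a DAB-stained RGB section
#'
#' Builds dynamic FWHM band masks for the blue-intensity and saturation
#' channels (each fit to the stain mode of its histogram), combines them with
#' a logical OR, labels connected components, removes components smaller than
#' `area_min_px` (default 2000 px, tied to 60x acquisition) and components
#' touching the image border, and finally erodes the survivors so the
#' regions conform to cell bodies.
#'
#' @param section An [rgb_section()].
#' @param area_min_px Minimum component area in pixels.
#' @param erode_radius Radius (pixels) of the disc structuring element used
#'   for the final erosion; 0 disables it.
#' @return A `labeled_regions` object (possibly with zero regions).
#' @export
segment_cell_bodies <- function(section, area_min_px = 2000L,
                                erode_radius = 2L) {
  stopifnot(inherits(section, "rgb_section"))
  blue <- section$pixels[, , 3]
  sat <- saturation_channel(section)
  mask <- stain_band_mask(blue, "low", "blue") |
    stain_band_mask(sat, "high", "saturation")
  # an FWHM band admits ~76% of a Gaussian mode, leaving salt-noise holes
  # inside stained areas; fill enclosed holes before labeling
  mask <- EBImage::fillHull(mask + 0) > 0
  mask <- filter_components(mask, area_min_px)
  if (erode_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(erode_radius) + 1L, "disc")
    mask <- EBImage::erode(mask + 0, brush) > 0
    # erosion severs thin stained processes from the soma; discard the
    # resulting fragments (anything far below the body scale)
    lab <- EBImage::bwlabel(mask)
    nlab <- max(lab)
    if (nlab > 0) {
      keep <- tabulate(lab[lab > 0], nbins = nlab) >= area_min_px / 4
      pos <- which(lab > 0)
      mask[pos[!keep[lab[pos]]]] <- FALSE
    }
  }
  label_regions(EBImage::bwlabel(mask))
}

#' Segment thin cellular processes and merge them with cell bodies
#'
#' Saturation-channel ridge segmentation for thin processes: Gaussian blur,
#' squaring, convolution with an edge-detection kernel, retention of
#' responses within 20% of the maximum (`>= keep_frac * max`), the same
#' small-object and border filtering as the body segmentation, outlining of
#' the resulting regions, subtraction of the body pixels, dilation, and a
#' union with the body mask.
#'
#' @param section An [rgb_section()].
#' @param bodies `labeled_regions` from [segment_cell_bodies()] on the same
#'   image.
#' @param blur_sigma Gaussian blur sigma in pixels.
#' @param keep_frac Fraction of the maximum response retained (default 0.8,
#'   i.e. within 20% of maximum).
#' @param max_quantile Quantile of the response used as the "maximum"
#'   reference. The strict maximum (`max_quantile = 1`) is dominated by
#'   isolated curvature spikes at junctions, so a robust maximum (default
#'   the 0.99 quantile) is used; set to 1 for the literal rule.
#' @param area_min_px Minimum component area (pixels) for the ridge regions.
#' @param dilate_radius Radius of the disc used to dilate the processes.
#' @param kernel Edge-detection kernel; default is a 3x3 Laplacian (negated
#'   so that bright ridges give positive responses).
#' @return A logical matrix: the combined body + process mask.
#' @export
segment_processes <- function(section, bodies, blur_sigma = 2,
                              keep_frac = 0.8, max_quantile = 0.99,
                              area_min_px = 2000L, dilate_radius = 2L,
                              kernel = matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0),
                                              3, 3)) {
  stopifnot(inherits(section, "rgb_section"), inherits(bodies, "labeled_regions"))
  body_mask <- bodies$labels > 0L
  sat <- saturation_channel(section) / 255
  g <- EBImage::gblur(sat, sigma = blur_sigma)
  resp <- EBImage::filter2(g^2, kernel)
  mx <- if (max_quantile >= 1) max(resp) else
    stats::quantile(resp, max_quantile, names = FALSE)
  if (mx <= 0) return(body_mask)
  ridge <- resp >= keep_frac * mx
  ridge <- filter_components(ridge, area_min_px)
  if (!any(ridge)) return(body_mask)
  # outline: reduce regions to single-pixel boundary lines
  outline <- ridge & !(EBImage::erode(ridge + 0, EBImage::makeBrush(3L, "box")) > 0)
  processes <- outline & !body_mask
  if (any(processes) && dilate_radius > 0) {
    brush <- EBImage::makeBrush(2L * as.integer(dilate_radius) + 1L, "disc")
    processes <- EBImage::dilate(processes + 0, brush) > 0
  }
  body_mask | processes
}

#' Area, perimeter and hydraulic radius of segmented regions
#'
#' The hydraulic radius is the area:perimeter ratio of a segmented cell; it
#' is used as a microglial activation index (amoeboid cells have large area
#' and small perimeter, hence a high index; ramified cells a low one).
#'
#' @param x A binary matrix (single region) or a `labeled_regions` object.
#' @param pixel_size Optional um/pixel; adds micrometre-scale columns.
#' @param estimator Perimeter estimator, see [region_perimeter()].
#' @return A data frame with one row per region: `cell_id`, `area_px`,
#'   `perimeter_px`, `hydraulic_radius_px` and, when `pixel_size` is given,
#'   `area_um2`, `perimeter_um`, `hydraulic_radius_um`.
#' @export
hydraulic_radius <- function(x, pixel_size = NULL,
                             estimator = c("contour", "crofton", "pixel")) {
  estimator <- match.arg(estimator)
  if (inherits(x, "labeled_regions")) {
    if (x$n_regions == 0) stop("no regions to measure")
    rows <- lapply(x$regions$region_id, function(id) {
      m <- x$labels == id
      data.frame(cell_id = id, area_px = sum(m),
                 perimeter_px = region_perimeter(m, estimator))
    })
    out <- do.call(rbind, rows)
  } else {
    m <- x > 0
    if (!any(m)) stop("empty region")
    out <- data.frame(cell_id = 1L, area_px = sum(m),
                      perimeter_px = region_perimeter(m, estimator))
  }
  out$hydraulic_radius_px <- out$area_px / out$perimeter_px
  if (!is.null(pixel_size)) {
    stopifnot(pixel_size > 0)
    out$area_um2 <- out$area_px * pixel_size^2
    out$perimeter_um <- out$perimeter_px * pixel_size
    out$hydraulic_radius_um <- out$area_um2 / out$perimeter_um
  }
  out
}

#' Select segmented regions for quantification
#'
#' In `"auto"` mode applies documented proxies for the manual criteria
#' (in focus, completely segmented, fully contained in the slice): regions
#' must not touch the border and must fall within `area_range`. In
#' `"manual"` mode replays a recorded choice table, making interactive
#' selections reproducible.
#'
#' @param regions A `labeled_regions` object.
#' @param mode `"auto"` or `"manual"`.
#' @param area_range Acceptable region area (pixels) in auto mode.
#' @param choices Data frame with columns `region_id` and `selected`
#'   (manual mode).
#' @return The `regions` data frame with a logical `selected` column.
#' @export
select_cells <- function(regions, mode = c("auto", "manual"),
                         area_range = c(2000, Inf), choices = NULL) {
  stopifnot(inherits(regions, "labeled_regions"))
  if (length(mode) != 1 || !mode %in% c("auto", "manual"))
    stop("unknown selection mode: ", paste(mode, collapse = "/"))
  df <- regions$regions
  if (mode == "auto") {
    df$selected <- !df$touches_border &
      df$area >= area_range[1] & df$area <= area_range[2]
  } else {
    if (is.null(choices) || !all(c("region_id", "selected") %in% names(choices)))
      stop("manual mode requires a choices table (region_id, selected)")
    df$selected <- df$region_id %in% choices$region_id[choices$selected]
    df$selected[df$touches_border] <- FALSE  # border rule always applies
  }
  df
}

#' Iba-1-positive cell density inside a region of interest
#'
#' Counts segmented cell centroids that fall inside an ROI polygon and
#' reports the density per square millimetre.
#'
#' @param regions A `labeled_regions` object or a 2-column matrix of
#'   centroids (row, column in pixels).
#' @param roi 2-column matrix of polygon vertices (row, column in pixels).
#' @param pixel_size um per pixel.
#' @return A list: `n_cells`, `roi_area_mm2`, `density_cells_per_mm2`.
#' @export
iba1_density <- function(regions, roi, pixel_size) {
  stopifnot(is.matrix(roi), ncol(roi) == 2, pixel_size > 0)
  area_px <- polygon_area(roi)
  if (area_px <= 0) stop("zero-area ROI")
  cent <- if (inherits(regions, "labeled_regions")) {
    cbind(regions$regions$centroid_x, regions$regions$centroid_y)
  } else {
    regions
  }
  n <- if (nrow(cent) == 0) 0L else
    sum(points_in_polygon(cent[, 1], cent[, 2], roi))
  area_mm2 <- area_px * pixel_size^2 / 1e6
  list(n_cells = n, roi_area_mm2 = area_mm2,
       density_cells_per_mm2 = n / area_mm2)
}

#' Group summary of the activation index
#'
#' Averages the hydraulic radius per animal first, then summarizes each
#' group as mean +/- SEM over its animals. A group with one animal reports
#' `NA` SEM (undefined, not zero).
#'
#' @param records Data frame with columns `animal_id`, `group` and
#'   `hydraulic_radius` (any scale).
#' @return A data frame: `group`, `n_animals`, `mean_index`, `sem`.
#' @export
activation_index_summary <- function(records) {
  stopifnot(all(c("animal_id", "group", "hydraulic_radius") %in% names(records)))
  if (nrow(records) == 0) stop("empty records")
  per_animal <- stats::aggregate(hydraulic_radius ~ animal_id + group,
                                 data = records, FUN = mean)
  groups <- unique(as.character(per_animal$group))
  out <- lapply(groups, function(g) {
    v <- per_animal$hydraulic_radius[per_animal$group == g]
    if (length(v) == 0) stop("empty group: ", g)
    data.frame(group = g, n_animals = length(v), mean_index = mean(v),
               sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
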