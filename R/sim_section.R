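#' Configuration for the synthetic stained-section generator
#'
#' Describes a bright-field RGB image of a DAB-stained section containing
#' ramified (soma plus thin branches) and amoeboid (compact blob) cells on a
#' light background. Per-cell ground-truth area and perimeter are measured on
#' the noise-free binary render of each cell.
#'
#' @param seed Integer seed.
#' @param width,height Image size in pixels.
#' @param n_ramified,n_amoeboid Cell counts per shape class.
#' @param soma_radius_range Soma radius range (pixels) for ramified cells.
#' @param amoeboid_radius_scale Amoeboid blob radii are drawn from
#'   `soma_radius_range * amoeboid_radius_scale`.
#' @param branch_count_range,branch_length_range Branch geometry (pixels).
#' @param branch_width Branch thickness in pixels (must be >= 1).
#' @param stain_color DAB-brown RGB triple (0-255); the default reproduces
#'   the low blue intensity and high saturation the segmentation exploits.
#' @param background_color Background RGB triple (0-255).
#' @param noise_sd Additive Gaussian noise sd per 8-bit channel.
#' @param pixel_size um per pixel.
#' @param overlap_allowed If `FALSE` (default), cells are placed so that
#'   their bounding discs do not overlap and do not touch the border.
#' @return An object of class `section_sim_config`.
#' @export
section_sim_config <- function(seed = 1L, width = 1024L, height = 1024L,
                               n_ramified = 8L, n_amoeboid = 8L,
                               soma_radius_range = c(28, 36),
                               amoeboid_radius_scale = 1.4,
                               branch_count_range = c(4L, 7L),
                               branch_length_range = c(60, 130),
                               branch_width = 3,
                               stain_color = c(120, 80, 40),
                               background_color = c(235, 230, 225),
                               noise_sd = 5, pixel_size = 0.11,
                               overlap_allowed = FALSE) {
  if (branch_width < 1) stop("branch_width must be at least 1 pixel")
  stopifnot(width >= 32, height >= 32, n_ramified >= 0, n_amoeboid >= 0,
            length(stain_color) == 3, length(background_color) == 3,
            soma_radius_range[1] > 0, diff(soma_radius_range) >= 0,
            pixel_size > 0, noise_sd >= 0)
  structure(list(seed = as.integer(seed), width = as.integer(width),
                 height = as.integer(height), n_ramified = as.integer(n_ramified),
                 n_amoeboid = as.integer(n_amoeboid),
                 soma_radius_range = soma_radius_range,
                 amoeboid_radius_scale = amoeboid_radius_scale,
                 branch_count_range = as.integer(branch_count_range),
                 branch_length_range = branch_length_range,
                 branch_width = branch_width, stain_color = stain_color,
                 background_color = background_color, noise_sd = noise_sd,
                 pixel_size = pixel_size, overlap_allowed = overlap_allowed),
            class = "section_sim_config")
}

#' RGB section container
#'
#' @param pixels Numeric array `height x width x 3`, 8-bit values (0-255).
#' @param pixel_size um per pixel (> 0).
#' @param provenance Free-text origin string.
#' @return An object of class `rgb_section`.
#' @export
rgb_section <- function(pixels, pixel_size, provenance = "") {
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] == 3, pixel_size > 0)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 provenance = provenance),
            class = "rgb_section")
}

#' @export
print.rgb_section <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("rgb_section: %d x %d px at %.3f um/px (%s)\n",
              d[1], d[2], x$pixel_size, x$provenance))
  invisible(x)
}

# binary render of one cell on the full canvas
render_cell_mask <- function(cfg, shape_class, cx, cy, radius) {
  H <- cfg$height
  W <- cfg$width
  if (shape_class == "amoeboid") {
    # compact blob: a disc (activated microglia retract their processes)
    mask <- rasterize_disc(H, W, cx, cy, radius)
  } else {
    mask <- rasterize_disc(H, W, cx, cy, radius)
    n_br <- sample(seq(cfg$branch_count_range[1], cfg$branch_count_range[2]), 1)
    base_ang <- stats::runif(1, 0, 2 * pi)
    for (b in seq_len(n_br)) {
      ang <- base_ang + 2 * pi * b / n_br + stats::rnorm(1, sd = 0.25)
      len <- stats::runif(1, cfg$branch_length_range[1], cfg$branch_length_range[2])
      x0 <- cx + (radius - 1) * cos(ang)
      y0 <- cy + (radius - 1) * sin(ang)
      x1 <- cx + (radius + len) * cos(ang)
      y1 <- cy + (radius + len) * sin(ang)
      mask <- mask | rasterize_segment(H, W, x0, y0, x1, y1, cfg$branch_width)
      # one secondary branchlet halfway along
      ang2 <- ang + sample(c(-1, 1), 1) * stats::runif(1, 0.5, 1.1)
      xm <- (x0 + x1) / 2
      ym <- (y0 + y1) / 2
      len2 <- len * stats::runif(1, 0.3, 0.5)
      mask <- mask | rasterize_segment(H, W, xm, ym, xm + len2 * cos(ang2),
                                       ym + len2 * sin(ang2), cfg$branch_width)
    }
  }
  mask
}

#' Simulate a DAB-stained bright-field section with ground truth
#'
#' Renders non-overlapping ramified and amoeboid cells in DAB brown on a
#' light background and records, for every cell, the true area and perimeter
#' measured on its noise-free binary render (default perimeter estimator,
#' see [region_perimeter()]).
#'
#' @param cfg A [section_sim_config()].
#' @return A list with `section` (an [rgb_section()]), `truth` (data frame:
#'   `cell_id`, `shape_class`, `x`, `y`, `true_area`, `true_perimeter`,
#'   `true_hydraulic_radius`) and `label_mask` (integer matrix of cell ids).
#' @export
make_section_image <- function(cfg) {
  stopifnot(inherits(cfg, "section_sim_config"))
  set.seed(cfg$seed)
  H <- cfg$height
  W <- cfg$width
  n <- cfg$n_ramified + cfg$n_amoeboid
  shape_class <- c(rep("ramified", cfg$n_ramified),
                   rep("amoeboid", cfg$n_amoeboid))
  # bounding radius per cell for overlap-free placement
  radius <- stats::runif(n, cfg$soma_radius_range[1], cfg$soma_radius_range[2])
  radius[shape_class == "amoeboid"] <- radius[shape_class == "amoeboid"] *
    cfg$amoeboid_radius_scale
  reach <- ifelse(shape_class == "ramified",
                  radius + cfg$branch_length_range[2] + cfg$branch_width,
                  radius * 1.5 + 2)
  centers <- matrix(NA_real_, n, 2)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 2000L * max(n, 1L))
      stop("could not place ", n, " non-overlapping cells; enlarge the image")
    i <- placed + 1L
    m <- reach[i] + 2
    if (2 * m >= min(H, W)) stop("image too small for the requested cells")
    cx <- stats::runif(1, m, H - m)
    cy <- stats::runif(1, m, W - m)
    if (!cfg$overlap_allowed && placed > 0) {
      d <- sqrt((centers[seq_len(placed), 1] - cx)^2 +
                  (centers[seq_len(placed), 2] - cy)^2)
      if (any(d < reach[seq_len(placed)] + reach[i])) next
    }
    placed <- i
    centers[i, ] <- c(cx, cy)
  }

  label_mask <- matrix(0L, H, W)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    mask <- render_cell_mask(cfg, shape_class[i], centers[i, 1], centers[i, 2],
                             radius[i])
    if (!cfg$overlap_allowed) mask <- mask & label_mask == 0L
    label_mask[mask] <- i
    truth[[i]] <- data.frame(
      cell_id = i, shape_class = shape_class[i],
      x = centers[i, 1], y = centers[i, 2],
      true_area = sum(mask),
      true_perimeter = region_perimeter(mask),
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth)
  if (n > 0)
    truth$true_hydraulic_radius <- truth$true_area / truth$true_perimeter

  px <- array(0, dim = c(H, W, 3))
  fg <- label_mask > 0L
  for (ch in 1:3) {
    plane <- matrix(cfg$background_color[ch], H, W)
    plane[fg] <- cfg$stain_color[ch]
    if (cfg$noise_sd > 0)
      plane <- plane + stats::rnorm(H * W, sd = cfg$noise_sd)
    px[, , ch] <- round(pmin(pmax(plane, 0), 255))
  }
  section <- rgb_section(px, cfg$pixel_size, provenance = "synthetic")
  list(section = section, truth = truth, label_mask = label_mask)
}
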