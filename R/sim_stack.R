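#' Configuration for the synthetic confocal stack generator
#'
#' Defines the acquisition geometry and ground-truth layout of a simulated
#' 4-channel confocal z-stack (DAPI / green / red / alpha-synuclein). Defaults
#' mirror the acquisition used for per-cell transfer scoring: 1024 x 1024
#' frames, 0.2 um z-steps over a ~15 um stack, 12-bit channels.
#'
#' @param seed Integer seed; the generator is a pure function of the config.
#' @param width,height Frame size in pixels.
#' @param n_z Number of z slices (default 75, i.e. 15 um at 0.2 um steps).
#' @param z_step z increment in um.
#' @param pixel_size Lateral pixel size in um/pixel.
#' @param n_cells Number of somata to plant.
#' @param marker_mix Fraction of cells carrying the TH (neuron) marker; the
#'   remainder carry Iba-1 (microglia). TH is rendered in the red channel and
#'   Iba-1 in the green channel by default.
#' @param frac_positive Fraction of cells planted with intracellular
#'   alpha-synuclein puncta, in `[0, 1]`. The positive count is
#'   `floor(n_cells * frac_positive + 0.5)`, assigned without replacement.
#' @param puncta_per_cell Number of puncta per positive cell.
#' @param punctum_radius Punctum radius in pixels.
#' @param soma_radius Soma radius in pixels.
#' @param psf_sigma Lateral Gaussian PSF sigma in pixels; the axial sigma is
#'   `psf_sigma * pixel_size / z_step` slices. 0 disables blurring.
#' @param poisson_scale Photon-scaling for Poisson noise: the observed value
#'   is `rpois(value * scale) / scale`. 0 disables Poisson noise.
#' @param gaussian_sd Additive read-noise standard deviation. 0 disables it.
#' @param bit_depth Bit depth of the stored channels (default 12).
#' @return An object of class `stack_sim_config`.
#' @export
stack_sim_config <- function(seed = 1L, width = 1024L, height = 1024L,
                             n_z = 75L, z_step = 0.2, pixel_size = 0.4,
                             n_cells = 10L, marker_mix = 0.5,
                             frac_positive = 0.5, puncta_per_cell = 4L,
                             punctum_radius = 3L, soma_radius = 15L,
                             psf_sigma = 2, poisson_scale = 0.25,
                             gaussian_sd = 20, bit_depth = 12L) {
  cfg <- list(seed = as.integer(seed), width = as.integer(width),
              height = as.integer(height), n_z = as.integer(n_z),
              z_step = z_step, pixel_size = pixel_size,
              n_cells = as.integer(n_cells), marker_mix = marker_mix,
              frac_positive = frac_positive,
              puncta_per_cell = as.integer(puncta_per_cell),
              punctum_radius = as.integer(punctum_radius),
              soma_radius = as.integer(soma_radius),
              psf_sigma = psf_sigma, poisson_scale = poisson_scale,
              gaussian_sd = gaussian_sd, bit_depth = as.integer(bit_depth))
  if (cfg$width < 8 || cfg$height < 8 || cfg$n_z < 1)
    stop("non-positive or degenerate stack dimensions")
  if (cfg$frac_positive < 0 || cfg$frac_positive > 1)
    stop("frac_positive must lie in [0, 1]")
  if (cfg$marker_mix < 0 || cfg$marker_mix > 1)
    stop("marker_mix must lie in [0, 1]")
  if (cfg$n_cells == 0 && cfg$frac_positive > 0)
    stop("frac_positive > 0 requires at least one cell")
  if (cfg$z_step <= 0 || cfg$pixel_size <= 0)
    stop("z_step and pixel_size must be positive")
  if (cfg$punctum_radius >= cfg$soma_radius)
    stop("punctum_radius must be smaller than soma_radius")
  class(cfg) <- "stack_sim_config"
  cfg
}

#' Multichannel confocal stack container
#'
#' @param voxels Numeric array `height x width x n_z x n_channels`.
#' @param channel_map Named integer vector mapping channel names
#'   (`dapi`, `green`, `red`, `syn`) to the 4th array index.
#' @param bit_depth Bit depth (values must be `< 2^bit_depth`).
#' @param pixel_size Lateral pixel size, um/pixel.
#' @param z_step Axial step, um.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(voxels, channel_map, bit_depth = 12L,
                          pixel_size = 0.4, z_step = 0.2) {
  stopifnot(length(dim(voxels)) == 4, is.numeric(voxels))
  if (is.null(names(channel_map)) || any(!channel_map %in% seq_len(dim(voxels)[4])))
    stop("channel_map must name valid channel indices")
  if (max(voxels) > 2^bit_depth - 1 || min(voxels) < 0)
    stop("voxel values outside the bit-depth range")
  structure(list(voxels = voxels, channel_map = channel_map,
                 bit_depth = as.integer(bit_depth), pixel_size = pixel_size,
                 z_step = z_step),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("channel_stack: %d x %d px, %d slices, channels [%s], %d-bit\n",
              d[1], d[2], d[3], paste(names(x$channel_map), collapse = ", "),
              x$bit_depth))
  invisible(x)
}

#' Extract a named channel from a stack
#'
#' @param stack A [channel_stack()].
#' @param name Channel name present in `stack$channel_map`.
#' @return A `height x width x n_z` array.
#' @export
get_channel <- function(stack, name) {
  if (!name %in% names(stack$channel_map))
    stop("missing channel: ", name)
  stack$voxels[, , , stack$channel_map[[name]], drop = TRUE]
}

# voxel coordinates (row, col, z) of a solid ellipsoid, clipped to dims
ball_voxels <- function(cx, cy, cz, r_xy, r_z, dims) {
  zmin <- max(1L, as.integer(ceiling(cz - r_z)))
  zmax <- min(dims[3], as.integer(floor(cz + r_z)))
  if (zmin > zmax) return(matrix(integer(0), 0, 3))
  out <- vector("list", zmax - zmin + 1L)
  for (z in zmin:zmax) {
    frac <- 1 - ((z - cz) / r_z)^2
    if (frac <= 0) next
    rz <- r_xy * sqrt(frac)
    rmin <- max(1L, as.integer(ceiling(cx - rz)))
    rmax <- min(dims[1], as.integer(floor(cx + rz)))
    cmin <- max(1L, as.integer(ceiling(cy - rz)))
    cmax <- min(dims[2], as.integer(floor(cy + rz)))
    if (rmin > rmax || cmin > cmax) next
    dx2 <- (rmin:rmax - cx)^2
    dy2 <- (cmin:cmax - cy)^2
    hit <- which(outer(dx2, dy2, "+") <= rz^2, arr.ind = TRUE)
    if (nrow(hit) == 0) next
    out[[z - zmin + 1L]] <- cbind(hit[, 1] + rmin - 1L, hit[, 2] + cmin - 1L,
                                  rep.int(z, nrow(hit)))
  }
  do.call(rbind, out[!vapply(out, is.null, logical(1))])
}

# Gaussian blur in 3-D: separable per-slice lateral blur plus axial
# convolution with sigma scaled by the voxel anisotropy.
blur_stack_channel <- function(vol, sigma_xy, sigma_z) {
  if (sigma_xy > 0) {
    for (z in seq_len(dim(vol)[3]))
      vol[, , z] <- EBImage::gblur(vol[, , z], sigma = sigma_xy)
  }
  if (sigma_z > 0.05 && dim(vol)[3] > 1) {
    half <- max(1L, ceiling(3 * sigma_z))
    k <- stats::dnorm(-half:half, sd = sigma_z)
    k <- k / sum(k)
    nz <- dim(vol)[3]
    flat <- matrix(vol, ncol = nz)
    out <- matrix(0, nrow(flat), nz)
    for (i in seq_along(k)) {
      off <- i - half - 1L
      src <- pmin(pmax(seq_len(nz) + off, 1L), nz)  # replicate boundary
      out <- out + k[i] * flat[, src]
    }
    vol <- array(out, dim = dim(vol))
  }
  vol
}

#' Simulate a multichannel confocal z-stack with ground truth
#'
#' Plants non-overlapping spherical somata (TH cells in the red channel,
#' Iba-1 cells in the green channel, nuclei in the DAPI channel) and, in a
#' seeded subset of cells, intracellular alpha-synuclein puncta in the `syn`
#' channel. The clean render is blurred by a Gaussian PSF, degraded by scaled
#' Poisson and additive Gaussian noise, then clipped and quantized to the
#' configured bit depth.
#'
#' @param cfg A [stack_sim_config()].
#' @return A list with elements `stack` (a [channel_stack()]) and `truth`
#'   (a list with per-cell `cells` data frame and `punctum_voxels`, an
#'   integer matrix of planted voxel coordinates `(row, col, z, cell_id)`).
#' @export
make_confocal_stack <- function(cfg) {
  stopifnot(inherits(cfg, "stack_sim_config"))
  set.seed(cfg$seed)
  H <- cfg$height; W <- cfg$width; nz <- cfg$n_z
  channels <- c(dapi = 1L, green = 2L, red = 3L, syn = 4L)
  vox <- array(0, dim = c(H, W, nz, 4L))
  background <- c(dapi = 60, green = 50, red = 50, syn = 40)
  for (ch in seq_len(4L)) vox[, , , ch] <- background[ch]

  r <- cfg$soma_radius
  r_z <- max(1.5, r * cfg$pixel_size / cfg$z_step)
  margin <- r + 3
  n <- cfg$n_cells
  cells <- NULL
  if (n > 0) {
    centers <- matrix(NA_real_, n, 3)
    min_sep <- 2 * r + 6
    tries <- 0L
    placed <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 500L * n)
        stop("could not place ", n, " non-overlapping cells; enlarge the frame")
      cx <- stats::runif(1, margin, H - margin)
      cy <- stats::runif(1, margin, W - margin)
      if (placed > 0) {
        d2 <- (centers[seq_len(placed), 1] - cx)^2 +
          (centers[seq_len(placed), 2] - cy)^2
        if (min(d2) < min_sep^2) next
      }
      cz <- if (nz > 2 * r_z + 2) stats::runif(1, r_z + 1, nz - r_z) else (nz + 1) / 2
      placed <- placed + 1L
      centers[placed, ] <- c(cx, cy, cz)
    }
    n_th <- floor(n * cfg$marker_mix + 0.5)
    marker <- rep("Iba1", n)
    if (n_th > 0) marker[sample.int(n, n_th)] <- "TH"
    n_pos <- floor(n * cfg$frac_positive + 0.5)
    is_positive <- rep(FALSE, n)
    if (n_pos > 0) is_positive[sample.int(n, n_pos)] <- TRUE

    punctum_voxels <- NULL
    dims <- c(H, W, nz)
    slab <- as.double(H) * W * nz
    paint_lin <- list()
    paint_val <- list()
    paint <- function(idx, ch, value) {
      if (is.null(idx) || nrow(idx) == 0) return(invisible())
      lin <- idx[, 1] + (idx[, 2] - 1) * as.double(H) +
        (idx[, 3] - 1) * as.double(H) * W + (ch - 1) * slab
      k <- length(paint_lin) + 1L
      paint_lin[[k]] <<- lin
      paint_val[[k]] <<- rep.int(value, length(lin))
      invisible()
    }
    for (i in seq_len(n)) {
      ch <- if (marker[i] == "TH") channels[["red"]] else channels[["green"]]
      soma_val <- stats::runif(1, 1600, 2400)
      paint(ball_voxels(centers[i, 1], centers[i, 2], centers[i, 3],
                        r, r_z, dims), ch, soma_val)
      paint(ball_voxels(centers[i, 1], centers[i, 2], centers[i, 3],
                        r * 0.45, max(1, r_z * 0.45), dims),
            channels[["dapi"]], 2000)
      if (is_positive[i]) {
        for (p in seq_len(cfg$puncta_per_cell)) {
          # rejection-sample a punctum centre well inside the soma
          repeat {
            off <- stats::runif(3, -1, 1)
            if (sum(off^2) <= 1) break
          }
          shrink <- (r - cfg$punctum_radius - 1) / r
          px <- centers[i, 1] + off[1] * r * shrink
          py <- centers[i, 2] + off[2] * r * shrink
          pz <- min(max(centers[i, 3] + off[3] * r_z * shrink, 1), nz)
          idx <- ball_voxels(px, py, pz, cfg$punctum_radius,
                             max(1, cfg$punctum_radius * cfg$pixel_size / cfg$z_step),
                             dims)
          paint(idx, channels[["syn"]], stats::runif(1, 2600, 3200))
          if (!is.null(idx) && nrow(idx) > 0)
            punctum_voxels <- rbind(punctum_voxels, cbind(idx, cell_id = i))
        }
      }
    }
    if (length(paint_lin) > 0) {
      lin <- unlist(paint_lin, use.names = FALSE)
      val <- unlist(paint_val, use.names = FALSE)
      o <- order(val)  # duplicate indices: last (largest) value wins
      lin <- lin[o]
      val <- val[o]
      vox[lin] <- pmax(vox[lin], val)
    }
    if (!is.null(punctum_voxels)) {
      colnames(punctum_voxels) <- c("row", "col", "z", "cell_id")
      punctum_voxels <- unique(punctum_voxels)
    }
    cells <- data.frame(cell_id = seq_len(n), x = centers[, 1],
                        y = centers[, 2], z = centers[, 3],
                        marker = marker, is_positive = is_positive,
                        stringsAsFactors = FALSE)
  } else {
    punctum_voxels <- NULL
  }

  sigma_z <- cfg$psf_sigma * cfg$pixel_size / cfg$z_step
  maxval <- 2^cfg$bit_depth - 1
  for (ch in seq_len(4L)) {
    v <- vox[, , , ch, drop = TRUE]
    dim(v) <- c(H, W, nz)
    if (cfg$psf_sigma > 0) v <- blur_stack_channel(v, cfg$psf_sigma, sigma_z)
    if (cfg$poisson_scale > 0)
      v <- stats::rpois(length(v), lambda = pmax(v, 0) * cfg$poisson_scale) /
        cfg$poisson_scale
    if (cfg$gaussian_sd > 0)
      v <- v + stats::rnorm(length(v), sd = cfg$gaussian_sd)
    vox[, , , ch] <- round(pmin(pmax(v, 0), maxval))
  }

  stack <- channel_stack(vox, channels, cfg$bit_depth, cfg$pixel_size, cfg$z_step)
  truth <- list(cells = cells, punctum_voxels = punctum_voxels)
  list(stack = stack, truth = truth)
}
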