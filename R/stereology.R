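#' Optical-fractionator sampling design
#'
#' The three sampling fractions of the optical fractionator: the section
#' sampling fraction `ssf = 1 / section_interval`, the area sampling
#' fraction `asf = frame area / grid area`, and the thickness sampling
#' fraction `tsf = dissector_height / section_thickness`.
#'
#' @param section_interval Every k-th section is sampled (ssf = 1/k).
#' @param frame_w,frame_h Counting-frame size, um.
#' @param grid_w,grid_h Sampling-grid step, um.
#' @param dissector_height Optical dissector height, um.
#' @param section_thickness Section thickness, um (nominal cut thickness by
#'   default since measured mounted thickness is often unavailable).
#' @param guard_zone Guard-zone depth at each surface, um.
#' @return An object of class `stereology_design`.
#' @export
stereology_design <- function(section_interval, frame_w, frame_h,
                              grid_w, grid_h, dissector_height,
                              section_thickness = 30, guard_zone = 2) {
  asf <- (frame_w * frame_h) / (grid_w * grid_h)
  tsf <- dissector_height / section_thickness
  if (section_interval < 1) stop("section_interval must be >= 1")
  if (asf <= 0 || asf > 1) stop("invalid area sampling fraction (0 < asf <= 1)")
  if (tsf <= 0 || tsf > 1) stop("invalid thickness sampling fraction")
  if (2 * guard_zone + dissector_height > section_thickness)
    stop("guard zones plus dissector height exceed the section thickness")
  structure(list(section_interval = section_interval,
                 frame_w = frame_w, frame_h = frame_h,
                 grid_w = grid_w, grid_h = grid_h,
                 dissector_height = dissector_height,
                 section_thickness = section_thickness,
                 guard_zone = guard_zone,
                 ssf = 1 / section_interval, asf = asf, tsf = tsf),
            class = "stereology_design")
}

#' Preset: intrastriatal graft TH counts
#'
#' Counting frame 70 x 70 um, grid 150 x 150 um, every 6th section
#' (180 um spacing of 30-um sections), dissector height 12 um, 2 um guards.
#'
#' @return A [stereology_design()].
#' @export
graft_design <- function() {
  stereology_design(section_interval = 6, frame_w = 70, frame_h = 70,
                    grid_w = 150, grid_h = 150, dissector_height = 12,
                    section_thickness = 30, guard_zone = 2)
}

#' Preset: nigral TH / Nissl counts
#'
#' Counting frame 100 x 100 um, grid 200 x 200 um, every 8th section
#' (240 um spacing), dissector height 12 um, 2 um guards.
#'
#' @return A [stereology_design()].
#' @export
nigral_design <- function() {
  stereology_design(section_interval = 8, frame_w = 100, frame_h = 100,
                    grid_w = 200, grid_h = 200, dissector_height = 12,
                    section_thickness = 30, guard_zone = 2)
}

#' Optical-fractionator total-number estimate
#'
#' `N_hat = sum(Q) * (1/ssf) * (1/asf) * (1/tsf)`, with `Q` the raw
#' dissector counts per sampled section.
#'
#' @param counts Integer vector of per-section dissector counts `Q`.
#' @param design A [stereology_design()].
#' @return The estimated total number (a single number).
#' @export
fractionator_estimate <- function(counts, design) {
  stopifnot(inherits(design, "stereology_design"))
  if (any(counts < 0)) stop("dissector counts must be non-negative")
  sum(counts) / (design$ssf * design$asf * design$tsf)
}

#' Gundersen-Jensen coefficient of error
#'
#' Predicted CE of a systematic fractionator sample:
#' `CE = sqrt(noise + var_srs) / sum(Q)` with `noise = sum(Q)` (Poisson
#' counting noise) and the systematic-sampling variance built from the
#' lag-0/1/2 products of the section counts,
#' `A = sum(Q_i^2)`, `B = sum(Q_i Q_{i+1})`, `C = sum(Q_i Q_{i+2})`:
#' `var_srs = (3(A - noise) - 4B + C) / 240` for smoothness class `m = 1`
#' (the default) or `/ 12` for `m = 0`, truncated at zero.
#'
#' @param counts Integer vector of per-section counts (>= 3 sections).
#' @param m Smoothness class of the sampled function, 0 or 1.
#' @return The coefficient of error (a single number).
#' @export
gundersen_ce <- function(counts, m = 1) {
  if (length(counts) < 3) stop("CE needs at least 3 sections")
  if (!m %in% c(0, 1)) stop("m must be 0 or 1")
  total <- sum(counts)
  if (total == 0) stop("zero total count")
  A <- sum(counts^2)
  B <- sum(counts[-length(counts)] * counts[-1])
  C <- if (length(counts) > 2)
    sum(counts[seq_len(length(counts) - 2)] * counts[-(1:2)]) else 0
  denom <- if (m == 1) 240 else 12
  var_srs <- max(0, (3 * (A - total) - 4 * B + C) / denom)
  sqrt(total + var_srs) / total
}

#' Simulate a 3-D point population
#'
#' Uniform random cell positions in a tissue block spanning
#' `extent_x` x `extent_y` um laterally and `n_sections` serial sections of
#' `section_thickness` um axially.
#'
#' @param n_points Number of cells.
#' @param extent_x,extent_y Lateral extent, um.
#' @param n_sections Number of serial sections.
#' @param section_thickness Section thickness, um.
#' @return A matrix with columns `x`, `y`, `z` (um).
#' @export
simulate_point_population <- function(n_points, extent_x = 1500,
                                      extent_y = 1500, n_sections = 36,
                                      section_thickness = 30) {
  cbind(x = stats::runif(n_points, 0, extent_x),
        y = stats::runif(n_points, 0, extent_y),
        z = stats::runif(n_points, 0, n_sections * section_thickness))
}

#' Draw one systematic fractionator sample from a point population
#'
#' Applies the design to a simulated population: a random starting section,
#' every `section_interval`-th section thereafter, a random-phase counting
#' grid in x and y (frames of `frame_w x frame_h` at `grid_w x grid_h`
#' steps, phase wrapped modulo the grid), and an optical dissector of
#' `dissector_height` um below the upper guard zone.
#'
#' @param points Matrix from [simulate_point_population()].
#' @param design A [stereology_design()].
#' @param n_sections Total number of serial sections in the block.
#' @return Integer vector of per-sampled-section counts `Q`.
#' @export
sample_fractionator_counts <- function(points, design, n_sections = 36) {
  stopifnot(inherits(design, "stereology_design"))
  t_sec <- design$section_thickness
  start <- sample.int(design$section_interval, 1)
  secs <- seq(start, n_sections, by = design$section_interval)
  phase_x <- stats::runif(1, 0, design$grid_w)
  phase_y <- stats::runif(1, 0, design$grid_h)
  in_frame <- ((points[, "x"] - phase_x) %% design$grid_w) < design$frame_w &
    ((points[, "y"] - phase_y) %% design$grid_h) < design$frame_h
  z0 <- stats::runif(1, 0, t_sec - design$dissector_height - 2 * design$guard_zone) +
    design$guard_zone
  q <- integer(length(secs))
  for (i in seq_along(secs)) {
    zmin <- (secs[i] - 1) * t_sec + z0
    q[i] <- sum(in_frame & points[, "z"] >= zmin &
                  points[, "z"] < zmin + design$dissector_height)
  }
  q
}
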