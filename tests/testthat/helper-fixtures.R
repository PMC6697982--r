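# shared fixture builders (all synthetic, generated at test time)

tiny_stack_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, width = 160L, height = 160L, n_z = 8L,
               n_cells = 4L, soma_radius = 10L, frac_positive = 0.5,
               puncta_per_cell = 3L, punctum_radius = 3L)
  args[names(list(...))] <- list(...)
  do.call(stack_sim_config, args)
}

tiny_section_cfg <- function(seed = 1L, ...) {
  args <- list(seed = seed, width = 700L, height = 700L, n_ramified = 2L,
               n_amoeboid = 2L, branch_length_range = c(40, 70))
  args[names(list(...))] <- list(...)
  do.call(section_sim_config, args)
}

# paint a DAB-brown disc cell onto a blank light-background section
disc_section <- function(H = 300L, W = 300L, cx = 150, cy = 150, r = 40,
                         stain = c(120, 80, 40), bg = c(235, 230, 225),
                         noise_sd = 4, seed = 11L) {
  set.seed(seed)
  mask <- rasterize_disc(H, W, cx, cy, r)
  px <- array(0, dim = c(H, W, 3))
  for (ch in 1:3) {
    plane <- matrix(bg[ch], H, W)
    plane[mask] <- stain[ch]
    plane <- plane + rnorm(H * W, sd = noise_sd)
    px[, , ch] <- round(pmin(pmax(plane, 0), 255))
  }
  rgb_section(px, pixel_size = 0.11, provenance = "helper")
}

# brute-force step-up BH oracle (independent of the implementation)
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# nearest-truth matching of detected cells to simulated cells
match_calls_to_truth <- function(calls, truth) {
  vapply(seq_len(nrow(calls)), function(i) {
    which.min((truth$x - calls$centroid_x[i])^2 +
                (truth$y - calls$centroid_y[i])^2)
  }, integer(1))
}
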