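test_that("the FWHM band matches the analytic Gaussian width", {
  set.seed(1)
  v <- rnorm(2e5, 100, 10)
  tp <- dynamic_threshold(v)
  # FWHM = 2.3548 sigma -> band [88.2, 111.8]
  expect_lt(abs(tp$low - 88.2), 1)
  expect_lt(abs(tp$high - 111.8), 1)
})

test_that("constant images have no dynamic threshold", {
  expect_error(dynamic_threshold(matrix(7, 10, 10)), "degenerate")
})

test_that("band end points always lie within the observed intensity range", {
  for (s in 1:10) {
    set.seed(s)
    v <- switch(1 + s %% 3,
                rnorm(5000, runif(1, 50, 200), runif(1, 2, 40)),
                rexp(5000, 1 / 50),
                c(rnorm(3000, 60, 8), rnorm(2000, 180, 15)))
    tp <- dynamic_threshold(v)
    expect_gte(tp$low, min(v))
    expect_lte(tp$high, max(v))
    expect_lte(tp$low, tp$high)
  }
})

test_that("hydraulic radius matches analytic values on canonical shapes", {
  disc <- rasterize_disc(201, 201, 101, 101, 50.5)
  expect_lt(abs(hydraulic_radius(disc)$hydraulic_radius_px - 25) / 25, 0.05)
  sq <- matrix(FALSE, 201, 201)
  sq[51:150, 51:150] <- TRUE
  expect_lt(abs(hydraulic_radius(sq)$hydraulic_radius_px - 25) / 25, 0.05)
  strip <- matrix(FALSE, 210, 210)
  strip[101, 6:205] <- TRUE
  expect_lt(abs(hydraulic_radius(strip)$hydraulic_radius_px - 0.5) / 0.5, 0.05)
  expect_error(hydraulic_radius(matrix(FALSE, 5, 5)), "empty region")
})

test_that("the naive pixel estimator shows its documented disc bias", {
  disc <- rasterize_disc(201, 201, 101, 101, 50.5)
  hr <- hydraulic_radius(disc, estimator = "pixel")$hydraulic_radius_px
  # boundary-edge counting biases A/P low by ~21% on discs
  expect_lt(hr, 21)
  expect_gt(hr, 18)
})

test_that("hydraulic radius is scale-covariant under 2x finer sampling", {
  # the same disc rasterized at half the pixel size (radius doubles in px)
  disc <- rasterize_disc(121, 121, 61, 61, 30.5)
  up <- rasterize_disc(241, 241, 121, 121, 61)
  r1 <- hydraulic_radius(disc)$hydraulic_radius_px
  r2 <- hydraulic_radius(up)$hydraulic_radius_px
  expect_lt(abs(r2 / r1 - 2) / 2, 0.05)
})

test_that("at fixed area the disc maximizes the index among tested shapes", {
  n <- 241L
  disc <- rasterize_disc(n, n, 121, 121, sqrt(10000 / pi))
  sq <- matrix(FALSE, n, n)
  sq[71:170, 71:170] <- TRUE
  cross <- matrix(FALSE, n, n)
  cross[107:134, 21:220] <- TRUE   # two 28 x 200 bars
  cross[21:220, 107:134] <- TRUE
  branch <- rasterize_disc(n, n, 121, 121, 30)
  for (a in seq(0, 5) * pi / 3) {
    branch <- branch | rasterize_segment(n, n, 121, 121,
                                         121 + 95 * cos(a), 121 + 95 * sin(a),
                                         width = 9)
  }
  idx <- vapply(list(disc, sq, cross, branch),
                function(m) hydraulic_radius(m)$hydraulic_radius_px, numeric(1))
  expect_true(all(diff(idx) < 0))  # disc > square > cross > branched
})

test_that("small and border components are removed exactly as specified", {
  # interior 5000-px cell (r ~ 40) -> kept
  s_big <- disc_section(r = sqrt(5000 / pi))
  expect_equal(segment_cell_bodies(s_big)$n_regions, 1L)
  # 1500-px cell (under the 2000-px rule) -> dropped
  s_small <- disc_section(r = sqrt(1500 / pi))
  expect_equal(segment_cell_bodies(s_small)$n_regions, 0L)
  # 5000-px cell intersecting the border -> dropped
  s_border <- disc_section(cx = 10, cy = 150, r = sqrt(5000 / pi))
  expect_equal(segment_cell_bodies(s_border)$n_regions, 0L)
  # empty result is a valid output, not an error
  s_blank <- disc_section(r = 5)  # far below the cutoff
  expect_s3_class(segment_cell_bodies(s_blank), "labeled_regions")
})

test_that("process segmentation grows ramified masks and leaves flat images empty", {
  cfg <- tiny_section_cfg(seed = 3L, noise_sd = 0, n_ramified = 2L,
                          n_amoeboid = 1L)
  sim <- make_section_image(cfg)
  bodies <- segment_cell_bodies(sim$section)
  expect_gt(bodies$n_regions, 0L)
  full <- segment_processes(sim$section, bodies, area_min_px = 400L)
  expect_gt(sum(full), sum(bodies$labels > 0))
  # body pixels are always preserved
  expect_true(all(full[bodies$labels > 0]))

  flat <- rgb_section(array(200, dim = c(64, 64, 3)), 0.11)
  none <- synspread:::label_regions(matrix(0L, 64, 64))
  expect_equal(sum(segment_processes(flat, none, area_min_px = 50L)), 0)
})

test_that("amoeboid-only masks stay close to the body mask", {
  cfg <- section_sim_config(seed = 8L, width = 420L, height = 420L,
                            n_ramified = 0L, n_amoeboid = 2L, noise_sd = 0)
  sim <- make_section_image(cfg)
  bodies <- segment_cell_bodies(sim$section)
  full <- segment_processes(sim$section, bodies, area_min_px = 400L)
  body <- bodies$labels > 0
  # additions are confined to a thin dilated outline around the bodies
  added <- full & !body
  grown <- EBImage::dilate(body + 0, EBImage::makeBrush(11L, "disc")) > 0
  expect_true(all(added == (added & grown)))
})

test_that("cell selection applies the border and size rules reproducibly", {
  cfg <- tiny_section_cfg(seed = 5L)
  sim <- make_section_image(cfg)
  regions <- segment_cell_bodies(sim$section)
  sel <- select_cells(regions, "auto")
  expect_true(all(sel$selected == (!sel$touches_border & sel$area >= 2000)))
  choices <- data.frame(region_id = sel$region_id,
                        selected = seq_len(nrow(sel)) %% 2 == 1)
  m1 <- select_cells(regions, "manual", choices = choices)
  m2 <- select_cells(regions, "manual", choices = choices)
  expect_identical(m1, m2)
  expect_error(select_cells(regions, "wizard"), "unknown selection mode")
  expect_error(select_cells(regions, "manual"), "choices")
})

test_that("density arithmetic and translation invariance hold", {
  # 10 centroids inside a 0.25 mm^2 ROI -> 40 cells/mm^2
  ps <- 1  # 1 um/px: 500 x 500 px = 0.25 mm^2
  roi <- cbind(c(1, 1, 500, 500), c(1, 500, 500, 1))
  cent <- cbind(runif(10, 50, 450), runif(10, 50, 450))
  d <- iba1_density(cent, roi, pixel_size = ps)
  expect_equal(d$n_cells, 10L)
  expect_equal(d$roi_area_mm2, 0.249001, tolerance = 1e-6)
  expect_equal(d$density_cells_per_mm2, 10 / d$roi_area_mm2)
  # empty ROI region
  far <- cbind(c(600, 600, 650, 650), c(600, 650, 650, 600))
  expect_equal(iba1_density(cent, far, ps)$density_cells_per_mm2, 0)
  # translation of ROI + cells together leaves density unchanged
  d2 <- iba1_density(cent + 37, roi + 37, ps)
  expect_equal(d2$density_cells_per_mm2, d$density_cells_per_mm2)
  expect_error(iba1_density(cent, cbind(c(1, 1, 1), c(1, 2, 3)), ps), "zero-area")
})

test_that("activation summary separates simulated groups and handles SEM edge cases", {
  recs <- list()
  for (s in 1:3) {
    amo <- make_section_image(section_sim_config(seed = s, width = 520L,
                                                 height = 520L, n_ramified = 0L,
                                                 n_amoeboid = 3L))
    ram <- make_section_image(tiny_section_cfg(seed = 10L + s, n_ramified = 3L,
                                               n_amoeboid = 0L))
    for (sim in list(amo, ram)) {
      b <- segment_cell_bodies(sim$section)
      if (b$n_regions == 0) next
      hr <- hydraulic_radius(b)
      recs[[length(recs) + 1L]] <- data.frame(
        animal_id = paste0("a", s),
        group = if (identical(sim, amo)) "amoeboid" else "ramified",
        hydraulic_radius = hr$hydraulic_radius_px)
    }
  }
  recs <- do.call(rbind, recs)
  summ <- activation_index_summary(recs)
  expect_gt(summ$mean_index[summ$group == "amoeboid"],
            summ$mean_index[summ$group == "ramified"])
  # single record: SEM undefined, reported missing
  one <- data.frame(animal_id = "a", group = "g", hydraulic_radius = 12)
  expect_true(is.na(activation_index_summary(one)$sem))
  # identical records from two animals: SEM zero
  two <- data.frame(animal_id = c("a", "b"), group = "g",
                    hydraulic_radius = c(12, 12))
  expect_equal(activation_index_summary(two)$sem, 0)
  expect_error(activation_index_summary(recs[0, ]), "empty")
})

test_that("index-based amoeboid/ramified classification is nearly perfect on fixtures", {
  # >= 20 cells per class across seeded sections
  scores <- list()
  for (s in 1:6) {
    sim <- make_section_image(tiny_section_cfg(seed = 20L + s, n_ramified = 2L,
                                               n_amoeboid = 2L))
    b <- segment_cell_bodies(sim$section)
    if (b$n_regions == 0) next
    hr <- hydraulic_radius(b)
    cls <- sim$truth$shape_class[match_calls_to_truth(
      data.frame(centroid_x = b$regions$centroid_x,
                 centroid_y = b$regions$centroid_y), sim$truth)]
    scores[[length(scores) + 1L]] <- data.frame(index = hr$hydraulic_radius_px,
                                                class = cls)
  }
  scores <- do.call(rbind, scores)
  expect_gte(sum(scores$class == "amoeboid"), 10L)
  expect_gte(sum(scores$class == "ramified"), 10L)
  pos <- scores$index[scores$class == "amoeboid"]
  neg <- scores$index[scores$class == "ramified"]
  auc <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_gte(auc, 0.95)
})
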