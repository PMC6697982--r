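# allowed configuration keys per pipeline stage
stage_config_keys <- list(
  simulate = c("stack", "section", "counts"),
  morph = c("sections", "pixel_size", "area_min_px", "estimator"),
  transfer = c("stacks", "channel_map", "min_punctum_px"),
  rnaseq = c("counts", "groups", "contrast", "cpm_threshold", "min_samples",
             "fdr", "abs_log2fc"),
  stereology = c("counts", "design")
)

# canonical md5 hash of a config list (via its serialized JSON)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  unname(tools::md5sum(tmp))
}

write_provenance <- function(out_dir, stage, config, seed) {
  sidecar <- list(stage = stage, config_hash = config_hash(config),
                  seed = seed,
                  package_version = as.character(utils::packageVersion("synspread")))
  jsonlite::write_json(sidecar, file.path(out_dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE)
  invisible(sidecar)
}

#' Run one pipeline stage
#'
#' Thin orchestration over the package's analysis functions. Each stage
#' writes CSV results plus a JSON provenance sidecar (stage name, config
#' hash, seed, package version) into `out_dir`.
#'
#' @param stage One of `"simulate"`, `"morph"`, `"transfer"`, `"rnaseq"`,
#'   `"stereology"`.
#' @param config Named list of stage parameters (or a YAML file path).
#'   Unknown keys are rejected.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing all randomness of the stage.
#' @return Named list of written file paths, invisibly.
#' @export
run_stage <- function(stage, config = list(), out_dir = ".", seed = 1L) {
  if (!stage %in% names(stage_config_keys))
    stop("unknown stage: ", stage, " (expected one of ",
         paste(names(stage_config_keys), collapse = ", "), ")")
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  unknown <- setdiff(names(config), stage_config_keys[[stage]])
  if (length(unknown) > 0)
    stop("unknown config key(s) for stage ", stage, ": ",
         paste(unknown, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  paths <- switch(stage,
    simulate = stage_simulate(config, out_dir, seed),
    morph = stage_morph(config, out_dir),
    transfer = stage_transfer(config, out_dir),
    rnaseq = stage_rnaseq(config, out_dir),
    stereology = stage_stereology(config, out_dir))
  write_provenance(out_dir, stage, config, seed)
  invisible(paths)
}

stage_simulate <- function(config, out_dir, seed) {
  paths <- list()
  stack_cfg <- do.call(stack_sim_config, c(list(seed = seed),
                                           config$stack %||% list()))
  sim <- make_confocal_stack(stack_cfg)
  paths$stack <- file.path(out_dir, "stack.tiff")
  write_stack_tiff(sim$stack, paths$stack)
  paths$stack_truth <- file.path(out_dir, "stack_truth.csv")
  utils::write.csv(sim$truth$cells, paths$stack_truth, row.names = FALSE)

  sec_cfg <- do.call(section_sim_config, c(list(seed = seed),
                                           config$section %||% list()))
  secsim <- make_section_image(sec_cfg)
  paths$section <- file.path(out_dir, "section.png")
  write_section_png(secsim$section, paths$section)
  paths$section_truth <- file.path(out_dir, "section_truth.csv")
  utils::write.csv(secsim$truth, paths$section_truth, row.names = FALSE)

  cnt_cfg <- do.call(count_sim_config, c(list(seed = seed),
                                         config$counts %||% list()))
  cnt <- make_count_matrix(cnt_cfg)
  paths$counts <- file.path(out_dir, "counts.tsv")
  utils::write.table(data.frame(gene_id = rownames(cnt$counts), cnt$counts,
                                check.names = FALSE),
                     paths$counts, sep = "\t", row.names = FALSE, quote = FALSE)
  paths$samples <- file.path(out_dir, "samples.csv")
  utils::write.csv(data.frame(sample_id = colnames(cnt$counts),
                              group = as.character(cnt$groups)),
                   paths$samples, row.names = FALSE)
  paths$counts_truth <- file.path(out_dir, "counts_truth.csv")
  utils::write.csv(cnt$truth, paths$counts_truth, row.names = FALSE)
  paths
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_morph <- function(config, out_dir) {
  stopifnot(!is.null(config$sections))
  pixel_size <- config$pixel_size %||% 0.11
  rows <- list()
  for (i in seq_along(config$sections)) {
    section <- read_section(config$sections[[i]], pixel_size)
    bodies <- segment_cell_bodies(section,
                                  area_min_px = config$area_min_px %||% 2000L)
    if (bodies$n_regions == 0) next
    rec <- hydraulic_radius(bodies, pixel_size = pixel_size,
                            estimator = config$estimator %||% "contour")
    sel <- select_cells(bodies, "auto")
    rec$selected <- sel$selected[match(rec$cell_id, sel$region_id)]
    rec$section <- basename(config$sections[[i]])
    rows[[length(rows) + 1L]] <- rec
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cell_id = integer(0))
  path <- file.path(out_dir, "morphometry.csv")
  utils::write.csv(out, path, row.names = FALSE)
  list(morphometry = path)
}

stage_transfer <- function(config, out_dir) {
  if (is.null(config$stacks)) stop("missing config key: stacks")
  if (is.null(config$channel_map)) stop("missing config key: channel_map")
  rows <- list()
  for (path in config$stacks) {
    stack <- read_stack_tiff(path)
    for (mk in c("TH", "Iba1")) {
      tab <- classify_cells(stack, mk,
                            min_punctum_px = config$min_punctum_px %||% 4L,
                            animal_id = basename(path))
      if (nrow(tab) > 0) rows[[length(rows) + 1L]] <- as.data.frame(tab)
    }
  }
  calls <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cell_id = integer(0))
  path <- file.path(out_dir, "cell_calls.csv")
  utils::write.csv(calls, path, row.names = FALSE)
  list(cell_calls = path)
}

stage_rnaseq <- function(config, out_dir) {
  if (is.null(config$counts)) stop("missing config key: counts")
  counts <- read_counts_table(config$counts)
  samples <- utils::read.csv(config$groups, stringsAsFactors = FALSE)
  groups <- samples$group[match(colnames(counts), samples$sample_id)]
  counts <- filter_min_cpm(counts, config$cpm_threshold %||% 0.1,
                           config$min_samples %||% 3L)
  nf <- tmm_norm_factors(counts)
  contrast <- config$contrast %||% c("LPS", "IL4")
  lcpm <- cpm(counts, norm_factors = nf, log = TRUE)
  keep <- filter_group_mean(lcpm, groups, contrast)
  det <- de_test(counts[keep, , drop = FALSE], groups, contrast,
                 norm_factors = nf)
  path <- file.path(out_dir, "de_table.csv")
  utils::write.csv(det, path, row.names = FALSE)
  sets <- apply_de_thresholds(det, config$fdr %||% 0.05,
                              config$abs_log2fc %||% 1)
  summ <- data.frame(n_tested = nrow(det),
                     n_significant = length(sets$significant),
                     n_high_magnitude = length(sets$high_magnitude))
  spath <- file.path(out_dir, "de_summary.csv")
  utils::write.csv(summ, spath, row.names = FALSE)
  list(de_table = path, de_summary = spath)
}

stage_stereology <- function(config, out_dir) {
  if (is.null(config$counts)) stop("missing config key: counts")
  q <- utils::read.csv(config$counts, stringsAsFactors = FALSE)
  design <- if (is.character(config$design)) {
    switch(config$design, graft = graft_design(), nigral = nigral_design(),
           do.call(stereology_design, yaml::read_yaml(config$design)))
  } else {
    do.call(stereology_design, config$design)
  }
  out <- data.frame(total_estimate = fractionator_estimate(q$Q, design),
                    sum_q = sum(q$Q),
                    ce_m0 = gundersen_ce(q$Q, m = 0),
                    ce_m1 = gundersen_ce(q$Q, m = 1))
  path <- file.path(out_dir, "stereology.csv")
  utils::write.csv(out, path, row.names = FALSE)
  list(stereology = path)
}

#' End-to-end demonstration run on synthetic fixtures
#'
#' Generates small synthetic stacks, sections and a count matrix for the
#' three treatment groups, runs every analysis stage, and writes result
#' tables plus a markdown report mirroring the study's readouts (percent
#' positive per group, hydraulic-radius summary, differential-expression
#' counts, a fractionator estimate). Fully deterministic in `seed`.
#'
#' @param seed Integer seed for all stages.
#' @param out_dir Output directory.
#' @return Invisibly, a list of the result tables.
#' @export
run_demo <- function(seed = 1L, out_dir = tempfile("synspread_demo")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  groups <- c(PBS = 0.2, LPS = 0.5, IL4 = 0.1)  # planted transfer rates

  # transfer: one small stack per group
  calls <- list()
  for (gi in seq_along(groups)) {
    cfg <- stack_sim_config(seed = seed + gi, width = 256L, height = 256L,
                            n_z = 12L, n_cells = 12L, soma_radius = 11L,
                            frac_positive = groups[[gi]])
    sim <- make_confocal_stack(cfg)
    for (mk in c("TH", "Iba1")) {
      tab <- classify_cells(sim$stack, mk, animal_id = paste0("m", gi),
                            group = names(groups)[gi])
      if (nrow(tab) > 0) calls[[length(calls) + 1L]] <- as.data.frame(tab)
    }
  }
  calls <- do.call(rbind, calls)
  pct <- percent_positive(calls)

  # morphology: one section per group with group-dependent composition
  amoe <- c(PBS = 2L, LPS = 6L, IL4 = 5L)
  morph <- list()
  for (gi in seq_along(amoe)) {
    cfg <- section_sim_config(seed = seed + 10L + gi, width = 900L,
                              height = 900L, n_ramified = 8L - amoe[[gi]],
                              n_amoeboid = amoe[[gi]],
                              branch_length_range = c(40, 80))
    sim <- make_section_image(cfg)
    bodies <- segment_cell_bodies(sim$section)
    if (bodies$n_regions == 0) next
    rec <- hydraulic_radius(bodies, pixel_size = cfg$pixel_size)
    rec$animal_id <- paste0("m", gi)
    rec$group <- names(amoe)[gi]
    morph[[length(morph) + 1L]] <- rec
  }
  morph <- do.call(rbind, morph)
  names(morph)[names(morph) == "hydraulic_radius_px"] <- "hydraulic_radius"
  morph_summary <- activation_index_summary(morph)

  # transcriptomics: small matrix at the study design
  cnt <- make_count_matrix(count_sim_config(seed = seed + 20L,
                                            n_genes = 4000L))
  counts <- filter_min_cpm(cnt$counts)
  nf <- tmm_norm_factors(counts)
  det <- de_test(counts, cnt$groups, norm_factors = nf)
  sets <- apply_de_thresholds(det)
  de_summary <- data.frame(n_tested = nrow(det),
                           n_significant = length(sets$significant),
                           n_high_magnitude = length(sets$high_magnitude))

  # stereology: worked fractionator sample
  pop <- simulate_point_population(3000)
  q <- sample_fractionator_counts(pop, graft_design())
  stereo <- data.frame(true_n = 3000,
                       estimate = fractionator_estimate(q, graft_design()),
                       ce_m1 = gundersen_ce(q, m = 1))

  utils::write.csv(calls, file.path(out_dir, "cell_calls.csv"), row.names = FALSE)
  utils::write.csv(pct$per_group, file.path(out_dir, "percent_positive.csv"),
                   row.names = FALSE)
  utils::write.csv(morph_summary, file.path(out_dir, "morphology_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(de_summary, file.path(out_dir, "de_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(stereo, file.path(out_dir, "stereology.csv"),
                   row.names = FALSE)

  fmt <- function(df) paste(utils::capture.output(print(df, row.names = FALSE)),
                            collapse = "\n")
  report <- paste0(
    "# synspread demonstration run (seed ", seed, ")\n\n",
    "## Percent of cells containing transferred alpha-synuclein\n\n```\n",
    fmt(pct$per_group), "\n```\n\n",
    "## Microglial activation index (hydraulic radius, px)\n\n```\n",
    fmt(morph_summary), "\n```\n\n",
    "## Differential expression (LPS vs IL-4)\n\n```\n",
    fmt(de_summary), "\n```\n\n",
    "## Optical fractionator\n\n```\n", fmt(stereo), "\n```\n")
  writeLines(report, file.path(out_dir, "report.md"))
  write_provenance(out_dir, "demo", list(seed = seed), seed)
  invisible(list(percent_positive = pct, morphology = morph_summary,
                 de_summary = de_summary, stereology = stereo,
                 out_dir = out_dir))
}
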