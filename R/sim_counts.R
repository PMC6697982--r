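#' Configuration for the synthetic RNA-seq count generator
#'
#' Negative-binomial gene-level counts for a three-group striatal injection
#' design. Group sizes default to the study design (4 PBS, 5 LPS, 8 IL-4).
#' A seeded fraction of genes is differentially expressed between the LPS
#' and IL-4 group means by `de_log2fc` (half up, half down in LPS).
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param group_sizes Named integer vector, default `c(PBS=4, LPS=5, IL4=8)`.
#' @param baseline_log2cpm_mean,baseline_log2cpm_sd Parameters of the normal
#'   distribution the per-gene baseline log2 CPM abundances are drawn from.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`); must be >= 0 (0 gives Poisson counts).
#' @param library_size_range Range library sizes are drawn from (uniform).
#' @param de_fraction Fraction of genes planted as differentially expressed,
#'   in `[0, 1]`.
#' @param de_log2fc Planted absolute log2 fold change (LPS vs IL-4).
#' @return An object of class `count_sim_config`.
#' @export
count_sim_config <- function(seed = 1L, n_genes = 20000L,
                             group_sizes = c(PBS = 4L, LPS = 5L, IL4 = 8L),
                             baseline_log2cpm_mean = 1,
                             baseline_log2cpm_sd = 2,
                             dispersion = 0.1,
                             library_size_range = c(15e6, 25e6),
                             de_fraction = 0.1, de_log2fc = 2) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]")
  if (dispersion < 0) stop("dispersion must be >= 0")
  stopifnot(n_genes >= 1, all(group_sizes >= 0),
            !is.null(names(group_sizes)), all(library_size_range > 0))
  structure(list(seed = as.integer(seed), n_genes = as.integer(n_genes),
                 group_sizes = group_sizes,
                 baseline_log2cpm_mean = baseline_log2cpm_mean,
                 baseline_log2cpm_sd = baseline_log2cpm_sd,
                 dispersion = dispersion,
                 library_size_range = library_size_range,
                 de_fraction = de_fraction, de_log2fc = de_log2fc),
            class = "count_sim_config")
}

#' Simulate a gene-level count matrix with planted differential expression
#'
#' Per-gene relative abundances are drawn on the log2 CPM scale, shifted by
#' +/- `de_log2fc / 2` in the LPS and IL-4 groups for the planted DE genes
#' (so the LPS - IL-4 contrast equals `de_log2fc` in magnitude), renormalized
#' to proportions per sample, and sampled as negative-binomial counts with
#' the configured dispersion. PBS samples sit at the baseline.
#'
#' @param cfg A [count_sim_config()].
#' @return A list with `counts` (integer matrix genes x samples), `groups`
#'   (factor), `lib_sizes` (the drawn target library sizes) and `truth`
#'   (data frame: `gene_id`, `is_de`, `true_log2fc`).
#' @export
make_count_matrix <- function(cfg) {
  stopifnot(inherits(cfg, "count_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes
  groups <- factor(rep(names(cfg$group_sizes), cfg$group_sizes),
                   levels = names(cfg$group_sizes))
  S <- length(groups)
  gene_id <- sprintf("gene%05d", seq_len(G))
  base <- stats::rnorm(G, cfg$baseline_log2cpm_mean, cfg$baseline_log2cpm_sd)
  n_de <- floor(G * cfg$de_fraction + 0.5)
  is_de <- rep(FALSE, G)
  true_lfc <- rep(0, G)
  if (n_de > 0) {
    idx <- sample.int(G, n_de)
    is_de[idx] <- TRUE
    sign <- rep_len(c(1, -1), n_de)
    true_lfc[idx] <- sign * cfg$de_log2fc
  }
  lib <- stats::runif(S, cfg$library_size_range[1], cfg$library_size_range[2])
  counts <- matrix(0L, G, S, dimnames = list(gene_id, sprintf(
    "%s_%d", as.character(groups), stats::ave(seq_len(S), groups, FUN = seq_along))))
  for (j in seq_len(S)) {
    shift <- switch(as.character(groups[j]),
                    LPS = true_lfc / 2, IL4 = -true_lfc / 2, 0)
    expr <- 2^(base + shift)
    p <- expr / sum(expr)
    mu <- p * lib[j]
    if (cfg$dispersion == 0) {
      counts[, j] <- stats::rpois(G, mu)
    } else {
      counts[, j] <- stats::rnbinom(G, mu = mu, size = 1 / cfg$dispersion)
    }
  }
  storage.mode(counts) <- "integer"
  truth <- data.frame(gene_id = gene_id, is_de = is_de, true_log2fc = true_lfc,
                      stringsAsFactors = FALSE)
  list(counts = counts, groups = groups, lib_sizes = lib, truth = truth)
}
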