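#' Counts per million
#'
#' `counts[i, j] / (lib_sizes[j] * norm_factors[j]) * 1e6`. With
#' `log = TRUE`, a library-size-adjusted pseudocount is added before the
#' log2 transform, following the usual convention: for prior count `p`,
#' the per-sample pseudocount is `p * L_j / mean(L)` (with `L_j` the
#' effective library size) and the returned value is
#' `log2((counts[i, j] + p_j) / (L_j + 2 * p_j) * 1e6)`.
#'
#' @param counts Non-negative matrix, genes x samples.
#' @param lib_sizes Library sizes (default: column sums). Must be > 0.
#' @param norm_factors Normalization factors (default 1).
#' @param log Return log2 values.
#' @param prior Pseudocount for the log transform (default 2).
#' @return Numeric matrix of (log2) CPM values.
#' @export
cpm <- function(counts, lib_sizes = colSums(counts),
                norm_factors = rep(1, ncol(counts)), log = FALSE, prior = 2) {
  counts <- as.matrix(counts)
  if (any(lib_sizes <= 0)) stop("zero or negative library size")
  eff <- lib_sizes * norm_factors
  if (!log) return(t(t(counts) / eff) * 1e6)
  pc <- prior * eff / mean(eff)
  log2(t((t(counts) + pc) / (eff + 2 * pc)) * 1e6)
}

#' Minimum-CPM expression filter
#'
#' Keeps genes with more than `threshold` counts per million in at least
#' `min_samples` samples (the pre-testing filter of the workflow; with the
#' defaults, genes without more than 0.1 CPM in at least 3 samples are
#' excluded).
#'
#' @param counts Genes x samples count matrix.
#' @param threshold CPM threshold (strict inequality).
#' @param min_samples Minimum number of samples exceeding the threshold.
#' @param lib_sizes,norm_factors Passed to [cpm()].
#' @return The filtered count matrix (attribute `"keep"` holds the logical
#'   gene filter).
#' @export
filter_min_cpm <- function(counts, threshold = 0.1, min_samples = 3L,
                           lib_sizes = colSums(counts),
                           norm_factors = rep(1, ncol(counts))) {
  x <- cpm(counts, lib_sizes, norm_factors)
  keep <- rowSums(x > threshold) >= min_samples
  out <- counts[keep, , drop = FALSE]
  attr(out, "keep") <- keep
  out
}

# single-pair TMM factor: doubly trimmed, precision-weighted mean of
# M-values (Robinson & Oshlack 2010)
tmm_pair_factor <- function(obs, ref, lib_obs, lib_ref,
                            trim_m = 0.3, trim_a = 0.05) {
  fin <- obs > 0 & ref > 0
  obs <- obs[fin]
  ref <- ref[fin]
  m <- log2((obs / lib_obs) / (ref / lib_ref))
  a <- (log2(obs / lib_obs) + log2(ref / lib_ref)) / 2
  w <- (lib_obs - obs) / (lib_obs * obs) + (lib_ref - ref) / (lib_ref * ref)
  ok <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[ok]; a <- a[ok]; w <- w[ok]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(m)
  ra <- rank(a)
  keep <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(keep)) return(1)
  2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Trimmed mean of M-values normalization factors
#'
#' Between-sample scaling factors robust to asymmetric differential
#' expression. The reference sample is the one whose upper-quartile CPM is
#' closest to the mean upper quartile; per sample, M-values (log ratios to
#' the reference) are trimmed by `trim_m` on M and `trim_a` on average
#' log intensity, averaged with inverse approximate-variance weights, and
#' the resulting factors are rescaled to geometric mean 1.
#'
#' @param counts Genes x samples count matrix (>= 2 samples).
#' @param trim_m Two-sided trim fraction on M-values.
#' @param trim_a Two-sided trim fraction on A-values.
#' @return Numeric vector of normalization factors (geometric mean 1).
#' @export
tmm_norm_factors <- function(counts, trim_m = 0.3, trim_a = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("all-zero column in the count matrix")
  uq <- apply(t(t(counts) / lib), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref) return(1)
    tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                    trim_m, trim_a)
  }, numeric(1))
  f / exp(mean(log(f)))
}

#' Group-mean expression filter
#'
#' Keeps genes whose mean log2 CPM exceeds `min_log2cpm` in at least one of
#' the named groups (the "either LPS or IL-4" minimum-average-expression
#' filter; log2 CPM > 0 is 1 CPM on the natural scale).
#'
#' @param log2cpm Genes x samples matrix of log2 CPM values.
#' @param groups Factor/character vector of sample group labels.
#' @param which_groups Groups the filter applies to.
#' @param min_log2cpm Threshold on the group-mean log2 CPM (strict).
#' @return Logical vector over genes (`TRUE` = kept).
#' @export
filter_group_mean <- function(log2cpm, groups,
                              which_groups = c("LPS", "IL4"),
                              min_log2cpm = 0) {
  groups <- as.character(groups)
  missing <- setdiff(which_groups, groups)
  if (length(missing) > 0)
    stop("unknown group(s): ", paste(missing, collapse = ", "))
  keep <- rep(FALSE, nrow(log2cpm))
  for (g in which_groups) {
    gm <- rowMeans(log2cpm[, groups == g, drop = FALSE])
    keep <- keep | gm > min_log2cpm
  }
  keep
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values: `fdr_(i) = min_{j >= i} p_(j) * m / j`,
#' capped at 1, in the original order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

# inverse of the trigamma function by Newton iteration
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

# moment estimation of the scaled-F prior for residual variances
# (empirical-Bayes variance moderation)
fit_f_dist <- function(s2, df1) {
  ok <- s2 > 0 & is.finite(s2)
  z <- log(s2[ok])
  e <- z - digamma(df1 / 2) + log(df1 / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df1 / 2)
  if (is.finite(evar) && evar > 0) {
    df2 <- 2 * trigamma_inverse(evar)
    s20 <- exp(emean + digamma(df2 / 2) - log(df2 / 2))
  } else {
    # no excess dispersion beyond chi-square sampling: infinite prior df,
    # pooled variance as the prior
    df2 <- Inf
    s20 <- mean(s2[ok])
  }
  list(df_prior = df2, s2_prior = s20)
}

#' Precision-weighted moderated differential expression test
#'
#' The count-based linear-modelling workflow: log2 CPM response with a
#' 0.5-count offset, per-gene ordinary least squares to estimate the
#' mean-variance relationship, a lowess trend of sqrt-standard-deviation
#' against average log2 count, inverse fourth-power observation weights
#' interpolated from the trend at each fitted log2 count, per-gene weighted
#' least squares, empirical-Bayes shrinkage of the residual variances toward
#' a scaled-F prior, and two-sided moderated t statistics with
#' Benjamini-Hochberg adjusted p-values.
#'
#' @param counts Genes x samples count matrix (all samples; only the two
#'   contrast groups enter the fit, so e.g. PBS columns are carried through
#'   normalization but excluded from the test).
#' @param groups Sample group labels.
#' @param contrast Length-2 character vector `c(test, reference)`; positive
#'   log2 fold changes are up in the first group (default LPS vs IL-4).
#' @param norm_factors Normalization factors for all columns of `counts`
#'   (default: TMM computed on `counts`).
#' @param span Lowess span for the mean-variance trend.
#' @return A `DETable` data frame: `gene_id`, `log2fc`, `ave_log2cpm`,
#'   `t`, `p`, `fdr`, `passes_fc_filter` (`|log2fc| > 1`).
#' @export
de_test <- function(counts, groups, contrast = c("LPS", "IL4"),
                    norm_factors = NULL, span = 0.5) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts), length(contrast) == 2)
  if (is.null(norm_factors)) norm_factors <- tmm_norm_factors(counts)
  sel <- groups %in% contrast
  if (sum(groups == contrast[1]) < 2 || sum(groups == contrast[2]) < 2)
    stop("need at least 2 samples per contrast group")
  y_counts <- counts[, sel, drop = FALSE]
  g <- groups[sel]
  lib <- colSums(counts)[sel] * norm_factors[sel]
  design <- cbind(intercept = 1, test = as.numeric(g == contrast[1]))
  if (qr(design)$rank < 2) stop("singular design")

  n <- ncol(y_counts)
  G <- nrow(y_counts)
  y <- log2(t((t(y_counts) + 0.5) / (lib + 1)) * 1e6)

  # pass 1: unweighted LS for the mean-variance trend
  qr_d <- qr(design)
  beta <- t(qr.coef(qr_d, t(y)))
  res <- y - beta %*% t(design)
  df_resid <- n - 2
  sigma <- sqrt(rowSums(res^2) / df_resid)
  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  keep_tr <- is.finite(sx) & is.finite(sy)
  lo <- stats::lowess(sx[keep_tr], sy[keep_tr], f = span)
  trend <- stats::approxfun(lo$x, lo$y, rule = 2, ties = "ordered")

  # observation weights from the trend at the fitted log2 counts
  fitted_logcpm <- beta %*% t(design)
  lambda <- t(t(fitted_logcpm) + log2(lib + 1)) - log2(1e6)
  w <- 1 / pmax(trend(lambda), 1e-4)^4
  dim(w) <- dim(lambda)

  # pass 2: per-gene weighted LS
  coef2 <- numeric(G)
  s2 <- numeric(G)
  unscaled <- numeric(G)
  for (i in seq_len(G)) {
    wi <- w[i, ]
    sw <- sqrt(wi)
    Xw <- design * sw
    yw <- y[i, ] * sw
    fit <- stats::lm.fit(Xw, yw)
    coef2[i] <- fit$coefficients[2]
    s2[i] <- sum(fit$residuals^2) / df_resid
    xtx_inv <- chol2inv(chol(crossprod(Xw)))
    unscaled[i] <- sqrt(xtx_inv[2, 2])
  }

  prior <- fit_f_dist(s2, df_resid)
  if (is.finite(prior$df_prior)) {
    s2_post <- (prior$df_prior * prior$s2_prior + df_resid * s2) /
      (prior$df_prior + df_resid)
    df_total <- df_resid + prior$df_prior
  } else {
    s2_post <- rep(prior$s2_prior, G)
    df_total <- Inf
  }
  tstat <- coef2 / (unscaled * sqrt(s2_post))
  p <- 2 * stats::pt(-abs(tstat), df_total)
  out <- data.frame(
    gene_id = if (!is.null(rownames(counts))) rownames(counts) else
      as.character(seq_len(G)),
    log2fc = coef2, ave_log2cpm = rowMeans(y), t = tstat, p = p,
    fdr = bh_adjust(p), stringsAsFactors = FALSE)
  out$passes_fc_filter <- abs(out$log2fc) > 1
  out
}

#' Apply the significance and fold-change thresholds
#'
#' @param det A `DETable` from [de_test()].
#' @param fdr FDR threshold (default 0.05).
#' @param abs_log2fc Secondary absolute log2 fold-change filter (strict,
#'   default 1, i.e. at least a two-fold change).
#' @return A list: `significant` (gene ids with FDR < `fdr`) and
#'   `high_magnitude` (the subset also passing `|log2fc| > abs_log2fc`).
#' @export
apply_de_thresholds <- function(det, fdr = 0.05, abs_log2fc = 1) {
  sig <- det$gene_id[det$fdr < fdr]
  high <- det$gene_id[det$fdr < fdr & abs(det$log2fc) > abs_log2fc]
  list(significant = sig, high_magnitude = high)
}

#' Z-scores against a reference group
#'
#' `z[i, j] = (x[i, j] - mean_ref[i]) / sd_ref[i]`, with the mean and
#' standard deviation taken over the reference-group samples only. Genes
#' with zero reference sd are returned as `NA` (flagged missing, not
#' infinite).
#'
#' @param expr Genes x samples expression matrix.
#' @param groups Sample group labels.
#' @param reference Reference group (default `"IL4"`).
#' @return Matrix of z-scores, same shape as `expr`.
#' @export
zscore_vs_reference <- function(expr, groups, reference = "IL4") {
  groups <- as.character(groups)
  ref <- groups == reference
  if (sum(ref) < 2) stop("reference group needs at least 2 samples")
  m <- rowMeans(expr[, ref, drop = FALSE])
  s <- apply(expr[, ref, drop = FALSE], 1, stats::sd)
  z <- (expr - m) / s
  z[s == 0, ] <- NA_real_
  z
}

#' Fragments per kilobase per million
#'
#' CPM divided by the gene's effective length in kilobases.
#'
#' @param counts Genes x samples count matrix.
#' @param length_kb Named numeric vector of effective lengths (kb) covering
#'   all genes of `counts`.
#' @param lib_sizes,norm_factors Passed to [cpm()].
#' @return FPKM matrix.
#' @export
fpkm <- function(counts, length_kb, lib_sizes = colSums(counts),
                 norm_factors = rep(1, ncol(counts))) {
  ids <- rownames(counts)
  if (is.null(ids)) {
    if (length(length_kb) != nrow(counts)) stop("missing gene lengths")
    len <- length_kb
  } else {
    if (!all(ids %in% names(length_kb)))
      stop("missing gene length(s): ",
           paste(utils::head(setdiff(ids, names(length_kb)), 3), collapse = ", "))
    len <- length_kb[ids]
  }
  if (any(!is.finite(len)) || any(len <= 0)) stop("gene lengths must be > 0")
  cpm(counts, lib_sizes, norm_factors) / len
}

#' Multidimensional scaling of samples on leading log fold changes
#'
#' The distance between two samples is the root mean square of the `top_n`
#' largest absolute log2 fold changes between them (the "leading log fold
#' change" convention); samples are embedded in 2 dimensions by classical
#' scaling of that distance matrix.
#'
#' @param log2cpm Genes x samples matrix of log2 CPM values (>= 3 samples).
#' @param top_n Number of top gene differences per pair (capped at the gene
#'   count).
#' @return A data frame `sample`, `dim1`, `dim2`; the distance matrix is
#'   attached as attribute `"distances"`.
#' @export
mds_coordinates <- function(log2cpm, top_n = 500L) {
  S <- ncol(log2cpm)
  if (S < 3) stop("MDS needs at least 3 samples")
  top_n <- min(top_n, nrow(log2cpm))
  d <- matrix(0, S, S)
  for (i in seq_len(S - 1)) {
    for (j in (i + 1):S) {
      diffs2 <- sort((log2cpm[, i] - log2cpm[, j])^2, decreasing = TRUE)
      d[i, j] <- d[j, i] <- sqrt(mean(diffs2[seq_len(top_n)]))
    }
  }
  coords <- stats::cmdscale(d, k = 2)
  out <- data.frame(sample = if (!is.null(colnames(log2cpm)))
    colnames(log2cpm) else as.character(seq_len(S)),
    dim1 = coords[, 1], dim2 = coords[, 2], stringsAsFactors = FALSE)
  attr(out, "distances") <- d
  out
}

#' Overlap of cell-type signatures with a differential gene set
#'
#' For each signature (e.g. the top-50 marker genes of a striatal cell
#' type), the fraction of its genes inside the analysis universe that are
#' also in the differential set:
#' `|signature and de_set| / |signature and universe|`.
#'
#' @param de_set Character vector of differential gene ids.
#' @param signatures Named list of character vectors.
#' @param universe Analysis universe (e.g. the minimally expressed genes).
#' @return A data frame `signature`, `n_in_universe`, `n_de`, `ratio`
#'   (`NA` when a signature has no genes in the universe).
#' @export
signature_overlap_ratio <- function(de_set, signatures, universe) {
  stopifnot(is.list(signatures), length(signatures) > 0)
  out <- lapply(names(signatures), function(nm) {
    s <- intersect(signatures[[nm]], universe)
    data.frame(signature = nm, n_in_universe = length(s),
               n_de = length(intersect(s, de_set)),
               ratio = if (length(s) == 0) NA_real_ else
                 length(intersect(s, de_set)) / length(s),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Hierarchical clustering with Euclidean distance and average linkage
#'
#' Agglomerative (UPGMA) merge tree over the rows of `x`.
#'
#' @param x Numeric matrix (>= 2 rows).
#' @param metric Distance metric for [stats::dist()].
#' @param linkage Linkage method for [stats::hclust()].
#' @return An object of class `hclust`.
#' @export
hcluster <- function(x, metric = "euclidean", linkage = "average") {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows to cluster")
  if (any(!is.finite(x))) stop("non-finite rows cannot be clustered")
  stats::hclust(stats::dist(x, method = metric), method = linkage)
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided hypergeometric tail probability of the overlap between a query
#' gene set and each category, against a fixed background universe, with
#' Benjamini-Hochberg adjustment across categories. Categories are
#' intersected with the background first.
#'
#' @param query Character vector of query gene ids (must be a subset of
#'   `background`).
#' @param categories Named list of character vectors.
#' @param background Character vector: the gene universe.
#' @return An `EnrichmentResult` data frame: `category_id`, `overlap`,
#'   `category_size`, `background_size`, `query_size`, `p`, `fdr`.
#' @export
enrich_hypergeometric <- function(query, categories, background) {
  query <- unique(query)
  background <- unique(background)
  if (!all(query %in% background))
    stop("query contains genes outside the background universe")
  N <- length(background)
  n <- length(query)
  out <- lapply(names(categories), function(nm) {
    cat_bg <- intersect(unique(categories[[nm]]), background)
    K <- length(cat_bg)
    k <- length(intersect(cat_bg, query))
    p <- if (K == 0) NA_real_ else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category_id = nm, overlap = k, category_size = K,
               background_size = N, query_size = n, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$fdr <- NA_real_
  ok <- !is.na(out$p)
  out$fdr[ok] <- bh_adjust(out$p[ok])
  out
}
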