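test_that("CPM definitions hold", {
  x <- matrix(c(10L, 990L, 5L, 95L), 2, 2)
  lib <- c(1e6, 100)
  expect_equal(cpm(x, lib_sizes = lib)[1, 1], 10)
  x2 <- matrix(rpois(40, 50), 10, 4)
  expect_true(all(abs(colSums(cpm(x2)) - 1e6) < 1e-6))
  # documented log formula at count 0
  x2[1, ] <- 0L
  eff <- colSums(x2)
  pc <- 2 * eff / mean(eff)
  lc <- cpm(x2, log = TRUE)
  expect_equal(lc[1, ], log2(pc / (eff + 2 * pc) * 1e6), ignore_attr = TRUE)
  expect_error(cpm(x2, lib_sizes = c(0, 1, 1, 1)), "library size")
})

test_that("log2 CPM agrees with the established implementation", {
  skip_if_not_installed("edgeR")
  x <- matrix(c(0L, 10L, 100L, 5L, 0L, 50L, 7L, 3L, 1L), 3, 3)
  nf <- c(0.9, 1.1, 1.0)
  mine <- cpm(x, norm_factors = nf, log = TRUE, prior = 2)
  ref <- edgeR::cpm(edgeR::DGEList(x, norm.factors = nf), log = TRUE,
                    prior.count = 2)
  expect_equal(unname(mine), unname(ref), tolerance = 1e-10)
})

test_that("the minimum-CPM filter applies the > threshold in >= k samples rule", {
  # libraries of 1e7 give gene A 0.2 CPM in 3 samples, gene B in only 2
  counts2 <- rbind(A = c(2L, 2L, 2L, 0L), B = c(2L, 2L, 0L, 0L),
                   C = c(50L, 50L, 50L, 50L))
  out <- filter_min_cpm(counts2, threshold = 0.1, min_samples = 3,
                        lib_sizes = rep(1e7, 4))
  expect_setequal(rownames(out), c("A", "C"))
  # identity when thresholds are vacuous
  out2 <- filter_min_cpm(counts2, threshold = 0, min_samples = 0)
  expect_identical(dim(out2), dim(counts2))
})

test_that("TMM factors satisfy their invariants and match hand computation", {
  # identical columns -> all factors 1
  x <- matrix(rep(c(10L, 50L, 200L, 1000L), 3), 4, 3)
  expect_equal(tmm_norm_factors(x), rep(1, 3))
  # geometric mean 1 always
  set.seed(4)
  y <- matrix(rnbinom(600, mu = 60, size = 3) + 1L, 100, 6)
  f <- tmm_norm_factors(y)
  expect_equal(exp(mean(log(f))), 1)
  expect_error(tmm_norm_factors(y[, 1, drop = FALSE]), "2 samples")
  expect_error(tmm_norm_factors(cbind(y[, 1], 0L)), "all-zero")
})

test_that("a two-sample spiked matrix reproduces the trimmed weighted-mean formula", {
  set.seed(9)
  base <- rpois(200, 100) + 1L
  obs <- base
  obs[1] <- 5000L  # one spiked gene, trimmed away
  x <- cbind(s1 = obs, s2 = base)
  f <- tmm_norm_factors(x)
  # independent evaluation of the doubly trimmed weighted mean
  lib <- colSums(x)
  m <- log2((x[, 1] / lib[1]) / (x[, 2] / lib[2]))
  a <- (log2(x[, 1] / lib[1]) + log2(x[, 2] / lib[2])) / 2
  w <- (lib[1] - x[, 1]) / (lib[1] * x[, 1]) + (lib[2] - x[, 2]) / (lib[2] * x[, 2])
  n <- length(m)
  keepm <- rank(m) >= floor(n * .3) + 1 & rank(m) <= n - floor(n * .3)
  keepa <- rank(a) >= floor(n * .05) + 1 & rank(a) <= n - floor(n * .05)
  keep <- keepm & keepa
  raw <- 2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  # reference column is s2 (factor 1 before rescaling)
  expected <- c(raw, 1) / exp(mean(log(c(raw, 1))))
  expect_equal(unname(f), unname(expected))
})

test_that("TMM matches the established implementation on simulated data", {
  skip_if_not_installed("edgeR")
  sim <- make_count_matrix(count_sim_config(seed = 11L, n_genes = 2000L))
  f1 <- tmm_norm_factors(sim$counts)
  f2 <- edgeR::calcNormFactors(sim$counts, method = "TMM")
  expect_equal(unname(f1), unname(f2), tolerance = 1e-12)
})

test_that("TMM recovers a planted composition bias within 2%", {
  # 10% of genes quadrupled in sample 1 (asymmetric DE, well inside the 30%
  # trim capacity); equalizing non-DE CPM requires f1/f2 = lib2/lib1
  set.seed(8)
  mu <- rexp(5000, 1 / 100)
  x1 <- rpois(5000, mu)
  x2 <- rpois(5000, mu)
  de <- seq_len(500)
  x1[de] <- rpois(500, 4 * mu[de])
  f <- tmm_norm_factors(cbind(x1, x2))
  ratio <- sum(mu) / (sum(mu) + 3 * sum(mu[de]))
  planted <- c(sqrt(ratio), sqrt(1 / ratio))
  expect_lt(max(abs(f / planted - 1)), 0.02)
})

test_that("group-mean filter implements 'either group' semantics", {
  lc <- rbind(g1 = c(0.5, 0.6, -2, -2, -2),
              g2 = c(-1, -1, -3, -3, -3),
              g3 = c(-5, -5, 4, 4, 4))
  groups <- c("LPS", "LPS", "IL4", "IL4", "IL4")
  keep <- filter_group_mean(lc, groups)
  expect_equal(unname(keep), c(TRUE, FALSE, TRUE))
  expect_error(filter_group_mean(lc, groups, which_groups = "XX"),
               "unknown group")
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  p <- c(0.005, 0.01, 0.03, 0.04)
  expect_equal(bh_adjust(p), bh_brute(p))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(2)
  for (i in 1:50) {
    p <- runif(sample(1:10, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
    expect_equal(bh_adjust(p), p.adjust(p, "BH"))  # independent cross-check
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("the moderated test matches the established voom pipeline", {
  skip_if_not_installed("limma")
  skip_if_not_installed("edgeR")
  sim <- make_count_matrix(count_sim_config(seed = 13L, n_genes = 1500L))
  counts <- filter_min_cpm(sim$counts)
  nf <- tmm_norm_factors(counts)
  det <- de_test(counts, sim$groups, norm_factors = nf)
  sel <- sim$groups %in% c("LPS", "IL4")
  d <- edgeR::DGEList(counts[, sel], norm.factors = nf[sel])
  design <- stats::model.matrix(~ factor(as.character(sim$groups[sel]),
                                         levels = c("IL4", "LPS")))
  v <- limma::voom(d, design)
  fit <- limma::eBayes(limma::lmFit(v, design))
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  expect_equal(det$log2fc, unname(tt$logFC), tolerance = 1e-8)
  expect_equal(det$p, unname(tt$P.Value), tolerance = 1e-4)
})

test_that("swapping the contrast groups negates every log fold change", {
  sim <- make_count_matrix(count_sim_config(seed = 14L, n_genes = 600L))
  nf <- tmm_norm_factors(sim$counts)
  d1 <- de_test(sim$counts, sim$groups, c("LPS", "IL4"), norm_factors = nf)
  d2 <- de_test(sim$counts, sim$groups, c("IL4", "LPS"), norm_factors = nf)
  expect_equal(d1$log2fc, -d2$log2fc)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
})

test_that("DE thresholds split significant and high-magnitude sets", {
  det <- data.frame(gene_id = c("a", "b", "c", "d"),
                    log2fc = c(0.5, 1.5, -2, 0.2),
                    p = c(0.001, 0.001, 0.001, 0.5),
                    fdr = c(0.04, 0.01, 0.02, 0.6))
  sets <- apply_de_thresholds(det)
  expect_setequal(sets$significant, c("a", "b", "c"))
  expect_setequal(sets$high_magnitude, c("b", "c"))
})

test_that("reference z-scores standardize the reference group", {
  set.seed(3)
  x <- matrix(rnorm(60, 5, 2), 6, 10)
  groups <- rep(c("LPS", "IL4"), each = 5)
  z <- zscore_vs_reference(x, groups, "IL4")
  ref <- z[, groups == "IL4"]
  expect_equal(unname(rowMeans(ref)), rep(0, 6))
  expect_equal(unname(apply(ref, 1, sd)), rep(1, 6))
  # adding a constant to a row shifts z consistently with the formula
  x2 <- x
  x2[1, ] <- x2[1, ] + 10
  z2 <- zscore_vs_reference(x2, groups, "IL4")
  expect_equal(z2[1, ], z[1, ])
  # constant reference -> missing, not infinite
  x3 <- x
  x3[2, groups == "IL4"] <- 7
  z3 <- zscore_vs_reference(x3, groups, "IL4")
  expect_true(all(is.na(z3[2, ])))
  expect_error(zscore_vs_reference(x, rep(c("LPS", "IL4"), c(9, 1)), "IL4"),
               "at least 2")
})

test_that("FPKM is CPM over kilobases", {
  x <- matrix(c(10L, 90L), 1, 2, dimnames = list("g1", NULL))
  lib <- c(1e6, 1e6)
  expect_equal(fpkm(x, c(g1 = 2), lib_sizes = lib)[1, ], c(5, 45))
  expect_equal(fpkm(x, c(g1 = 1), lib_sizes = lib),
               cpm(x, lib_sizes = lib))
  set.seed(5)
  y <- matrix(rpois(30, 40), 5, 6,
              dimnames = list(paste0("g", 1:5), NULL))
  len <- setNames(runif(5, 0.5, 4), rownames(y))
  expect_equal(fpkm(y, len), cpm(y) / len)
  expect_error(fpkm(y, len[1:3]), "missing gene length")
})

test_that("MDS distances behave as leading log fold changes", {
  set.seed(6)
  l <- matrix(rnorm(300), 100, 3)
  l <- cbind(l, l[, 3])  # duplicated sample
  mds <- mds_coordinates(l, top_n = 100)
  d <- attr(mds, "distances")
  expect_equal(d[3, 4], 0)
  # with top_n = all genes, 3 points embed exactly in 2-D
  m3 <- mds_coordinates(l[, 1:3], top_n = 100)
  emb <- as.matrix(dist(cbind(m3$dim1, m3$dim2)))
  expect_equal(unname(emb), unname(attr(m3, "distances")), tolerance = 1e-8)
  expect_error(mds_coordinates(l[, 1:2]), "at least 3")
  # separated groups: within-group distances < between-group distances
  sim <- make_count_matrix(count_sim_config(seed = 15L, n_genes = 2000L,
                                            de_fraction = 0.3, de_log2fc = 4))
  lc <- cpm(sim$counts, log = TRUE)
  dd <- attr(mds_coordinates(lc), "distances")
  lps <- which(sim$groups == "LPS")
  il4 <- which(sim$groups == "IL4")
  expect_lt(max(dd[lps, lps]), min(dd[lps, il4]))
  expect_lt(max(dd[il4, il4]), min(dd[lps, il4]))
})

test_that("signature overlap ratios follow the definition", {
  uni <- paste0("g", 1:100)
  de <- paste0("g", 1:10)
  sigs <- list(a = paste0("g", 1:50),            # 10 of 50 in the DE set
               b = paste0("g", 101:120),         # outside universe
               c = paste0("g", 90:99))           # disjoint from de
  r <- signature_overlap_ratio(de, sigs, uni)
  expect_equal(r$ratio[r$signature == "a"], 0.2)
  expect_true(is.na(r$ratio[r$signature == "b"]))
  expect_equal(r$ratio[r$signature == "c"], 0)
  r2 <- signature_overlap_ratio(uni, sigs[c(1, 3)], uni)
  expect_true(all(r2$ratio == 1))
})

test_that("UPGMA clustering merges by hand-computed heights", {
  # 3 points on a line with pairwise distances 1, 2, 3
  x <- matrix(c(0, 1, 3), ncol = 1)
  hc <- hcluster(x)
  expect_equal(hc$height, c(1, 2.5))  # first merge at 1, then (2+3)/2
  # duplicated rows merge at height 0 first
  y <- rbind(c(1, 2), c(5, 7), c(1, 2))
  hc2 <- hcluster(y)
  expect_equal(hc2$height[1], 0)
  # merge heights are non-decreasing
  set.seed(7)
  z <- matrix(rnorm(80), 20, 4)
  expect_true(all(diff(hcluster(z)$height) >= -1e-12))
  expect_error(hcluster(rbind(c(1, NaN), c(0, 1))), "non-finite")
})

test_that("hypergeometric enrichment equals exact enumeration", {
  bg <- paste0("g", 1:20)
  categories <- list(cat5 = paste0("g", 1:5), all = bg,
                     none = paste0("g", 18:20))
  query <- paste0("g", c(1, 2, 3, 10))
  res <- enrich_hypergeometric(query, categories, bg)
  # brute force: P(overlap >= 3) for |cat|=5, |bg|=20, |query|=4
  brute <- sum(choose(5, 3:4) * choose(15, 4 - (3:4))) / choose(20, 4)
  expect_equal(res$p[res$category_id == "cat5"], brute)
  expect_equal(res$p[res$category_id == "all"], 1)
  expect_gt(res$p[res$category_id == "none"], 0.4)
  expect_true(all(res$overlap <= pmin(res$category_size, res$query_size)))
  expect_error(enrich_hypergeometric(c(query, "gX"), categories, bg),
               "outside the background")
})

test_that("cpm-then-filter commutes with column subsetting on kept genes", {
  sim <- make_count_matrix(count_sim_config(seed = 16L, n_genes = 500L))
  x <- sim$counts
  keep <- attr(filter_min_cpm(x), "keep")
  sub <- x[, 1:6]
  full_cpm <- cpm(x)[keep, 1:6]
  sub_cpm <- cpm(sub)[keep, ]
  expect_equal(full_cpm, sub_cpm)
})
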