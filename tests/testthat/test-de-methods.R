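test_that("size factors match the median-of-ratios definition", {
  # identical columns -> unit factors
  cm <- count_matrix(matrix(c(5, 9, 20), 3, 4,
                            dimnames = list(letters[1:3], NULL)),
                     c("A", "A", "B", "B"))
  expect_equal(unname(size_factors(cm)), rep(1, 4))
  # doubled column: ratios to the per-gene geometric mean give (1/sqrt2, sqrt2)
  m <- cbind(s1 = c(10, 100, 4), s2 = c(20, 200, 8))
  rownames(m) <- letters[1:3]
  cm2 <- count_matrix(m, c("A", "B"))
  expect_equal(unname(size_factors(cm2)), c(1 / sqrt(2), sqrt(2)))
  # independent brute-force oracle on an asymmetric 3x3 matrix
  m3 <- matrix(c(10, 100, 4, 20, 200, 8, 10, 100, 4), 3, 3,
               dimnames = list(letters[1:3], paste0("s", 1:3)))
  gm <- apply(m3, 1, function(r) prod(r)^(1 / 3))
  oracle <- apply(m3 / gm, 2, median)
  cm3 <- count_matrix(m3, c("A", "A", "B"))
  expect_equal(size_factors(cm3), oracle)
  # all-zero-containing genes only -> error
  bad <- count_matrix(matrix(c(0, 1, 1, 0), 2, 2,
                             dimnames = list(c("a", "b"), NULL)),
                      c("A", "B"))
  expect_error(size_factors(bad), "all-positive")
})

test_that("dispersion estimation recovers planted parameters", {
  cfg <- sim_config(n_genes = 2000, n_per_group = 10, de_fraction = 0,
                    disp_a0 = 0, disp_a1 = 0.1, seed = 3)
  sim <- simulate_counts(cfg)
  dm <- estimate_dispersion(sim$counts, size_factors(sim$counts))
  expect_gt(dm$common_dispersion, 0.08)
  expect_lt(dm$common_dispersion, 0.12)
  # Poisson data -> essentially zero
  cfg0 <- sim_config(n_genes = 2000, n_per_group = 10, de_fraction = 0,
                     disp_a0 = 0, disp_a1 = 0, libsize_cv = 0, seed = 3)
  sim0 <- simulate_counts(cfg0)
  dm0 <- estimate_dispersion(sim0$counts, size_factors(sim0$counts))
  expect_lte(dm0$common_dispersion, 0.01)
  # trend recovery within 25%
  cfgt <- sim_config(n_genes = 2000, n_per_group = 10, de_fraction = 0,
                     disp_a0 = 1, disp_a1 = 0.05, seed = 3)
  simt <- simulate_counts(cfgt)
  dmt <- estimate_dispersion(simt$counts, size_factors(simt$counts))
  expect_lt(abs(dmt$a0 / 1 - 1), 0.25)
  expect_lt(abs(dmt$a1 / 0.05 - 1), 0.25)
  # single sample per group is unidentifiable
  one <- count_matrix(matrix(1:8, 4, 2,
                             dimnames = list(letters[1:4], NULL)),
                      c("A", "B"))
  expect_error(estimate_dispersion(one, c(1, 1)), "2 samples")
})

test_that("nb_exact_test matches enumeration, symmetry and Poisson limits", {
  # symmetric observation is the mode -> p = 1
  expect_equal(nb_exact_test(7, 7, 5, 5, 0.1), 1)
  # k_S = 2 equal groups: direct enumeration over (0,2),(1,1),(2,0)
  expect_equal(nb_exact_test(0, 2, 3, 3, 0.2),
               brute_nb_exact(0, 2, 3, 3, 0.2), tolerance = 1e-12)
  # brute-force agreement across a parameter sweep
  for (disp in c(0, 0.1, 1)) {
    for (ks in c(1, 5, 17)) {
      for (ka in 0:ks) {
        expect_equal(nb_exact_test(ka, ks - ka, 4, 7, disp),
                     brute_nb_exact(ka, ks - ka, 4, 7, disp),
                     tolerance = 1e-10)
      }
    }
  }
  # Poisson limit with equal groups = central two-sided binomial test
  for (ka in c(0, 3, 10, 14)) {
    expect_equal(nb_exact_test(ka, 20 - ka, 6, 6, 0),
                 binom.test(ka, 20, 0.5)$p.value, tolerance = 1e-9)
  }
  expect_error(nb_exact_test(-1, 2, 3, 3, 0.1), "negative")
})

test_that("bh_adjust implements the step-up rule", {
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  # oracle: stats::p.adjust on random vectors; monotone in rank order
  set.seed(1)
  for (i in 1:5) {
    p <- runif(50)^2
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
})

test_that("the two NB methods share the exact-test core", {
  sh <- shared_sim()
  sf <- size_factors(sh$sim$counts)
  disp <- rep(0.1, nrow(sh$sim$counts$counts))
  a <- coregtopo:::.exact_test_all(sh$sim$counts, sf, disp)
  b <- coregtopo:::.exact_test_all(sh$sim$counts, sf, disp)
  expect_identical(a$p, b$p)
  # all four methods: one record per gene, p and adj_p in [0,1], adj >= p
  for (m in DE_METHODS) {
    res <- run_de_method(sh$sim$counts, m)
    expect_identical(nrow(res), nrow(sh$sim$counts$counts))
    expect_true(all(res$p_value >= 0 & res$p_value <= 1))
    expect_true(all(res$adj_p_value >= res$p_value - 1e-12))
  }
})

test_that("all-zero genes get p = 1 and planted signal is recovered", {
  cfg <- sim_config(n_genes = 600, n_tfs = 50, n_mirnas = 30,
                    n_per_group = 20, seed = 3)
  sim <- simulate_counts(cfg)
  cm <- sim$counts
  cm$counts[1, ] <- 0L  # force an all-zero gene
  res <- run_deseq_like(cm)
  expect_equal(res$p_value[1], 1)
  expect_equal(res$log2fc[1], 0)
  # >= 60% of strong planted effects recovered at adj p < 0.05
  big <- sim$truth$is_de & abs(sim$truth$true_log2fc) >= 2 &
    sim$truth$gene_id != sim$truth$gene_id[1]
  expect_gte(mean(res$adj_p_value[big] < 0.05), 0.6)
  # DE set size within [0.8, 1.2] x planted count
  n_hit <- length(significant_genes(res)$genes)
  expect_gt(n_hit, 0.8 * sum(sim$truth$is_de))
  expect_lt(n_hit, 1.2 * sum(sim$truth$is_de))
})

test_that("vst matches its closed forms and stabilizes the variance", {
  sh <- shared_sim()
  sf <- size_factors(sh$sim$counts)
  dm <- estimate_dispersion(sh$sim$counts, sf)
  # Poisson case: tau(q) = 2 sqrt(q)
  dm0 <- dm; dm0$a0 <- 0; dm0$a1 <- 0
  tm0 <- vst_transform(sh$sim$counts, dm0)
  q <- sweep(sh$sim$counts$counts, 2, sf, "/")
  expect_equal(tm0$values, 2 * sqrt(q), tolerance = 1e-12)
  # constant alpha: derivative of asinh form equals 1/sqrt(w) numerically
  alpha <- 0.15
  tau <- function(q) (2 / sqrt(alpha)) * asinh(sqrt(alpha * q))
  for (qq in c(10, 100, 1000)) {
    h <- qq * 1e-6
    expect_equal((tau(qq + h) - tau(qq - h)) / (2 * h),
                 1 / sqrt(qq + alpha * qq^2), tolerance = 1e-6)
  }
  # flatness: per-decile SD of transformed values varies < 2x
  cfgt <- sim_config(n_genes = 3000, n_per_group = 10, de_fraction = 0,
                     disp_a0 = 1, disp_a1 = 0.05, seed = 21)
  simt <- simulate_counts(cfgt)
  sft <- size_factors(simt$counts)
  dmt <- estimate_dispersion(simt$counts, sft)
  tmt <- vst_transform(simt$counts, dmt)
  mu <- rowMeans(sweep(simt$counts$counts, 2, sft, "/"))
  keep <- mu > 5   # counting noise floor dominates below
  sds <- apply(tmt$values[keep, ], 1, sd)
  dec <- tapply(sds, cut(rank(mu[keep], ties.method = "first"), 10), median)
  expect_lt(max(dec) / min(dec), 2)
  # non-monotone variance fit errors
  dm_bad <- dm; dm_bad$a1 <- -0.1
  expect_error(vst_transform(sh$sim$counts, dm_bad), "monotone")
})

test_that("voom weights behave", {
  sh <- shared_sim()
  tm <- voom_transform(sh$sim$counts)
  expect_true(all(is.finite(tm$weights)) && all(tm$weights > 0))
  # doubling library sizes barely changes log-cpm; the +0.5/+1
  # pseudocount effect is ~0.25/((k+0.5) ln 2), so < 0.01 needs k >= ~36
  cm2 <- count_matrix(2L * sh$sim$counts$counts, sh$sim$counts$groups)
  tm2 <- voom_transform(cm2)
  big <- sh$sim$counts$counts >= 40
  expect_lt(max(abs(tm2$values[big] - tm$values[big])), 0.01)
  med <- sh$sim$counts$counts >= 10
  expect_lt(max(abs(tm2$values[med] - tm$values[med])), 0.04)
  # identical genes -> identical weights
  flat <- count_matrix(matrix(rep(c(4L, 9L, 25L, 50L), each = 12), 12, 4,
                              byrow = TRUE,
                              dimnames = list(paste0("g", 1:12), NULL)),
                       c("A", "A", "B", "B"))
  wt <- voom_transform(flat)$weights
  expect_true(all(abs(wt / wt[1, 1] - 1) < 1e-12))
  expect_error(voom_transform(count_matrix(
    matrix(1:8, 4, 2, dimnames = list(letters[1:4], NULL)), c("A", "B"))),
    ">= 10 genes")
})

test_that("moderated t has the right limits and null calibration", {
  set.seed(77)
  x <- matrix(rnorm(5000 * 10), 5000, 10,
              dimnames = list(sprintf("g%04d", 1:5000), NULL))
  groups <- rep(c("A", "B"), each = 5)
  cm_like <- transformed_matrix(x, transform_name = "vst", groups = groups)
  # d0 = 0 reduces to the ordinary two-sample equal-variance t-test
  res0 <- moderated_t(cm_like, prior_df = 0)
  ts <- vapply(1:50, function(i)
    t.test(x[i, 6:10], x[i, 1:5], var.equal = TRUE)$p.value, numeric(1))
  expect_equal(res0$p_value[1:50], ts, tolerance = 1e-10)
  # d0 = Inf pools all variances: p monotone in |effect|
  resI <- moderated_t(cm_like, prior_df = Inf)
  o <- order(abs(resI$log2fc))
  expect_true(all(diff(resI$p_value[o]) <= 1e-4))
  # Gaussian null: raw p approximately uniform (KS distance < 0.03)
  res <- moderated_t(cm_like)
  ks <- max(abs(sort(res$p_value) - (1:5000) / 5000))
  expect_lt(ks, 0.03)
})

test_that("significant_genes applies a strict threshold", {
  p <- c(0.2, 1, 1, 1)
  res <- coregtopo:::.de_result(letters[1:4], rep(0, 4), p, "deseq_like")
  expect_length(significant_genes(res, 0.05)$genes, 0)
  # alpha = 1 with strict '<' keeps only adj_p < 1
  expect_identical(significant_genes(res, 1)$genes, "a")
})

test_that("edgeR-like and DESeq-like DE sets agree on simulated data", {
  cfg <- sim_config(n_genes = 1500, n_tfs = 120, n_mirnas = 60,
                    n_per_group = 10, de_fraction = 0.2, seed = 31)
  sim <- simulate_counts(cfg)
  a <- significant_genes(run_deseq_like(sim$counts))$genes
  b <- significant_genes(run_edger_like(sim$counts))$genes
  expect_gte(overlap_coefficient(a, b), 0.8)
})
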