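test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(de_fraction = 1.2), "de_fraction")
  expect_error(sim_config(de_fraction = NA), "finite")
  expect_error(sim_config(n_tfs = 30, n_genes = 20), "n_tfs")
  expect_error(sim_config(lfc_scale = 0), "lfc_scale")
})

test_that("simulate_counts honours the planted design", {
  cfg <- sim_config(n_genes = 300, n_tfs = 40, n_mirnas = 20,
                    n_per_group = 4, seed = 5)
  out <- simulate_counts(cfg)
  expect_s3_class(out$counts, "count_matrix")
  expect_identical(dim(out$counts$counts), c(300L, 8L))
  expect_true(all(out$counts$counts >= 0))
  expect_identical(sum(out$truth$is_de), as.integer(round(0.35 * 300)))
  # no planted effect <=> zero log2fc, and |lfc| >= 1 on DE genes
  expect_true(all(out$truth$true_log2fc[!out$truth$is_de] == 0))
  expect_true(all(abs(out$truth$true_log2fc[out$truth$is_de]) >= 1))
  # dispersion follows the declared trend
  expect_equal(out$truth$true_dispersion,
               cfg$disp_a1 + cfg$disp_a0 / out$truth$true_mu)
  # de_fraction = 0 plants nothing
  none <- simulate_counts(sim_config(n_genes = 100, n_tfs = 20, n_mirnas = 10,
                                     n_per_group = 3, de_fraction = 0,
                                     seed = 5))
  expect_identical(sum(none$truth$is_de), 0L)
})

test_that("simulation is deterministic given the seed", {
  cfg <- sim_config(n_genes = 200, n_tfs = 30, n_mirnas = 15,
                    n_per_group = 3, seed = 42)
  a <- simulate_counts(cfg); b <- simulate_counts(cfg)
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth, b$truth)
  dba <- simulate_interaction_db(cfg); dbb <- simulate_interaction_db(cfg)
  expect_identical(dba$edges, dbb$edges)
  da <- simulate_disease_annotation(dba, cfg, a$truth)
  db2 <- simulate_disease_annotation(dbb, cfg, b$truth)
  expect_identical(da$nodes, db2$nodes)
  # different seed, different data
  c2 <- simulate_counts(sim_config(n_genes = 200, n_tfs = 30, n_mirnas = 15,
                                   n_per_group = 3, seed = 43))
  expect_false(identical(a$counts$counts, c2$counts$counts))
})

test_that("NB mean-variance moments match the dispersion trend", {
  # one long two-group experiment: per-gene sample variance over 1e4
  # replicates should track mu + alpha(mu) mu^2 within 10% per mean decile
  cfg <- sim_config(n_genes = 200, n_tfs = 10, n_mirnas = 5,
                    n_per_group = 5000, de_fraction = 0, disp_a0 = 0,
                    disp_a1 = 0.1, libsize_cv = 0, seed = 8)
  out <- simulate_counts(cfg)
  mu <- out$truth$true_mu
  v_emp <- apply(out$counts$counts, 1, var)
  v_th <- mu + 0.1 * mu^2
  dec <- cut(rank(mu, ties.method = "first"), 10)
  ratio <- tapply(v_emp / v_th, dec, mean)
  expect_true(all(abs(ratio - 1) < 0.10))
})

test_that("column sums recover the planted size factors", {
  cfg <- sim_config(n_genes = 5000, n_per_group = 6, de_fraction = 0,
                    libsize_cv = 0.4, seed = 12)
  out <- simulate_counts(cfg)
  planted <- attr(out$truth, "size_factors")
  cs <- colSums(out$counts$counts)
  rel <- (cs / mean(cs)) / (planted / mean(planted))
  expect_true(max(abs(rel - 1)) < 0.05)
})

test_that("interaction db is typed, deduplicated and heavy-tailed", {
  cfg <- sim_config(seed = 2)
  db <- simulate_interaction_db(cfg)
  expect_s3_class(db, "interaction_db")
  expect_setequal(unique(db$edges$type),
                  c("TF->gene", "TF->miRNA", "miRNA->gene", "miRNA->miRNA"))
  expect_false(any(db$edges$source == db$edges$target))
  expect_identical(anyDuplicated(db$edges), 0L)
  outdeg <- table(db$edges$source)
  expect_gt(max(outdeg), 5 * median(outdeg))
  # no miRNAs -> only TF->gene edges
  db2 <- simulate_interaction_db(sim_config(n_genes = 100, n_tfs = 20,
                                            n_mirnas = 0, seed = 2))
  expect_setequal(unique(db2$edges$type), "TF->gene")
  expect_error(simulate_interaction_db(
    sim_config(n_genes = 50, n_tfs = 0, n_mirnas = 0, seed = 1)),
    "no regulators")
})

test_that("disease annotation is enriched around planted-DE regulators", {
  sh <- shared_sim()
  cfg <- sh$cfg; db <- sh$db; truth <- sh$sim$truth
  dis <- simulate_disease_annotation(db, cfg, truth)
  expect_true(all(dis$nodes %in% db$node_types$node))
  expect_identical(length(dis$nodes),
                   as.integer(round(cfg$disease_fraction * nrow(db$node_types))))
  tfs <- db$node_types$node[db$node_types$type == "TF"]
  de_tfs <- intersect(truth$gene_id[truth$is_de], tfs)
  frac_in <- mean(de_tfs %in% dis$nodes)
  expect_gt(frac_in, cfg$disease_fraction)
  # boundary fractions
  all_cfg <- sim_config(n_genes = 400, n_tfs = 50, n_mirnas = 30,
                        n_per_group = 6, disease_fraction = 1, seed = 101)
  expect_setequal(simulate_disease_annotation(db, all_cfg, truth)$nodes,
                  db$node_types$node)
  zero_cfg <- sim_config(n_genes = 400, n_tfs = 50, n_mirnas = 30,
                         n_per_group = 6, disease_fraction = 0, seed = 101)
  expect_length(simulate_disease_annotation(db, zero_cfg, truth)$nodes, 0)
})

test_that("cohort-scale simulation has the right shape", {
  cfg <- sim_config(n_genes = 20501, n_tfs = 800, n_mirnas = 300,
                    n_per_group = 50, seed = 9)
  out <- simulate_counts(cfg)
  expect_identical(dim(out$counts$counts), c(20501L, 100L))
})

test_that("TSV round-trips preserve the three input objects", {
  sh <- shared_sim()
  td <- withr::local_tempdir()
  p <- function(f) file.path(td, f)
  write_count_matrix(sh$sim$counts, p("c.tsv"), p("g.tsv"))
  cm2 <- read_count_matrix(p("c.tsv"), p("g.tsv"))
  expect_identical(cm2$counts, sh$sim$counts$counts)
  expect_identical(cm2$groups, sh$sim$counts$groups)
  write_interaction_db(sh$db, p("e.tsv"), p("n.tsv"))
  db2 <- read_interaction_db(p("e.tsv"), p("n.tsv"))
  expect_identical(db2$edges, sh$db$edges)
  dis <- simulate_disease_annotation(sh$db, sh$cfg, sh$sim$truth)
  write_disease_annotation(dis, p("d.tsv"))
  expect_identical(read_disease_annotation(p("d.tsv"))$nodes, dis$nodes)
})
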