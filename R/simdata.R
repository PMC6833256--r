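#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator. Counts are drawn from
#' a negative binomial with mean `mu` and variance `mu + alpha(mu) * mu^2`,
#' where the dispersion follows the mean-dependent trend
#' `alpha(mu) = disp_a1 + disp_a0 / mu`. A fixed fraction of genes carries a
#' planted log2 fold change with `|lfc| >= 1` (shifted exponential with
#' scale `lfc_scale`), preferentially placed on regulators and their targets
#' (weight 3:1) so that downstream disease networks built from different DE
#' calls share structure.
#'
#' @param n_genes number of genes in the count matrix (the first `n_tfs` of
#'   them are transcription factors).
#' @param n_tfs number of TF nodes.
#' @param n_mirnas number of miRNA nodes (not part of the count matrix;
#'   recovered downstream by enrichment).
#' @param n_per_group samples per condition (two conditions, "A" and "B").
#' @param de_fraction fraction of genes with a planted fold change.
#' @param lfc_scale scale of the exponential spread of planted `|log2 FC|`
#'   above the minimum of 1.
#' @param disp_a0,disp_a1 dispersion trend coefficients,
#'   `alpha(mu) = disp_a1 + disp_a0 / mu`.
#' @param libsize_cv coefficient of variation of the log-normal per-sample
#'   size factors.
#' @param disease_fraction fraction of the node universe annotated to the
#'   simulated disease.
#' @param driver_mirna_fraction fraction of miRNAs simulated as disease
#'   drivers: their targets and regulator TFs are sampled with extra weight
#'   toward planted-DE genes, so that miRNA recovery by enrichment has
#'   signal to find.
#' @param seed integer seed; all generator randomness derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000, n_tfs = 150, n_mirnas = 80,
                       n_per_group = 10, de_fraction = 0.35,
                       lfc_scale = 1, disp_a0 = 1, disp_a1 = 0.05,
                       libsize_cv = 0.2, disease_fraction = 0.35,
                       driver_mirna_fraction = 0.3, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
              n_mirnas = as.integer(n_mirnas),
              n_per_group = as.integer(n_per_group),
              de_fraction = de_fraction, lfc_scale = lfc_scale,
              disp_a0 = disp_a0, disp_a1 = disp_a1,
              libsize_cv = libsize_cv, disease_fraction = disease_fraction,
              driver_mirna_fraction = driver_mirna_fraction,
              seed = as.integer(seed))
  num <- unlist(cfg[c("de_fraction", "lfc_scale", "disp_a0", "disp_a1",
                      "libsize_cv", "disease_fraction",
                      "driver_mirna_fraction")])
  if (any(!is.finite(num)))
    stop("sim_config: all numeric fields must be finite")
  if (cfg$n_genes < 1 || cfg$n_per_group < 1)
    stop("sim_config: n_genes and n_per_group must be positive")
  if (cfg$n_tfs < 0 || cfg$n_mirnas < 0 || cfg$n_tfs > cfg$n_genes)
    stop("sim_config: need 0 <= n_tfs <= n_genes and n_mirnas >= 0")
  for (f in c("de_fraction", "disease_fraction", "driver_mirna_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("sim_config: ", f, " must lie in [0, 1]")
  if (cfg$lfc_scale <= 0 || cfg$disp_a0 < 0 || cfg$disp_a1 < 0 ||
      cfg$libsize_cv < 0)
    stop("sim_config: lfc_scale must be > 0; disp_a0, disp_a1, libsize_cv >= 0")
  structure(cfg, class = "sim_config")
}

#' Count matrix with two-group sample annotation
#'
#' @param counts non-negative integer matrix, genes x samples, with unique
#'   rownames (gene ids) and colnames (sample ids).
#' @param groups character/factor of "A"/"B" per sample.
#' @return an object of class `count_matrix` with elements `counts` and
#'   `groups` (a factor named by sample).
#' @export
count_matrix <- function(counts, groups) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample_%03d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts)))
    stop("count_matrix: gene ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("count_matrix: counts must be non-negative integers")
  groups <- factor(as.character(groups), levels = c("A", "B"))
  if (length(groups) != ncol(counts) || anyNA(groups))
    stop("count_matrix: groups must be one of 'A','B' per sample")
  if (!all(c("A", "B") %in% groups))
    stop("count_matrix: both groups must be non-empty")
  names(groups) <- colnames(counts)
  structure(list(counts = counts, groups = groups), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples (%d A, %d B)\n",
              nrow(x$counts), ncol(x$counts),
              sum(x$groups == "A"), sum(x$groups == "B")))
  invisible(x)
}

# Heavy-tailed out-degree: discrete Pareto with minimum dmin, exponent gam,
# capped at dmax.
.powerlaw_degrees <- function(n, dmin, gam, dmax) {
  d <- floor(dmin * runif(n)^(-1 / (gam - 1)))
  pmin(pmax(d, dmin), dmax)
}

# Shared structural core: gene/TF/miRNA universe, typed edges and the
# planted-DE gene assignment. Deterministic given config (own seed stream),
# so simulate_counts and simulate_interaction_db agree on structure.
.sim_core <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, "db"), {
    n_genes <- config$n_genes
    gene_ids <- sprintf("g%05d", seq_len(n_genes))
    tf_ids <- if (config$n_tfs > 0) gene_ids[seq_len(config$n_tfs)] else character()
    mirna_ids <- if (config$n_mirnas > 0)
      sprintf("mir%04d", seq_len(config$n_mirnas)) else character()
    non_tf_genes <- setdiff(gene_ids, tf_ids)

    src <- tgt <- typ <- list()
    add_edges <- function(s, t, ty) {
      k <- length(src) + 1L
      src[[k]] <<- s; tgt[[k]] <<- t; typ[[k]] <<- rep(ty, length(s))
    }

    # TF -> gene (targets may themselves be TFs: TFs are genes)
    if (length(tf_ids) > 0) {
      dmax <- max(10L, round(0.08 * n_genes))
      degs <- .powerlaw_degrees(length(tf_ids), dmin = 12, gam = 2.3, dmax = dmax)
      for (i in seq_along(tf_ids)) {
        pool <- setdiff(gene_ids, tf_ids[i])
        t_i <- sample(pool, min(degs[i], length(pool)))
        add_edges(rep(tf_ids[i], length(t_i)), t_i, "TF->gene")
      }
    }
    tf_targets <- unique(unlist(tgt))

    # Planted DE genes: regulators and their targets weighted 3:1.
    regulators <- unique(unlist(src))
    w <- rep(1, n_genes)
    w[gene_ids %in% c(regulators, tf_targets)] <- 3
    n_de <- round(config$de_fraction * n_genes)
    de_genes <- if (n_de > 0) sample(gene_ids, n_de, prob = w) else character()
    is_de <- gene_ids %in% de_genes
    de_tfs <- intersect(de_genes, tf_ids)

    drivers <- character()
    if (length(mirna_ids) > 0) {
      n_drv <- round(config$driver_mirna_fraction * length(mirna_ids))
      drivers <- if (n_drv > 0) sample(mirna_ids, n_drv) else character()

      # miRNA -> gene; driver miRNAs co-target the deregulated module
      for (m in mirna_ids) {
        if (m %in% drivers) {
          d <- .powerlaw_degrees(1, dmin = 18, gam = 2.5,
                                 dmax = max(30L, round(0.05 * n_genes)))
          wt <- ifelse(is_de, 8, 1)
        } else {
          d <- .powerlaw_degrees(1, dmin = 4, gam = 2.3,
                                 dmax = max(10L, round(0.03 * n_genes)))
          wt <- rep(1, n_genes)
        }
        t_m <- sample(gene_ids, min(d, n_genes), prob = wt)
        add_edges(rep(m, length(t_m)), t_m, "miRNA->gene")
      }

      # TF -> miRNA; driver miRNAs are regulated mostly by DE TFs
      if (length(tf_ids) > 0) {
        for (m in mirna_ids) {
          if (m %in% drivers) {
            k <- sample(10:18, 1)
            wt <- ifelse(tf_ids %in% de_tfs, 25, 1)
          } else {
            k <- sample(0:4, 1)
            wt <- rep(1, length(tf_ids))
          }
          if (k > 0) {
            r_m <- sample(tf_ids, min(k, length(tf_ids)), prob = wt)
            add_edges(r_m, rep(m, length(r_m)), "TF->miRNA")
          }
        }
        if (!any(unlist(typ) == "TF->miRNA"))
          add_edges(tf_ids[1], mirna_ids[1], "TF->miRNA")
      }

      # miRNA -> miRNA
      if (length(mirna_ids) >= 2) {
        for (m in mirna_ids) {
          if (runif(1) < 0.2) {
            t_m <- sample(setdiff(mirna_ids, m), sample(1:2, 1))
            add_edges(rep(m, length(t_m)), t_m, "miRNA->miRNA")
          }
        }
        if (!any(unlist(typ) == "miRNA->miRNA"))
          add_edges(mirna_ids[1], mirna_ids[2], "miRNA->miRNA")
      }
    }

    edges <- data.frame(source = unlist(src), target = unlist(tgt),
                        type = unlist(typ), stringsAsFactors = FALSE)
    edges <- edges[edges$source != edges$target, , drop = FALSE]
    edges <- unique(edges)
    edges <- edges[order(edges$type, edges$source, edges$target), ]
    rownames(edges) <- NULL

    node_types <- data.frame(
      node = c(gene_ids, mirna_ids),
      type = c(ifelse(gene_ids %in% tf_ids, "TF", "gene"),
               rep("miRNA", length(mirna_ids))),
      stringsAsFactors = FALSE)

    list(gene_ids = gene_ids, tf_ids = tf_ids, mirna_ids = mirna_ids,
         edges = edges, node_types = node_types, is_de = is_de,
         de_genes = de_genes, drivers = drivers)
  })
}

#' Simulate a typed regulatory interaction database
#'
#' Emulates a curated TF/miRNA interaction repository: heavy-tailed
#' regulator out-degrees and the four interaction types TF->gene, TF->miRNA,
#' miRNA->gene and miRNA->miRNA. A configurable fraction of miRNAs are
#' disease drivers whose targets / regulator TFs concentrate on the planted
#' deregulated module (see [sim_config()]). Deterministic given the config.
#'
#' @param config a [sim_config()].
#' @return an `interaction_db`: list with `edges` (data.frame source,
#'   target, type) and `node_types` (data.frame node, type in TF/miRNA/gene).
#' @export
simulate_interaction_db <- function(config) {
  if (config$n_tfs == 0 && config$n_mirnas == 0)
    stop("simulate_interaction_db: no regulators (n_tfs = n_mirnas = 0)")
  core <- .sim_core(config)
  interaction_db(core$edges, core$node_types)
}

#' Construct an interaction database
#'
#' @param edges data.frame with columns source, target, type (one of
#'   "TF->gene", "TF->miRNA", "miRNA->gene", "miRNA->miRNA").
#' @param node_types data.frame with columns node, type (TF/miRNA/gene).
#'   TFs are protein-coding genes, so the `gene` side of an edge type also
#'   accepts a TF endpoint.
#' @return an object of class `interaction_db`.
#' @export
interaction_db <- function(edges, node_types) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  node_types <- as.data.frame(node_types, stringsAsFactors = FALSE)
  stopifnot(all(c("source", "target", "type") %in% names(edges)),
            all(c("node", "type") %in% names(node_types)))
  ok_types <- c("TF->gene", "TF->miRNA", "miRNA->gene", "miRNA->miRNA")
  if (nrow(edges) > 0 && !all(edges$type %in% ok_types))
    stop("interaction_db: unknown edge type")
  if (anyDuplicated(node_types$node))
    stop("interaction_db: duplicate node ids in node_types")
  tmap <- setNames(node_types$type, node_types$node)
  if (nrow(edges) > 0) {
    if (any(edges$source == edges$target))
      stop("interaction_db: self-loops are not allowed")
    if (anyDuplicated(edges[c("source", "target", "type")]))
      stop("interaction_db: duplicate (source, target, type) triples")
    st <- tmap[edges$source]; tt <- tmap[edges$target]
    if (anyNA(st) || anyNA(tt))
      stop("interaction_db: edge endpoint missing from node_types")
    src_cls <- ifelse(grepl("^TF", edges$type), "TF", "miRNA")
    tgt_cls <- ifelse(grepl("miRNA$", edges$type), "miRNA", "gene")
    bad <- st != src_cls | !(tt == tgt_cls | (tgt_cls == "gene" & tt == "TF"))
    if (any(bad))
      stop("interaction_db: edge type inconsistent with endpoint node types")
  }
  structure(list(edges = edges, node_types = node_types),
            class = "interaction_db")
}

#' @export
print.interaction_db <- function(x, ...) {
  cat(sprintf("interaction_db: %d nodes (%s), %d edges\n",
              nrow(x$node_types),
              paste(sprintf("%d %s", table(x$node_types$type),
                            names(table(x$node_types$type))), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Simulate a count matrix with planted differential expression
#'
#' Baseline means are log-normal (meanlog 4, sdlog 2, clipped below at 1);
#' per-sample size factors are log-normal with coefficient of variation
#' `libsize_cv` (renormalised to geometric mean 1); counts are negative
#' binomial with mean `s_j * mu_i * 2^(+/- lfc_i/2)` (plus for group B,
#' minus for A) and dispersion `alpha(mu_i) = disp_a1 + disp_a0 / mu_i`.
#' Exactly `round(de_fraction * n_genes)` genes carry a nonzero planted
#' log2 fold change, preferentially on regulators and their targets.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth`, a
#'   data.frame (gene_id, is_de, true_log2fc, true_mu, true_dispersion)
#'   carrying the planted per-sample size factors as attribute
#'   `size_factors`.
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  core <- .sim_core(config)
  with_seed(child_seed(config$seed, "counts"), {
    n <- config$n_genes
    m <- 2L * config$n_per_group
    mu <- pmax(1, rlnorm(n, meanlog = 4, sdlog = 2))
    lfc <- numeric(n)
    n_de <- sum(core$is_de)
    if (n_de > 0) {
      mag <- 1 + rexp(n_de, rate = 1 / config$lfc_scale)
      sgn <- sample(c(-1, 1), n_de, replace = TRUE)
      lfc[core$is_de] <- sgn * mag
    }
    disp <- config$disp_a1 + config$disp_a0 / mu
    sdl <- sqrt(log(1 + config$libsize_cv^2))
    sf <- rlnorm(m, meanlog = 0, sdlog = sdl)
    sf <- sf / geometric_mean(sf)
    groups <- rep(c("A", "B"), each = config$n_per_group)
    fc_half <- outer(lfc / 2, ifelse(groups == "B", 1, -1))  # genes x samples
    mean_mat <- (mu %o% sf) * 2^fc_half
    cnt <- if (all(disp < 1e-12)) {
      rpois(n * m, lambda = as.vector(mean_mat))
    } else {
      rnbinom(n * m, mu = as.vector(mean_mat), size = rep(1 / disp, times = m))
    }
    counts <- matrix(as.integer(cnt), nrow = n, ncol = m,
                     dimnames = list(core$gene_ids,
                                     sprintf("sample_%03d", seq_len(m))))
    cm <- count_matrix(counts, groups)
    truth <- data.frame(gene_id = core$gene_ids, is_de = core$is_de,
                        true_log2fc = lfc, true_mu = mu,
                        true_dispersion = disp, stringsAsFactors = FALSE)
    attr(truth, "size_factors") <- setNames(sf, colnames(counts))
    list(counts = cm, truth = truth)
  })
}

#' Simulate a disease annotation enriched around planted regulators
#'
#' Samples `round(disease_fraction * n_nodes)` nodes from the database node
#' universe, with weight 2 on the "disease module" (planted-DE TFs, their
#' targets, driver miRNAs and the planted-DE targets of driver miRNAs) and
#' weight 1 elsewhere, so disease filtering concentrates the per-method
#' networks on shared structure.
#'
#' @param db an `interaction_db`.
#' @param config the [sim_config()] used to generate `db`.
#' @param truth the truth table from [simulate_counts()].
#' @return a `disease_annotation`: list with `disease_name` and `nodes`.
#' @export
simulate_disease_annotation <- function(db, config, truth) {
  stopifnot(inherits(db, "interaction_db"))
  if (nrow(db$node_types) == 0) stop("simulate_disease_annotation: empty db")
  with_seed(child_seed(config$seed, "disease"), {
    universe <- db$node_types$node
    n_dis <- round(config$disease_fraction * length(universe))
    if (n_dis == 0)
      return(disease_annotation("synthetic_disease", character()))
    de_genes <- truth$gene_id[truth$is_de]
    tf_ids <- db$node_types$node[db$node_types$type == "TF"]
    de_tfs <- intersect(de_genes, tf_ids)
    e <- db$edges
    tf_targets <- e$target[e$source %in% de_tfs]
    # driver miRNAs: the ones whose targets concentrate on planted-DE genes
    mg <- e[e$type == "miRNA->gene", ]
    de_frac_by_m <- tapply(mg$target %in% de_genes, mg$source, mean)
    drivers <- names(de_frac_by_m)[de_frac_by_m >= 2 * config$de_fraction]
    drv_de_targets <- intersect(mg$target[mg$source %in% drivers], de_genes)
    hot <- unique(c(de_tfs, intersect(tf_targets, de_genes),
                    drivers, drv_de_targets))
    w <- ifelse(universe %in% hot, 4, 1)
    nodes <- sort(sample(universe, n_dis, prob = w))
    disease_annotation("synthetic_disease", nodes)
  })
}

#' Construct a disease annotation
#'
#' @param disease_name label for the disease.
#' @param nodes character vector of disease-associated node ids.
#' @return an object of class `disease_annotation`.
#' @export
disease_annotation <- function(disease_name, nodes) {
  structure(list(disease_name = as.character(disease_name),
                 nodes = unique(as.character(nodes))),
            class = "disease_annotation")
}
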