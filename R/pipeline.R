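#' Pipeline configuration
#'
#' Settings for [run_full_study()]. Inputs are either generated by the
#' synthetic-data module (give `sim`) or read from TSV files (give the
#' paths).
#'
#' @param out_dir output directory for all reports.
#' @param sim optional [sim_config()]; when given, inputs are simulated and
#'   also written to `out_dir`.
#' @param counts_file,groups_file,db_edges_file,db_nodes_file,disease_file
#'   input paths (ignored when `sim` is given).
#' @param methods DE methods to run (subset of `DE_METHODS`).
#' @param de_alpha adjusted-p DE threshold (default 0.05).
#' @param enrich_cutoff miRNA-recovery BH cutoff (default 0.001).
#' @param hub_fraction hub fraction (default 0.10).
#' @param disease_mode disease-filter semantics ("both" endpoints, or
#'   "either").
#' @param n_random robustness replicates (0 skips the robustness stage).
#' @param random_set_size pseudo-DE set size; default: the same fraction of
#'   the gene universe as the original study's random draws (11000 of
#'   20501 assayed genes, about 54%), which makes the random networks
#'   comparable in size to the method networks rather than degenerate.
#' @param reference_method reference for the robustness comparison.
#' @param seed integer seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, sim = NULL, counts_file = NULL,
                            groups_file = NULL, db_edges_file = NULL,
                            db_nodes_file = NULL, disease_file = NULL,
                            methods = DE_METHODS, de_alpha = 0.05,
                            enrich_cutoff = 0.001, hub_fraction = 0.10,
                            disease_mode = "both", n_random = 100,
                            random_set_size = NULL,
                            reference_method = "deseq_like", seed = 1L) {
  if (length(methods) == 0 || !all(methods %in% DE_METHODS))
    stop("pipeline_config: methods must be a non-empty subset of DE_METHODS")
  for (thr in c(de_alpha, enrich_cutoff, hub_fraction))
    if (!is.finite(thr) || thr <= 0 || thr > 1)
      stop("pipeline_config: thresholds must lie in (0, 1]")
  structure(list(out_dir = out_dir, sim = sim, counts_file = counts_file,
                 groups_file = groups_file, db_edges_file = db_edges_file,
                 db_nodes_file = db_nodes_file, disease_file = disease_file,
                 methods = methods, de_alpha = de_alpha,
                 enrich_cutoff = enrich_cutoff, hub_fraction = hub_fraction,
                 disease_mode = disease_mode, n_random = n_random,
                 random_set_size = random_set_size,
                 reference_method = reference_method,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full study
#'
#' Orchestrates the five stages on one input set: DE calling per method,
#' DE-set overlap table, disease-specific network construction (with
#' hypergeometric miRNA recovery), key-player extraction, pairwise
#' key-player overlap tables, node/edge Venn counts, and the
#' random-gene-set robustness test. Every table is written as TSV into
#' `config$out_dir`; a manifest records the configuration so the run can
#' be reproduced. Outputs are deterministic given the seed.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with all in-memory results.
#' @export
run_full_study <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  pth <- function(...) file.path(out, paste0(...))
  stage <- function(name, expr) {
    message("[coregtopo] stage: ", name)
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  inputs <- stage("inputs", {
    if (!is.null(config$sim)) {
      sim <- simulate_counts(config$sim)
      db <- simulate_interaction_db(config$sim)
      dis <- simulate_disease_annotation(db, config$sim, sim$truth)
      write_count_matrix(sim$counts, pth("counts.tsv"), pth("groups.tsv"))
      write_interaction_db(db, pth("db_edges.tsv"), pth("db_nodes.tsv"))
      write_disease_annotation(dis, pth("disease.tsv"))
      .write_tsv(sim$truth, pth("truth.tsv"))
      list(cm = sim$counts, truth = sim$truth, db = db, disease = dis)
    } else {
      list(cm = read_count_matrix(config$counts_file, config$groups_file),
           truth = NULL,
           db = read_interaction_db(config$db_edges_file,
                                    config$db_nodes_file),
           disease = read_disease_annotation(config$disease_file))
    }
  })

  de <- stage("de", {
    res <- lapply(config$methods, function(m) run_de_method(inputs$cm, m))
    names(res) <- config$methods
    for (m in config$methods) {
      write_de_result(res[[m]], pth("de_", m, ".tsv"))
      gs <- significant_genes(res[[m]], config$de_alpha)
      .write_tsv(data.frame(gene = sort(gs$genes)), pth("de_genes_", m, ".tsv"))
      message(sprintf("[coregtopo]   %s: %d DE genes", m, length(gs$genes)))
    }
    res
  })
  de_sets <- lapply(de, significant_genes, alpha = config$de_alpha)

  if (length(config$methods) >= 2) {
    stage("de_overlap", {
      prs <- combn(config$methods, 2, simplify = FALSE)
      tab <- do.call(rbind, lapply(prs, function(pr) {
        X <- de_sets[[pr[1]]]$genes; Y <- de_sets[[pr[2]]]$genes
        data.frame(method_a = pr[1], method_b = pr[2],
                   size_a = length(X), size_b = length(Y),
                   intersection_size = length(intersect(X, Y)),
                   overlap_pct = if (min(length(X), length(Y)) == 0) NA_real_
                                 else 100 * overlap_coefficient(X, Y))
      }))
      .write_tsv(tab, pth("de_overlap.tsv"))
    })
  } else message("[coregtopo] single method: overlap tables skipped")

  nets <- stage("network", {
    nets <- list()
    for (m in config$methods) {
      rec <- recover_mirnas(inputs$db, de_sets[[m]],
                            cutoff = config$enrich_cutoff)
      if (nrow(rec) > 0) .write_tsv(rec, pth("enrichment_", m, ".tsv"))
      net <- build_network(inputs$db, de_sets[[m]], rec)
      net <- disease_filter(net, inputs$disease, mode = config$disease_mode)
      if (nrow(net$nodes) == 0)
        message("[coregtopo]   ", m, ": empty disease network")
      write_network(net, pth("network_", m, "_edges.tsv"),
                    pth("network_", m, "_nodes.tsv"))
      message(sprintf("[coregtopo]   %s network: %d nodes, %d edges",
                      m, nrow(net$nodes), nrow(net$edges)))
      nets[[m]] <- net
    }
    nets
  })

  kps <- stage("topology", {
    kps <- lapply(nets, key_player_report, hub_fraction = config$hub_fraction)
    for (m in config$methods)
      write_key_player_report(kps[[m]], pth("keyplayers_", m, ".tsv"))
    kps
  })

  cmp <- list(pw = NULL, common = NULL, venn = NULL)
  if (length(config$methods) >= 2) {
    cmp <- stage("compare", {
      pw <- pairwise_overlap_matrix(kps)
      .write_tsv(pw, pth("overlap_pairwise.tsv"))
      common <- lapply(c(hubs = "hubs", mds = "mds", mcds = "mcds"),
                       function(f) common_across_methods(
                         lapply(kps, `[[`, f)))
      .write_tsv(data.frame(
        feature = rep(names(common), lengths(common)),
        node = unlist(common, use.names = FALSE)), pth("common_keyplayers.tsv"))
      venn <- venn_counts(nets)
      .write_tsv(data.frame(region = names(venn$nodes),
                            n = as.integer(venn$nodes)), pth("venn_nodes.tsv"))
      .write_tsv(data.frame(region = names(venn$edges),
                            n = as.integer(venn$edges)), pth("venn_edges.tsv"))
      list(pw = pw, common = common, venn = venn)
    })
  }

  robust <- NULL
  if (config$n_random > 0 && length(config$methods) >= 2 &&
      config$reference_method %in% config$methods) {
    robust <- stage("robustness", {
      ref <- config$reference_method
      m_size <- config$random_set_size %||%
        round(11000 / 20501 * nrow(inputs$cm$counts))
      rb <- random_baseline(
        universe = rownames(inputs$cm$counts), m = m_size,
        n_random = config$n_random, reference = kps[[ref]],
        db = inputs$db, disease = inputs$disease,
        comparisons = kps[setdiff(config$methods, ref)],
        enrich_cutoff = config$enrich_cutoff,
        hub_fraction = config$hub_fraction, seed = config$seed)
      .write_tsv(rb$features, pth("robustness.tsv"))
      .write_tsv(as.data.frame(rb$random_overlaps),
                 pth("robustness_random_overlaps.tsv"))
      rb
    })
  }

  stage("manifest", {
    # out_dir is a run location, not part of the reproducible configuration
    cfgv <- config[setdiff(names(config), c("sim", "out_dir"))]
    cfgv <- cfgv[!vapply(cfgv, is.null, logical(1))]
    man <- data.frame(
      key = c("package_version",
              names(cfgv),
              if (!is.null(config$sim)) paste0("sim.", names(config$sim))),
      value = c(as.character(packageVersion("coregtopo")),
                vapply(cfgv, function(v) paste(v, collapse = ","),
                       character(1)),
                if (!is.null(config$sim))
                  vapply(config$sim, as.character, character(1))))
    .write_tsv(man, pth("manifest.tsv"))
  })

  invisible(list(inputs = inputs, de = de, de_sets = de_sets,
                 networks = nets, key_players = kps,
                 pairwise_overlap = cmp$pw, common = cmp$common,
                 venn = cmp$venn, robustness = robust, config = config))
}
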