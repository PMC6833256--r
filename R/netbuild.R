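#' Upper-tail hypergeometric p-value
#'
#' `P(X >= overlap)` for `X ~ Hypergeometric(universe, successes,
#' sample_size)`: the probability of drawing at least `overlap` successes
#' when `sample_size` items are drawn without replacement from a universe
#' containing `successes` marked items.
#'
#' @param overlap observed number of marked items in the draw.
#' @param sample_size number of items drawn.
#' @param successes number of marked items in the universe.
#' @param universe universe size.
#' @return p-value in (0, 1].
#' @export
hypergeom_pvalue <- function(overlap, sample_size, successes, universe) {
  if (any(c(overlap, sample_size, successes, universe) < 0))
    stop("hypergeom_pvalue: negative counts")
  if (overlap > min(sample_size, successes) ||
      sample_size > universe || successes > universe)
    stop("hypergeom_pvalue: inconsistent counts")
  if (overlap == 0) return(1)
  phyper(overlap - 1, m = successes, n = universe - successes,
         k = sample_size, lower.tail = FALSE)
}

#' Recover co-regulating miRNAs for a DE gene set
#'
#' For every miRNA in the database, tests whether (i) its target genes and
#' (ii) its regulator TFs are enriched within the DE genes, using the
#' hypergeometric upper tail against the database gene universe (all
#' gene/TF nodes). Each test family is BH-adjusted separately across
#' miRNAs; a miRNA is recovered iff both adjusted p-values fall strictly
#' below `cutoff`.
#'
#' @param db an `interaction_db`.
#' @param de_genes a `de_gene_set` (or character vector of gene ids).
#' @param cutoff BH-adjusted significance cutoff (default 0.001).
#' @return data.frame (class `enrichment_records`) with one row per miRNA:
#'   mirna_id, n_targets, n_target_de, p_target, n_tfs, n_tf_de, p_tf,
#'   adj_p_target, adj_p_tf, recovered.
#' @export
recover_mirnas <- function(db, de_genes, cutoff = 0.001) {
  stopifnot(inherits(db, "interaction_db"))
  genes <- if (inherits(de_genes, "de_gene_set")) de_genes$genes
           else as.character(de_genes)
  gene_universe <- db$node_types$node[db$node_types$type %in% c("gene", "TF")]
  mirnas <- sort(db$node_types$node[db$node_types$type == "miRNA"])
  if (length(mirnas) == 0)
    return(structure(data.frame(), class = c("enrichment_records",
                                             "data.frame")))
  de_in_univ <- intersect(genes, gene_universe)
  N <- length(gene_universe); K <- length(de_in_univ)
  e <- db$edges
  tgt_by_m <- split(e$target[e$type == "miRNA->gene"],
                    e$source[e$type == "miRNA->gene"])
  tf_by_m <- split(e$source[e$type == "TF->miRNA"],
                   e$target[e$type == "TF->miRNA"])
  one <- function(members) {
    members <- unique(members)
    k <- length(members)
    x <- length(intersect(members, de_in_univ))
    p <- if (k == 0 || K == 0) 1 else hypergeom_pvalue(x, k, K, N)
    c(n = k, x = x, p = p)
  }
  tstats <- t(vapply(mirnas, function(m) one(tgt_by_m[[m]]), numeric(3)))
  fstats <- t(vapply(mirnas, function(m) one(tf_by_m[[m]]), numeric(3)))
  rec <- data.frame(mirna_id = mirnas,
                    n_targets = as.integer(tstats[, "n"]),
                    n_target_de = as.integer(tstats[, "x"]),
                    p_target = tstats[, "p"],
                    n_tfs = as.integer(fstats[, "n"]),
                    n_tf_de = as.integer(fstats[, "x"]),
                    p_tf = fstats[, "p"],
                    stringsAsFactors = FALSE)
  rec$adj_p_target <- bh_adjust(rec$p_target)
  rec$adj_p_tf <- bh_adjust(rec$p_tf)
  rec$recovered <- rec$adj_p_target < cutoff & rec$adj_p_tf < cutoff
  rownames(rec) <- NULL
  class(rec) <- c("enrichment_records", "data.frame")
  rec
}

#' Construct a regulatory network object
#'
#' @param nodes data.frame with columns id, type.
#' @param edges data.frame with columns source, target, type.
#' @param provenance label of the DE method (or other origin) of the input
#'   gene set.
#' @param disease disease name, or "unfiltered".
#' @return an object of class `regulatory_network`.
#' @export
regulatory_network <- function(nodes, edges, provenance = "unknown",
                               disease = "unfiltered") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (nrow(nodes) == 0) nodes <- data.frame(id = character(),
                                            type = character())
  if (nrow(edges) == 0) edges <- data.frame(source = character(),
                                            target = character(),
                                            type = character())
  if (nrow(edges) > 0 &&
      !all(c(edges$source, edges$target) %in% nodes$id))
    stop("regulatory_network: edge endpoint not in node table")
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, provenance = provenance,
                 disease = disease),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat(sprintf("regulatory_network [%s, %s]: %d nodes, %d edges\n",
              x$provenance, x$disease, nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of nodes / edges of a regulatory network
#' @param net a `regulatory_network`.
#' @return integer count.
#' @export
network_size <- function(net) c(nodes = nrow(net$nodes),
                                edges = nrow(net$edges))

# igraph view of a regulatory_network (directed)
.as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$edges[, c("source", "target")],
                                directed = TRUE,
                                vertices = net$nodes$id)
}

#' Build a co-regulatory network from a DE gene set
#'
#' Candidate nodes are the DE genes plus the recovered miRNAs; an edge of
#' the database is included iff both endpoints are candidates. Candidates
#' left without any edge are dropped (no isolated nodes).
#'
#' @param db an `interaction_db`.
#' @param de_genes a `de_gene_set` (or character vector).
#' @param recovered character vector of recovered miRNA ids (e.g. from
#'   [recover_mirnas()]).
#' @return a `regulatory_network`.
#' @export
build_network <- function(db, de_genes, recovered = character()) {
  stopifnot(inherits(db, "interaction_db"))
  genes <- if (inherits(de_genes, "de_gene_set")) de_genes$genes
           else as.character(de_genes)
  prov <- if (inherits(de_genes, "de_gene_set")) de_genes$method_name
          else "gene_list"
  if (inherits(recovered, "enrichment_records"))
    recovered <- recovered$mirna_id[recovered$recovered]
  cand <- unique(c(genes, as.character(recovered)))
  e <- db$edges[db$edges$source %in% cand & db$edges$target %in% cand, ,
                drop = FALSE]
  used <- unique(c(e$source, e$target))
  nt <- db$node_types[db$node_types$node %in% used, , drop = FALSE]
  nodes <- data.frame(id = nt$node, type = nt$type, stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  e <- e[order(e$type, e$source, e$target), , drop = FALSE]
  regulatory_network(nodes, e, provenance = prov)
}

#' Filter a network to disease-associated nodes
#'
#' Keeps an edge iff the required endpoints are disease-annotated
#' (`mode = "both"`, the default, requires both; `"either"` requires at
#' least one), then drops isolated nodes.
#'
#' @param net a `regulatory_network`.
#' @param disease a `disease_annotation`.
#' @param mode "both" or "either".
#' @return the filtered `regulatory_network` (provenance kept, disease name
#'   recorded).
#' @export
disease_filter <- function(net, disease, mode = c("both", "either")) {
  stopifnot(inherits(net, "regulatory_network"),
            inherits(disease, "disease_annotation"))
  mode <- match.arg(mode)
  dn <- disease$nodes
  e <- net$edges
  keep <- if (mode == "both") e$source %in% dn & e$target %in% dn
          else e$source %in% dn | e$target %in% dn
  e <- e[keep, , drop = FALSE]
  used <- unique(c(e$source, e$target))
  nodes <- net$nodes[net$nodes$id %in% used, , drop = FALSE]
  regulatory_network(nodes, e, provenance = net$provenance,
                     disease = disease$disease_name)
}
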