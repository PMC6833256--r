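# Tabular I/O: everything is TSV with a header line.

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

#' Write / read a count matrix and its sample annotation
#'
#' The counts file has the gene id in the first column (`gene`) and one
#' column per sample; the groups file has two columns (`sample`, `group`).
#'
#' @param cm a [count_matrix()].
#' @param counts_file,groups_file output / input paths.
#' @return `write_count_matrix` the paths (invisibly);
#'   `read_count_matrix` a [count_matrix()].
#' @export
write_count_matrix <- function(cm, counts_file, groups_file) {
  stopifnot(inherits(cm, "count_matrix"))
  df <- data.frame(gene = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_tsv(df, counts_file)
  .write_tsv(data.frame(sample = names(cm$groups),
                        group = as.character(cm$groups)), groups_file)
  invisible(c(counts_file, groups_file))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_file, groups_file) {
  df <- read.delim(counts_file, check.names = FALSE,
                   stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  gr <- read.delim(groups_file, stringsAsFactors = FALSE)
  counts <- counts[, gr$sample, drop = FALSE]
  count_matrix(counts, gr$group)
}

#' Write / read an interaction database
#'
#' Edges as 3-column TSV (source, target, type); node types as 2-column
#' TSV (node, type).
#'
#' @param db an [interaction_db()].
#' @param edges_file,nodes_file output / input paths.
#' @return `write_interaction_db` the paths (invisibly);
#'   `read_interaction_db` an [interaction_db()].
#' @export
write_interaction_db <- function(db, edges_file, nodes_file) {
  stopifnot(inherits(db, "interaction_db"))
  .write_tsv(db$edges, edges_file)
  .write_tsv(db$node_types, nodes_file)
  invisible(c(edges_file, nodes_file))
}

#' @rdname write_interaction_db
#' @export
read_interaction_db <- function(edges_file, nodes_file) {
  interaction_db(read.delim(edges_file, stringsAsFactors = FALSE),
                 read.delim(nodes_file, stringsAsFactors = FALSE))
}

#' Write / read a disease annotation (1-column TSV of node ids)
#'
#' @param da a [disease_annotation()].
#' @param path output / input path.
#' @param disease_name name used when reading.
#' @return `write_disease_annotation` the path (invisibly);
#'   `read_disease_annotation` a [disease_annotation()].
#' @export
write_disease_annotation <- function(da, path) {
  stopifnot(inherits(da, "disease_annotation"))
  .write_tsv(data.frame(node = da$nodes), path)
  invisible(path)
}

#' @rdname write_disease_annotation
#' @export
read_disease_annotation <- function(path, disease_name = "disease") {
  disease_annotation(disease_name, read.delim(path,
                                              stringsAsFactors = FALSE)$node)
}

#' Write a DE result / significant gene list
#' @param res a `de_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_de_result <- function(res, path) {
  .write_tsv(res, path)
}

#' Write a network as an edge-list TSV plus a node-table TSV
#' @param net a `regulatory_network`.
#' @param edges_file,nodes_file output paths.
#' @return the paths, invisibly.
#' @export
write_network <- function(net, edges_file, nodes_file) {
  stopifnot(inherits(net, "regulatory_network"))
  .write_tsv(net$edges, edges_file)
  .write_tsv(net$nodes, nodes_file)
  invisible(c(edges_file, nodes_file))
}

#' Read a network from edge-list + node-table TSVs
#' @param edges_file,nodes_file input paths.
#' @param provenance,disease provenance labels.
#' @return a `regulatory_network`.
#' @export
read_network <- function(edges_file, nodes_file, provenance = "file",
                         disease = "unfiltered") {
  regulatory_network(read.delim(nodes_file, stringsAsFactors = FALSE),
                     read.delim(edges_file, stringsAsFactors = FALSE),
                     provenance = provenance, disease = disease)
}

#' Write a key-player report as a long TSV (node, in_hubs, in_mds, in_mcds)
#' @param kp a `key_player_report`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_key_player_report <- function(kp, path) {
  stopifnot(inherits(kp, "key_player_report"))
  nodes <- sort(unique(c(kp$hubs, kp$mds, kp$mcds)))
  .write_tsv(data.frame(node = nodes,
                        in_hubs = as.integer(nodes %in% kp$hubs),
                        in_mds = as.integer(nodes %in% kp$mds),
                        in_mcds = as.integer(nodes %in% kp$mcds)), path)
}

#' Read a key-player report written by [write_key_player_report()]
#' @param path input path.
#' @param network_id label for the report.
#' @return a `key_player_report` (lcc_size unknown, recorded as NA).
#' @export
read_key_player_report <- function(path, network_id = "file") {
  df <- read.delim(path, stringsAsFactors = FALSE)
  structure(list(network_id = network_id,
                 hubs = df$node[df$in_hubs == 1],
                 mds = df$node[df$in_mds == 1],
                 mcds = df$node[df$in_mcds == 1],
                 lcc_size = NA_integer_,
                 optimality = c(mds = "proven", mcds = "heuristic")),
            class = "key_player_report")
}
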