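#' Overlap coefficient of two sets
#'
#' `|X ∩ Y| / min(|X|, |Y|)` — 1 whenever one set contains the other.
#'
#' @param x,y vectors treated as sets.
#' @return numeric in \[0, 1\].
#' @export
overlap_coefficient <- function(x, y) {
  x <- unique(x); y <- unique(y)
  if (length(x) == 0 || length(y) == 0)
    stop("overlap_coefficient: undefined for empty sets")
  length(intersect(x, y)) / min(length(x), length(y))
}

#' Pairwise overlap table for key-player reports
#'
#' One row per unordered method pair and feature (hubs, mds, mcds) with the
#' full-precision overlap percentage; pairs where either feature set is
#' empty are recorded as missing (`NA`), not as 0.
#'
#' @param reports named list of `key_player_report`s (names = methods).
#' @param features which feature sets to compare.
#' @return data.frame (class `overlap_report`): feature, method_a,
#'   method_b, size_a, size_b, intersection_size, overlap_pct.
#' @export
pairwise_overlap_matrix <- function(reports,
                                    features = c("hubs", "mds", "mcds")) {
  if (length(reports) < 2)
    stop("pairwise_overlap_matrix: need >= 2 methods")
  methods <- names(reports)
  if (is.null(methods)) stop("pairwise_overlap_matrix: reports must be named")
  prs <- combn(methods, 2, simplify = FALSE)
  rows <- list()
  for (f in features) for (pr in prs) {
    X <- reports[[pr[1]]][[f]]; Y <- reports[[pr[2]]][[f]]
    pct <- if (length(X) == 0 || length(Y) == 0) NA_real_
           else 100 * overlap_coefficient(X, Y)
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, method_a = pr[1], method_b = pr[2],
      size_a = length(unique(X)), size_b = length(unique(Y)),
      intersection_size = length(intersect(X, Y)),
      overlap_pct = pct, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("overlap_report", "data.frame")
  out
}

#' Intersection across all methods
#'
#' @param sets list of >= 2 vectors (node sets).
#' @return their common elements.
#' @export
common_across_methods <- function(sets) {
  if (length(sets) < 2) stop("common_across_methods: need >= 2 sets")
  Reduce(intersect, sets)
}

#' Venn region counts for nodes and edges of several networks
#'
#' Every node id (and every (source, target, type) edge) is assigned to the
#' exclusive Venn region given by the subset of networks containing it;
#' region labels join method names with `&`. Region counts sum to the size
#' of the union.
#'
#' @param networks named list of `regulatory_network`s.
#' @return list with `nodes` and `edges`, each a named integer vector of
#'   exclusive region counts.
#' @export
venn_counts <- function(networks) {
  if (length(networks) < 2) stop("venn_counts: need >= 2 networks")
  methods <- names(networks)
  region_counts <- function(sets) {
    u <- unique(unlist(sets))
    if (length(u) == 0) return(setNames(integer(0), character(0)))
    memb <- vapply(sets, function(s) u %in% s, logical(length(u)))
    if (length(u) == 1) memb <- matrix(memb, nrow = 1)
    lab <- apply(memb, 1, function(r) paste(methods[r], collapse = "&"))
    tab <- table(lab)
    setNames(as.integer(tab), names(tab))
  }
  node_sets <- lapply(networks, function(n) n$nodes$id)
  edge_sets <- lapply(networks, function(n)
    if (nrow(n$edges) == 0) character(0)
    else paste(n$edges$source, n$edges$target, n$edges$type, sep = "\t"))
  list(nodes = region_counts(node_sets), edges = region_counts(edge_sets))
}

#' Random-gene-set robustness test
#'
#' Repeats the network-construction and key-player stages on `n_random`
#' pseudo DE sets of `m` genes sampled without replacement from the gene
#' universe, records the overlap coefficient of each feature (hubs, MDS,
#' MCDS) with the reference report, and computes the add-one empirical
#' p-value `(r + 1) / (n_random + 1)` with `r` the number of random
#' replicates whose overlap reaches the real overlap. The real overlap per
#' feature is the minimum overlap of the reference with the `comparisons`
#' reports (or can be supplied directly via `real_overlap`). Replicates
#' whose network lacks a feature score an overlap of 0 (conservative null).
#'
#' @param universe character vector of candidate genes (the simulated count
#'   matrix's genes play the role of the assayed genome).
#' @param m random DE-set size.
#' @param n_random number of random replicates (default 100).
#' @param reference `key_player_report` of the reference (e.g. DESeq-like)
#'   network.
#' @param db the `interaction_db` used for all networks.
#' @param disease the `disease_annotation` used for all networks (set to
#'   `NULL` to skip disease filtering).
#' @param comparisons list of `key_player_report`s of the other methods;
#'   used to derive the real overlap per feature (minimum over
#'   comparisons). Ignored when `real_overlap` is given.
#' @param real_overlap optional named numeric (hubs, mds, mcds), percents.
#' @param enrich_cutoff miRNA-recovery cutoff (default 0.001).
#' @param hub_fraction hub fraction (default 0.10).
#' @param seed integer seed for the random draws.
#' @return a `robustness_report`: list with `features` (data.frame feature,
#'   real_overlap_pct, empirical_p), `random_overlaps` (n_random x 3
#'   matrix, percents), `n_random`, `random_set_size`, `seed`.
#' @export
random_baseline <- function(universe, m, n_random = 100, reference,
                            db, disease = NULL, comparisons = NULL,
                            real_overlap = NULL, enrich_cutoff = 0.001,
                            hub_fraction = 0.10, seed = 1L) {
  if (n_random < 1) stop("random_baseline: n_random must be >= 1")
  if (m > length(universe))
    stop("random_baseline: m exceeds the universe size")
  stopifnot(inherits(reference, "key_player_report"),
            inherits(db, "interaction_db"))
  feats <- c("hubs", "mds", "mcds")
  if (is.null(real_overlap)) {
    if (is.null(comparisons) || length(comparisons) == 0)
      stop("random_baseline: provide comparisons or real_overlap")
    real_overlap <- vapply(feats, function(f) {
      vals <- vapply(comparisons, function(rep) {
        X <- reference[[f]]; Y <- rep[[f]]
        if (length(X) == 0 || length(Y) == 0) 0
        else 100 * overlap_coefficient(X, Y)
      }, numeric(1))
      min(vals)
    }, numeric(1))
  }
  real_overlap <- real_overlap[feats]

  ov <- matrix(0, nrow = n_random, ncol = 3,
               dimnames = list(NULL, feats))
  with_seed(child_seed(seed, "robust"), {
    for (r in seq_len(n_random)) {
      genes <- sample(universe, m)
      pseudo <- de_gene_set("random", genes)
      rec <- recover_mirnas(db, pseudo, cutoff = enrich_cutoff)
      net <- build_network(db, pseudo, rec)
      if (!is.null(disease)) net <- disease_filter(net, disease)
      if (nrow(net$nodes) == 0) next  # all-zero overlaps recorded
      kp <- key_player_report(net, hub_fraction)
      for (f in feats) {
        X <- reference[[f]]; Y <- kp[[f]]
        ov[r, f] <- if (length(X) == 0 || length(Y) == 0) 0
                    else 100 * overlap_coefficient(X, Y)
      }
    }
  })
  emp_p <- vapply(feats, function(f)
    (sum(ov[, f] >= real_overlap[[f]]) + 1) / (n_random + 1), numeric(1))
  structure(list(
    features = data.frame(feature = feats,
                          real_overlap_pct = as.numeric(real_overlap),
                          empirical_p = as.numeric(emp_p),
                          stringsAsFactors = FALSE),
    random_overlaps = ov, n_random = n_random, random_set_size = m,
    seed = seed), class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat(sprintf("robustness_report: %d random sets of %d genes (seed %d)\n",
              x$n_random, x$random_set_size, x$seed))
  print(x$features, row.names = FALSE)
  invisible(x)
}
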