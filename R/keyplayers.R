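#' Hub-degree nodes
#'
#' Ranks nodes by total degree (in + out) and returns the top
#' `ceil(fraction * n)`; ties are broken by higher degree first, then by
#' lexicographic node id.
#'
#' @param net a `regulatory_network`.
#' @param fraction fraction of nodes to return (default 0.10).
#' @return character vector of hub node ids (sorted).
#' @export
hub_nodes <- function(net, fraction = 0.10) {
  stopifnot(inherits(net, "regulatory_network"))
  ids <- net$nodes$id
  if (length(ids) == 0) stop("hub_nodes: empty network")
  deg <- table(factor(c(net$edges$source, net$edges$target), levels = ids))
  k <- ceiling(fraction * length(ids))
  ord <- order(-as.integer(deg), ids)
  sort(ids[ord][seq_len(k)])
}

# internal: adjacency bookkeeping on integer indices (ids sorted)
.net_index <- function(net) {
  ids <- sort(net$nodes$id)
  n <- length(ids)
  si <- match(net$edges$source, ids)
  ti <- match(net$edges$target, ids)
  out_adj <- lapply(seq_len(n), function(i) integer(0))
  in_adj <- lapply(seq_len(n), function(i) integer(0))
  if (length(si)) {
    for (e in seq_along(si)) {
      out_adj[[si[e]]] <- c(out_adj[[si[e]]], ti[e])
      in_adj[[ti[e]]] <- c(in_adj[[ti[e]]], si[e])
    }
    out_adj <- lapply(out_adj, function(v) sort(unique(v)))
    in_adj <- lapply(in_adj, function(v) sort(unique(v)))
  }
  und_adj <- lapply(seq_len(n), function(i)
    sort(unique(c(out_adj[[i]], in_adj[[i]]))))
  list(ids = ids, n = n, out_adj = out_adj, in_adj = in_adj,
       und_adj = und_adj)
}

#' Exact minimum dominating set
#'
#' Smallest node set S such that every node either belongs to S or receives
#' an edge from a member of S (directed domination: a regulator controls
#' its out-neighbors and itself). Solved exactly by set-cover
#' branch-and-bound with forced zero-in-degree nodes, unit propagation, a
#' dominance reduction, a greedy upper bound and a disjoint-cover lower
#' bound; among all optima the lexicographically smallest set is returned.
#'
#' @param net a `regulatory_network`.
#' @return character vector of node ids (sorted); attribute `optimality`
#'   is "proven".
#' @export
minimum_dominating_set <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  ix <- .net_index(net)
  if (ix$n == 0) stop("minimum_dominating_set: empty network")
  n <- ix$n
  cover <- lapply(seq_len(n), function(i) c(i, ix$out_adj[[i]]))
  coverers <- lapply(seq_len(n), function(i) sort(c(i, ix$in_adj[[i]])))

  S <- which(lengths(ix$in_adj) == 0)          # forced: only self-coverage
  covered <- rep(FALSE, n)
  for (u in S) covered[cover[[u]]] <- TRUE
  avail <- rep(TRUE, n); avail[S] <- FALSE

  # unit propagation: an uncovered node with a single available coverer
  repeat {
    forced <- integer(0)
    for (v in which(!covered)) {
      cs <- coverers[[v]]
      cs <- cs[avail[cs] | cs %in% S]
      csa <- coverers[[v]][avail[coverers[[v]]]]
      if (length(csa) == 1 && !covered[v]) forced <- c(forced, csa)
    }
    forced <- unique(forced)
    if (length(forced) == 0) break
    for (u in forced) {
      if (!avail[u]) next
      S <- c(S, u); avail[u] <- FALSE
      covered[cover[[u]]] <- TRUE
    }
  }

  U <- which(!covered)
  if (length(U) == 0) {
    res <- sort(ix$ids[S])
    attr(res, "optimality") <- "proven"
    return(res)
  }

  cand <- which(avail & vapply(cover, function(cv) any(cv %in% U), logical(1)))
  cov_u <- lapply(seq_len(n), function(i)
    if (i %in% cand) intersect(cover[[i]], U) else integer(0))

  # dominance: drop candidate u if a smaller-id candidate covers a superset
  drop <- rep(FALSE, n)
  for (u in cand) for (w in cand) {
    if (w < u && !drop[w] && all(cov_u[[u]] %in% cov_u[[w]])) {
      drop[u] <- TRUE; break
    }
  }
  cand <- cand[!drop[cand]]

  coverers_u <- lapply(seq_len(n), function(v)
    if (v %in% U) intersect(coverers[[v]], cand) else integer(0))

  greedy_cover <- function(U0) {
    sel <- integer(0)
    while (length(U0) > 0) {
      gains <- vapply(cand, function(u) sum(cov_u[[u]] %in% U0), integer(1))
      u <- cand[order(-gains, cand)][1]
      sel <- c(sel, u)
      U0 <- setdiff(U0, cov_u[[u]])
    }
    sel
  }
  best <- greedy_cover(U)
  best_size <- length(best)
  best_set <- sort(c(S, best))

  lower_bound <- function(U0) {
    lb <- 0L
    while (length(U0) > 0) {
      v <- U0[1]
      lb <- lb + 1L
      hit <- unique(unlist(cov_u[coverers_u[[v]]]))
      U0 <- setdiff(U0, c(v, hit))
    }
    lb
  }

  lex_less <- function(a, b) {
    # a, b sorted integer vectors of equal length
    d <- which(a != b)
    length(d) > 0 && a[d[1]] < b[d[1]]
  }

  search <- function(sel, U0) {
    if (length(U0) == 0) {
      sz <- length(sel)
      full <- sort(c(S, sel))
      if (sz < best_size ||
          (sz == best_size && lex_less(full, best_set))) {
        best_size <<- sz
        best_set <<- full
      }
      return(invisible(NULL))
    }
    if (length(sel) + lower_bound(U0) > best_size) return(invisible(NULL))
    ncov <- vapply(U0, function(v) length(coverers_u[[v]]), integer(1))
    v <- U0[order(ncov, U0)][1]
    opts <- coverers_u[[v]]
    gains <- vapply(opts, function(u) sum(cov_u[[u]] %in% U0), integer(1))
    for (u in opts[order(-gains, opts)]) {
      search(c(sel, u), setdiff(U0, cov_u[[u]]))
    }
    invisible(NULL)
  }
  search(integer(0), U)

  res <- sort(ix$ids[best_set])
  attr(res, "optimality") <- "proven"
  res
}

#' Largest (weakly) connected component
#'
#' Connectivity is evaluated on the underlying undirected graph; ties in
#' component size are broken by the component containing the
#' lexicographically smallest node id. Returns the node-induced
#' subnetwork.
#'
#' @param net a `regulatory_network`.
#' @return a `regulatory_network` restricted to the LCC.
#' @export
largest_connected_component <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  if (nrow(net$nodes) == 0) stop("largest_connected_component: empty network")
  g <- .as_igraph(net)
  comp <- igraph::components(g, mode = "weak")
  mx <- max(comp$csize)
  in_max <- which(comp$csize == mx)
  members <- lapply(in_max, function(ci)
    igraph::V(g)$name[comp$membership == ci])
  pick <- in_max[order(vapply(members, min, character(1)))][1]
  keep <- igraph::V(g)$name[comp$membership == pick]
  nodes <- net$nodes[net$nodes$id %in% keep, , drop = FALSE]
  edges <- net$edges[net$edges$source %in% keep & net$edges$target %in% keep,
                     , drop = FALSE]
  regulatory_network(nodes, edges, provenance = net$provenance,
                     disease = net$disease)
}

#' Greedy minimum connected dominating set of the LCC
#'
#' Deterministic Guha-Khuller-style heuristic on the largest weakly
#' connected component: start from the maximum-total-degree node; repeatedly
#' add the undirected neighbor of the current set that dominates the most
#' not-yet-dominated LCC nodes (ties: higher degree, then lexicographic
#' id); when no frontier node gains coverage, step along the shortest
#' undirected path toward the nearest undominated node. Afterwards, members
#' are pruned in reverse insertion order when their removal preserves both
#' connectivity (undirected, induced) and domination (directed). The result
#' is feasible by construction but not guaranteed minimum.
#'
#' @param net a `regulatory_network`.
#' @return character vector of node ids (sorted); attribute `optimality`
#'   is "heuristic".
#' @export
minimum_connected_dominating_set <- function(net) {
  stopifnot(inherits(net, "regulatory_network"))
  lcc <- largest_connected_component(net)
  ix <- .net_index(lcc)
  n <- ix$n
  dom <- lapply(seq_len(n), function(i) c(i, ix$out_adj[[i]]))
  deg <- lengths(ix$in_adj) + lengths(ix$out_adj)

  if (n == 1) {
    res <- ix$ids
    attr(res, "optimality") <- "heuristic"
    return(res)
  }

  start <- order(-deg, ix$ids)[1]
  S <- start
  dominated <- rep(FALSE, n)
  dominated[dom[[start]]] <- TRUE

  bfs_step <- function(S) {
    # first step from S toward the nearest undominated node
    dist <- rep(NA_integer_, n); first <- rep(NA_integer_, n)
    queue <- S; dist[S] <- 0L
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in ix$und_adj[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          first[w] <- if (dist[v] == 0L) w else first[v]
          queue <- c(queue, w)
        }
      }
    }
    und <- which(!dominated & !is.na(dist))
    if (length(und) == 0) return(NA_integer_)
    tgt <- und[order(dist[und], und)][1]
    first[tgt]
  }

  while (!all(dominated)) {
    frontier <- setdiff(sort(unique(unlist(ix$und_adj[S]))), S)
    gains <- vapply(frontier, function(u) sum(!dominated[dom[[u]]]),
                    integer(1))
    if (length(frontier) > 0 && max(gains) > 0) {
      u <- frontier[order(-gains, -deg[frontier], frontier)][1]
    } else {
      u <- bfs_step(S)
      if (is.na(u)) {  # unreachable guard; cannot occur inside one component
        u <- which(!dominated)[1]
      }
    }
    S <- c(S, u)
    dominated[dom[[u]]] <- TRUE
  }

  dominates_all <- function(S0) {
    d <- rep(FALSE, n)
    for (u in S0) d[dom[[u]]] <- TRUE
    all(d)
  }
  connected_sub <- function(S0) {
    if (length(S0) <= 1) return(TRUE)
    seen <- rep(FALSE, n); seen[S0[1]] <- TRUE
    queue <- S0[1]
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (w in ix$und_adj[[v]]) if (w %in% S0 && !seen[w]) {
        seen[w] <- TRUE; queue <- c(queue, w)
      }
    }
    all(seen[S0])
  }
  for (u in rev(S)) {
    if (length(S) == 1) break
    S2 <- setdiff(S, u)
    if (dominates_all(S2) && connected_sub(S2)) S <- S2
  }

  res <- sort(ix$ids[S])
  attr(res, "optimality") <- "heuristic"
  res
}

#' Key-player report for one network
#'
#' @param net a `regulatory_network`.
#' @param hub_fraction hub fraction (default 0.10).
#' @return a `key_player_report`: list with `network_id`, `hubs`, `mds`,
#'   `mcds`, `lcc_size`, `optimality`.
#' @export
key_player_report <- function(net, hub_fraction = 0.10) {
  stopifnot(inherits(net, "regulatory_network"))
  if (nrow(net$nodes) == 0) {
    return(structure(list(network_id = net$provenance, hubs = character(),
                          mds = character(), mcds = character(),
                          lcc_size = 0L,
                          optimality = c(mds = "proven", mcds = "heuristic")),
                     class = "key_player_report"))
  }
  lcc <- largest_connected_component(net)
  structure(list(network_id = net$provenance,
                 hubs = hub_nodes(net, hub_fraction),
                 mds = as.character(minimum_dominating_set(net)),
                 mcds = as.character(minimum_connected_dominating_set(net)),
                 lcc_size = nrow(lcc$nodes),
                 optimality = c(mds = "proven", mcds = "heuristic")),
            class = "key_player_report")
}

#' @export
print.key_player_report <- function(x, ...) {
  cat(sprintf("key_player_report [%s]: %d hubs, %d MDS, %d MCDS (LCC %d)\n",
              x$network_id, length(x$hubs), length(x$mds), length(x$mcds),
              x$lcc_size))
  invisible(x)
}
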