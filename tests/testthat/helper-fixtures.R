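# Shared fixtures and independent brute-force oracles.

# build a regulatory_network from edge vectors (node types default "gene")
make_net <- function(from = character(), to = character(),
                     isolated = character(), types = NULL) {
  ids <- sort(unique(c(from, to, isolated)))
  if (is.null(types)) types <- rep("gene", length(ids))
  nodes <- data.frame(id = ids, type = types, stringsAsFactors = FALSE)
  edges <- if (length(from) == 0)
    data.frame(source = character(), target = character(),
               type = character())
  else data.frame(source = from, target = to,
                  type = rep("TF->gene", length(from)),
                  stringsAsFactors = FALSE)
  regulatory_network(nodes, edges, provenance = "fixture")
}

# seeded random digraph with n nodes and edge probability p
rand_digraph <- function(n, p, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n))
  pairs <- expand.grid(from = ids, to = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$from != pairs$to, ]
  pick <- runif(nrow(pairs)) < p
  make_net(pairs$from[pick], pairs$to[pick], isolated = ids)
}

.adj_oracle <- function(net) {
  ids <- sort(net$nodes$id)
  n <- length(ids)
  si <- match(net$edges$source, ids); ti <- match(net$edges$target, ids)
  out_adj <- lapply(seq_len(n), function(i) unique(ti[si == i]))
  und_adj <- lapply(seq_len(n), function(i)
    unique(c(ti[si == i], si[ti == i])))
  list(ids = ids, n = n, out = out_adj, und = und_adj)
}

oracle_dominates <- function(net, S) {
  a <- .adj_oracle(net)
  idx <- match(S, a$ids)
  dom <- unique(c(idx, unlist(a$out[idx])))
  length(setdiff(seq_len(a$n), dom)) == 0
}

oracle_connected <- function(net, S) {
  a <- .adj_oracle(net)
  idx <- match(S, a$ids)
  if (length(idx) <= 1) return(TRUE)
  seen <- idx[1]; queue <- idx[1]
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    nb <- intersect(a$und[[v]], idx)
    new <- setdiff(nb, seen)
    seen <- c(seen, new); queue <- c(queue, new)
  }
  setequal(seen, idx)
}

# exhaustive minimum dominating set size (directed domination)
brute_mds_size <- function(net) {
  a <- .adj_oracle(net)
  n <- a$n
  dom <- lapply(seq_len(n), function(i) unique(c(i, a$out[[i]])))
  for (k in 0:n) {
    for (S in utils::combn(n, k, simplify = FALSE)) {
      if (length(setdiff(seq_len(n), unique(unlist(dom[S])))) == 0)
        return(k)
    }
  }
  n
}

# exhaustive minimum connected dominating set size of the LCC
brute_mcds_size <- function(net) {
  lcc <- largest_connected_component(net)
  a <- .adj_oracle(lcc)
  n <- a$n
  dom <- lapply(seq_len(n), function(i) unique(c(i, a$out[[i]])))
  for (k in 1:n) {
    for (S in utils::combn(n, k, simplify = FALSE)) {
      if (length(setdiff(seq_len(n), unique(unlist(dom[S])))) > 0) next
      if (oracle_connected(lcc, a$ids[S])) return(k)
    }
  }
  n
}

# hypergeometric upper tail by direct combinatorial enumeration
brute_hyper <- function(x, k, K, N) {
  j <- x:min(k, K)
  sum(choose(K, j) * choose(N - K, k - j)) / choose(N, k)
}

# conditional NB exact test by naive enumeration (no log-space tricks)
brute_nb_exact <- function(k_a, k_b, n_a, n_b, disp) {
  ks <- k_a + k_b
  if (ks == 0) return(1)
  mu <- ks / (n_a + n_b)
  pr <- function(x, n) {
    if (disp <= 1e-12) dpois(x, n * mu)
    else dnbinom(x, size = n / disp, mu = n * mu)
  }
  a <- 0:ks
  mass <- pr(a, n_a) * pr(ks - a, n_b)
  obs <- mass[k_a + 1]
  sum(mass[mass <= obs * (1 + 1e-7)]) / sum(mass)
}

# small simulated dataset reused across test files
shared_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_genes = 400, n_tfs = 50, n_mirnas = 30,
                        n_per_group = 6, seed = 101)
      cache <<- list(cfg = cfg, sim = simulate_counts(cfg),
                     db = simulate_interaction_db(cfg))
    }
    cache
  }
})
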