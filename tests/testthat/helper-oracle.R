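# Exhaustive least-squares oracle for small unrooted trees, independent of
# the package's neighbor-joining implementation. Trees are edge matrices over
# leaves 1..n and internal nodes n+1..2n-2.

enumerate_topologies <- function(n) {
  stopifnot(n >= 3)
  trees <- list(matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L),
                       ncol = 2, byrow = TRUE))
  if (n == 3) return(trees)
  for (l in 4:n) {
    new_node <- n + l - 2L
    out <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr))) {
        t2 <- rbind(tr[-e, , drop = FALSE],
                    c(tr[e, 1], new_node),
                    c(new_node, tr[e, 2]),
                    c(new_node, l))
        out[[length(out) + 1L]] <- t2
      }
    }
    trees <- out
  }
  trees
}

# Pair x edge incidence matrix: which edges lie on the leaf-to-leaf path.
edge_incidence <- function(edges, n_leaf) {
  nmax <- max(edges)
  adj <- vector("list", nmax)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- rbind(adj[[a]], c(k, b))
    adj[[b]] <- rbind(adj[[b]], c(k, a))
  }
  path_from <- function(src) {
    prev_edge <- rep(NA_integer_, nmax)
    prev_node <- rep(NA_integer_, nmax)
    seen <- rep(FALSE, nmax); seen[src] <- TRUE
    queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- adj[[v]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        u <- nb[r, 2]
        if (!seen[u]) {
          seen[u] <- TRUE
          prev_edge[u] <- nb[r, 1]; prev_node[u] <- v
          queue <- c(queue, u)
        }
      }
    }
    list(pe = prev_edge, pn = prev_node)
  }
  pairs <- utils::combn(n_leaf, 2)
  A <- matrix(0, ncol(pairs), nrow(edges))
  for (p in seq_len(ncol(pairs))) {
    bt <- path_from(pairs[1, p])
    v <- pairs[2, p]
    while (v != pairs[1, p]) {
      A[p, bt$pe[v]] <- 1
      v <- bt$pn[v]
    }
  }
  list(A = A, pairs = pairs)
}

ls_fit_topology <- function(edges, dmat) {
  n <- nrow(dmat)
  inc <- edge_incidence(edges, n)
  y <- dmat[cbind(inc$pairs[1, ], inc$pairs[2, ])]
  fit <- stats::lm.fit(inc$A, y)
  fitted <- as.vector(inc$A %*% fit$coefficients)
  list(rss = sum((y - fitted)^2), fitted = fitted,
       pairs = inc$pairs, coef = fit$coefficients)
}

# Leaves reachable from `start` after deleting one edge.
component_leaves <- function(edges, start, n_leaf) {
  nmax <- max(c(edges, start, n_leaf))
  adj <- vector("list", nmax)
  for (k in seq_len(nrow(edges))) {
    a <- edges[k, 1]; b <- edges[k, 2]
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  seen <- rep(FALSE, nmax); seen[start] <- TRUE
  queue <- start
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (u in adj[[v]]) if (!seen[u]) { seen[u] <- TRUE; queue <- c(queue, u) }
  }
  which(seen[seq_len(n_leaf)])
}

# Canonical nontrivial bipartition keys of an edge-matrix tree, in the same
# format the package uses (side not containing the first sorted taxon).
oracle_bipartition_keys <- function(edges, taxa) {
  n <- length(taxa)
  anchor <- sort(taxa)[1]
  keys <- character(0)
  for (k in seq_len(nrow(edges))) {
    side <- taxa[component_leaves(edges[-k, , drop = FALSE], edges[k, 1], n)]
    if (length(side) < 2 || length(side) > n - 2) next
    if (anchor %in% side) side <- setdiff(taxa, side)
    keys <- c(keys, paste(sort(side), collapse = "\r"))
  }
  sort(unique(keys))
}

oracle_best_tree <- function(dmat) {
  topos <- enumerate_topologies(nrow(dmat))
  fits <- lapply(topos, ls_fit_topology, dmat = dmat)
  best <- which.min(vapply(fits, `[[`, 0, "rss"))
  list(edges = topos[[best]], fit = fits[[best]],
       keys = oracle_bipartition_keys(topos[[best]], rownames(dmat)))
}

# Draw a random additive distance matrix from a random topology with edge
# lengths uniform in [0.1, 1].
random_additive_matrix <- function(n, taxa = sprintf("t%02d", seq_len(n))) {
  topos <- enumerate_topologies(n)
  edges <- topos[[sample.int(length(topos), 1)]]
  lens <- stats::runif(nrow(edges), 0.1, 1)
  inc <- edge_incidence(edges, n)
  pl <- as.vector(inc$A %*% lens)
  d <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (p in seq_len(ncol(inc$pairs))) {
    i <- inc$pairs[1, p]; j <- inc$pairs[2, p]
    d[i, j] <- d[j, i] <- pl[p]
  }
  list(d = d, edges = edges, keys = oracle_bipartition_keys(edges, taxa))
}

# Bipartition keys of an ape phylo tree (package-internal canonical form).
phylo_keys <- function(tree) sort(unname(tpsminer:::bipartition_keys(tree)))
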