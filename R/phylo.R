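# Distance phylogenetics: p-distances with pairwise deletion, neighbor
# joining, bootstrap supports, and clade-based subfamily assignment against
# a labeled reference panel. Trees are ape "phylo" objects throughout.

#' Phylogeny configuration
#'
#' @param bootstrap_replicates Column-resampling replicates (default 1000).
#' @param support_threshold Percent support required before a clade is used
#'   for subfamily assignment (default 80).
#' @param rng_seed Seed for the bootstrap resampling.
#' @param negative_branch_policy Only \code{"clamp_to_zero"} is implemented:
#'   negative NJ branch-length estimates are reported as 0.
#' @return A \code{PhyloConfig}.
#' @export
phylo_config <- function(bootstrap_replicates = 1000L,
                         support_threshold = 80,
                         rng_seed = 1L,
                         negative_branch_policy = "clamp_to_zero") {
  stopifnot(bootstrap_replicates >= 1, support_threshold > 0,
            support_threshold <= 100,
            negative_branch_policy == "clamp_to_zero")
  structure(list(bootstrap_replicates = as.integer(bootstrap_replicates),
                 support_threshold = support_threshold,
                 rng_seed = rng_seed,
                 negative_branch_policy = negative_branch_policy),
            class = "PhyloConfig")
}

#' Stack equal-rate sequences into an alignment view
#'
#' Right-pads sequences with gap characters to a common length. Intended for
#' indel-free sequence sets (such as the synthetic panels, where proteins of
#' one subfamily share coordinates); it is not an aligner.
#'
#' @param seqs Named character vector of residue strings.
#' @return Named character vector of equal-length rows.
#' @export
stack_alignment <- function(seqs) {
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  L <- max(nchar(seqs))
  pad <- function(s) paste0(s, strrep("-", L - nchar(s)))
  stats::setNames(vapply(seqs, pad, character(1)), names(seqs))
}

# Alignment rows -> integer matrix (taxa x sites); NA marks gap/missing.
alignment_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  if (length(unique(nchar(alignment))) != 1)
    stop("alignment rows of unequal length")
  m <- do.call(rbind, lapply(alignment, function(s) {
    v <- match(split_chars(s), AA20)   # gap '-', '?', 'X', '*' -> NA
    v
  }))
  rownames(m) <- names(alignment)
  m
}

#' Pairwise p-distances with pairwise deletion
#'
#' \eqn{d_{ij}} is the proportion of differing residues over the sites where
#' both rows carry a defined residue; a gap (\code{-}) or missing (\code{?})
#' symbol in either row excludes that site for that pair only. A pair with
#' zero comparable sites is an error naming the pair.
#'
#' @param alignment Named character vector of equal-length rows (or a
#'   pre-built integer site matrix).
#' @return Symmetric distance matrix with zero diagonal, values in [0, 1].
#' @export
pairwise_p_distance <- function(alignment) {
  m <- alignment_matrix(alignment)
  if (nrow(m) < 2) stop("need at least 2 taxa")
  def <- !is.na(m)
  storage.mode(def) <- "double"
  comparable <- tcrossprod(def)
  eq <- matrix(0, nrow(m), nrow(m))
  for (a in sort(unique(m[def > 0]))) {
    ia <- (m == a & !is.na(m))
    storage.mode(ia) <- "double"
    eq <- eq + tcrossprod(ia)
  }
  off <- which(comparable == 0, arr.ind = TRUE)
  off <- off[off[, 1] < off[, 2], , drop = FALSE]
  if (nrow(off))
    stop("zero comparable sites for pair ",
         rownames(m)[off[1, 1]], ", ", rownames(m)[off[1, 2]])
  d <- (comparable - eq) / comparable
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}

#' Neighbor joining
#'
#' Standard Saitou-Nei agglomeration: repeatedly join the pair (i, j)
#' minimizing \eqn{Q(i,j) = (n-2) d_{ij} - \sum_k d_{ik} - \sum_k d_{jk}}.
#' Ties are broken by the lexicographically smallest taxon pair (a merged
#' node is represented by the smallest leaf label underneath it). Branch
#' lengths come from the standard formulas; negative estimates are clamped
#' to zero when the tree is emitted (raw values are kept in the
#' \code{raw_edge_length} attribute). On an additive distance matrix the
#' output tree reproduces the matrix exactly.
#'
#' @param dm Symmetric distance matrix with taxon dimnames.
#' @return Unrooted \code{ape::phylo} tree.
#' @export
neighbor_joining <- function(dm) {
  dm <- as.matrix(dm)
  if (nrow(dm) != ncol(dm)) stop("non-square distance matrix")
  if (max(abs(dm - t(dm))) > 1e-12) stop("asymmetric distance matrix")
  taxa <- rownames(dm)
  if (is.null(taxa)) stop("distance matrix must carry taxon names")
  n <- length(taxa)
  if (n < 3) stop("need at least 3 taxa")

  raw <- numeric(0)
  # Each active node is a Newick fragment; rep = smallest leaf label under it.
  frag <- taxa
  rep_lab <- taxa
  D <- dm
  clamp <- function(x) {
    raw <<- c(raw, x)
    max(x, 0)
  }
  fmt <- function(x) sprintf("%.15g", x)

  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    keys <- apply(cand, 1, function(ij) {
      pr <- sort(c(rep_lab[ij[1]], rep_lab[ij[2]]))
      paste(pr, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    vj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    new_frag <- paste0("(", frag[i], ":", fmt(vi), ",",
                       frag[j], ":", fmt(vj), ")")
    new_rep <- min(rep_lab[i], rep_lab[j])
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    rep_lab <- c(rep_lab[keep], new_rep)
    D <- D2
  }

  if (nrow(D) == 3) {
    va <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
    vb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
    vc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
    newick <- paste0("(", frag[1], ":", fmt(va), ",",
                     frag[2], ":", fmt(vb), ",",
                     frag[3], ":", fmt(vc), ");")
  } else {
    stop("need at least 3 taxa")
  }
  tree <- ape::read.tree(text = newick)
  attr(tree, "raw_edge_length") <- raw
  tree
}

# Tip labels under each internal node (node id -> character vector).
node_tip_sets <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  sets <- vector("list", n_tip + n_node)
  for (i in seq_len(n_tip)) sets[[i]] <- tree$tip.label[i]
  # edges in postorder: children resolved before parents
  ord <- ape::reorder.phylo(tree, "postorder")
  for (k in seq_len(nrow(ord$edge))) {
    par <- ord$edge[k, 1]; chi <- ord$edge[k, 2]
    sets[[par]] <- c(sets[[par]], sets[[chi]])
  }
  sets
}

# Canonical bipartition keys for all internal edges. The side not containing
# the alphabetically first taxon is sorted and collapsed into the key, so
# keys are invariant to taxon input order and to tree rotations.
bipartition_keys <- function(tree) {
  n_tip <- length(tree$tip.label)
  all_taxa <- sort(tree$tip.label)
  anchor <- all_taxa[1]
  sets <- node_tip_sets(tree)
  root <- n_tip + 1L
  internal <- setdiff(seq_len(n_tip + tree$Nnode), c(seq_len(n_tip), root))
  keys <- vapply(internal, function(v) {
    side <- sets[[v]]
    if (anchor %in% side) side <- setdiff(all_taxa, side)
    paste(sort(side), collapse = "\r")
  }, character(1))
  stats::setNames(keys, internal)
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Columns of the alignment are resampled with replacement (same length),
#' the p-distance matrix and NJ tree are recomputed per replicate, and the
#' support of each internal edge of the full-data tree is the percentage of
#' replicates containing the same bipartition. Supports are stored as integer
#' node labels on the internal nodes (the basal node of the unrooted tree,
#' which defines no bipartition, is left blank). Resampling is keyed to
#' column positions, so results are invariant to taxon input order under a
#' fixed seed.
#'
#' @param alignment Named character vector of equal-length rows.
#' @param config A \code{PhyloConfig}.
#' @return \code{ape::phylo} tree with integer percent supports in
#'   \code{node.label} and a \code{supports} attribute (named by node id).
#' @export
bootstrap_support <- function(alignment, config = phylo_config()) {
  m <- alignment_matrix(alignment)
  if (nrow(m) < 4) stop("need at least 4 taxa for bootstrap supports")
  m <- m[order(rownames(m)), , drop = FALSE]
  L <- ncol(m)
  tree <- neighbor_joining(pairwise_p_distance(m))
  keys <- bipartition_keys(tree)
  counts <- stats::setNames(numeric(length(keys)), keys)

  with_seed(config$rng_seed, {
    for (b in seq_len(config$bootstrap_replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      mb <- m[, cols, drop = FALSE]
      tb <- tryCatch(neighbor_joining(pairwise_p_distance(mb)),
                     error = function(e)
                       stop("bootstrap replicate ", b, ": ",
                            conditionMessage(e)))
      kb <- bipartition_keys(tb)
      hit <- names(counts) %in% kb
      counts[hit] <- counts[hit] + 1
    }
  })

  supports <- round(100 * counts / config$bootstrap_replicates)
  n_tip <- length(tree$tip.label)
  labels <- rep("", tree$Nnode)
  node_ids <- as.integer(names(keys))
  labels[node_ids - n_tip] <- as.character(as.integer(supports))
  tree$node.label <- labels
  attr(tree, "supports") <- stats::setNames(as.integer(supports),
                                            names(keys))
  tree
}

#' Assign TPS subfamilies by clade membership
#'
#' For each query taxon, the smallest clade (bipartition side) that contains
#' the query, at least one labeled reference, and has bootstrap support at or
#' above the threshold determines the call: the majority reference label in
#' that clade (a label tie gives \code{unclassified} with note \code{TIE}).
#' When no such clade exists the nearest reference by patristic distance is
#' used, flagged \code{FALLBACK_NEAREST}.
#'
#' @param tree Tree with supports from [bootstrap_support()].
#' @param reference_labels Named character vector mapping reference taxon
#'   names to subfamily labels.
#' @param queries Character vector of query taxon names.
#' @param config A \code{PhyloConfig} (support threshold).
#' @return data.frame with \code{gene_id}, \code{subfamily}, \code{support},
#'   \code{note}.
#' @export
assign_subfamily <- function(tree, reference_labels, queries,
                             config = phylo_config()) {
  refs <- names(reference_labels)
  if (!any(refs %in% tree$tip.label))
    stop("tree contains no labeled reference taxa")
  n_tip <- length(tree$tip.label)
  sets <- node_tip_sets(tree)
  supports <- attr(tree, "supports")
  if (is.null(supports)) {
    lab <- suppressWarnings(as.integer(tree$node.label))
    internal <- setdiff(seq_len(n_tip + tree$Nnode),
                        c(seq_len(n_tip), n_tip + 1L))
    supports <- stats::setNames(lab[internal - n_tip], internal)
  }
  all_taxa <- tree$tip.label
  patristic <- NULL

  res <- lapply(queries, function(q) {
    best <- NULL
    for (v in names(supports)) {
      s <- supports[[v]]
      if (is.na(s) || s < config$support_threshold) next
      inside <- sets[[as.integer(v)]]
      side <- if (q %in% inside) inside else setdiff(all_taxa, inside)
      r_in <- intersect(side, refs)
      if (!length(r_in)) next
      size <- length(side)
      if (is.null(best) || size < best$size ||
          (size == best$size && s > best$support)) {
        best <- list(size = size, support = s, refs = r_in)
      }
    }
    if (!is.null(best)) {
      tab <- sort(table(reference_labels[best$refs]), decreasing = TRUE)
      if (length(tab) > 1 && tab[1] == tab[2]) {
        return(data.frame(gene_id = q, subfamily = "unclassified",
                          support = best$support, note = "TIE",
                          stringsAsFactors = FALSE))
      }
      return(data.frame(gene_id = q, subfamily = names(tab)[1],
                        support = best$support, note = "",
                        stringsAsFactors = FALSE))
    }
    if (is.null(patristic))
      patristic <<- stats::cophenetic(tree)
    dq <- patristic[q, intersect(refs, all_taxa)]
    nearest <- names(dq)[which.min(dq)]
    data.frame(gene_id = q, subfamily = reference_labels[[nearest]],
               support = NA_integer_, note = "FALLBACK_NEAREST",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
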