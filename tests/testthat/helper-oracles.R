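# Brute-force oracles, deliberately independent of the package's postorder
# accumulation engines: every quantity is derived from explicit root-to-tip
# edge paths on the raw edge matrix.

# List of edge-row indices on the path from the root down to a tip.
path_edges <- function(tree, tip_label) {
  i <- match(tip_label, tree$tip.label)
  stopifnot(!is.na(i))
  edges <- integer()
  node <- i
  repeat {
    row <- which(tree$edge[, 2] == node)
    if (length(row) == 0L) break
    edges <- c(edges, row)
    node <- tree$edge[row, 1]
  }
  edges
}

spanning_edges <- function(tree, taxa) {
  unique(unlist(lapply(taxa, path_edges, tree = tree)))
}

oracle_pd <- function(tree, taxa) {
  sum(tree$edge.length[spanning_edges(tree, taxa)]) + (tree$root.edge %||% 0)
}

oracle_dist <- function(tree, a, b) {
  if (a == b) return(0)
  pa <- path_edges(tree, a)
  pb <- path_edges(tree, b)
  sym <- c(setdiff(pa, pb), setdiff(pb, pa))
  sum(tree$edge.length[sym])
}

oracle_mpd <- function(tree, taxa) {
  pairs <- utils::combn(taxa, 2)
  mean(apply(pairs, 2, function(p) oracle_dist(tree, p[1], p[2])))
}

oracle_mntd <- function(tree, taxa) {
  mean(vapply(taxa, function(a) {
    min(vapply(setdiff(taxa, a), function(b) oracle_dist(tree, a, b), numeric(1)))
  }, numeric(1)))
}

oracle_phylosor <- function(tree, taxa_a, taxa_b) {
  ea <- spanning_edges(tree, taxa_a)
  eb <- spanning_edges(tree, taxa_b)
  re <- tree$root.edge %||% 0
  shared <- sum(tree$edge.length[intersect(ea, eb)]) + re
  2 * shared / (oracle_pd(tree, taxa_a) + oracle_pd(tree, taxa_b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Fixtures -------------------------------------------------------------------

demo_tree <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")

# A small six-island flora exercising all the assembly rules.
demo_flora <- function() {
  island_flora(
    tibble::tibble(
      species = c("a", "b", "c", "x"),
      status = c("native", "native", "native", "exotic"),
      extinct = c(FALSE, TRUE, FALSE, FALSE),
      isla = c(1, 1, 1, 1),
      islb = c(0, 1, 1, 0)
    ),
    tibble::tibble(island = c("isla", "islb"), lat = c(-27, -33), lon = c(-109, -80))
  )
}

# Balanced binary chronogram with unit branch lengths and 2^k tips.
balanced_tree <- function(k) {
  tr <- ape::stree(2^k, type = "balanced")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- sprintf("t%02d", seq_len(2^k))
  tr$root.edge <- 0
  tr
}

# Random chronogram with tips relabelled s1..sn.
random_coalescent <- function(n) {
  tr <- ape::rcoal(n)
  tr$tip.label <- paste0("s", seq_len(n))
  tr
}

# Build a pure chain tree root -> n1 -> ... -> tip programmatically (ape's
# Newick reader misorders labels on nested singleton nodes).
chain_tree <- function(n_internal, labels = c("root", paste0("n", seq_len(n_internal - 1)))) {
  stopifnot(n_internal >= 1, length(labels) == n_internal)
  children <- if (n_internal == 1L) 1L else c(3:(n_internal + 1L), 1L)
  edge <- cbind(2:(n_internal + 1L), children)
  structure(
    list(
      edge = matrix(as.integer(edge), ncol = 2),
      Nnode = as.integer(n_internal),
      tip.label = "t",
      node.label = labels
    ),
    class = "phylo"
  )
}
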