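# --- metric engines ---------------------------------------------------------
#
# All alpha and beta metrics run off one preprocessed context per tree:
#  * edge_tips: logical edges x tips matrix, TRUE when the tip descends from
#    the edge's child node (so an edge belongs to the root-inclusive spanning
#    subtree of a set S iff it subtends >= 1 member of S);
#  * len / root_edge: branch lengths aligned with edge_tips rows;
#  * dist: tip-tip patristic distance matrix (lazy; only built when a
#    distance metric is requested).
metric_context <- function(tree, need_dist = FALSE) {
  validate_phylogeny(tree)
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  n <- ape::Ntip(tree)
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  post <- rev(edge_preorder(tree))
  desc <- vector("list", n + tree$Nnode)
  desc[seq_len(n)] <- as.list(seq_len(n))
  for (e in post) {
    desc[[parent[e]]] <- c(desc[[parent[e]]], desc[[child[e]]])
  }
  edge_tips <- matrix(FALSE, length(parent), n)
  for (e in seq_along(parent)) edge_tips[e, desc[[child[e]]]] <- TRUE
  list(
    n = n,
    labels = tree$tip.label,
    edge_tips = edge_tips,
    len = tree$edge.length,
    root_edge = tree$root.edge %||% 0,
    dist = if (need_dist) stats::cophenetic(tree)[tree$tip.label, tree$tip.label]
  )
}

ctx_pd <- function(ctx, idx) {
  hit <- rowSums(ctx$edge_tips[, idx, drop = FALSE]) > 0
  sum(ctx$len[hit]) + ctx$root_edge
}

ctx_mpd <- function(ctx, idx) {
  d <- ctx$dist[idx, idx]
  mean(d[lower.tri(d)])
}

ctx_mntd <- function(ctx, idx) {
  d <- ctx$dist[idx, idx]
  diag(d) <- Inf
  mean(apply(d, 1L, min))
}

ctx_metric <- function(ctx, idx, metric) {
  switch(metric,
    pd = ctx_pd(ctx, idx),
    mpd = ctx_mpd(ctx, idx),
    mntd = ctx_mntd(ctx, idx)
  )
}

# --- user-facing metrics ----------------------------------------------------

#' Patristic distance between two tips
#'
#' Sum of branch lengths along the path connecting two tips.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param a,b Tip labels.
#' @return A nonnegative number; 0 iff `a == b`.
#' @export
pairwise_distance <- function(tree, a, b) {
  idx <- c(tip_index(tree, a), tip_index(tree, b))
  if (a == b) return(0)
  d <- node_depths(tree)
  mrca <- ape::getMRCA(tree, idx)
  d[idx[1]] + d[idx[2]] - 2 * d[mrca]
}

#' Faith's phylogenetic diversity
#'
#' Total branch length of the minimal subtree connecting the taxa and the
#' root (root-inclusive convention, so the PD of a single species is the
#' length of its path to the root and PD is well-defined for any nonempty
#' set). Equals the total tree length on the full tip set.
#'
#' @param tree A `phylo` object with branch lengths.
#' @param taxa Character vector of tip labels (nonempty; all must be in the
#'   tree).
#' @return PD in branch-length units (millions of years on a chronogram).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
#' faith_pd(tr, c("A", "B"))
#' @export
faith_pd <- function(tree, taxa) {
  idx <- tip_index(tree, taxa)
  ctx <- metric_context(tree)
  ctx_pd(ctx, match(tree$tip.label[idx], ctx$labels))
}

#' Mean pairwise phylogenetic distance (MPD)
#'
#' Mean patristic distance over all unordered pairs of taxa
#' (presence-weighted; no abundances). Sensitive to the deep structure of
#' the phylogeny (orders, families).
#'
#' @inheritParams faith_pd
#' @param taxa At least two tip labels.
#' @return MPD in branch-length units.
#' @export
mpd <- function(tree, taxa) {
  idx <- tip_index(tree, taxa)
  if (length(idx) < 2L) abort("mpd requires at least 2 taxa")
  ctx <- metric_context(tree, need_dist = TRUE)
  ctx_mpd(ctx, match(tree$tip.label[idx], ctx$labels))
}

#' Mean nearest taxon distance (MNTD)
#'
#' Mean, over the taxa, of the patristic distance to the closest other
#' member of the set. Sensitive to the terminal structure of the phylogeny
#' (recent events such as local extinction or introduction of close
#' relatives).
#'
#' @inheritParams mpd
#' @return MNTD in branch-length units; always `<=` MPD.
#' @export
mntd <- function(tree, taxa) {
  idx <- tip_index(tree, taxa)
  if (length(idx) < 2L) abort("mntd requires at least 2 taxa")
  ctx <- metric_context(tree, need_dist = TRUE)
  ctx_mntd(ctx, match(tree$tip.label[idx], ctx$labels))
}

# Match assemblage species to tree tips, honouring skip_missing.
match_assemblage <- function(ctx, species, skip_missing, where) {
  idx <- match(species, ctx$labels)
  miss <- species[is.na(idx)]
  if (length(miss) && !skip_missing) {
    abort(paste0(
      where, ": species absent from the tree: ", paste(miss, collapse = ", "),
      " (use skip_missing = TRUE to drop them)"
    ))
  }
  if (length(miss)) {
    rlang::inform(paste0(where, ": dropping ", length(miss), " species absent from the tree"))
  }
  idx[!is.na(idx)]
}

#' Phylogenetic alpha diversity per island, period, and scope
#'
#' Computes Faith's PD, MPD, and MNTD for every requested island x period x
#' scope assemblage against the full regional chronogram (assemblages are
#' scored in place; pruning preserves all pairwise distances, so re-pruning
#' is never needed). MPD and MNTD are `NA` for assemblages of fewer than two
#' matched species.
#'
#' @param tree Regional chronogram (`phylo` with branch lengths).
#' @param flora An `island_flora` object.
#' @param periods Periods to score.
#' @param scopes Scopes to score (the invalid pre-European exotic
#'   combination is skipped automatically).
#' @param skip_missing Drop species missing from the tree (with a message)
#'   instead of erroring. Silent drops corrupt standardized effect sizes, so
#'   the default is to error.
#' @return A tibble with columns `island`, `period`, `scope`, `n_species`,
#'   `n_matched`, `pd`, `mpd`, `mntd`.
#' @export
alpha_diversity <- function(tree, flora,
                            periods = c("pre_european", "current"),
                            scopes = c("complete", "native_only"),
                            skip_missing = FALSE) {
  stopifnot(inherits(flora, "island_flora"))
  ctx <- metric_context(tree, need_dist = TRUE)
  grid <- tidyr::expand_grid(
    island = flora$island_names, period = periods, scope = scopes
  ) |>
    dplyr::filter(!(.data$period == "pre_european" & .data$scope == "exotic_only"))
  purrr::pmap_dfr(grid, function(island, period, scope) {
    sp <- assemble(flora, island, period, scope)
    idx <- if (length(sp)) {
      match_assemblage(ctx, sp, skip_missing, paste(island, period, scope, sep = "/"))
    } else integer()
    tibble(
      island = island, period = period, scope = scope,
      n_species = length(sp), n_matched = length(idx),
      pd = if (length(idx) >= 1L) ctx_pd(ctx, idx) else NA_real_,
      mpd = if (length(idx) >= 2L) ctx_mpd(ctx, idx) else NA_real_,
      mntd = if (length(idx) >= 2L) ctx_mntd(ctx, idx) else NA_real_
    )
  })
}
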