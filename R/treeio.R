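#' Parse a Newick string into a rooted phylogeny
#'
#' Reads a single rooted tree in Newick format. Branch lengths are optional
#' and, when present, are interpreted in millions of years. Internal node
#' labels (family/order names used as graft points) are preserved verbatim;
#' underscores in labels are treated literally, quoted labels are honoured.
#'
#' @param text A Newick string (one tree, terminated by `;`).
#' @return An object of class `phylo` (see \pkg{ape}).
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
#' total_branch_length(tr)
#' @seealso [read_newick()], [write_newick()]
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  scan_newick(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) abort(paste0("failed to parse Newick: ", conditionMessage(e)))
  )
  if (is.null(tree)) abort("failed to parse Newick: no tree found in input")
  if (inherits(tree, "multiPhylo")) abort("expected a single tree, found several")
  validate_phylogeny(tree)
  tree
}

#' Read a phylogeny from a Newick file
#'
#' @param path Path to a file holding a single Newick tree.
#' @return A `phylo` object.
#' @export
read_newick <- function(path) {
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a phylogeny to Newick
#'
#' Unset branch lengths are omitted (absence is not written as zero). The
#' output re-parses to a tree with identical topology, labels, and branch
#' lengths to the stated precision.
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Number of significant digits for branch lengths (default 6).
#' @return The Newick string (invisibly when `file` is given).
#' @export
write_newick <- function(tree, file = NULL, digits = 6) {
  validate_phylogeny(tree)
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

# Structural scan used for error reporting with a character offset: ape's
# parser is permissive and its messages carry no position.
scan_newick <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  in_quote <- FALSE
  quote_start <- NA_integer_
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_quote) {
      if (ch == "'") in_quote <- FALSE
      next
    }
    if (ch == "'") {
      in_quote <- TRUE
      quote_start <- i
    } else if (ch == "(") {
      depth <- depth + 1L
    } else if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        abort(sprintf("malformed Newick: unmatched ')' at character %d", i))
      }
    }
  }
  if (in_quote) {
    abort(sprintf("malformed Newick: unterminated quote opened at character %d", quote_start))
  }
  if (depth > 0L) {
    abort(sprintf(
      "malformed Newick: %d unclosed '(' at end of input (character %d)",
      depth, length(chars)
    ))
  }
  invisible(TRUE)
}

#' Validate a phylogeny
#'
#' Checks the invariants assumed throughout the package: a single rooted
#' tree, unique nonempty tip labels, and nonnegative branch lengths where
#' lengths are present.
#'
#' @param tree A `phylo` object.
#' @return `tree`, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) abort("not a 'phylo' object")
  labs <- tree$tip.label
  if (any(is.na(labs) | labs == "")) abort("tip labels must be nonempty")
  dup <- unique(labs[duplicated(labs)])
  if (length(dup)) {
    abort(paste0("duplicate tip labels: ", paste(dup, collapse = ", ")))
  }
  if (!is.null(tree$edge.length)) {
    if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
      abort("branch lengths must be nonnegative and non-missing")
    }
  }
  invisible(tree)
}

#' Total branch length of a tree
#'
#' Sum of all branch lengths including the root edge, if one is stored.
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A nonnegative number (millions of years for a chronogram).
#' @export
total_branch_length <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  sum(tree$edge.length) + (tree$root.edge %||% 0)
}

# Edge indices ordered parent-before-child (preorder). Unlike
# ape::reorder.phylo this is reliable on trees with degree-2 (singleton)
# nodes, which age-calibration chains contain. rev() of it is a postorder.
edge_preorder <- function(tree) {
  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  kids <- split(seq_along(parent), parent)
  root <- unique(parent[!(parent %in% child)])
  out <- integer(length(parent))
  queue <- as.character(root)
  k <- 0L
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    es <- kids[[v]]
    if (is.null(es)) next
    out[k + seq_along(es)] <- es
    k <- k + length(es)
    queue <- c(queue, as.character(child[es]))
  }
  out
}

# Map taxon names to tip indices, erroring with the full list of misses.
tip_index <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0L) abort("taxon set is empty")
  idx <- match(taxa, tree$tip.label)
  if (anyNA(idx)) {
    abort(paste0(
      "taxa not found in tree: ",
      paste(taxa[is.na(idx)], collapse = ", ")
    ))
  }
  idx
}

# Depth (distance from the root, in branch-length units) of every node.
node_depths <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Graft a subtree under a named interior node
#'
#' Attaches the root of `subtree` as a new child of the interior node of
#' `tree` whose label is `at` — the megatree workflow in which species or
#' clades missing from a backbone are hung under their family or order.
#' All other structure is unchanged. If the subtree carries a `root.edge`
#' it becomes the connecting branch length; otherwise the connection has
#' length 0.
#'
#' @param tree A `phylo` object with labelled interior nodes.
#' @param at Name of an interior node of `tree`; must be unique.
#' @param subtree A `phylo` object (may be a single tip) whose tip labels
#'   are disjoint from those of `tree`.
#' @return A `phylo` object with `Ntip(tree) + Ntip(subtree)` tips.
#' @examples
#' back <- parse_newick("((A:1,B:1)Poaceae:1,(C:1,D:1)Fabaceae:1)root:0;")
#' out <- graft(back, "Poaceae", parse_newick("(X:1);"))
#' sort(out$tip.label)
#' @export
graft <- function(tree, at, subtree) {
  validate_phylogeny(tree)
  validate_phylogeny(subtree)
  stopifnot(is.character(at), length(at) == 1L)
  if (is.null(tree$node.label)) abort("tree has no interior node labels")
  hits <- which(tree$node.label == at)
  if (length(hits) == 0L) abort(paste0("attachment node not found: ", at))
  if (length(hits) > 1L) abort(paste0("attachment node name is ambiguous: ", at))
  clash <- intersect(tree$tip.label, subtree$tip.label)
  if (length(clash)) {
    abort(paste0("tip labels already present in tree: ", paste(clash, collapse = ", ")))
  }
  if (is.null(subtree$root.edge)) subtree$root.edge <- 0
  single <- ape::Ntip(subtree) == 1L
  out <- ape::bind.tree(tree, subtree, where = ape::Ntip(tree) + hits)
  # A one-tip subtree leaves a degree-2 stub node behind; collapse it so the
  # tip hangs directly under the attachment node.
  if (single) out <- ape::collapse.singles(out)
  validate_phylogeny(out)
  out
}

#' Prune a phylogeny to a subset of taxa
#'
#' Returns the subtree spanning `taxa`. Degree-2 nodes created by the
#' pruning are collapsed with their branch lengths summed, so all pairwise
#' tip-to-tip path lengths among retained taxa are preserved. The path from
#' the original root down to the base of the retained set is kept as the
#' `root.edge` of the result, so root-inclusive phylogenetic diversity is
#' unchanged by pruning.
#'
#' @param tree A `phylo` object.
#' @param taxa Character vector of tip labels to keep (at least one).
#' @return A `phylo` object with exactly `taxa` as tips.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
#' pr <- prune_to(tr, c("A", "C"))
#' pairwise_distance(pr, "A", "C")
#' @export
prune_to <- function(tree, taxa) {
  validate_phylogeny(tree)
  idx <- tip_index(tree, taxa)
  has_len <- !is.null(tree$edge.length)
  root_edge <- tree$root.edge %||% 0

  if (length(idx) == ape::Ntip(tree)) return(tree)

  if (length(idx) == 1L) {
    # keep.tip() cannot return a one-tip tree; build it directly.
    edge_row <- which(tree$edge[, 2] == idx)
    out <- structure(
      list(
        edge = matrix(c(2L, 1L), 1L, 2L),
        Nnode = 1L,
        tip.label = tree$tip.label[idx]
      ),
      class = "phylo", order = "cladewise"
    )
    if (has_len) {
      tip_edge <- tree$edge.length[edge_row]
      out$edge.length <- tip_edge
      out$root.edge <- root_edge + node_depths(tree)[idx] - tip_edge
    }
    return(out)
  }

  out <- ape::keep.tip(tree, idx)
  if (has_len) {
    # keep.tip reroots at the MRCA of the retained set; restore the stem.
    mrca <- if (length(idx) == 1L) idx else ape::getMRCA(tree, idx)
    out$root.edge <- root_edge + node_depths(tree)[mrca]
  }
  validate_phylogeny(out)
  out
}
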