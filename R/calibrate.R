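#' Read a node-age calibration table
#'
#' A two-column CSV `node_name,age` with ages in millions of years.
#'
#' @param path Path to the CSV file.
#' @return A tibble with columns `node_name` and `age`.
#' @export
read_node_ages <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  as_node_ages(tbl)
}

# Normalize age input (tibble/data.frame or named numeric) and validate.
as_node_ages <- function(ages) {
  if (is.numeric(ages) && !is.null(names(ages))) {
    ages <- tibble(node_name = names(ages), age = unname(ages))
  }
  if (!is.data.frame(ages) || !all(c("node_name", "age") %in% names(ages))) {
    abort("ages must be a data frame with columns 'node_name' and 'age', or a named numeric vector")
  }
  ages <- tibble(node_name = as.character(ages$node_name), age = as.numeric(ages$age))
  if (anyNA(ages$age) || any(ages$age < 0)) abort("ages must be nonnegative and non-missing")
  dup <- unique(ages$node_name[duplicated(ages$node_name)])
  if (length(dup)) abort(paste0("duplicate node names in age table: ", paste(dup, collapse = ", ")))
  ages
}

#' Age-calibrate a tree by even placement of undated nodes (BLADJ)
#'
#' Fixes the ages of named nodes from a calibration table, sets all tip ages
#' to zero, and places every undated internal node by spacing it evenly
#' along the chain between its nearest dated ancestor and its nearest dated
#' descendant (or a tip). Branch lengths of the returned chronogram are
#' parent age minus child age, so the tree is ultrametric: every tip sits at
#' depth equal to the root age.
#'
#' For a chain of `u` undated nodes between a dated ancestor of age `a` and
#' a nearest dated descendant of age `b`, the `j`-th node from the ancestor
#' receives age `a - j * (a - b) / (u + 1)`. When an undated node has
#' several dated descendants, the constraint is taken from the path with the
#' fewest intervening undated nodes (ties resolved toward the oldest
#' constraint). Input branch lengths are ignored; only the topology and the
#' age table matter, which makes the operation idempotent.
#'
#' @param tree A `phylo` object whose interior node labels identify the
#'   nodes named in `ages`. The root must be dated.
#' @param ages A data frame with columns `node_name`, `age` (millions of
#'   years), or a named numeric vector. Tips may only be listed with age 0.
#' @return A `phylo` chronogram with an attribute `node_ages`: a numeric
#'   vector of length `Ntip + Nnode` giving the age assigned to every node
#'   (tips first, in `ape`'s node numbering).
#' @examples
#' tr <- parse_newick("((a:1,b:1)gen:1,c:2)root;")
#' cal <- bladj(tr, c(root = 10, gen = 4))
#' cal$edge.length
#' attr(cal, "node_ages")
#' @export
bladj <- function(tree, ages) {
  validate_phylogeny(tree)
  ages <- as_node_ages(ages)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  n_all <- ntip + nnode
  root <- ntip + 1L

  node_names <- c(tree$tip.label, tree$node.label %||% rep("", nnode))
  display <- ifelse(
    node_names == "" | is.na(node_names),
    paste0("<node ", seq_len(n_all), ">"),
    node_names
  )

  age <- rep(NA_real_, n_all)
  age[seq_len(ntip)] <- 0

  for (k in seq_len(nrow(ages))) {
    nm <- ages$node_name[k]
    hits <- which(node_names == nm)
    if (length(hits) == 0L) abort(paste0("age table names a node absent from the tree: ", nm))
    if (length(hits) > 1L) abort(paste0("age table node name is ambiguous in the tree: ", nm))
    if (hits <= ntip && ages$age[k] != 0) {
      abort(paste0("tip '", nm, "' may not carry a nonzero age (extant taxa have age 0)"))
    }
    age[hits] <- ages$age[k]
  }
  dated <- !is.na(age)
  if (!dated[root]) abort("the root must be dated (directly or by name) for calibration")

  parent <- tree$edge[, 1]
  child <- tree$edge[, 2]
  pre <- edge_preorder(tree)
  post <- rev(pre)

  # Nearest dated ancestor age and count of undated nodes above (inclusive);
  # also check the no-inversion precondition while walking down.
  anc_age <- rep(NA_real_, n_all)
  anc_id <- rep(NA_integer_, n_all)
  d_up <- integer(n_all)
  for (e in pre) {
    p <- parent[e]
    v <- child[e]
    if (dated[p]) {
      anc_age[v] <- age[p]
      anc_id[v] <- p
      d_up[v] <- 1L
    } else {
      anc_age[v] <- anc_age[p]
      anc_id[v] <- anc_id[p]
      d_up[v] <- d_up[p] + 1L
    }
    if (dated[v] && age[v] > anc_age[v]) {
      abort(sprintf(
        "age inversion: '%s' (%.6g) is older than its dated ancestor '%s' (%.6g)",
        display[v], age[v], display[anc_id[v]], anc_age[v]
      ))
    }
  }

  # Downward constraints, per node: (i) fewest intervening undated nodes to
  # a dated descendant (d_down) and the age found there (b), ties -> oldest
  # b; (ii) the oldest dated age anywhere below (m_age) with the undated
  # count on the path reaching it (m_cnt), which bounds any valid placement.
  d_down <- rep(NA_integer_, n_all)
  b_age <- rep(NA_real_, n_all)
  m_age <- rep(NA_real_, n_all)
  m_cnt <- rep(NA_integer_, n_all)
  for (e in post) {
    p <- parent[e]
    v <- child[e]
    cnt <- if (dated[v]) 0L else d_down[v] + 1L
    b <- if (dated[v]) age[v] else b_age[v]
    if (is.na(d_down[p]) || cnt < d_down[p] || (cnt == d_down[p] && b > b_age[p])) {
      d_down[p] <- cnt
      b_age[p] <- b
    }
    mc <- if (dated[v]) 0L else m_cnt[v] + 1L
    mb <- if (dated[v]) age[v] else m_age[v]
    if (is.na(m_age[p]) || mb > m_age[p] || (mb == m_age[p] && mc < m_cnt[p])) {
      m_age[p] <- mb
      m_cnt[p] <- mc
    }
  }

  # Assign ages root-down. A valid placement must sit strictly between the
  # node's oldest dated descendant and its (already assigned) parent; when
  # the even-spacing value from the minimal path violates that — possible
  # when dated descendants on different branches disagree — the node is
  # re-anchored by even spacing between the parent and the oldest dated
  # descendant instead. Along consistent chains the re-anchor never fires.
  assigned <- age
  for (e in pre) {
    p <- parent[e]
    v <- child[e]
    if (dated[v]) next
    a <- anc_age[v]
    u <- d_up[v] + d_down[v]
    val <- a - d_up[v] * (a - b_age[v]) / (u + 1)
    pa <- assigned[p]
    if (!(val < pa && val > m_age[v])) {
      val <- pa - (pa - m_age[v]) / (m_cnt[v] + 2)
    }
    assigned[v] <- val
  }

  out <- tree
  out$edge.length <- assigned[tree$edge[, 1]] - assigned[tree$edge[, 2]]
  if (any(out$edge.length < -1e-9)) abort("internal error: negative branch length after calibration")
  out$edge.length[out$edge.length < 0] <- 0
  attr(out, "node_ages") <- setNames(assigned, display)
  out
}
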