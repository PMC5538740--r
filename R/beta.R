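# Shared branch length of two root-inclusive spanning subtrees: edges that
# subtend at least one member of each set, plus the stored root edge.
ctx_shared <- function(ctx, idx_a, idx_b) {
  hit_a <- rowSums(ctx$edge_tips[, idx_a, drop = FALSE]) > 0
  hit_b <- rowSums(ctx$edge_tips[, idx_b, drop = FALSE]) > 0
  sum(ctx$len[hit_a & hit_b]) + ctx$root_edge
}

ctx_phylosor <- function(ctx, idx_a, idx_b) {
  2 * ctx_shared(ctx, idx_a, idx_b) / (ctx_pd(ctx, idx_a) + ctx_pd(ctx, idx_b))
}

#' PhyloSor similarity between two assemblages
#'
#' The fraction of branch length shared by the root-inclusive spanning
#' subtrees of the two assemblages: `2 * BL_shared / (PD_a + PD_b)`.
#' Identical assemblages give 1; assemblages from disjoint clades joined at
#' a zero-length root give 0. Phylogenetic beta diversity is
#' `1 - phylosor()` ([phylo_beta()]): 0 means phylogenetic homogenization,
#' 1 complete turnover.
#'
#' @param tree A `phylo` chronogram.
#' @param taxa_a,taxa_b Nonempty assemblage tip-label vectors.
#' @return Similarity in `[0, 1]`.
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1):0;")
#' phylosor(tr, c("A", "B"), c("A", "C"))
#' @export
phylosor <- function(tree, taxa_a, taxa_b) {
  idx_a <- tip_index(tree, taxa_a)
  idx_b <- tip_index(tree, taxa_b)
  ctx <- metric_context(tree)
  ctx_phylosor(ctx, idx_a, idx_b)
}

#' Phylogenetic beta diversity (1 - PhyloSor)
#'
#' @inheritParams phylosor
#' @return Dissimilarity in `[0, 1]`.
#' @export
phylo_beta <- function(tree, taxa_a, taxa_b) {
  1 - phylosor(tree, taxa_a, taxa_b)
}

# SES engine for 1 - PhyloSor. One permutation is shared by both
# assemblages, preserving their sizes and overlap (the community
# presence-absence matrix is maintained; only the phylogeny's labels move).
ses_phylosor_engine <- function(ctx, idx_a, idx_b, n_rand) {
  observed <- 1 - ctx_phylosor(ctx, idx_a, idx_b)
  null_vals <- vapply(seq_len(n_rand), function(i) {
    p <- sample.int(ctx$n)
    1 - ctx_phylosor(ctx, p[idx_a], p[idx_b])
  }, numeric(1))
  null_mean <- mean(null_vals)
  null_sd <- sd(null_vals)
  degenerate <- !is.finite(null_sd) || null_sd < 1e-12
  tibble(
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    ses = if (degenerate) NA_real_ else (observed - null_mean) / null_sd,
    n_rand = as.integer(n_rand),
    degenerate = degenerate
  )
}

#' Standardized effect size of phylogenetic beta diversity
#'
#' Compares the observed `1 - PhyloSor` dissimilarity of two assemblages
#' with its distribution under tip-label shuffles of the phylogeny, holding
#' both memberships (and hence their richness and overlap) fixed. Values in
#' `(-1.96, 1.96)` indicate no deviation from chance. A zero-variance null
#' (e.g. identical assemblages, always at dissimilarity 0) is returned as a
#' flagged degenerate result.
#'
#' @inheritParams phylosor
#' @param n_rand Number of randomizations (default 999).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `observed`, `null_mean`, `null_sd`, `ses`,
#'   `n_rand`, `degenerate`.
#' @export
ses_phylosor <- function(tree, taxa_a, taxa_b, n_rand = 999, seed = NULL) {
  idx_a <- tip_index(tree, taxa_a)
  idx_b <- tip_index(tree, taxa_b)
  if (n_rand < 1) abort("n_rand must be >= 1")
  ctx <- metric_context(tree)
  with_optional_seed(seed, ses_phylosor_engine(ctx, idx_a, idx_b, n_rand))
}

#' Temporal phylogenetic beta diversity per island
#'
#' `1 - PhyloSor` between the pre-European and the current assemblage of
#' each island, on the same regional chronogram for both periods (only the
#' period membership changes). Islands with an empty assemblage in either
#' period are skipped with a warning. Optionally adds the tip-shuffle SES
#' of each temporal comparison.
#'
#' @inheritParams alpha_diversity
#' @param scope `"complete"` or `"native_only"`.
#' @param ses Also compute `ses_phylosor` per island?
#' @param n_rand,seed Randomization settings when `ses = TRUE`.
#' @return A tibble with one row per retained island: `island`, `beta`,
#'   and when requested `ses`, `null_mean`, `null_sd`, `degenerate`.
#' @export
temporal_beta <- function(tree, flora, scope = c("complete", "native_only"),
                          ses = FALSE, n_rand = 999, seed = NULL,
                          skip_missing = FALSE) {
  stopifnot(inherits(flora, "island_flora"))
  scope <- match.arg(scope)
  ctx <- metric_context(tree)
  run <- function() {
    purrr::map_dfr(flora$island_names, function(isl) {
      pre <- assemble(flora, isl, "pre_european", scope)
      cur <- assemble(flora, isl, "current", scope)
      if (length(pre) == 0L || length(cur) == 0L) {
        rlang::warn(paste0("island '", isl, "' has an empty assemblage in one period; skipped"))
        return(NULL)
      }
      ia <- match_assemblage(ctx, pre, skip_missing, paste0(isl, "/pre_european"))
      ib <- match_assemblage(ctx, cur, skip_missing, paste0(isl, "/current"))
      if (length(ia) == 0L || length(ib) == 0L) {
        rlang::warn(paste0("island '", isl, "' has no tree-matched species in one period; skipped"))
        return(NULL)
      }
      row <- tibble(island = isl, beta = 1 - ctx_phylosor(ctx, ia, ib))
      if (ses) {
        s <- ses_phylosor_engine(ctx, ia, ib, n_rand)
        row <- dplyr::bind_cols(row, s[, c("ses", "null_mean", "null_sd", "degenerate")])
      }
      row
    })
  }
  with_optional_seed(seed, run())
}

#' Pairwise phylogenetic beta diversity among islands within a period
#'
#' Builds the symmetric matrix of `1 - PhyloSor` between every pair of
#' island assemblages of one period/scope, optionally with the matching
#' matrix of tip-shuffle standardized effect sizes.
#'
#' @inheritParams temporal_beta
#' @param period `"pre_european"` or `"current"`.
#' @return An object of class `beta_matrix`: a list with `labels`, `beta`
#'   (symmetric matrix, zero diagonal), `ses` (matrix or `NULL`), `period`,
#'   `scope`. Use [tidy()] for a long tibble of pairs or `as.matrix()` for
#'   the raw matrix.
#' @export
spatial_beta <- function(tree, flora, period = c("pre_european", "current"),
                         scope = c("complete", "native_only"),
                         ses = FALSE, n_rand = 999, seed = NULL,
                         skip_missing = FALSE) {
  stopifnot(inherits(flora, "island_flora"))
  period <- match.arg(period)
  scope <- match.arg(scope)
  ctx <- metric_context(tree)
  members <- lapply(flora$island_names, function(isl) {
    sp <- assemble(flora, isl, period, scope)
    if (length(sp) == 0L) return(integer())
    match_assemblage(ctx, sp, skip_missing, paste(isl, period, scope, sep = "/"))
  })
  names(members) <- flora$island_names
  keep <- vapply(members, length, integer(1)) > 0
  if (any(!keep)) {
    rlang::warn(paste0(
      "islands with empty assemblages skipped: ",
      paste(flora$island_names[!keep], collapse = ", ")
    ))
  }
  members <- members[keep]
  labels <- names(members)
  m <- length(labels)
  if (m < 2L) abort("need at least 2 non-empty island assemblages")
  beta <- matrix(0, m, m, dimnames = list(labels, labels))
  ses_m <- if (ses) beta else NULL
  run <- function() {
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        beta[i, j] <<- beta[j, i] <<- 1 - ctx_phylosor(ctx, members[[i]], members[[j]])
        if (ses) {
          s <- ses_phylosor_engine(ctx, members[[i]], members[[j]], n_rand)
          ses_m[i, j] <<- ses_m[j, i] <<- if (s$degenerate) NA_real_ else s$ses
        }
      }
    }
  }
  with_optional_seed(seed, run())
  structure(
    list(labels = labels, beta = beta, ses = ses_m, period = period, scope = scope),
    class = "beta_matrix"
  )
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat(sprintf(
    "<beta_matrix> 1 - PhyloSor among %d assemblages (%s, %s)%s\n",
    length(x$labels), x$period, x$scope,
    if (is.null(x$ses)) "" else ", with SES"
  ))
  print(round(x$beta, 3))
  invisible(x)
}

#' @export
as.matrix.beta_matrix <- function(x, ...) x$beta

#' @describeIn spatial_beta Long tibble of island pairs with `beta` (and
#'   `ses` when present).
#' @param x A `beta_matrix`.
#' @param ... Unused.
#' @export
tidy.beta_matrix <- function(x, ...) {
  m <- length(x$labels)
  pairs <- which(upper.tri(x$beta), arr.ind = TRUE)
  out <- tibble(
    island_a = x$labels[pairs[, 1]],
    island_b = x$labels[pairs[, 2]],
    beta = x$beta[pairs]
  )
  if (!is.null(x$ses)) out$ses <- x$ses[pairs]
  out
}

#' Great-circle distance between coordinates, in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. Coordinates are
#' decimal degrees, south and west negative. Vectorised over its arguments.
#'
#' @param lat_a,lon_a,lat_b,lon_b Decimal-degree coordinates.
#' @return Distance(s) in km.
#' @export
great_circle_km <- function(lat_a, lon_a, lat_b, lon_b) {
  geosphere::distHaversine(cbind(lon_a, lat_a), cbind(lon_b, lat_b), r = 6371)
}

#' Pairwise great-circle distances among islands
#'
#' @param islands A tibble with columns `island`, `lat`, `lon` (as stored
#'   in an [island_flora()]), or an `island_flora` with metadata.
#' @return A symmetric matrix of distances in km with island dimnames.
#' @export
island_distance_km <- function(islands) {
  if (inherits(islands, "island_flora")) islands <- islands$islands
  if (is.null(islands)) abort("no island metadata available")
  n <- nrow(islands)
  d <- matrix(0, n, n, dimnames = list(islands$island, islands$island))
  for (i in seq_len(n)) {
    d[i, ] <- great_circle_km(islands$lat[i], islands$lon[i], islands$lat, islands$lon)
  }
  d[abs(d) < 1e-9] <- 0
  (d + t(d)) / 2
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the corresponding off-diagonal entries, with a
#' permutation p-value obtained by jointly permuting the rows and columns
#' of `y`. The default is one-tailed against positive association (distance
#' decay is a directional hypothesis); `alternative = "two.sided"` tests
#' the magnitude. `p = (1 + #{permuted r >= observed r}) / (1 + n_perm)`.
#'
#' @param x,y Symmetric numeric matrices (or `dist` objects) over the same
#'   labels; when both carry dimnames, `y` is aligned to `x`.
#' @param n_perm Number of permutations (default 999).
#' @param seed Optional integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return A one-row tibble: `r`, `p`, `n_perm`, `alternative`,
#'   `degenerate` (`TRUE`, with `r`/`p` set to `NA`, when either matrix has
#'   zero variance).
#' @export
mantel_test <- function(x, y, n_perm = 999, seed = NULL,
                        alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  if (inherits(x, "beta_matrix")) x <- x$beta
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!isTRUE(all.equal(dim(x), dim(y)))) abort("matrices must have the same dimensions")
  n <- nrow(x)
  if (n < 3L) abort("Mantel test needs at least 3 labels")
  if (!is.null(dimnames(x)[[1]]) && !is.null(dimnames(y)[[1]])) {
    if (!setequal(rownames(x), rownames(y))) abort("matrix labels differ")
    y <- y[rownames(x), rownames(x)]
  }
  lt <- lower.tri(x)
  xv <- x[lt]
  if (sd(xv) < 1e-12 || sd(y[lt]) < 1e-12) {
    return(tibble(
      r = NA_real_, p = NA_real_, n_perm = as.integer(n_perm),
      alternative = alternative, degenerate = TRUE
    ))
  }
  r_obs <- cor(xv, y[lt])
  perm_r <- with_optional_seed(seed, vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    cor(xv, y[p, p][lt])
  }, numeric(1)))
  hits <- if (alternative == "greater") {
    sum(perm_r >= r_obs)
  } else {
    sum(abs(perm_r) >= abs(r_obs))
  }
  tibble(
    r = r_obs, p = (1 + hits) / (1 + n_perm), n_perm = as.integer(n_perm),
    alternative = alternative, degenerate = FALSE
  )
}
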