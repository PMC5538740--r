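#' Shuffle tip labels of a phylogeny
#'
#' Returns a tree with identical topology and branch lengths whose tip
#' labels have been permuted uniformly at random — the null model used for
#' all standardized effect sizes here. Shuffling labels across the whole
#' tree (rather than randomizing the community matrix) preserves the
#' spatial structure of the occurrence data.
#'
#' @param tree A `phylo` object.
#' @param seed Optional integer seed for reproducibility.
#' @return A `phylo` object with permuted tip labels.
#' @export
tip_shuffle <- function(tree, seed = NULL) {
  validate_phylogeny(tree)
  perm <- with_optional_seed(seed, sample.int(ape::Ntip(tree)))
  tree$tip.label <- tree$tip.label[perm]
  tree
}

with_optional_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(seed, expr)
}

classify_ses <- function(ses, threshold = 1.96) {
  dplyr::case_when(
    is.na(ses) ~ NA_character_,
    ses < -threshold ~ "clustered",
    ses > threshold ~ "overdispersed",
    TRUE ~ "indistinct"
  )
}

# Core SES engine on a metric context. The tip-label null is drawn by the
# permutation-preimage shortcut: shuffling all tip labels and scoring a
# fixed assemblage is distributionally identical to scoring a uniformly
# random tip subset of the same size on the unshuffled tree.
ses_engine <- function(ctx, idx, metric, n_rand) {
  observed <- ctx_metric(ctx, idx, metric)
  k <- length(idx)
  null_vals <- vapply(
    seq_len(n_rand),
    function(i) ctx_metric(ctx, sample.int(ctx$n, k), metric),
    numeric(1)
  )
  null_mean <- mean(null_vals)
  null_sd <- sd(null_vals)
  degenerate <- !is.finite(null_sd) || null_sd < 1e-12
  ses <- if (degenerate) NA_real_ else (observed - null_mean) / null_sd
  tibble(
    metric = metric,
    n_taxa = k,
    observed = observed,
    null_mean = null_mean,
    null_sd = null_sd,
    ses = ses,
    n_rand = as.integer(n_rand),
    classification = classify_ses(ses),
    degenerate = degenerate
  )
}

#' Standardized effect size of an alpha-diversity metric
#'
#' Compares the observed PD, MPD, or MNTD of an assemblage with its
#' distribution under `n_rand` tip-label shuffles of the phylogeny
#' (assemblage membership held fixed): `ses = (observed - null mean) / null
#' sd`. Negative values indicate phylogenetic clustering (observed diversity
#' below the null), positive values overdispersion; `|ses| > 1.96` is
#' classified accordingly. The Webb-convention indices are the sign flips
#' NRI = -SES(MPD) and NTI = -SES(MNTD), reported in the `webb` column for
#' the distance metrics so either convention can be read off directly.
#'
#' A zero-variance null (e.g. the full tip set, whose metric is invariant
#' under relabelling) yields a flagged degenerate result with `ses = NA`
#' rather than an error.
#'
#' @param tree A `phylo` chronogram.
#' @param taxa Assemblage tip labels (at least two for `mpd`/`mntd`).
#' @param metric One of `"pd"`, `"mpd"`, `"mntd"`.
#' @param n_rand Number of randomizations (default 999).
#' @param seed Optional integer seed.
#' @return A one-row tibble: `metric`, `n_taxa`, `observed`, `null_mean`,
#'   `null_sd`, `ses`, `webb`, `n_rand`, `classification`, `degenerate`.
#' @examples
#' tr <- ape::rphylo(32, 0.1, 0)
#' ses(tr, tr$tip.label[1:8], "mpd", n_rand = 99, seed = 1)
#' @export
ses <- function(tree, taxa, metric = c("pd", "mpd", "mntd"), n_rand = 999, seed = NULL) {
  metric <- match.arg(metric)
  idx <- tip_index(tree, taxa)
  if (metric != "pd" && length(idx) < 2L) {
    abort(paste0(metric, " requires at least 2 taxa"))
  }
  if (n_rand < 1) abort("n_rand must be >= 1")
  ctx <- metric_context(tree, need_dist = metric != "pd")
  out <- with_optional_seed(seed, ses_engine(ctx, idx, metric, n_rand))
  out$webb <- if (metric == "pd") NA_real_ else -out$ses
  out[, c(
    "metric", "n_taxa", "observed", "null_mean", "null_sd",
    "ses", "webb", "n_rand", "classification", "degenerate"
  )]
}

#' Standardized effect sizes for every island, period, scope, and metric
#'
#' Runs [ses()] over the cross of islands, periods, scopes, and metrics on
#' a single shared context, so the whole table is computed with one
#' preprocessing pass of the tree. Assemblages too small for a metric are
#' returned with `NA` and flagged.
#'
#' @inheritParams alpha_diversity
#' @param metrics Metrics to standardize.
#' @param n_rand Number of tip-shuffle randomizations per assemblage.
#' @param seed Integer seed governing the whole table (results are
#'   reproducible for a fixed seed).
#' @return A tibble with one row per island x period x scope x metric.
#' @export
ses_table <- function(tree, flora,
                      metrics = c("pd", "mpd", "mntd"),
                      periods = c("pre_european", "current"),
                      scopes = c("complete", "native_only"),
                      n_rand = 999, seed = NULL, skip_missing = FALSE) {
  stopifnot(inherits(flora, "island_flora"))
  ctx <- metric_context(tree, need_dist = any(metrics != "pd"))
  grid <- tidyr::expand_grid(
    island = flora$island_names, period = periods, scope = scopes, metric = metrics
  ) |>
    dplyr::filter(!(.data$period == "pre_european" & .data$scope == "exotic_only"))
  run <- function() {
    purrr::pmap_dfr(grid, function(island, period, scope, metric) {
      sp <- assemble(flora, island, period, scope)
      idx <- if (length(sp)) {
        match_assemblage(ctx, sp, skip_missing, paste(island, period, scope, sep = "/"))
      } else integer()
      min_n <- if (metric == "pd") 1L else 2L
      base <- tibble(island = island, period = period, scope = scope)
      if (length(idx) < min_n) {
        return(dplyr::bind_cols(base, tibble(
          metric = metric, n_taxa = length(idx), observed = NA_real_,
          null_mean = NA_real_, null_sd = NA_real_, ses = NA_real_,
          webb = NA_real_, n_rand = as.integer(n_rand),
          classification = NA_character_, degenerate = TRUE
        )))
      }
      row <- ses_engine(ctx, idx, metric, n_rand)
      row$webb <- if (metric == "pd") NA_real_ else -row$ses
      dplyr::bind_cols(base, row[, c(
        "metric", "n_taxa", "observed", "null_mean", "null_sd",
        "ses", "webb", "n_rand", "classification", "degenerate"
      )])
    })
  }
  with_optional_seed(seed, run())
}

#' Pooled confidence-interval check for SES values
#'
#' Summarises a set of per-assemblage SES (or NRI/NTI) values, as done when
#' pooling the islands of an archipelago system: mean, standard error, and
#' the `mean +/- 1.96 SE` interval, classified as clustering when the whole
#' interval is below -1.96, overdispersion when above 1.96 (raw-SES sign
#' convention), and neither otherwise.
#'
#' @param values Numeric SES values (NAs dropped).
#' @return A one-row tibble: `n`, `mean`, `se`, `lower`, `upper`, `signal`.
#' @export
pooled_ses_ci <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2L) abort("need at least 2 SES values to pool")
  m <- mean(values)
  se <- sd(values) / sqrt(n)
  lower <- m - 1.96 * se
  upper <- m + 1.96 * se
  tibble(
    n = n, mean = m, se = se, lower = lower, upper = upper,
    signal = dplyr::case_when(
      upper < -1.96 ~ "clustered",
      lower > 1.96 ~ "overdispersed",
      TRUE ~ "none"
    )
  )
}
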