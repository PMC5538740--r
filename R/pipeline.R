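#' Contrasts of richness percent changes from a richness table
#'
#' Fixture-mode entry point: takes a per-island richness table (as returned
#' by [richness_table()] or [pacific_richness()], i.e. columns `island`,
#' `pre_european`, `current_total`, `current_native`) and computes the
#' percent change of the complete and native floras per island plus the
#' two-tailed one-sample t test of the mean change against 0.
#'
#' @param richness A richness tibble with columns `island`, `pre_european`,
#'   `current_total`, `current_native`.
#' @return A list with `change_summary` elements `complete` and `native`.
#' @examples
#' rc <- richness_contrasts(pacific_richness())
#' glance(rc$complete)
#' @export
richness_contrasts <- function(richness) {
  need <- c("island", "pre_european", "current_total", "current_native")
  if (!all(need %in% names(richness))) {
    abort(paste0("richness table must have columns: ", paste(need, collapse = ", ")))
  }
  list(
    complete = change_summary(richness$island, richness$pre_european, richness$current_total),
    native = change_summary(richness$island, richness$pre_european, richness$current_native)
  )
}

#' Contrasts of alpha-diversity percent changes from a metric table
#'
#' Fixture-mode entry point: takes a long per-island alpha-diversity table
#' (columns `island`, `period`, `scope`, `pd`, `mpd`, `mntd`; periods
#' `pre_european` and `current`) and, for every metric x scope combination
#' present in both periods, computes per-island percent changes and their
#' one-sample t test against 0.
#'
#' The pre-European rows of a published table typically carry only the
#' complete flora (the pre-European flora has no exotics and equals its
#' native flora); in that case native-scope current values are contrasted
#' against the pre-European complete values.
#'
#' @param alpha A long alpha-diversity tibble as described above.
#' @param scopes Scopes to contrast (default complete and native-only).
#' @return A tibble with one row per metric x scope: `metric`, `scope`,
#'   `n`, `mean_change_pct`, `se`, `t`, `df`, `p`, `degenerate`.
#' @examples
#' alpha_contrasts(pacific_alpha())
#' @export
alpha_contrasts <- function(alpha, scopes = c("complete", "native_only")) {
  need <- c("island", "period", "scope", "pd", "mpd", "mntd")
  if (!all(need %in% names(alpha))) {
    abort(paste0("alpha table must have columns: ", paste(need, collapse = ", ")))
  }
  pre_all <- dplyr::filter(alpha, .data$period == "pre_european")
  cur_all <- dplyr::filter(alpha, .data$period == "current")
  purrr::map_dfr(scopes, function(sc) {
    pre <- dplyr::filter(pre_all, .data$scope == sc)
    if (nrow(pre) == 0L && sc == "native_only") {
      # pre-European natives are the pre-European complete flora
      pre <- dplyr::filter(pre_all, .data$scope == "complete")
    }
    cur <- dplyr::filter(cur_all, .data$scope == sc)
    isl <- intersect(pre$island, cur$island)
    if (length(isl) < 2L) abort(paste0("fewer than 2 islands shared across periods for scope ", sc))
    pre <- pre[match(isl, pre$island), ]
    cur <- cur[match(isl, cur$island), ]
    purrr::map_dfr(c("pd", "mpd", "mntd"), function(met) {
      ok <- !is.na(pre[[met]]) & !is.na(cur[[met]])
      test <- one_sample_t(percent_change(pre[[met]][ok], cur[[met]][ok]))
      dplyr::bind_cols(
        tibble(metric = met, scope = sc),
        dplyr::rename(test, mean_change_pct = "mean")
      )
    })
  })
}

#' Run the full temporal community-phylogenetics analysis
#'
#' Orchestrates every stage on a chronogram plus occurrence data: the
#' richness table with percent-change contrasts, alpha diversity (PD, MPD,
#' MNTD) per island x period x scope with percent-change contrasts,
#' standardized effect sizes with paired pre/current t tests and the pooled
#' confidence-interval check, temporal beta diversity per island with its
#' t test against 0, and spatial beta matrices per period with Mantel tests
#' against great-circle distance (when island coordinates are available).
#'
#' All randomization flows from `seed`; two runs with identical inputs and
#' seed produce identical outputs.
#'
#' @inheritParams alpha_diversity
#' @param n_rand Tip-shuffle randomizations for all SES layers.
#' @param seed Integer seed for the run.
#' @param beta_ses Also compute SES matrices for spatial/temporal beta
#'   (slower).
#' @return An object of class `islephylo_report`: a list of tibbles (see
#'   names of the returned object) plus a `manifest`.
#' @examples
#' sys <- simulate_system(sim_config(native_pool = 30, exotic_pool = 40,
#'                                   introductions = 5), seed = 1)
#' rep <- run_analysis(sys$tree, sys$flora, n_rand = 49, seed = 1)
#' names(rep)
#' @export
run_analysis <- function(tree, flora, n_rand = 999, seed = 1,
                         scopes = c("complete", "native_only"),
                         beta_ses = FALSE, skip_missing = FALSE) {
  stopifnot(inherits(flora, "island_flora"))
  validate_phylogeny(tree)

  richness <- richness_table(flora)
  rich_con <- richness_contrasts(richness)

  alpha <- alpha_diversity(tree, flora, scopes = scopes, skip_missing = skip_missing)
  alpha_con <- alpha_contrasts(alpha, scopes = scopes)

  ses_tbl <- ses_table(tree, flora, scopes = scopes, n_rand = n_rand,
                       seed = seed, skip_missing = skip_missing)
  ses_con <- ses_tbl |>
    dplyr::select("island", "period", "scope", "metric", "ses") |>
    tidyr::pivot_wider(names_from = "period", values_from = "ses") |>
    dplyr::group_by(.data$metric, .data$scope) |>
    dplyr::group_modify(function(d, key) {
      ok <- !is.na(d$pre_european) & !is.na(d$current)
      if (sum(ok) < 2L) return(tibble(n = sum(ok)))
      paired_t(d$pre_european[ok], d$current[ok])
    }) |>
    dplyr::ungroup()
  pooled <- ses_tbl |>
    dplyr::filter(!is.na(.data$ses)) |>
    dplyr::group_by(.data$metric, .data$period, .data$scope) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2L) return(tibble(n = nrow(d)))
      pooled_ses_ci(d$ses)
    }) |>
    dplyr::ungroup()

  temporal <- purrr::map_dfr(intersect(scopes, c("complete", "native_only")), function(sc) {
    tb <- temporal_beta(tree, flora, scope = sc, ses = beta_ses,
                        n_rand = n_rand, seed = seed, skip_missing = skip_missing)
    dplyr::bind_cols(tibble(scope = sc), tb)
  })
  temporal_tests <- temporal |>
    dplyr::group_by(.data$scope) |>
    dplyr::group_modify(function(d, key) one_sample_t(d$beta)) |>
    dplyr::ungroup()

  spatial <- list()
  mantel <- NULL
  for (per in c("pre_european", "current")) {
    for (sc in intersect(scopes, c("complete", "native_only"))) {
      if (per == "pre_european" && sc == "native_only") next # identical to complete
      bm <- spatial_beta(tree, flora, period = per, scope = sc, ses = beta_ses,
                         n_rand = n_rand, seed = seed, skip_missing = skip_missing)
      spatial[[paste(per, sc, sep = ".")]] <- bm
      if (!is.null(flora$islands)) {
        geo <- island_distance_km(flora)
        geo <- geo[bm$labels, bm$labels]
        mt <- mantel_test(bm, geo, n_perm = n_rand, seed = seed)
        mantel <- dplyr::bind_rows(mantel, dplyr::bind_cols(
          tibble(period = per, scope = sc), mt
        ))
      }
    }
  }

  manifest <- tibble(
    key = c("package", "version", "seed", "n_rand", "n_islands", "n_species", "n_tips"),
    value = as.character(c(
      "islephylo", as.character(utils::packageVersion("islephylo")),
      seed, n_rand, length(flora$island_names), nrow(flora$occurrences),
      ape::Ntip(tree)
    ))
  )

  structure(
    list(
      richness = richness,
      richness_contrasts = rich_con,
      alpha = alpha,
      alpha_contrasts = alpha_con,
      ses = ses_tbl,
      ses_contrasts = ses_con,
      ses_pooled = pooled,
      temporal_beta = temporal,
      temporal_beta_tests = temporal_tests,
      spatial_beta = spatial,
      mantel = mantel,
      manifest = manifest
    ),
    class = "islephylo_report"
  )
}

#' @export
print.islephylo_report <- function(x, ...) {
  cat("<islephylo_report>\n")
  cat("richness (", nrow(x$richness), " islands); mean complete change ",
      sprintf("%.1f%%", glance(x$richness_contrasts$complete)$mean), "\n", sep = "")
  cat("alpha table: ", nrow(x$alpha), " rows; SES table: ", nrow(x$ses), " rows\n", sep = "")
  cat("temporal beta: ", nrow(x$temporal_beta), " island x scope values\n", sep = "")
  cat("spatial beta matrices: ", paste(names(x$spatial_beta), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write every table of a report to CSV
#'
#' Emits one CSV per tabular component under `dir` (created if needed),
#' square beta matrices with a leading label column, and the run manifest.
#' Output is deterministic: identical inputs and seed give byte-identical
#' files.
#'
#' @param report An `islephylo_report`.
#' @param dir Output directory.
#' @return The paths written, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "islephylo_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(tbl, name) {
    p <- file.path(dir, paste0(name, ".csv"))
    readr::write_csv(tbl, p)
    paths <<- c(paths, p)
  }
  emit(report$richness, "richness")
  emit(tidy(report$richness_contrasts$complete), "richness_change_complete")
  emit(dplyr::bind_rows(
    dplyr::bind_cols(tibble(scope = "complete"), glance(report$richness_contrasts$complete)),
    dplyr::bind_cols(tibble(scope = "native_only"), glance(report$richness_contrasts$native))
  ), "richness_change_tests")
  emit(report$alpha, "alpha")
  emit(report$alpha_contrasts, "alpha_contrasts")
  emit(report$ses, "ses")
  emit(report$ses_contrasts, "ses_contrasts")
  emit(report$ses_pooled, "ses_pooled")
  emit(report$temporal_beta, "temporal_beta")
  emit(report$temporal_beta_tests, "temporal_beta_tests")
  for (nm in names(report$spatial_beta)) {
    bm <- report$spatial_beta[[nm]]
    sq <- dplyr::bind_cols(tibble(island = bm$labels), as_tibble(bm$beta))
    emit(sq, paste0("spatial_beta_", nm))
  }
  if (!is.null(report$mantel)) emit(report$mantel, "mantel")
  emit(report$manifest, "manifest")
  invisible(paths)
}
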