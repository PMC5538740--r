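#' Build an island flora (occurrence matrix with status flags)
#'
#' The central community container: one row per species with its status
#' (`native` or `exotic`), an extinction flag (meaningful only for natives;
#' extinction is treated as a species-level attribute), and one 0/1 presence
#' column per island. Optional island metadata (decimal-degree coordinates,
#' south and west negative) supports geographic-distance analyses.
#'
#' @param occurrences A data frame with columns `species`, `status`,
#'   `extinct`, then one 0/1 (or logical) column per island.
#' @param islands Optional data frame with columns `island`, `lat`, `lon`.
#'   Island names must match the presence columns.
#' @return An object of class `island_flora`.
#' @examples
#' fl <- island_flora(tibble::tibble(
#'   species = c("a", "b", "x"),
#'   status = c("native", "native", "exotic"),
#'   extinct = c(FALSE, TRUE, FALSE),
#'   isla = c(1, 1, 1), islb = c(1, 0, 0)
#' ))
#' assemble(fl, "isla", "current", "complete")
#' @export
island_flora <- function(occurrences, islands = NULL) {
  occurrences <- as_tibble(occurrences)
  need <- c("species", "status", "extinct")
  if (!all(need %in% names(occurrences))) {
    abort("occurrences must have columns 'species', 'status', 'extinct' plus one column per island")
  }
  island_names <- setdiff(names(occurrences), need)
  if (length(island_names) == 0L) abort("no island presence columns found")

  occurrences$species <- as.character(occurrences$species)
  occurrences$status <- as.character(occurrences$status)
  occurrences$extinct <- as.logical(occurrences$extinct)

  if (any(is.na(occurrences$species) | occurrences$species == "")) {
    abort("species names must be nonempty")
  }
  dup <- unique(occurrences$species[duplicated(occurrences$species)])
  if (length(dup)) abort(paste0("duplicate species: ", paste(dup, collapse = ", ")))
  bad <- setdiff(unique(occurrences$status), c("native", "exotic"))
  if (length(bad)) abort(paste0("unknown status values: ", paste(bad, collapse = ", ")))
  if (anyNA(occurrences$extinct)) abort("extinct flags must be TRUE/FALSE")
  offender <- occurrences$species[occurrences$status == "exotic" & occurrences$extinct]
  if (length(offender)) {
    abort(paste0("exotic species cannot be flagged extinct: ", paste(offender, collapse = ", ")))
  }

  pres <- as.matrix(occurrences[island_names])
  if (anyNA(pres) || !all(pres %in% c(0, 1))) abort("presence entries must be 0/1")
  mode(pres) <- "logical"
  orphan <- occurrences$species[rowSums(pres) == 0]
  if (length(orphan)) {
    abort(paste0("species present on no island: ", paste(orphan, collapse = ", ")))
  }
  for (nm in island_names) occurrences[[nm]] <- as.integer(pres[, nm])

  if (!is.null(islands)) {
    islands <- as_tibble(islands)
    if (!all(c("island", "lat", "lon") %in% names(islands))) {
      abort("islands must have columns 'island', 'lat', 'lon'")
    }
    islands$island <- as.character(islands$island)
    if (!setequal(islands$island, island_names)) {
      abort("island metadata names do not match the presence columns")
    }
    if (any(abs(islands$lat) > 90) || any(abs(islands$lon) > 180)) {
      abort("coordinates out of range: |lat| <= 90, |lon| <= 180")
    }
    islands <- islands[match(island_names, islands$island), ]
  }

  structure(
    list(occurrences = occurrences, islands = islands, island_names = island_names),
    class = "island_flora"
  )
}

#' @export
print.island_flora <- function(x, ...) {
  occ <- x$occurrences
  n_nat <- sum(occ$status == "native")
  cat(sprintf(
    "<island_flora> %d species (%d native, %d exotic; %d extinct) x %d islands\n",
    nrow(occ), n_nat, nrow(occ) - n_nat, sum(occ$extinct), length(x$island_names)
  ))
  cat("islands:", paste(x$island_names, collapse = ", "), "\n")
  invisible(x)
}

#' Read an island flora from CSV
#'
#' Expects one row per species: `species,status,extinct,<island1>,...` with
#' 0/1 presences, plus (optionally) an island metadata CSV `island,lat,lon`.
#'
#' @param path Path to the occurrence CSV.
#' @param islands_path Optional path to the island metadata CSV.
#' @return An `island_flora` object.
#' @export
read_flora_csv <- function(path, islands_path = NULL) {
  occ <- readr::read_csv(path, show_col_types = FALSE)
  isl <- if (!is.null(islands_path)) readr::read_csv(islands_path, show_col_types = FALSE)
  island_flora(occ, isl)
}

#' Write an island flora to CSV
#'
#' @param flora An `island_flora` object.
#' @param path Path for the occurrence CSV.
#' @param islands_path Optional path for the island metadata CSV.
#' @return `flora`, invisibly.
#' @export
write_flora_csv <- function(flora, path, islands_path = NULL) {
  stopifnot(inherits(flora, "island_flora"))
  readr::write_csv(flora$occurrences, path)
  if (!is.null(islands_path) && !is.null(flora$islands)) {
    readr::write_csv(flora$islands, islands_path)
  }
  invisible(flora)
}

check_period_scope <- function(period, scope) {
  period <- match.arg(period, c("pre_european", "current"))
  scope <- match.arg(scope, c("complete", "native_only", "exotic_only"))
  if (period == "pre_european" && scope == "exotic_only") {
    abort("the pre-European flora has no exotic species; (pre_european, exotic_only) is rejected")
  }
  list(period = period, scope = scope)
}

#' Assemble a period-specific flora for one island
#'
#' Applies the two-period assembly rules: the pre-European flora is the
#' native species present on the island including those now extinct; the
#' current flora is the surviving (non-extinct) natives plus the exotic
#' species present. `scope` restricts the result to natives or exotics;
#' `(pre_european, exotic_only)` is empty by construction and rejected.
#'
#' @param flora An `island_flora` object.
#' @param island Island name.
#' @param period `"pre_european"` or `"current"`.
#' @param scope `"complete"`, `"native_only"`, or `"exotic_only"`.
#' @return A character vector of species names (possibly empty).
#' @export
assemble <- function(flora, island, period = c("pre_european", "current"),
                     scope = c("complete", "native_only", "exotic_only")) {
  stopifnot(inherits(flora, "island_flora"))
  ps <- check_period_scope(period[1], scope[1])
  if (!island %in% flora$island_names) abort(paste0("unknown island: ", island))
  occ <- flora$occurrences
  here <- occ[[island]] == 1L
  native <- occ$status == "native"
  keep <- if (ps$period == "pre_european") {
    here & native
  } else {
    switch(ps$scope,
      complete = here & (!native | !occ$extinct),
      native_only = here & native & !occ$extinct,
      exotic_only = here & !native
    )
  }
  if (ps$period == "pre_european" && ps$scope == "exotic_only") keep <- rep(FALSE, nrow(occ))
  occ$species[keep]
}

#' Occupancy spectrum of a period-specific species pool
#'
#' For the species selected by a period/scope pair, tabulates how many
#' islands each occupies and returns the fraction of species at each
#' occupancy level (fractions sum to 1). For the current period the islands
#' counted are those where the species belongs to the current flora.
#'
#' @inheritParams assemble
#' @return A tibble with columns `n_islands`, `n_species`, `fraction`.
#' @export
occurrence_spectrum <- function(flora, period = c("pre_european", "current"),
                                scope = c("complete", "native_only", "exotic_only")) {
  stopifnot(inherits(flora, "island_flora"))
  ps <- check_period_scope(period[1], scope[1])
  members <- lapply(flora$island_names, function(isl) assemble(flora, isl, ps$period, ps$scope))
  counts <- table(unlist(members))
  if (length(counts) == 0L) abort("no species selected by this period/scope")
  tab <- table(factor(as.integer(counts), levels = seq_along(flora$island_names)))
  tibble(
    n_islands = as.integer(names(tab)),
    n_species = as.integer(tab),
    fraction = as.integer(tab) / sum(tab)
  ) |>
    dplyr::filter(.data$n_species > 0)
}

#' Richness table with percent changes between periods
#'
#' Per island: pre-European richness (all natives, including extinct),
#' current total richness (surviving natives plus exotics), current native
#' richness, the number of exotics, and the percent changes of the complete
#' and native floras between the two periods.
#'
#' @param flora An `island_flora` object.
#' @return A tibble with one row per island.
#' @export
richness_table <- function(flora) {
  stopifnot(inherits(flora, "island_flora"))
  purrr::map_dfr(flora$island_names, function(isl) {
    pre <- length(assemble(flora, isl, "pre_european", "complete"))
    cur <- length(assemble(flora, isl, "current", "complete"))
    cur_nat <- length(assemble(flora, isl, "current", "native_only"))
    tibble(
      island = isl,
      pre_european = pre,
      current_total = cur,
      current_native = cur_nat,
      exotic = cur - cur_nat,
      change_complete_pct = if (pre > 0) percent_change(pre, cur) else NA_real_,
      change_native_pct = if (pre > 0) percent_change(pre, cur_nat) else NA_real_
    )
  })
}
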