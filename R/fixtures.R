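#' Published summaries of the southeastern Pacific island floras
#'
#' Small plain-text tables transcribed from published floristic
#' compilations of the six southeastern Pacific oceanic islands (Juan
#' Fernandez and Desventuradas archipelagos plus Easter Island), shipped
#' under `inst/extdata`. They let the contrast layer of the pipeline run on
#' the published per-island numbers without the underlying (unpublished)
#' curated chronogram.
#'
#' * `pacific_islands()`: island names and decimal-degree coordinates.
#' * `pacific_richness()`: per-island angiosperm richness by period —
#'   pre-European natives (including species now extinct), current total
#'   (surviving natives plus exotics), current natives, and exotics.
#' * `pacific_alpha()`: per-island Faith's PD, MPD, and MNTD (millions of
#'   years) by period and scope, as printed in the published study system
#'   summary.
#'
#' @return A tibble.
#' @examples
#' pacific_richness()
#' @name pacific_data
NULL

pacific_extdata <- function(name) {
  path <- system.file("extdata", name, package = "islephylo", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}

#' @rdname pacific_data
#' @export
pacific_islands <- function() pacific_extdata("pacific_islands.csv")

#' @rdname pacific_data
#' @export
pacific_richness <- function() pacific_extdata("pacific_richness.csv")

#' @rdname pacific_data
#' @export
pacific_alpha <- function() pacific_extdata("pacific_alpha.csv")
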