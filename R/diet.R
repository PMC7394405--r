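# Dietary contributions at pooled and feeding-station scales, top-species
# selection, Schoener's dietary overlap, and seasonal diet expansion.

#' Dietary contributions from bite records
#'
#' Proportion of the diet contributed by each species, from bite counts.
#' Two scales are supported:
#' * `"pooled"` (default): species bite count / total bite count over the
#'   whole group, the scale defined by the contribution formula.
#' * `"station"`: contributions computed within each feeding station, then
#'   averaged with equal station weight. The two scales differ whenever
#'   stations have unequal bite counts.
#'
#' @param bites Data frame with a `species` column (and `station_index` for
#'   the station scale), or a character vector of per-bite species.
#' @param scale `"pooled"` or `"station"`.
#' @return Named numeric vector of proportions summing to 1, sorted by
#'   decreasing contribution then species name; attributes `n_bites` and
#'   `scale`.
#' @examples
#' diet_contributions(c("A", "A", "A", "B", "B"))
#' @export
diet_contributions <- function(bites, scale = c("pooled", "station")) {
  scale <- match.arg(scale)
  if (is.data.frame(bites)) {
    stopifnot("species" %in% names(bites))
    species <- as.character(bites$species)
    station <- if ("station_index" %in% names(bites)) bites$station_index else NULL
  } else {
    species <- as.character(bites)
    station <- NULL
  }
  if (length(species) == 0) stop("no bites in group", call. = FALSE)
  if (scale == "pooled") {
    p <- table(species) / length(species)
    p <- stats::setNames(as.numeric(p), names(p))
  } else {
    if (is.null(station)) {
      stop("station scale requires a `station_index` column", call. = FALSE)
    }
    sp_levels <- sort(unique(species))
    per_station <- tapply(species, station, function(s) {
      tab <- table(factor(s, levels = sp_levels))
      as.numeric(tab) / length(s)
    })
    p <- Reduce(`+`, per_station) / length(per_station)
    names(p) <- sp_levels
  }
  p <- p[order(-p, names(p))]
  structure(p, n_bites = length(species), scale = scale)
}

as_diet_vector <- function(x, arg = "diet") {
  if (!is.numeric(x) || is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("`", arg, "` must be a named numeric vector of proportions ",
         "(e.g. from diet_contributions())", call. = FALSE)
  }
  if (any(x < 0)) stop("`", arg, "` has negative proportions", call. = FALSE)
  x
}

#' Smallest set of top-contributing species exceeding a threshold
#'
#' Species are ranked by decreasing contribution (ties broken by species
#' label, so the selection is deterministic) and the smallest prefix whose
#' cumulative contribution exceeds `threshold` is returned.
#'
#' @param diet Named numeric vector of contributions (proportions).
#' @param threshold Cumulative contribution to exceed, in (0, 1].
#' @return Named numeric vector: the selected species and their contributions,
#'   in rank order.
#' @export
top_species <- function(diet, threshold = 0.9) {
  diet <- as_diet_vector(diet)
  if (threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  diet <- diet[order(-diet, names(diet))]
  if (threshold == 1) return(diet[diet > 0])
  k <- which(cumsum(diet) > threshold - 1e-12)[1]
  if (is.na(k)) k <- length(diet)
  diet[seq_len(k)]
}

#' Schoener's dietary overlap index
#'
#' O = 1 - 1/2 * sum_i |P_i(j) - P_i(k)| over the union of diet items, with
#' absent items counted as zero. O is symmetric and lies in \[0, 1\]:
#' 0 for disjoint diets, 1 for identical diets.
#'
#' By default contributions are used as supplied over the species union,
#' without renormalisation; `renormalize = TRUE` rescales each diet to sum to
#' 1 first (useful when diets were truncated to top species).
#'
#' @param diet_j,diet_k Named numeric contribution vectors (e.g. from
#'   [diet_contributions()]). If both carry a `scale` attribute the scales
#'   must match.
#' @param renormalize Rescale each diet to sum to 1 before comparing.
#' @return List of class `overlap_result`: `schoener`, `species_union`.
#' @examples
#' schoener_overlap(c(A = 0.7, B = 0.3), c(A = 0.3, B = 0.7))  # 0.6
#' @export
schoener_overlap <- function(diet_j, diet_k, renormalize = FALSE) {
  diet_j <- as_diet_vector(diet_j, "diet_j")
  diet_k <- as_diet_vector(diet_k, "diet_k")
  sj <- attr(diet_j, "scale")
  sk <- attr(diet_k, "scale")
  if (!is.null(sj) && !is.null(sk) && !identical(sj, sk)) {
    stop("scale mismatch: '", sj, "' vs '", sk, "'", call. = FALSE)
  }
  if (renormalize) {
    diet_j <- diet_j / sum(diet_j)
    diet_k <- diet_k / sum(diet_k)
  }
  union <- sort(union(names(diet_j), names(diet_k)))
  pj <- stats::setNames(rep(0, length(union)), union)
  pk <- pj
  pj[names(diet_j)] <- diet_j
  pk[names(diet_k)] <- diet_k
  o <- 1 - 0.5 * sum(abs(pj - pk))
  structure(list(schoener = o, species_union = union), class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf("Schoener overlap: %.4f over %d diet items\n",
              x$schoener, length(x$species_union)))
  invisible(x)
}

#' Seasonal diet expansion
#'
#' Between-season Schoener overlap plus the species newly included in (and
#' newly dropped from) the second diet relative to the first. Only species
#' with non-zero contribution count as present.
#'
#' @param diet_wet,diet_dry Named contribution vectors for the two seasons.
#' @param renormalize Passed to [schoener_overlap()].
#' @return List: `overlap` (Schoener), `newly_included` (in dry, absent from
#'   wet), `newly_dropped` (in wet, absent from dry).
#' @export
diet_expansion <- function(diet_wet, diet_dry, renormalize = FALSE) {
  ov <- schoener_overlap(diet_wet, diet_dry, renormalize = renormalize)
  wet_sp <- names(diet_wet)[diet_wet > 0]
  dry_sp <- names(diet_dry)[diet_dry > 0]
  list(
    overlap = ov$schoener,
    newly_included = sort(setdiff(dry_sp, wet_sp)),
    newly_dropped = sort(setdiff(wet_sp, dry_sp))
  )
}

#' Reference dietary-contribution table
#'
#' The published field-study dietary contributions (percent of bites) of grass
#' species for cattle (wet season) and oribi (wet and dry seasons) at low,
#' intermediate and high cattle stocking rates. Shipped as plain text under
#' `inst/extdata` and used as the default species-composition input of the
#' synthetic-data generator.
#'
#' @return Long tibble: `species`, `stocking` (low/intermediate/high),
#'   `herbivore`, `season`, `contribution_pct`.
#' @export
reference_diet_table <- function() {
  path <- system.file("extdata", "diet_contributions_reference.csv",
                      package = "grazekit", mustWork = TRUE)
  readr::read_csv(path, col_types = "ccccd", progress = FALSE,
                  show_col_types = FALSE)
}

#' One column of the reference diet table as a contribution vector
#'
#' @param stocking `"low"`, `"intermediate"` or `"high"`.
#' @param herbivore `"oribi"` or `"cattle"`.
#' @param season `"wet"` or `"dry"`.
#' @param normalize Rescale to sum exactly to 1 (printed percentages carry
#'   rounding error of a few hundredths).
#' @return Named numeric vector of proportions (zero entries dropped).
#' @export
reference_diet <- function(stocking, herbivore, season, normalize = FALSE) {
  tab <- reference_diet_table()
  col <- tab[tab$stocking == stocking & tab$herbivore == herbivore &
               tab$season == season, ]
  if (nrow(col) == 0) {
    stop("no reference diet for ", stocking, "/", herbivore, "/", season,
         call. = FALSE)
  }
  p <- stats::setNames(col$contribution_pct / 100, col$species)
  p <- p[p > 0]
  if (normalize) p <- p / sum(p)
  p[order(-p, names(p))]
}
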