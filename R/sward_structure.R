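# Sward availability summaries: greenness binning, height heterogeneity (CV),
# and greenness availability distributions per camp x season.

#' Collapse Walker greenness classes into four bins
#'
#' Maps the eight-point greenness scale onto four categories:
#' 0 and 1-10 percent -> very brown; 11-25 and 26-50 -> mainly brown;
#' 51-75 and 76-90 -> mainly green; 91-99 and 100 -> very green.
#' This is the single place the binning map lives.
#'
#' @param walker_class Character vector of Walker class labels
#'   (see [walker_classes()]).
#' @return Character vector of four-bin labels (see [greenness_bins()]).
#' @examples
#' bin_greenness(c("26-50", "100", "0"))
#' @export
bin_greenness <- function(walker_class) {
  map <- c(
    "0" = "very brown", "1-10" = "very brown",
    "11-25" = "mainly brown", "26-50" = "mainly brown",
    "51-75" = "mainly green", "76-90" = "mainly green",
    "91-99" = "very green", "100" = "very green"
  )
  walker_class <- as.character(walker_class)
  bad <- setdiff(unique(walker_class), names(map))
  if (length(bad) > 0) {
    stop("unknown greenness class label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  unname(map[walker_class])
}

#' Structural heterogeneity of sward height per camp and season
#'
#' Summarises transect quadrats grouped by camp and season: mean, observed
#' min/max, and the coefficient of variation CV = 100 * sd / mean, the
#' study's measure of structural heterogeneity. The sample (n - 1) standard
#' deviation is used.
#'
#' @param quadrats Quadrat table (schema `quadrats`), or any data frame with
#'   `camp_id`, `season`, `sward_height_cm`.
#' @return Tibble with one row per camp x season: `camp_id`, `season`,
#'   `n_quadrats`, `mean_height_cm`, `min_height_cm`, `max_height_cm`,
#'   `cv_pct`.
#' @export
heterogeneity <- function(quadrats) {
  stopifnot(all(c("camp_id", "season", "sward_height_cm") %in% names(quadrats)))
  out <- quadrats |>
    dplyr::group_by(.data$camp_id, .data$season) |>
    dplyr::summarise(
      n_quadrats = dplyr::n(),
      mean_height_cm = mean(.data$sward_height_cm),
      min_height_cm = min(.data$sward_height_cm),
      max_height_cm = max(.data$sward_height_cm),
      cv_pct = 100 * stats::sd(.data$sward_height_cm) / mean(.data$sward_height_cm),
      .groups = "drop"
    )
  if (any(out$n_quadrats < 2)) {
    small <- out[out$n_quadrats < 2, ]
    stop("CV undefined for group(s) with fewer than 2 quadrats: ",
         paste(small$camp_id, small$season, sep = "/", collapse = ", "),
         call. = FALSE)
  }
  out
}

#' Greenness availability distribution per camp and season
#'
#' Proportion of quadrats in each of the four greenness bins, per camp x
#' season. Proportions sum to 1 within each group; all four bins are always
#' present (zero where unobserved).
#'
#' @param quadrats Quadrat table with `camp_id`, `season`,
#'   `greenness_pct_class` (Walker labels).
#' @return Long tibble: `camp_id`, `season`, `greenness4`, `proportion`.
#' @export
greenness_availability <- function(quadrats) {
  stopifnot(all(c("camp_id", "season", "greenness_pct_class") %in% names(quadrats)))
  if (nrow(quadrats) == 0) stop("no quadrats supplied", call. = FALSE)
  bins <- greenness_bins()
  quadrats |>
    dplyr::mutate(greenness4 = factor(bin_greenness(.data$greenness_pct_class),
                                      levels = bins)) |>
    dplyr::count(.data$camp_id, .data$season, .data$greenness4,
                 .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$camp_id, .data$season) |>
    dplyr::filter(sum(.data$n) > 0) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(greenness4 = as.character(.data$greenness4)) |>
    dplyr::select("camp_id", "season", "greenness4", "proportion")
}
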