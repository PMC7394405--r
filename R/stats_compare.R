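# Gamma GLM (log link) group comparisons: omnibus likelihood-ratio chi-square
# against the null model, pairwise Wald contrasts, the pooling rule, and
# green-bite diet proportions.

#' Gamma GLM group comparison with log link
#'
#' Fits `value ~ group` with a Gamma family and log link and tests the group
#' factor against the intercept-only null. The test statistic is the deviance
#' difference scaled by the Pearson (moment) estimate of the Gamma dispersion
#' from the full model, referred to a chi-square distribution with
#' (levels - 1) degrees of freedom; the small-sample F version is reported
#' alongside. With a factor-only design and log link, fitted group means
#' equal the arithmetic group means.
#'
#' Responses must be strictly positive: pass regrowth values through
#' [shift_transform()] first.
#'
#' @param values Positive numeric responses.
#' @param groups Group labels (coerced to factor), same length as `values`.
#' @param response Optional label for reporting.
#' @return Object of class `glm_compare`: `lr_chisq`, `df`, `p_value`,
#'   `f_stat`, `p_value_f`, `dispersion`, `group_means`, `coefficients`,
#'   `model`, `response`, `levels`.
#' @export
gamma_glm_compare <- function(values, groups, response = "value") {
  stopifnot(is.numeric(values), length(values) == length(groups))
  if (any(!is.finite(values)) || any(values <= 0)) {
    stop("all responses must be positive for the Gamma family; ",
         "apply shift_transform() to regrowth-type data first", call. = FALSE)
  }
  groups <- factor(groups)
  if (nlevels(groups) < 2) {
    stop("need at least 2 groups to compare", call. = FALSE)
  }
  sizes <- table(groups)
  if (any(sizes < 2)) {
    stop("every group needs at least 2 values; too small: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(value = values, group = groups)
  full <- stats::glm(value ~ group, family = stats::Gamma(link = "log"),
                     data = dat)
  dispersion <- summary(full)$dispersion  # Pearson moment estimator
  df <- nlevels(groups) - 1L
  dev_drop <- full$null.deviance - full$deviance
  lr_chisq <- dev_drop / dispersion
  f_stat <- (dev_drop / df) / dispersion
  structure(
    list(
      response = response,
      levels = levels(groups),
      coefficients = stats::coef(full),
      lr_chisq = lr_chisq,
      df = df,
      p_value = stats::pchisq(lr_chisq, df, lower.tail = FALSE),
      f_stat = f_stat,
      p_value_f = stats::pf(f_stat, df, full$df.residual, lower.tail = FALSE),
      dispersion = dispersion,
      group_means = tapply(values, groups, mean),
      n = as.integer(sizes),
      model = full
    ),
    class = "glm_compare"
  )
}

#' @export
print.glm_compare <- function(x, ...) {
  cat(sprintf("Gamma GLM (log link), response: %s\n", x$response))
  cat(sprintf("  LR chi-square = %.3f, df = %d, P = %.4g\n",
              x$lr_chisq, x$df, x$p_value))
  cat("  group means:\n")
  for (l in x$levels) {
    cat(sprintf("    %s: %.4g\n", l, x$group_means[[l]]))
  }
  invisible(x)
}

#' Pairwise Wald contrasts between group means
#'
#' All pairwise contrasts of group means on the log scale from a fitted
#' [gamma_glm_compare()] result, with unadjusted and Holm-adjusted p-values.
#' Requires at least 3 groups (with 2 the omnibus test is the comparison).
#'
#' @param result A `glm_compare` object.
#' @return Tibble: `group_a`, `group_b`, `log_ratio`, `se`, `z`, `p_value`,
#'   `p_holm`.
#' @export
pairwise_contrasts <- function(result) {
  stopifnot(inherits(result, "glm_compare"))
  k <- length(result$levels)
  if (k < 3) {
    stop("pairwise contrasts need >= 3 groups; use the omnibus test",
         call. = FALSE)
  }
  V <- stats::vcov(result$model)
  beta <- stats::coef(result$model)
  # log mean of level i: beta0 (+ beta_i for non-reference levels)
  contrast_vec <- function(i) {
    v <- numeric(length(beta))
    if (i > 1) v[i] <- 1
    v
  }
  pairs <- utils::combn(k, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(m) {
    i <- pairs[1, m]; j <- pairs[2, m]
    cv <- contrast_vec(j) - contrast_vec(i)
    est <- sum(cv * beta)
    se <- sqrt(drop(t(cv) %*% V %*% cv))
    z <- est / se
    tibble::tibble(
      group_a = result$levels[i], group_b = result$levels[j],
      log_ratio = est, se = se, z = z,
      p_value = 2 * stats::pnorm(-abs(z))
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Pool group labels
#'
#' Replaces the listed group labels with one pooled label, leaving values
#' untouched (e.g. pooling the stocking-rate camps before comparing against a
#' cattle-free camp).
#'
#' @param groups Vector of group labels.
#' @param pool Labels to merge.
#' @param pooled_label Replacement label.
#' @return Character vector of relabelled groups, same length as `groups`.
#' @export
pool_groups <- function(groups, pool, pooled_label = "pooled") {
  groups <- as.character(groups)
  unknown <- setdiff(pool, unique(groups))
  if (length(unknown) > 0) {
    stop("unknown group label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  groups[groups %in% pool] <- pooled_label
  groups
}

#' Proportion of green-grass bites per camp
#'
#' Restricts bites to the mainly green and very green categories (the
#' categories the antelope actually feed from) and, per camp, divides the
#' bite count in each category by the camp's total green-bite count.
#'
#' @param bites Bite-level data with `camp_id` and `greenness4` columns (join
#'   observation metadata on first if needed).
#' @return Tibble: `camp_id`, `greenness4`, `n`, `proportion`; the two
#'   proportions per camp sum to 1.
#' @export
greenness_diet_proportions <- function(bites) {
  stopifnot(all(c("camp_id", "greenness4") %in% names(bites)))
  green <- bites[bites$greenness4 %in% c("mainly green", "very green"), ]
  if (nrow(green) == 0) {
    stop("no bites in the mainly green / very green categories", call. = FALSE)
  }
  green |>
    dplyr::mutate(greenness4 = factor(.data$greenness4,
                                      levels = c("mainly green", "very green"))) |>
    dplyr::count(.data$camp_id, .data$greenness4, .drop = FALSE, name = "n") |>
    dplyr::group_by(.data$camp_id) |>
    dplyr::filter(sum(.data$n) > 0) |>
    dplyr::mutate(proportion = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(greenness4 = as.character(.data$greenness4))
}
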