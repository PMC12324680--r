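# Rank-based group comparison of per-image alignment scores and
# fluorescence-ratio error propagation.

#' Mann-Whitney comparison of two score samples
#'
#' Two-sided Mann-Whitney U test with the conventions spelled out: U from
#' rank sums with midranks for ties; exact p by enumeration when the
#' smaller sample has at most `exact_max` observations and the pooled data
#' are tie-free, otherwise the normal approximation with tie correction and
#' continuity correction. Also reports per-group medians, means, standard
#' deviations and the ratio of medians.
#'
#' @param a,b Numeric score vectors, each nonempty.
#' @param exact Force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   branch.
#' @param exact_max Largest min-group size for the automatic exact branch.
#' @return An object of class `group_comparison`; see [tidy()] and
#'   [glance()] methods. Fields: `groups` (per-group summary tibble), `U`
#'   (statistic for `a`), `p_value`, `ratio_of_medians` (median a / median
#'   b), `exact`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5)) # exact two-sided p = 0.2
mann_whitney <- function(a, b, exact = NULL, exact_max = 8) {
  stopifnot(
    "both groups must be nonempty numeric vectors" =
      is.numeric(a) && is.numeric(b) && length(a) > 0 && length(b) > 0
  )
  n_a <- length(a)
  n_b <- length(b)
  pooled <- c(a, b)
  ties <- anyDuplicated(pooled) > 0
  if (is.null(exact)) exact <- min(n_a, n_b) <= exact_max && !ties
  if (length(unique(pooled)) == 1) {
    warning("all pooled values identical; p set to 1")
    U <- n_a * n_b / 2
    p <- 1
    exact <- FALSE
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, exact = exact, correct = TRUE)
    )
    U <- unname(wt$statistic)
    p <- wt$p.value
  }
  groups <- tibble::tibble(
    group = c("a", "b"),
    n = c(n_a, n_b),
    median = c(stats::median(a), stats::median(b)),
    mean = c(mean(a), mean(b)),
    sd = c(stats::sd(a), stats::sd(b))
  )
  structure(
    list(
      groups = groups,
      data = tibble::tibble(
        group = rep(c("a", "b"), c(n_a, n_b)),
        value = c(a, b)
      ),
      U = U,
      p_value = p,
      ratio_of_medians = stats::median(a) / stats::median(b),
      exact = exact,
      method = if (exact) {
        "Mann-Whitney U, exact"
      } else {
        "Mann-Whitney U, normal approximation with continuity correction"
      }
    ),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "<group_comparison> U = %g, two-sided p = %.4g (%s)\n",
    x$U, x$p_value, x$method
  ))
  cat(sprintf(
    "  medians %.4g / %.4g (ratio %.3g)\n",
    x$groups$median[1], x$groups$median[2], x$ratio_of_medians
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-group summaries of a comparison
#'
#' @param x A [mann_whitney()] result.
#' @param ... Unused.
#' @return A tibble with one row per group: `group`, `n`, `median`,
#'   `mean`, `sd`.
#' @export
tidy.group_comparison <- function(x, ...) {
  x$groups
}

#' One-row summary of a comparison
#'
#' @param x A [mann_whitney()] result.
#' @param ... Unused.
#' @return A one-row tibble: `U`, `p_value`, `ratio_of_medians`, `exact`,
#'   `method`.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble::tibble(
    U = x$U,
    p_value = x$p_value,
    ratio_of_medians = x$ratio_of_medians,
    exact = x$exact,
    method = x$method
  )
}

#' Fluorescence ratio with propagated uncertainty
#'
#' Ratio of mean fluorescence increments (exposed over control) with the
#' first-order compound-error propagation
#' `sd = ratio * sqrt((sd_e/mean_e)^2 + (sd_c/mean_c)^2)`.
#'
#' @param exposed_mean,exposed_sd Mean and standard deviation of the
#'   exposed-group increments.
#' @param control_mean,control_sd Mean and standard deviation of the
#'   control-group increments; `control_mean` must be positive.
#' @return A one-row tibble: `ratio`, `sd`.
#' @export
#' @examples
#' fluorescence_ratio(110, 11, 100, 10)
fluorescence_ratio <- function(exposed_mean, exposed_sd,
                               control_mean, control_sd) {
  stopifnot(
    "control mean must be positive" = control_mean > 0,
    exposed_sd >= 0, control_sd >= 0
  )
  ratio <- exposed_mean / control_mean
  tibble::tibble(
    ratio = ratio,
    sd = abs(ratio) * sqrt(
      (exposed_sd / exposed_mean)^2 + (control_sd / control_mean)^2
    )
  )
}

#' Combine replicate ratios by inverse-variance weighting
#'
#' Aggregates k replicate ratio estimates into one, weighting each by the
#' inverse of its variance; the propagated standard deviation of the
#' combination is `sqrt(1 / sum(1/sd^2))`.
#'
#' @param ratio Numeric vector of replicate ratios.
#' @param sd Matching vector of positive standard deviations.
#' @return A one-row tibble: `ratio`, `sd`, `n_replicates`.
#' @export
#' @examples
#' combine_ratios(c(1.05, 1.10, 1.08), c(0.10, 0.12, 0.08))
combine_ratios <- function(ratio, sd) {
  stopifnot(
    length(ratio) == length(sd), length(ratio) >= 1,
    "all replicate sds must be positive for inverse-variance weighting" =
      all(sd > 0)
  )
  w <- 1 / sd^2
  k <- length(ratio)
  tibble::tibble(
    ratio = sum(w * ratio) / sum(w),
    sd = sqrt(1 / sum(w)),
    n_replicates = k
  )
}
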