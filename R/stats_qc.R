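# Replicate aggregation, pathlength outlier screening, and two-sample
# Kolmogorov-Smirnov comparability tests across configurations.

#' Flag pathlength outliers
#'
#' Applies the protocol's outlier rule to per-replicate estimates: a
#' pathlength of 0 m (up to a small numerical tolerance) or strictly above
#' 0.23 m is an outlier, as is any record whose inversion failed. The rule is
#' idempotent and order-independent.
#'
#' @param estimates a gas-estimates tibble (see [invert_scans()]).
#' @param low lower bound, metres; pathlengths `<= low + eps` are outliers.
#' @param high upper bound, metres; pathlengths strictly above are outliers.
#' @param eps numerical tolerance for the "0 m" class.
#' @return `estimates` with its `outlier` column set.
#' @examples
#' est <- tibble::tibble(pathlength_m = c(0, 0.10, 0.231), valid = TRUE)
#' flag_outliers(est)$outlier  # TRUE FALSE TRUE
#' @export
flag_outliers <- function(estimates, low = 0, high = 0.23, eps = 1e-12) {
  stopifnot(low < high, "pathlength_m" %in% names(estimates))
  valid <- if ("valid" %in% names(estimates)) estimates$valid else TRUE
  dplyr::mutate(
    estimates,
    outlier = .data$pathlength_m <= low + eps |
      .data$pathlength_m > high | !valid
  )
}

#' Aggregate replicate estimates per configuration
#'
#' Mean and sample standard deviation (n - 1 denominator) of pathlength and
#' O2 fraction over the valid, non-outlier replicates of each configuration.
#' Configurations whose replicates are all excluded are kept with `NA`
#' statistics and `empty = TRUE` rather than dropped.
#'
#' @param estimates a gas-estimates tibble with its `outlier` column set
#'   (see [flag_outliers()]).
#' @param ... additional grouping columns (tidy-select), e.g. `o2_nominal`
#'   to aggregate per concentration step.
#' @return a tibble with one row per configuration (x extra groups):
#'   `config_id`, `n_total`, `n_outliers`, `n_used`, `mean_pathlength_m`,
#'   `sd_pathlength_m`, `mean_o2`, `sd_o2`, `empty`.
#' @export
aggregate_replicates <- function(estimates, ...) {
  stopifnot(all(c("config_id", "pathlength_m", "outlier") %in%
                  names(estimates)))
  grouped <- dplyr::group_by(estimates, .data$config_id, ...)
  dplyr::ungroup(dplyr::summarise(
    grouped,
    n_total = dplyr::n(),
    n_outliers = sum(.data$outlier),
    n_used = sum(!.data$outlier),
    mean_pathlength_m = if (any(!.data$outlier)) {
      mean(.data$pathlength_m[!.data$outlier])
    } else NA_real_,
    sd_pathlength_m = if (sum(!.data$outlier) > 1) {
      stats::sd(.data$pathlength_m[!.data$outlier])
    } else if (any(!.data$outlier)) 0 else NA_real_,
    mean_o2 = if (any(!.data$outlier & !is.na(.data$o2_fraction))) {
      mean(.data$o2_fraction[!.data$outlier], na.rm = TRUE)
    } else NA_real_,
    sd_o2 = if (sum(!.data$outlier & !is.na(.data$o2_fraction)) > 1) {
      stats::sd(.data$o2_fraction[!.data$outlier], na.rm = TRUE)
    } else if (any(!.data$outlier & !is.na(.data$o2_fraction))) 0
      else NA_real_,
    empty = !any(!.data$outlier),
    .groups = "drop"
  ))
}

# Two-sample KS statistic, ties handled by evaluating the ECDF difference
# only after all observations at a tied value are consumed.
ks_d_statistic <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  pooled <- c(x, y)
  steps <- cumsum(ifelse(order(pooled) <= n1, 1 / n1, -1 / n2))
  ties <- c(diff(sort(pooled)) != 0, TRUE)
  max(abs(steps[ties]))
}

# Asymptotic two-sided p-value with the small-sample effective-size
# correction lambda = (sqrt(ne) + 0.12 + 0.11/sqrt(ne)) * D.
ks_asymptotic_p <- function(d, n1, n2, tol = 1e-10, max_terms = 100L) {
  if (d <= 0) {
    return(1)
  }
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * d
  total <- 0
  for (k in seq_len(max_terms)) {
    term <- (-1)^(k - 1) * exp(-2 * k^2 * lambda^2)
    total <- total + term
    if (abs(term) < tol) break
  }
  min(max(2 * total, 0), 1)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Nonparametric comparison of two samples through the supremum distance
#' between their empirical distribution functions, with the asymptotic
#' two-sided p-value (effective-sample-size corrected Kolmogorov series).
#' Two samples are declared *comparable* — statistically indistinguishable
#' in the protocol's sense — when `p > alpha`.
#'
#' @param x,y numeric samples, each non-empty.
#' @param alpha comparability threshold on the p-value.
#' @return an object of class `ks_result`: `d_statistic`, `p_value`, `n1`,
#'   `n2`, `comparable`.
#' @examples
#' ks_two_sample(rnorm(21), rnorm(21))
#' @export
ks_two_sample <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 1L || length(y) < 1L) {
    stop("both samples must contain at least one non-missing value.",
         call. = FALSE)
  }
  d <- ks_d_statistic(x, y)
  p <- ks_asymptotic_p(d, length(x), length(y))
  structure(
    list(d_statistic = d, p_value = p, n1 = length(x), n2 = length(y),
         comparable = p > alpha),
    class = "ks_result"
  )
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D = %.4f, p = %.4f (n1 = %d, n2 = %d) %s\n",
              x$d_statistic, x$p_value, x$n1, x$n2,
              if (x$comparable) "comparable" else "distinguishable"))
  invisible(x)
}

#' Pairwise KS comparability across groups
#'
#' Runs the two-sample KS test on every pair of levels of a grouping column,
#' optionally within cells of another column (e.g. concentration groups
#' within each source-detector configuration). By default no multiple-testing
#' correction is applied, matching the protocol's per-comparison p > 0.05
#' reading; Holm correction is available.
#'
#' @param estimates a tibble of per-replicate values.
#' @param group bare column name whose levels are compared.
#' @param value bare column name of the compared values.
#' @param within optional bare column name; comparisons are made within each
#'   of its cells.
#' @param alpha comparability threshold.
#' @param p_adjust `"none"` (default) or `"holm"`.
#' @return a tibble with one row per comparison: the `within` cell (if any),
#'   `group1`, `group2`, `n1`, `n2`, `d_statistic`, `p_value`, `comparable`.
#' @examples
#' est <- tibble::tibble(
#'   config_id = rep("a", 20),
#'   o2_nominal = rep(c(0.21, 0.30), each = 10),
#'   pathlength_m = stats::rnorm(20, 0.1, 0.01)
#' )
#' compare_configurations(est, group = o2_nominal, value = pathlength_m,
#'                        within = config_id)
#' @export
compare_configurations <- function(estimates, group, value = pathlength_m,
                                   within = NULL, alpha = 0.05,
                                   p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  group <- rlang::enquo(group)
  value <- rlang::enquo(value)
  within <- rlang::enquo(within)
  for (q in list(group, value)) {
    nm <- rlang::as_name(q)
    if (!nm %in% names(estimates)) {
      stop("unknown pairing column: ", nm, call. = FALSE)
    }
  }
  has_within <- !rlang::quo_is_null(within)
  if (has_within) {
    nm <- rlang::as_name(within)
    if (!nm %in% names(estimates)) {
      stop("unknown pairing column: ", nm, call. = FALSE)
    }
    cells <- split(estimates, dplyr::pull(estimates, !!within))
  } else {
    cells <- list(estimates)
  }
  rows <- list()
  for (cell_name in names(cells) %||% "") {
    cell <- if (has_within) cells[[cell_name]] else cells[[1]]
    g <- dplyr::pull(cell, !!group)
    v <- dplyr::pull(cell, !!value)
    keep <- !is.na(v)
    g <- g[keep]
    v <- v[keep]
    levels <- sort(unique(g))
    if (length(levels) < 2L) next
    pairs <- utils::combn(levels, 2L, simplify = FALSE)
    for (pr in pairs) {
      xs <- v[g == pr[1]]
      ys <- v[g == pr[2]]
      if (length(xs) < 1L || length(ys) < 1L) next
      ks <- ks_two_sample(xs, ys, alpha = alpha)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        within = if (has_within) cell_name else NA_character_,
        group1 = pr[1], group2 = pr[2],
        n1 = ks$n1, n2 = ks$n2,
        d_statistic = ks$d_statistic, p_value = ks$p_value
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(within = character(), group1 = numeric(),
                          group2 = numeric(), n1 = integer(), n2 = integer(),
                          d_statistic = numeric(), p_value = numeric(),
                          p_adjusted = numeric(), comparable = logical()))
  }
  out$p_adjusted <- stats::p.adjust(out$p_value, method = p_adjust)
  out$comparable <- out$p_adjusted > alpha
  if (has_within) {
    names(out)[names(out) == "within"] <- rlang::as_name(within)
  } else {
    out$within <- NULL
  }
  out
}

#' Box-plot statistics per concentration group
#'
#' Median, quartiles (linear-interpolation quantile convention, type 7),
#' 1.5 IQR whiskers and the points beyond the fences, grouped by nominal
#' concentration — the summary behind concentration box plots.
#'
#' @param estimates a gas-estimates tibble.
#' @param value bare column name of the summarised values.
#' @param group bare column name of the grouping labels.
#' @param drop_na drop missing values before summarising.
#' @return a tibble with one row per group: `group`, `n`, `median`, `q1`,
#'   `q3`, `whisker_low`, `whisker_high`, and a list-column
#'   `outlier_values`.
#' @export
concentration_boxes <- function(estimates, value = o2_fraction,
                                group = o2_nominal, drop_na = TRUE) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  v <- dplyr::pull(estimates, !!value)
  g <- dplyr::pull(estimates, !!group)
  if (drop_na) {
    keep <- !is.na(v)
    v <- v[keep]
    g <- g[keep]
  }
  levels <- sort(unique(g))
  purrr::map_dfr(levels, function(lv) {
    x <- v[g == lv]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    inside <- x[x >= lo_fence & x <= hi_fence]
    tibble::tibble(
      group = lv, n = length(x),
      median = q[2], q1 = q[1], q3 = q[3],
      whisker_low = min(inside), whisker_high = max(inside),
      outlier_values = list(sort(x[x < lo_fence | x > hi_fence]))
    )
  })
}
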