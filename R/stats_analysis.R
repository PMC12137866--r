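# Statistical summaries: quadrant count ratio for bivariate association and
# two-sample / one-sample condition comparisons.

#' Quadrant count ratio
#'
#' A robust, nonparametric association statistic for a bivariate point set
#' (e.g. compartment volume vs content density). Quadrants are defined by the
#' medians of the two coordinates; points lying exactly on a median line are
#' excluded. With quadrants numbered counter-clockwise (quadrant I has both
#' coordinates above their medians), the statistic is
#' `((n_I + n_III) - (n_II + n_IV)) / N'`, bounded in \[-1, 1\], invariant
#' under strictly monotone transforms of either axis, and sign-flipped by
#' negating one axis.
#'
#' @param points Data frame whose first two numeric columns are the
#'   coordinates, or a two-column matrix.
#' @return A single number in \[-1, 1\].
#' @examples
#' quadrant_count_ratio(data.frame(u = 1:10, v = (1:10)^3))  # 1
#' @export
quadrant_count_ratio <- function(points) {
  m <- as.data.frame(points)
  num <- vapply(m, is.numeric, TRUE)
  if (sum(num) < 2) stop("points must have two numeric columns")
  u <- m[[which(num)[1]]]; v <- m[[which(num)[2]]]
  if (anyNA(u) || anyNA(v) || any(!is.finite(c(u, v))))
    stop("points must be finite")
  mu <- stats::median(u); mv <- stats::median(v)
  off <- u != mu & v != mv
  n <- sum(off)
  if (n < 4) stop("fewer than 4 points off the median lines")
  du <- u[off] > mu; dv <- v[off] > mv
  concordant <- sum(du == dv)   # quadrants I and III
  (concordant - (n - concordant)) / n
}

#' Compare metric values across acquisition conditions
#'
#' Pairwise two-tailed two-sample t-tests between all condition pairs (pooled
#' variance by default, Welch optionally), flagged at `alpha`, plus an
#' optional one-sample t-test of each condition against a set value `mu`
#' (used for ratios normalised to a reference, where the null is 1).
#'
#' @param data Data frame with a grouping column and a value column, or a
#'   named list of numeric vectors.
#' @param value,group Column names when `data` is a data frame.
#' @param var_equal Pooled-variance t-test (default `TRUE`); `FALSE` for
#'   Welch.
#' @param alpha Significance level for the flag.
#' @param mu If non-`NULL`, also test each group against this value.
#' @return A `leap_comparison` object; `tidy()` returns the pairwise table,
#'   `glance()` a one-row summary.
#' @export
compare_conditions <- function(data, value = "value", group = "condition",
                               var_equal = TRUE, alpha = 0.05, mu = NULL) {
  groups <- if (is.data.frame(data)) split(data[[value]], data[[group]])
            else data
  if (length(groups) < 2 && is.null(mu))
    stop("need at least two groups (or mu for one-sample tests)")
  if (any(vapply(groups, length, 1L) < 2))
    stop("every group needs at least 2 observations")
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(p) {
    a <- groups[[p[1]]]; b <- groups[[p[2]]]
    tt <- stats::t.test(a, b, var.equal = var_equal)
    tibble::tibble(group1 = p[1], group2 = p[2],
                   mean1 = mean(a), mean2 = mean(b),
                   mean_diff = mean(a) - mean(b),
                   statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value,
                   significant = tt$p.value < alpha)
  })
  one_sample <- NULL
  if (!is.null(mu)) {
    one_sample <- purrr::imap_dfr(groups, function(g, nm) {
      if (stats::sd(g) == 0) {
        tibble::tibble(group = nm, mean = mean(g), mu = mu,
                       statistic = if (mean(g) == mu) 0 else Inf,
                       p_value = if (mean(g) == mu) 1 else 0,
                       significant = mean(g) != mu)
      } else {
        tt <- stats::t.test(g, mu = mu)
        tibble::tibble(group = nm, mean = mean(g), mu = mu,
                       statistic = unname(tt$statistic), p_value = tt$p.value,
                       significant = tt$p.value < alpha)
      }
    })
  }
  structure(list(pairwise = pairwise, one_sample = one_sample,
                 alpha = alpha, var_equal = var_equal,
                 groups = groups), class = "leap_comparison")
}

#' @export
print.leap_comparison <- function(x, ...) {
  cat(sprintf("<leap_comparison> %d group(s), %s t-test, alpha = %g\n",
              length(x$groups), if (x$var_equal) "pooled" else "Welch",
              x$alpha))
  print(x$pairwise)
  if (!is.null(x$one_sample)) {
    cat("one-sample tests:\n")
    print(x$one_sample)
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.leap_comparison <- function(x, ...) x$pairwise

#' @export
glance.leap_comparison <- function(x, ...) {
  tibble::tibble(n_groups = length(x$groups),
                 n_pairs = nrow(x$pairwise),
                 n_significant = sum(x$pairwise$significant),
                 alpha = x$alpha,
                 pooled = x$var_equal)
}
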