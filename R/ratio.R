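#' Build a 2x2 contingency table
#'
#' Rows are the two comparison groups (for the cohort analyses: clinical
#' status), columns are finding present / absent. Cell layout:
#' \preformatted{
#'              present  absent
#'   group1        a        b
#'   group2        c        d
#' }
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param groups Length-2 character vector naming the rows, `groups[1]` is the
#'   numerator group of the ratio estimates.
#' @param outcome Label for the outcome being counted.
#' @return An object of class `two_by_two`.
#' @examples
#' two_by_two(22, 719, 1, 121, groups = c("symptomatic", "asymptomatic"))
#' @export
two_by_two <- function(a, b, c, d,
                       groups = c("group1", "group2"),
                       outcome = "finding") {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != trunc(cells))) {
    validation_error("2x2 cells must be non-negative integers.")
  }
  structure(
    list(a = a, b = b, c = c, d = d, groups = groups, outcome = outcome),
    class = "two_by_two"
  )
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
              dimnames = list(x$groups, c("present", "absent")))
  cat("2x2 table (", x$outcome, ")\n", sep = "")
  print(m)
  invisible(x)
}

#' @export
as.matrix.two_by_two <- function(x, ...) {
  matrix(c(x$a, x$c, x$b, x$d), nrow = 2,
         dimnames = list(x$groups, c("present", "absent")))
}

ratio_estimate <- function(measure, point, se_log, tab, ci_z, method) {
  z <- log(point) / se_log
  structure(
    list(
      measure = measure,
      direction = tab$groups,
      point = point,
      ci_low = exp(log(point) - ci_z * se_log),
      ci_high = exp(log(point) + ci_z * se_log),
      se_log = se_log,
      p_value = 2 * stats::pnorm(-abs(z)),
      method = method,
      table = tab
    ),
    class = "ratio_estimate"
  )
}

haldane_shift <- function(tab) {
  # bypasses the integer-cell validation deliberately: corrected cells are
  # half-integers by construction
  structure(
    list(a = tab$a + 0.5, b = tab$b + 0.5, c = tab$c + 0.5, d = tab$d + 0.5,
         groups = tab$groups, outcome = tab$outcome),
    class = "two_by_two"
  )
}

check_cells <- function(tab, cells, haldane) {
  vals <- unlist(tab[cells])
  if (any(vals == 0)) {
    if (haldane) return(haldane_shift(tab))
    validation_error(paste0(
      "Zero cell(s) ", paste(cells[vals == 0], collapse = ","),
      " make the estimate degenerate; use `haldane = TRUE` for the +0.5 correction."
    ))
  }
  tab
}

#' Risk ratio with Wald confidence interval
#'
#' Ratio of outcome frequencies between the two row groups, with the
#' log-scale Wald interval and a two-sided normal-tail p-value for the null
#' ratio of 1. `ci_z` defaults to 1.96 (two-sided 95%).
#'
#' @param tab A [two_by_two()] table.
#' @param haldane Apply the Haldane-Anscombe +0.5 correction to all cells
#'   when a cell is zero (default `FALSE`: zero `a` or `c` is an error).
#' @param ci_z Normal quantile for the interval half-width.
#' @return A `ratio_estimate` object; see [tidy.ratio_estimate()].
#' @examples
#' rr <- risk_ratio(two_by_two(22, 719, 1, 121))
#' round_half_up(rr$point, 1)   # 3.6
#' round_half_up(rr$p_value, 2) # 0.21
#' @export
risk_ratio <- function(tab, haldane = FALSE, ci_z = 1.96) {
  stopifnot(inherits(tab, "two_by_two"))
  if ((tab$a + tab$b) == 0 || (tab$c + tab$d) == 0) {
    validation_error("Both row totals of the 2x2 table must be positive.")
  }
  tab <- check_cells(tab, c("a", "c"), haldane)
  n1 <- tab$a + tab$b
  n2 <- tab$c + tab$d
  point <- (tab$a / n1) / (tab$c / n2)
  se <- sqrt(1 / tab$a - 1 / n1 + 1 / tab$c - 1 / n2)
  ratio_estimate("RISK_RATIO", point, se, tab, ci_z, "wald_log_rr")
}

#' Odds ratio with Wald confidence interval
#'
#' Cross-product odds ratio `(a d) / (b c)` with log-scale Wald interval and
#' two-sided normal-tail p-value.
#'
#' @inheritParams risk_ratio
#' @return A `ratio_estimate` object.
#' @examples
#' or <- odds_ratio(two_by_two(1, 121, 15, 726))
#' round_half_up(or$point, 2)   # 0.40
#' round_half_up(or$p_value, 2) # 0.38
#' @export
odds_ratio <- function(tab, haldane = FALSE, ci_z = 1.96) {
  stopifnot(inherits(tab, "two_by_two"))
  tab <- check_cells(tab, c("a", "b", "c", "d"), haldane)
  point <- (tab$a * tab$d) / (tab$b * tab$c)
  se <- sqrt(1 / tab$a + 1 / tab$b + 1 / tab$c + 1 / tab$d)
  ratio_estimate("ODDS_RATIO", point, se, tab, ci_z, "wald_log_or")
}

#' Swap the comparison direction of a 2x2 table
#'
#' @param tab A [two_by_two()] table.
#' @return The table with its rows (groups) exchanged.
#' @export
swap_groups <- function(tab) {
  two_by_two(tab$c, tab$d, tab$a, tab$b,
             groups = rev(tab$groups), outcome = tab$outcome)
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf(
    "%s (%s vs %s): %.3f [%.3f, %.3f], p = %.4g (%s)\n",
    x$measure, x$direction[1], x$direction[2],
    x$point, x$ci_low, x$ci_high, x$p_value, x$method
  ))
  invisible(x)
}

#' Tidy a ratio estimate
#'
#' @param x A `ratio_estimate` from [risk_ratio()] or [odds_ratio()].
#' @param ... Unused.
#' @return A one-row tibble with `measure`, `comparison`, `estimate`,
#'   `conf.low`, `conf.high`, `std.error` (log scale), `p.value`, `method`.
#' @method tidy ratio_estimate
#' @export
tidy.ratio_estimate <- function(x, ...) {
  tibble(
    measure = x$measure,
    comparison = paste(x$direction, collapse = " vs "),
    estimate = x$point,
    conf.low = x$ci_low,
    conf.high = x$ci_high,
    std.error = x$se_log,
    p.value = x$p_value,
    method = x$method
  )
}

#' @method glance ratio_estimate
#' @export
glance.ratio_estimate <- function(x, ...) tidy(x, ...)

#' Two-sided Fisher exact p-value by hypergeometric enumeration
#'
#' Enumerates all 2x2 tables with the observed margins and sums the
#' probabilities of tables no more probable than the observed one (the
#' standard two-sided convention). Provided as an exact cross-check on the
#' Wald p-values; small tables only.
#'
#' @param tab A [two_by_two()] table with integer cells.
#' @return The two-sided exact p-value.
#' @examples
#' fisher_p(two_by_two(3, 7, 8, 2))
#' @export
fisher_p <- function(tab) {
  stopifnot(inherits(tab, "two_by_two"))
  a <- tab$a; b <- tab$b; c <- tab$c; d <- tab$d
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  ks <- max(0L, k - n):min(k, m)
  # P(table with cell a = x | margins), via the hypergeometric mass
  probs <- exp(
    lchoose(m, ks) + lchoose(n, k - ks) - lchoose(m + n, k)
  )
  p_obs <- probs[ks == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Plot a ratio estimate
#'
#' Point estimate with its Wald interval on a log-scaled axis.
#'
#' @param object A `ratio_estimate`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ratio_estimate
#' @export
autoplot.ratio_estimate <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$comparison)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = sprintf("%s (log scale)", df$measure),
      y = NULL,
      title = sprintf("%s with Wald 95%% interval", df$measure)
    ) +
    ggplot2::theme_minimal()
}

#' Relative change between two panel-version frequencies
#'
#' Relative increase, in percent, of a frequency under the current panel
#' version over the frequency under an older version, computed (as in the
#' source tables this mirrors) on the rounded printed percents.
#'
#' @param pct_new,pct_old Percentages (e.g. participant-level SF frequencies);
#'   `pct_old` must be positive.
#' @param decimals Decimal places for the returned relative change.
#' @return `100 * (pct_new - pct_old) / pct_old`, rounded half-up.
#' @examples
#' version_comparison(2.7, 2.4) # 12.5
#' @export
version_comparison <- function(pct_new, pct_old, decimals = 1) {
  if (any(pct_old <= 0)) {
    validation_error("`pct_old` must be positive.")
  }
  round_half_up(100 * (pct_new - pct_old) / pct_old, decimals)
}
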