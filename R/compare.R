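#' Significance stars
#'
#' `***` for p <= 0.001, `**` for p <= 0.01, `*` for p <= 0.05, empty
#' otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(p <= 0.001 ~ "***",
                   p <= 0.01 ~ "**",
                   p <= 0.05 ~ "*",
                   TRUE ~ "")
}

#' Compare per-embryo values between conditions
#'
#' Each mutant condition is compared with the control by an unpaired
#' two-tailed t test (classic equal-variance by default, Welch via
#' `var_equal = FALSE`); with three or more conditions a one-way ANOVA
#' across all of them is added. Per-condition mean, SD and SEM are reported.
#' Each embryo must contribute exactly one value.
#'
#' @param embryo_values Tibble with one row per embryo.
#' @param value Name of the value column (string).
#' @param condition Name of the condition column (string).
#' @param control Control condition label; defaults to the first condition
#'   in order of appearance.
#' @param var_equal Use the classic equal-variance t statistic (default
#'   `TRUE`).
#' @return A `group_comparison` object with `summary`, `tests` and `anova`
#'   components; see [tidy()] and [glance()] methods.
#' @export
compare_groups <- function(embryo_values, value, condition = "condition",
                           control = NULL, var_equal = TRUE) {
  vals <- embryo_values[[value]]
  cond <- as.character(embryo_values[[condition]])
  if (is.null(control)) control <- cond[1]
  if (!control %in% cond) stop("control condition not present")
  counts <- table(cond)
  if (any(counts < 2)) stop("every condition needs at least 2 embryos")
  levels <- unique(cond)
  summary <- tibble(condition = levels) |>
    dplyr::rowwise() |>
    dplyr::mutate(
      n = sum(cond == .data$condition),
      mean = mean(vals[cond == .data$condition]),
      sd = sd(vals[cond == .data$condition]),
      sem = .data$sd / sqrt(.data$n)) |>
    dplyr::ungroup()
  others <- setdiff(levels, control)
  tests <- purrr::map_dfr(others, function(g) {
    tt <- stats::t.test(vals[cond == g], vals[cond == control],
                        var.equal = var_equal)
    tibble(condition = g, control = control,
           statistic = unname(tt$statistic), df = unname(tt$parameter),
           p.value = tt$p.value, stars = significance_stars(tt$p.value))
  })
  anova <- NULL
  if (length(levels) >= 3) {
    fit <- aov(vals ~ factor(cond))
    s <- summary(fit)[[1]]
    anova <- tibble(statistic = s[["F value"]][1],
                    df1 = s[["Df"]][1], df2 = s[["Df"]][2],
                    p.value = s[["Pr(>F)"]][1])
  }
  structure(list(summary = summary, tests = tests, anova = anova,
                 value = value, control = control,
                 data = tibble(condition = cond, value = vals)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s, control = %s\n", x$value, x$control))
  print(x$summary)
  if (nrow(x$tests) > 0) print(x$tests)
  if (!is.null(x$anova))
    cat(sprintf("one-way ANOVA: F(%d, %d) = %.3g, p = %.3g\n",
                x$anova$df1, x$anova$df2, x$anova$statistic, x$anova$p.value))
  invisible(x)
}

#' Tidy a group comparison
#'
#' One row per mutant-vs-control t test: `condition`, `control`,
#' `statistic`, `df`, `p.value`, `stars`.
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
tidy.group_comparison <- function(x, ...) x$tests

#' One-row summary of a group comparison
#'
#' Reports the number of conditions and embryos and, when computed, the
#' one-way ANOVA F statistic and p-value.
#'
#' @param x A `group_comparison`.
#' @param ... Unused.
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(n_conditions = nrow(x$summary),
         n_embryos = sum(x$summary$n),
         anova_statistic = if (is.null(x$anova)) NA_real_ else x$anova$statistic,
         anova_p.value = if (is.null(x$anova)) NA_real_ else x$anova$p.value)
}

#' Dot plot of per-embryo values with mean and error bars
#'
#' Each embryo is a dot; horizontal bars show the condition mean with
#' mean +/- SEM (default) or +/- SD whiskers.
#'
#' @param object A `group_comparison`.
#' @param error `"sem"` or `"sd"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_comparison <- function(object, error = c("sem", "sd"), ...) {
  error <- match.arg(error)
  s <- object$summary
  s$err <- if (error == "sem") s$sem else s$sd
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$condition, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, size = 2, alpha = 0.8) +
    ggplot2::geom_errorbar(
      data = s,
      ggplot2::aes(x = .data$condition, y = .data$mean,
                   ymin = .data$mean - .data$err,
                   ymax = .data$mean + .data$err),
      width = 0.25, inherit.aes = FALSE) +
    ggplot2::stat_summary(
      data = object$data, fun = mean, geom = "crossbar",
      width = 0.4, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = object$value) +
    ggplot2::theme_classic()
}
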