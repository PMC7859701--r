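# coerce a named list of numeric vectors or a (value, group) data.frame
# into a named list of groups
as_group_list <- function(x, values = NULL, groups = NULL) {
  if (is.data.frame(x)) {
    values <- if (is.null(values)) x$value else x[[values]]
    groups <- if (is.null(groups)) x$group else x[[groups]]
    check_that(!is.null(values) && !is.null(groups),
               "data.frame input needs value and group columns")
    keep <- is.finite(values) & !is.na(groups)
    split(values[keep], factor(groups[keep]))
  } else {
    check_that(is.list(x) && !is.null(names(x)) && all(nzchar(names(x))),
               "groups must be a named list of numeric vectors")
    lapply(x, as.numeric)
  }
}

#' Shapiro-Wilk normality gate
#'
#' Runs the Shapiro-Wilk test on each group and flags the comparison as
#' parametric when every group passes at the 0.05 level. This is the gate
#' that decides between ANOVA/Tukey and Kruskal-Wallis/Dunn in
#' [compare_groups].
#'
#' @param groups named list of numeric vectors (each n >= 3), or a
#'   `data.frame` with `value` and `group` columns.
#' @return A list with `p_values` (named, per group) and `parametric`
#'   (logical: all p > 0.05).
#' @export
shapiro_gate <- function(groups) {
  g <- as_group_list(groups)
  ns <- vapply(g, length, 0L)
  if (any(ns < 3))
    stop("group(s) with fewer than 3 observations: ",
         paste(names(g)[ns < 3], collapse = ", "), call. = FALSE)
  p <- vapply(g, function(v) {
    if (length(unique(v)) == 1) return(0) # degenerate: certainly non-normal
    shapiro.test(v)$p.value
  }, 0)
  list(p_values = p, parametric = all(p > 0.05))
}

new_comparison <- function(metric, g, test_used, statistic, df, p_value,
                           pairwise, alpha, normality, forced) {
  structure(list(
    metric = metric,
    groups = data.frame(group = names(g), n = vapply(g, length, 0L),
                        mean = vapply(g, mean, 0),
                        sd = vapply(g, sd, 0), row.names = NULL),
    test_used = test_used, statistic = statistic, df = df,
    p_value = p_value, pairwise = pairwise, alpha = alpha,
    normality = normality, forced = forced), class = "tz_comparison")
}

#' One-way ANOVA with Tukey's HSD post hoc test
#'
#' Omnibus one-way ANOVA followed by Tukey's honestly-significant-
#' difference pairwise comparisons (Tukey-Kramer on unequal group sizes),
#' via [stats::aov] and [stats::TukeyHSD].
#'
#' @param groups named list of numeric vectors (each n >= 2), or a
#'   `data.frame` with `value` and `group` columns.
#' @param alpha significance level for flagging pairs (default 0.05).
#' @param metric metric name recorded in the result.
#' @return A `tz_comparison` object.
#' @export
anova_tukey <- function(groups, alpha = 0.05, metric = "value") {
  g <- as_group_list(groups)
  check_that(length(g) >= 2, "need at least 2 groups")
  check_that(all(vapply(g, length, 0L) >= 2), "each group needs n >= 2")
  if (all(vapply(g, function(v) length(unique(v)), 0L) == 1))
    stop("degenerate variance: all values identical within groups",
         call. = FALSE)
  df <- data.frame(value = unlist(g, use.names = FALSE),
                   group = factor(rep(names(g), vapply(g, length, 0L))))
  fit <- aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pw <- data.frame(group_a = pairs[, 2], group_b = pairs[, 1],
                   estimate = tk[, "diff"], p_adj = tk[, "p adj"],
                   row.names = NULL)
  pw$significant <- pw$p_adj < alpha
  new_comparison(metric, g, "anova_tukey",
                 statistic = c(F = an["group", "F value"]),
                 df = c(an["group", "Df"], an["Residuals", "Df"]),
                 p_value = an["group", "Pr(>F)"],
                 pairwise = pw, alpha = alpha, normality = NULL,
                 forced = FALSE)
}

# tie-corrected Dunn z statistics on pooled ranks, Bonferroni-adjusted
dunn_pairwise <- function(g, alpha) {
  all_v <- unlist(g, use.names = FALSE)
  rk <- rank(all_v)
  N <- length(all_v)
  grp <- rep(names(g), vapply(g, length, 0L))
  rbar <- tapply(rk, grp, mean)
  n <- tapply(rk, grp, length)
  ties <- table(all_v)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term
  combos <- combn(names(g), 2)
  z <- apply(combos, 2, function(p) {
    (rbar[p[1]] - rbar[p[2]]) /
      sqrt(s2 * (1 / n[p[1]] + 1 / n[p[2]]))
  })
  p_raw <- 2 * pnorm(-abs(z))
  p_adj <- p.adjust(p_raw, method = "bonferroni")
  data.frame(group_a = combos[1, ], group_b = combos[2, ],
             estimate = z, p_adj = p_adj,
             significant = p_adj < alpha, row.names = NULL)
}

#' Kruskal-Wallis test with Dunn's post hoc test
#'
#' Tie-corrected Kruskal-Wallis omnibus test (via [stats::kruskal.test])
#' followed by Dunn's pairwise z tests on the pooled ranks, with
#' Bonferroni adjustment over all pairs (the adjustment method is recorded
#' in the result for transparency).
#'
#' @inheritParams anova_tukey
#' @return A `tz_comparison` object.
#' @export
kruskal_dunn <- function(groups, alpha = 0.05, metric = "value") {
  g <- as_group_list(groups)
  check_that(length(g) >= 2, "need at least 2 groups")
  check_that(all(vapply(g, length, 0L) >= 2), "each group needs n >= 2")
  if (length(unique(unlist(g))) == 1)
    stop("all values identical across groups", call. = FALSE)
  df <- data.frame(value = unlist(g, use.names = FALSE),
                   group = factor(rep(names(g), vapply(g, length, 0L))))
  kw <- kruskal.test(value ~ group, data = df)
  res <- new_comparison(metric, g, "kruskal_dunn",
                        statistic = c(H = unname(kw$statistic)),
                        df = unname(kw$parameter),
                        p_value = kw$p.value,
                        pairwise = dunn_pairwise(g, alpha),
                        alpha = alpha, normality = NULL, forced = FALSE)
  res$p_adjust_method <- "bonferroni"
  res
}

#' Normality-gated multi-group comparison
#'
#' The statistical workflow applied to every metric: a Shapiro-Wilk test
#' per group decides between parametric (one-way ANOVA + Tukey's HSD) and
#' nonparametric (Kruskal-Wallis + Dunn's test) multi-group comparison at
#' `alpha = 0.05`. The gate verdict is attached to the result; a
#' `force_test` override is honoured and recorded.
#'
#' @param data named list of numeric vectors, or a `data.frame`.
#' @param values,groups column names when `data` is a `data.frame`
#'   (defaults `"value"` and `"group"`).
#' @param alpha significance level (default 0.05).
#' @param force_test `NULL` (gate decides), `"anova_tukey"` or
#'   `"kruskal_dunn"`.
#' @param metric metric name recorded in the result.
#' @return A `tz_comparison` object.
#' @export
compare_groups <- function(data, values = NULL, groups = NULL,
                           alpha = 0.05, force_test = NULL,
                           metric = "value") {
  g <- as_group_list(data, values, groups)
  gate <- shapiro_gate(g)
  if (is.null(force_test)) {
    test <- if (gate$parametric) "anova_tukey" else "kruskal_dunn"
    forced <- FALSE
  } else {
    test <- match.arg(force_test, c("anova_tukey", "kruskal_dunn"))
    forced <- TRUE
  }
  res <- if (test == "anova_tukey") anova_tukey(g, alpha, metric)
         else kruskal_dunn(g, alpha, metric)
  res$normality <- gate
  res$forced <- forced
  res
}

#' @export
print.tz_comparison <- function(x, ...) {
  cat(sprintf("Multi-group comparison of '%s' (%d groups)\n", x$metric,
              nrow(x$groups)))
  cat(sprintf("  test: %s%s | omnibus %s = %.4g, p = %.3g (alpha %.2f)\n",
              x$test_used, if (isTRUE(x$forced)) " (forced)" else "",
              names(x$statistic)[1], x$statistic[1], x$p_value, x$alpha))
  if (!is.null(x$normality))
    cat(sprintf("  normality gate: %s (min Shapiro-Wilk p = %.3g)\n",
                if (x$normality$parametric) "parametric" else "nonparametric",
                min(x$normality$p_values)))
  sig <- x$pairwise[x$pairwise$significant, , drop = FALSE]
  cat(sprintf("  significant pairs: %d of %d\n", nrow(sig), nrow(x$pairwise)))
  invisible(x)
}

#' @export
summary.tz_comparison <- function(object, ...) {
  print(object)
  cat("\nGroups:\n")
  print(object$groups, row.names = FALSE)
  cat("\nPairwise comparisons:\n")
  pw <- object$pairwise
  pw$p_adj <- signif(pw$p_adj, 3)
  print(pw, row.names = FALSE)
  invisible(object)
}
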