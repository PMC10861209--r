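# Group statistics, regression with confidence bands, radar summary.

#' Compare metric values across groups
#'
#' Two groups: two-sided unpaired Student's t test (equal variance by
#' default, Welch by flag). More than two: one-way ANOVA followed by
#' Tukey's HSD. A Shapiro-Wilk normality screen per group is reported as a
#' diagnostic only.
#'
#' @param values Numeric vector.
#' @param group Factor/character of the same length (>= 2 values per
#'   group).
#' @param welch Use Welch's t instead of the equal-variance Student's t.
#' @return A list of class `group_comparison`: `groups` (per-group n,
#'   mean, sem, shapiro_p), `test` ("t" or "anova_tukey"), `statistic`,
#'   `p_value`, and `tukey` (pairwise table, multi-group only).
#' @export
compare_groups <- function(values, group, welch = FALSE) {
  group <- factor(group)
  stopifnot(length(values) == length(group))
  if (any(table(group) < 2)) stop("need >= 2 values per group")
  gstats <- do.call(rbind, lapply(levels(group), function(g) {
    v <- values[group == g]
    data.frame(group = g, n = length(v), mean = mean(v),
               sem = stats::sd(v) / sqrt(length(v)),
               shapiro_p = if (length(v) >= 3 && stats::sd(v) > 0)
                 stats::shapiro.test(v)$p.value else NA_real_)
  }))
  if (nlevels(group) == 2) {
    v1 <- values[group == levels(group)[1]]
    v2 <- values[group == levels(group)[2]]
    if (stats::sd(values) == 0) {
      tt <- list(statistic = c(t = 0), p.value = 1)  # degenerate: all equal
    } else {
      tt <- stats::t.test(v1, v2, var.equal = !welch)
    }
    out <- list(groups = gstats, test = "t",
                statistic = unname(tt$statistic), p_value = tt$p.value,
                tukey = NULL)
  } else {
    fit <- stats::aov(values ~ group)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$group
    out <- list(groups = gstats, test = "anova_tukey",
                statistic = an$`F value`[1], p_value = an$`Pr(>F)`[1],
                tukey = data.frame(pair = rownames(tk), diff = tk[, "diff"],
                                   p_adj = tk[, "p adj"],
                                   row.names = NULL))
  }
  structure(out, class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  print(x$groups)
  invisible(x)
}

#' Per-group least-squares fit with a confidence band
#'
#' Ordinary least squares of y on x within each group, with the pointwise
#' mean-response confidence band at the requested level evaluated on a
#' grid over the group's x-range, plus the between-group slope difference
#' and its standard error (two-group case).
#'
#' @param x,y Numeric vectors (e.g. cell area and total force).
#' @param group Group labels (single group allowed).
#' @param level Confidence level of the band (default 0.90).
#' @param n_grid Band evaluation points per group.
#' @return A list of class `regression_fit`: `fits` (per group: slope,
#'   intercept, slope_se), `band` (data.frame group, x, fit, lower,
#'   upper), and `slope_difference` (first minus second group, with SE;
#'   two groups only).
#' @export
regression_with_band <- function(x, y, group = NULL, level = 0.90,
                                 n_grid = 50L) {
  if (is.null(group)) group <- rep("all", length(x))
  group <- factor(group)
  fits <- list(); band <- NULL
  for (g in levels(group)) {
    xs <- x[group == g]; ys <- y[group == g]
    if (length(xs) < 3) stop("need >= 3 points per group")
    if (stats::sd(xs) == 0) stop("x is constant within a group")
    fit <- stats::lm(ys ~ xs)
    grid <- data.frame(xs = seq(min(xs), max(xs), length.out = n_grid))
    ci <- stats::predict(fit, grid, interval = "confidence",
                         level = level)
    band <- rbind(band, data.frame(group = g, x = grid$xs,
                                   fit = ci[, "fit"], lower = ci[, "lwr"],
                                   upper = ci[, "upr"]))
    sm <- summary(fit)$coefficients
    fits[[g]] <- c(slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   slope_se = sm[2, "Std. Error"])
  }
  slope_diff <- NULL
  if (nlevels(group) == 2) {
    f1 <- fits[[levels(group)[1]]]; f2 <- fits[[levels(group)[2]]]
    slope_diff <- c(diff = unname(f1["slope"] - f2["slope"]),
                    se = unname(sqrt(f1["slope_se"]^2 + f2["slope_se"]^2)))
  }
  structure(list(fits = fits, band = band, slope_difference = slope_diff,
                 level = level),
            class = "regression_fit")
}

#' Min-max normalized group means for radar plots
#'
#' Each metric column is min-max normalized over all cells (constant
#' metrics map to 0.5 by convention), then averaged per group.
#'
#' @param metrics Numeric data.frame/matrix, cells x metrics.
#' @param group Group label per row.
#' @return A list of class `radar_summary`: `table` (groups x metrics of
#'   normalized means), `normalized` (per-cell normalized matrix).
#' @export
radar_summary <- function(metrics, group) {
  metrics <- as.data.frame(metrics)
  group <- factor(group)
  stopifnot(nrow(metrics) == length(group))
  norm <- vapply(metrics, function(v) {
    r <- range(v, na.rm = TRUE)
    if (diff(r) == 0) {
      warning("constant metric: normalized to 0.5 by convention")
      return(rep(0.5, length(v)))
    }
    (v - r[1]) / diff(r)
  }, numeric(nrow(metrics)))
  norm <- matrix(norm, nrow = nrow(metrics),
                 dimnames = list(NULL, names(metrics)))
  tab <- do.call(rbind, lapply(levels(group), function(g)
    colMeans(norm[group == g, , drop = FALSE], na.rm = TRUE)))
  rownames(tab) <- levels(group)
  structure(list(table = tab, normalized = norm),
            class = "radar_summary")
}
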