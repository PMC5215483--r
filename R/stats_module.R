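# Per-animal aggregation and normality-gated group statistics.
#
# The experimental unit is the animal: observations (ROIs, plaques, traces,
# boxes) are first reduced to one value per animal per metric, and group
# tests run on those per-animal summaries. Test selection is gated on the
# Shapiro-Wilk normality test at alpha = 0.05, and every decision taken on
# the way to a p-value is recorded in a decision trail.

#' Aggregate observations to one value per animal
#'
#' For each animal, the Shapiro-Wilk test is applied to its observations:
#' when normality is not rejected (p >= alpha) the animal's mean is used,
#' otherwise its median. Animals with fewer than 3 observations (normality
#' untestable) get the mean, flagged.
#'
#' @param observations data.frame with columns `animal_id`, `genotype`, and
#'   the value column.
#' @param metric name of the value column.
#' @param alpha normality gate level.
#' @return data.frame: one row per animal with `value`, `aggregation`
#'   (`"mean"`/`"median"`), `n_obs`, `shapiro_p`, `flagged`.
#' @export
aggregate_per_animal <- function(observations, metric = "value",
                                 alpha = 0.05) {
  stopifnot(all(c("animal_id", "genotype", metric) %in%
                  names(observations)))
  by_animal <- split(observations, observations$animal_id)
  out <- lapply(by_animal, function(d) {
    x <- d[[metric]]
    x <- x[is.finite(x)]
    n <- length(x)
    if (n < 3L) {
      agg <- "mean"; sw <- NA_real_; flag <- TRUE
    } else if (length(unique(x)) == 1L) {
      # Shapiro-Wilk is undefined for constant data; mean == median anyway.
      agg <- "mean"; sw <- NA_real_; flag <- TRUE
    } else {
      sw <- stats::shapiro.test(x)$p.value
      agg <- if (sw >= alpha) "mean" else "median"
      flag <- FALSE
    }
    data.frame(animal_id = d$animal_id[1L],
               genotype = d$genotype[1L],
               metric = metric,
               value = if (agg == "mean") mean(x) else stats::median(x),
               aggregation = agg,
               n_obs = n,
               shapiro_p = sw,
               flagged = flag)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

test_result <- function(test, statistic, df, p_value, groups, trail,
                        extra = NULL) {
  structure(
    c(list(test = test, statistic = statistic, df = df, p_value = p_value,
           groups = groups, decision_trail = trail), extra),
    class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p_value))
  cat("decision trail:\n")
  for (s in x$decision_trail) cat("  - ", s, "\n", sep = "")
  invisible(x)
}

#' Compare groups of per-animal summaries with a normality gate
#'
#' The Shapiro-Wilk test (alpha = 0.05) on the pooled within-group residuals
#' selects the branch: parametric (Welch t-test for 2 groups; one-way ANOVA
#' with Tukey HSD for more) when normality is not rejected, nonparametric
#' (Mann-Whitney for 2 groups; Kruskal-Wallis for more) otherwise. A group
#' with zero variance forces the nonparametric branch. Every choice is
#' logged in the decision trail.
#'
#' @param summaries data.frame with `value` and `genotype` (or `group`)
#'   columns, one row per animal.
#' @param alpha significance and gate level.
#' @param gate `"residuals"` (test pooled residuals, default) or
#'   `"per_group"` (every group must pass).
#' @param var_equal use the pooled-variance Student t-test instead of Welch.
#' @return a `test_result` with statistic, df, p-value, per-group
#'   summaries, the decision trail, and Tukey HSD results when applicable.
#' @export
compare_groups <- function(summaries, alpha = 0.05,
                           gate = c("residuals", "per_group"),
                           var_equal = FALSE) {
  gate <- match.arg(gate)
  grp_col <- if ("genotype" %in% names(summaries)) "genotype" else "group"
  stopifnot(all(c("value", grp_col) %in% names(summaries)))
  g <- factor(summaries[[grp_col]])
  x <- summaries$value
  stopifnot(nlevels(g) >= 2L, all(table(g) >= 2L))
  trail <- character(0)

  grp_stats <- do.call(rbind, lapply(levels(g), function(l) {
    xs <- x[g == l]
    data.frame(group = l, n = length(xs), mean = mean(xs),
               median = stats::median(xs), sd = stats::sd(xs))
  }))

  zero_var <- any(grp_stats$sd == 0)
  sw_p <- tryCatch({
    if (gate == "residuals") {
      res <- x - stats::ave(x, g)
      stats::shapiro.test(res)$p.value
    } else {
      min(vapply(levels(g), function(l) {
        stats::shapiro.test(x[g == l])$p.value
      }, numeric(1)))
    }
  }, error = function(e) NA_real_)
  trail <- c(trail, sprintf(
    "Shapiro-Wilk on %s: p = %s",
    if (gate == "residuals") "pooled residuals" else "each group (min)",
    format(sw_p, digits = 4)))

  parametric <- !is.na(sw_p) && sw_p >= alpha && !zero_var
  if (zero_var) {
    trail <- c(trail,
               "a group has zero variance: falling back to nonparametric")
  } else {
    trail <- c(trail, sprintf(
      "normality %s at alpha = %g: %s branch",
      if (parametric) "not rejected" else "rejected", alpha,
      if (parametric) "parametric" else "nonparametric"))
  }

  if (nlevels(g) == 2L) {
    if (parametric) {
      tt <- stats::t.test(x ~ g, var.equal = var_equal)
      trail <- c(trail, sprintf("2 groups: %s t-test",
                                if (var_equal) "Student" else "Welch"))
      test_result(if (var_equal) "Student t-test" else "Welch t-test",
                  unname(tt$statistic), unname(tt$parameter), tt$p.value,
                  grp_stats, trail)
    } else {
      wt <- stats::wilcox.test(x ~ g, exact = FALSE)
      trail <- c(trail, "2 groups: Mann-Whitney U")
      test_result("Mann-Whitney U", unname(wt$statistic), NA_real_,
                  wt$p.value, grp_stats, trail)
    }
  } else {
    if (parametric) {
      fit <- stats::aov(x ~ g)
      an <- summary(fit)[[1L]]
      tk <- stats::TukeyHSD(fit)
      trail <- c(trail, "> 2 groups: one-way ANOVA with Tukey HSD post hoc")
      test_result("one-way ANOVA", an[["F value"]][1L],
                  an[["Df"]], an[["Pr(>F)"]][1L],
                  grp_stats, trail, extra = list(tukey = tk$g))
    } else {
      kw <- stats::kruskal.test(x ~ g)
      trail <- c(trail, "> 2 groups: Kruskal-Wallis")
      test_result("Kruskal-Wallis", unname(kw$statistic),
                  unname(kw$parameter), kw$p.value, grp_stats, trail)
    }
  }
}

#' Two-way ANOVA: genotype x plaque distance
#'
#' Each animal contributes one near-plaque and one far-from-plaque summary;
#' the model is `value ~ genotype * distance_class` with type-II sums of
#' squares (robust to the slightly unbalanced group sizes). Animals missing
#' either distance class are dropped and logged.
#'
#' @param summaries data.frame with `animal_id`, `genotype`,
#'   `distance_class` (`"near"`/`"far"`) and `value`.
#' @return a `test_result`; `$effects` holds F, df and p for genotype,
#'   distance, and their interaction.
#' @export
two_way_distance_genotype <- function(summaries) {
  stopifnot(all(c("animal_id", "genotype", "distance_class", "value") %in%
                  names(summaries)))
  trail <- character(0)
  tab <- table(summaries$animal_id, summaries$distance_class)
  complete <- rownames(tab)[rowSums(tab > 0) == 2L]
  dropped <- setdiff(rownames(tab), complete)
  if (length(dropped)) {
    trail <- c(trail, sprintf(
      "dropped %d animal(s) missing a distance class: %s",
      length(dropped), paste(dropped, collapse = ", ")))
    summaries <- summaries[summaries$animal_id %in% complete, ]
  }
  summaries$genotype <- factor(summaries$genotype)
  summaries$distance_class <- factor(summaries$distance_class,
                                     levels = c("far", "near"))
  if (stats::var(summaries$value) == 0) {
    # degenerate design: no variance anywhere, every effect is null
    eff <- data.frame(effect = c("genotype", "distance", "interaction"),
                      F = 0, df1 = NA_real_, df2 = NA_real_, p = 1)
    trail <- c(trail, "all values identical: F = 0, p = 1 for every effect")
    return(test_result("two-way ANOVA (genotype x distance)",
                       0, NA_real_, 1, NULL, trail,
                       extra = list(effects = eff)))
  }
  fit <- stats::lm(value ~ genotype * distance_class, data = summaries)
  an <- car::Anova(fit, type = 2)
  df_res <- an["Residuals", "Df"]
  eff <- data.frame(
    effect = c("genotype", "distance", "interaction"),
    F = an[1:3, "F value"],
    df1 = an[1:3, "Df"],
    df2 = df_res,
    p = an[1:3, "Pr(>F)"])
  rownames(eff) <- NULL
  trail <- c(trail,
             "two-way ANOVA, type-II sums of squares, alpha = 0.05")
  test_result("two-way ANOVA (genotype x distance)",
              eff$F[2L], c(eff$df1[2L], df_res), eff$p[2L],
              NULL, trail, extra = list(effects = eff))
}
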