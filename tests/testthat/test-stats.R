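obs_df <- function(values, animal = "a1", genotype = "APP_PS1") {
  data.frame(animal_id = animal, genotype = genotype, value = values)
}

test_that("per-animal aggregation picks mean or median by normality", {
  # small symmetric sample: mean branch, value 2.0
  a <- aggregate_per_animal(obs_df(c(1, 2, 3)))
  expect_equal(a$value, 2.0)
  expect_equal(a$aggregation, "mean")
  # under 3 observations the gate cannot run: mean, flagged
  b <- aggregate_per_animal(obs_df(c(4, 8)))
  expect_equal(b$value, 6)
  expect_true(b$flagged)
  # symmetric data: branch choice does not change the value
  x <- c(-2, -1, 0, 1, 2)
  s <- aggregate_per_animal(obs_df(x))
  expect_equal(s$value, mean(x))
  expect_equal(mean(x), stats::median(x))
})

test_that("a skewed animal reliably takes the median branch", {
  picks <- 0L
  for (s in 1:100) {
    set.seed(s)
    a <- aggregate_per_animal(obs_df(stats::rlnorm(50, 0, 1)))
    if (a$aggregation == "median") picks <- picks + 1L
  }
  expect_gte(picks, 90L)
})

test_that("identical groups give a null test statistic", {
  d <- data.frame(
    animal_id = sprintf("a%d", 1:12),
    genotype = rep(c("APP_PS1", "APP_PS1_rTg21221"), each = 6),
    value = rep(c(1.1, 0.9, 1.0, 1.2, 0.8, 1.05), 2))
  r <- compare_groups(d)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_gt(r$p_value, 0.99)
  expect_true(any(grepl("t-test", r$decision_trail)))
})

test_that("the parametric branch has power against a 2-sigma shift", {
  rej <- 0L
  for (s in 1:500) {
    set.seed(s)
    d <- data.frame(
      animal_id = sprintf("a%d", 1:40),
      genotype = rep(c("g1", "g2"), each = 20),
      value = c(stats::rnorm(20, 0, 1), stats::rnorm(20, 2, 1)))
    if (compare_groups(d)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 500, 0.95)
})

test_that("zero-variance groups fall back to the nonparametric branch", {
  d <- data.frame(
    animal_id = sprintf("a%d", 1:8),
    genotype = rep(c("g1", "g2"), each = 4),
    value = c(rep(1, 4), c(2, 2.2, 1.9, 2.1)))
  r <- compare_groups(d)
  expect_equal(r$test, "Mann-Whitney U")
  expect_true(any(grepl("zero variance", r$decision_trail)))
})

test_that("three groups route to ANOVA + Tukey or Kruskal-Wallis", {
  set.seed(42)
  d <- data.frame(
    animal_id = sprintf("a%d", 1:18),
    genotype = rep(c("APP_PS1", "APP_PS1_rTg21221", "rTg21221"), each = 6),
    value = stats::rnorm(18, rep(c(0, 1.5, 0), each = 6), 0.6))
  r <- compare_groups(d)
  expect_equal(r$test, "one-way ANOVA")
  expect_false(is.null(r$tukey))
  skewed <- d
  set.seed(43)
  skewed$value <- stats::rlnorm(18, 0, 1.5)^2
  r2 <- compare_groups(skewed)
  expect_equal(r2$test, "Kruskal-Wallis")
})

test_that("the decision trail reproduces the branch deterministically", {
  set.seed(11)
  d <- data.frame(animal_id = sprintf("a%d", 1:12),
                  genotype = rep(c("g1", "g2"), each = 6),
                  value = stats::rnorm(12))
  r1 <- compare_groups(d)
  r2 <- compare_groups(d)
  expect_identical(r1$decision_trail, r2$decision_trail)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(length(r1$decision_trail), 0)
})

test_that("a flat two-way design returns zero F", {
  d <- expand.grid(animal_id = sprintf("a%d", 1:8),
                   distance_class = c("near", "far"))
  d$genotype <- rep(rep(c("g1", "g2"), each = 4), 2)
  d$value <- 3.3
  r <- two_way_distance_genotype(d)
  expect_equal(r$effects$F, rep(0, 3))
  expect_equal(r$effects$p, rep(1, 3))
})

test_that("animals missing a distance class are dropped and logged", {
  d <- generate_cohort_summaries(c(g1 = 4L, g2 = 4L), seed = 2L)
  agg_near <- aggregate_per_animal(d[d$distance_class == "near", ],
                                   metric = "density")
  agg_far <- aggregate_per_animal(d[d$distance_class == "far", ],
                                  metric = "density")
  agg_near$distance_class <- "near"; agg_far$distance_class <- "far"
  s <- rbind(agg_near, agg_far)
  s <- s[!(s$animal_id == "a01" & s$distance_class == "near"), ]
  r <- two_way_distance_genotype(s)
  expect_true(any(grepl("dropped 1 animal", r$decision_trail)))
  expect_equal(r$effects$df2[1], 2 * 7 - 4)
})

test_that("a planted distance effect is detected with no genotype effect", {
  d <- generate_cohort_summaries(seed = 7L, loss_fraction = 0.4)
  agg <- do.call(rbind, lapply(c("near", "far"), function(dc) {
    a <- aggregate_per_animal(d[d$distance_class == dc, ],
                              metric = "density")
    a$distance_class <- dc
    a
  }))
  r <- two_way_distance_genotype(agg)
  eff <- r$effects
  expect_lt(eff$p[eff$effect == "distance"], 0.05)
  expect_gt(eff$p[eff$effect == "genotype"], 0.05)
})

test_that("permuting genotype labels gives a uniform genotype p-value", {
  # Fresh balanced data per iteration with genotype labels assigned at
  # random; animal_cv = 0 so near/far cells are independent and the
  # model's assumptions hold exactly. (With a shared per-animal baseline
  # the genotype test is anti-conservative; see the vignette.)
  ps <- numeric(300)
  for (i in seq_along(ps)) {
    d <- generate_cohort_summaries(c(g1 = 6L, g2 = 6L), seed = 2000L + i,
                                   animal_cv = 0)
    agg <- do.call(rbind, lapply(c("near", "far"), function(dc) {
      a <- aggregate_per_animal(d[d$distance_class == dc, ],
                                metric = "density")
      a$distance_class <- dc
      a
    }))
    animals <- unique(agg$animal_id)
    set.seed(90000 + i)
    newg <- sample(rep(c("g1", "g2"), each = 6))
    names(newg) <- animals
    agg$genotype <- newg[agg$animal_id]
    eff <- two_way_distance_genotype(agg)$effects
    ps[i] <- eff$p[eff$effect == "genotype"]
  }
  expect_lt(abs(mean(ps) - 0.5), 0.08)
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.05)
})
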