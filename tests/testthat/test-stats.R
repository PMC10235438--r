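two_groups <- function(x, y) {
  data.frame(value = c(x, y), group = rep(c("a", "b"), c(length(x), length(y))))
}

test_that("normality gate separates normal from bimodal samples", {
  set.seed(51)
  calls <- vapply(1:40, function(i) {
    d <- two_groups(rnorm(50), rnorm(50))
    normality_gate(d, value, group)$decision
  }, character(1))
  expect_gte(mean(calls == "parametric"), 0.9)
  calls2 <- vapply(1:40, function(i) {
    bimodal <- c(rnorm(50, -4), rnorm(50, 4))
    d <- two_groups(bimodal, rnorm(100))
    normality_gate(d, value, group)$decision
  }, character(1))
  expect_true(all(calls2 == "nonparametric"))
  tiny <- two_groups(c(1, 2), rnorm(10))
  expect_identical(normality_gate(tiny, value, group)$decision,
    "indeterminate")
})

test_that("two-group comparison handles its degenerate fixed points", {
  x <- c(1.2, 3.4, 2.2, 4.1, 2.8)
  same <- two_groups(x, x)
  ks <- compare_two(same, value, group, mode = "ks")
  expect_equal(ks$statistic, 0)
  expect_equal(ks$p_value, 1)
  # paired ratios of exactly 1 give t = 0
  d <- data.frame(value = c(x, x), group = rep(c("a", "b"), each = 5),
    id = rep(1:5, 2))
  rt <- compare_two(d, value, group, pair = id, mode = "ratio_paired_t")
  expect_equal(rt$statistic, 0)
  expect_identical(rt$method, "ratio paired t")
  expect_error(compare_two(d[-1, ], value, group, pair = id,
    mode = "ratio_paired_t"), "equal n")
  expect_error(compare_two(two_groups(c(1, 2), c(2, 3)), value, group,
    mode = "auto"), "too small")
})

test_that("t and KS statistics match hand-computed 3-point cases", {
  x <- c(1, 2, 3)
  y <- c(2, 3, 4)
  d <- two_groups(x, y)
  tt <- compare_two(d, value, group, mode = "t")
  sp <- sqrt((var(x) * 2 + var(y) * 2) / 4)
  expect_equal(tt$statistic, (mean(x) - mean(y)) / (sp * sqrt(2 / 3)),
    tolerance = 1e-12)
  expect_equal(tt$df, 4)
  ks <- compare_two(d, value, group, mode = "ks")
  # ecdf difference is maximal (1/3) at 1 and at 4... enumerated by hand: 1/3
  expect_equal(ks$statistic, 1 / 3, tolerance = 1e-12)
})

test_that("auto mode has power against a 2-sigma mean shift", {
  set.seed(52)
  rej <- vapply(1:200, function(i) {
    d <- two_groups(rnorm(50), rnorm(50, 2))
    compare_two(d, value, group, mode = "auto")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.99)
})

test_that("p adjustments match worked examples and stay above raw p", {
  expect_equal(adjust_p(0.03, "BH"), 0.03)
  expect_equal(adjust_p(0.03, "holm_sidak"), 0.03)
  expect_equal(adjust_p(c(0.01, 0.02, 0.03), "BH"), c(0.03, 0.03, 0.03))
  expect_equal(adjust_p(c(0.04, 0.5), "bonferroni"), c(0.08, 1.0))
  set.seed(53)
  for (m in c("BH", "holm_sidak", "holm", "bonferroni")) {
    p <- runif(25)
    expect_true(all(adjust_p(p, m) >= p))
  }
  expect_error(adjust_p(c(0.5, 1.2), "BH"), "\\[0, 1\\]")
})

test_that("own adjustments agree with stats::p.adjust where both exist", {
  set.seed(54)
  for (i in 1:20) {
    p <- runif(sample(2:30, 1))
    expect_equal(adjust_p(p, "BH"), p.adjust(p, "BH"), tolerance = 1e-12)
    expect_equal(adjust_p(p, "holm"), p.adjust(p, "holm"), tolerance = 1e-12)
    expect_equal(adjust_p(p, "bonferroni"), p.adjust(p, "bonferroni"),
      tolerance = 1e-12)
  }
})

test_that("two-way ANOVA: null factor gives F ~ 0, planted effects are found", {
  # each A level receives an identical copy of the data: the A sum of
  # squares is exactly zero while the residual variance is not
  set.seed(57)
  half <- expand.grid(B = c("u", "v"), rep = 1:6)
  half$value <- rnorm(nrow(half)) + (half$B == "u") * 2
  d <- rbind(cbind(half, A = "x"), cbind(half, A = "y"))
  fit <- anova_factorial(d, value, A, B)
  tab <- tidy(fit)
  expect_lt(tab$F[tab$term == "A"], 1e-12)
  expect_gt(tab$p[tab$term == "A"], 0.999)
  set.seed(55)
  hits <- vapply(1:100, function(i) {
    dd <- expand.grid(A = c("x", "y"), B = c("u", "v"), rep = 1:10)
    dd$value <- rnorm(nrow(dd)) + (dd$A == "x") * 1.5 + (dd$B == "u") * 1.5
    tt <- tidy(anova_factorial(dd, value, A, B))
    all(tt$p[tt$term %in% c("A", "B")] < 0.05)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  one <- data.frame(A = "x", B = c("u", "v"), value = 1:2)
  expect_error(anova_factorial(one, value, A, B), "2 levels")
})

test_that("repeated-measures ANOVA applies a fractional GG correction", {
  set.seed(56)
  n_sub <- 12
  k <- 4
  # strong sphericity violation: a random slope across the within levels
  d <- expand.grid(subject = 1:n_sub, time = 1:k)
  d$grp <- ifelse(d$subject <= n_sub / 2, "ctl", "trt")
  slope <- rnorm(n_sub, sd = 3)
  d$value <- slope[d$subject] * d$time + rnorm(nrow(d), sd = 0.5) +
    (d$grp == "trt") * 1
  d$time <- factor(d$time)
  fit <- anova_factorial(d, value, grp, time, subject = subject,
    repeated = TRUE)
  tab <- tidy(fit)
  eps <- tab$epsilon[tab$term == "B"]
  expect_lt(eps, 0.85)
  expect_gt(eps, 1 / (k - 1) - 1e-9)
  expect_false(isTRUE(all.equal(tab$df1_gg[tab$term == "B"],
    round(tab$df1_gg[tab$term == "B"]))))
  # against car's Greenhouse-Geisser machinery on the same data
  wide <- tidyr::pivot_wider(d[, c("subject", "time", "value")],
    names_from = time, values_from = value)
  grp <- d$grp[match(wide$subject, d$subject)]
  mlm <- lm(as.matrix(wide[, -1]) ~ grp)
  ca <- car::Anova(mlm, idata = data.frame(time = factor(1:k)),
    idesign = ~time, type = 3)
  cs <- summary(ca, multivariate = FALSE)
  car_eps <- cs$pval.adjustments["time", "GG eps"]
  expect_equal(eps, unname(car_eps), tolerance = 1e-6)
  # missing cells are refused
  expect_error(anova_factorial(d[-1, ], value, grp, time, subject = subject,
    repeated = TRUE), "one observation")
  # per-timepoint post hoc with BH
  ph <- anova_factorial(d, value, grp, time, subject = subject,
    repeated = TRUE, posthoc = "per_level_bh")$posthoc
  expect_identical(nrow(ph), as.integer(k))
  expect_true(all(ph$p_adj >= ph$p))
})
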