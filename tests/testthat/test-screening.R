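test_that("box-plot discrimination fires the right criterion", {
  r <- boxplot_discrimination(c(10, 11, 12, 13), c(1, 2, 3, 4))
  expect_true(r$pass)
  expect_equal(r$criterion, "IQR-disjoint")

  same <- c(3, 5, 7, 9, 11)
  r <- boxplot_discrimination(same, same)
  expect_false(r$pass)

  # interleaved quartiles with mutually outside medians
  ref <- c(0, 0, 0, 10, 10)       # IQR [0, 10], median 0
  imp <- c(4, 8, 8, 8, 12)        # IQR [8, 8],  median 8... overlaps
  stopifnot(oracle_boxplot(ref, imp) == "none")
  ref2 <- c(-5, 0, 1, 10, 11)     # IQR [0, 10], median 1
  imp2 <- c(4, 5, 14, 15, 16)     # IQR [5, 15], median 14; IQRs overlap
  r2 <- boxplot_discrimination(ref2, imp2)
  expect_true(r2$pass)
  expect_equal(r2$criterion, "median-outside")
  expect_equal(r2$criterion, oracle_boxplot(ref2, imp2))

  expect_true(is.na(boxplot_discrimination(c(1, 2, 3), c(4, 5, 6, 7))$pass))
})

test_that("box-plot rule agrees with an interval-overlap oracle", {
  set.seed(101)
  for (i in 1:1000) {
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1)
    # mix of separations so all three outcomes occur
    ref <- round(rnorm(n1, 0, 2), 1)
    imp <- round(rnorm(n2, sample(c(0, 2, 5), 1), 2), 1)
    got <- boxplot_discrimination(ref, imp)$criterion
    expect_equal(got, oracle_boxplot(ref, imp))
  }
})

test_that("Mann-Whitney confirmation matches exact enumeration", {
  set.seed(7)
  for (sizes in list(c(4, 5), c(6, 6), c(8, 8))) {
    x <- rnorm(sizes[1]); y <- rnorm(sizes[2]) + 0.8
    got <- mann_whitney_confirm(x, y)
    expect_equal(got$U, oracle_U(x, y))
    expect_equal(got$p, oracle_mw_exact_p(x, y), tolerance = 1e-10)
  }

  # identical groups: p ~ 1, not sensitive
  z <- c(2, 2, 2, 2, 2)
  r <- mann_whitney_confirm(z, z)
  expect_equal(r$p, 1)
  expect_false(r$sensitive)

  # fully separated groups of 8 vs 8: exact p well below 0.001
  r <- mann_whitney_confirm(1:8, 101:108)
  expect_lt(r$p, 0.001)
  expect_true(r$sensitive)

  # the sensitivity decision is strict: p < alpha, not <=
  # (3 vs 3 fully separated has exact two-sided p = 0.1)
  x <- c(1, 2, 3); y <- c(10, 11, 12)
  r <- mann_whitney_confirm(x, y, alpha = 0.1)
  expect_equal(r$p, 0.1)
  expect_false(r$sensitive)
  expect_true(mann_whitney_confirm(x, y, alpha = 0.100001)$sensitive)
})

test_that("the normality gate flags the right distributions", {
  set.seed(42)
  r <- normality_gate(rnorm(200))
  expect_true(r$normal)
  r <- normality_gate(rexp(200))
  expect_false(r$normal)
  r <- normality_gate(rep(3, 10))
  expect_false(r$normal)
  expect_error(normality_gate(c(1, 2, 3)), "at least 5")
})

test_that("seasonality screen matches a first-principles Kruskal-Wallis", {
  # identical wet/dry values: trivially stable
  r <- seasonality_screen(list(wet = c(4, 4, 4), dry = c(4, 4, 4)))
  expect_true(r$stable)
  expect_equal(r$H, 0)

  # disjoint seasons at n = 4,4: H matches the hand-rolled statistic and
  # both the chi-square and the exact-enumeration p reject stability
  wet <- c(1, 2, 3, 4); dry <- c(10, 11, 12, 13)
  r <- seasonality_screen(list(wet = wet, dry = dry))
  expect_equal(r$H, oracle_kw_H(c(wet, dry), rep(1:2, each = 4)),
               tolerance = 1e-12)
  expect_false(r$stable)
  expect_lt(oracle_kw_exact_p(wet, dry), 0.05)

  # with two untied groups, H is the squared standardised U statistic
  set.seed(5)
  x <- rnorm(6); y <- rnorm(7) + 1
  r <- seasonality_screen(list(wet = x, dry = y))
  u <- oracle_U(x, y)
  z2 <- (u - 6 * 7 / 2)^2 / (6 * 7 * (6 + 7 + 1) / 12)
  expect_equal(r$H, z2, tolerance = 1e-10)

  expect_error(seasonality_screen(list(wet = c(1, 2), dry = numeric(0))),
               "dry")
})

test_that("redundancy groups form from |rho| >= cutoff, inclusively", {
  set.seed(9)
  n <- 100
  a <- rnorm(n)
  mat <- data.frame(a = a, b = exp(2 * a), c = rnorm(n), d = rnorm(n),
                    check.names = FALSE)
  red <- redundancy_screen(mat)
  g <- setNames(red$group, red$metric)
  expect_equal(g[["a"]], g[["b"]])          # monotone transform: rho = 1
  expect_equal(length(unique(g)), 3)        # c and d are singletons

  # cutoff boundary: an attained rho equal to the cutoff is redundant
  x <- 1:20
  y <- x; y[1:2] <- y[2:1]; y[5:7] <- y[c(6, 7, 5)]
  rho <- suppressWarnings(cor.test(x, y, method = "spearman"))$estimate
  red <- redundancy_screen(data.frame(x = x, y = y, z = rnorm(20)),
                           cutoff = unname(abs(rho)))
  g <- setNames(red$group, red$metric)
  expect_equal(g[["x"]], g[["y"]])

  # anti-correlated metrics are redundant too
  red <- redundancy_screen(data.frame(x = a, y = -a + rnorm(n, 0, 0.01),
                                      z = rnorm(n)))
  g <- setNames(red$group, red$metric)
  expect_equal(g[["x"]], g[["y"]])

  expect_warning(red <- redundancy_screen(
    data.frame(x = rnorm(20), flat = rep(1, 20))), "flat")
  expect_true(is.na(red$group[red$metric == "flat"]))
})

test_that("final selection honours preferences, then smallest p", {
  report <- data.frame(
    metric = c("m1", "m2", "m3", "m4", "m5"),
    mw_p = c(0.001, 0.0005, 0.002, 0.01, 0.001),
    sensitive = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    seasonally_stable = c(TRUE, TRUE, TRUE, TRUE, TRUE),
    redundancy_group = c(1L, 1L, 1L, 2L, NA),
    stringsAsFactors = FALSE)
  # preference names the 2nd member of the group of three
  expect_equal(select_final_metrics(report, preferences = "m2"),
               c("m2", "m4"))
  # no preferences: smallest Mann-Whitney p wins
  expect_equal(select_final_metrics(report), c("m2", "m4"))
  # ties break alphabetically
  tied <- report
  tied$mw_p[1:3] <- 0.001
  expect_equal(select_final_metrics(tied), c("m1", "m4"))
  expect_warning(select_final_metrics(report, preferences = "nope"),
                 "unknown")
})

test_that("screening is invariant to metric column order", {
  sim <- simulate_survey(simulation_config(seed = 12))
  mm <- compute_metric_matrix(sim$abundance, traits = sim$traits)
  rep1 <- screen_metrics(mm, sim$categories)

  perm <- rev(metric_names(mm))
  mm2 <- mm[, c("station", "date", "season", perm)]
  attr(mm2, "directions") <- attr(mm, "directions")[perm]
  class(mm2) <- class(mm)
  rep2 <- screen_metrics(mm2, sim$categories)

  expect_setequal(attr(rep1, "retained"), attr(rep2, "retained"))
  m1 <- as.data.frame(rep1)[order(rep1$metric),
                            c("metric", "sensitive", "seasonally_stable")]
  m2 <- as.data.frame(rep2)[order(rep2$metric),
                            c("metric", "sensitive", "seasonally_stable")]
  expect_equal(m1, m2, ignore_attr = TRUE)
})

test_that("screening on the default survey flags planted metrics", {
  sim <- simulate_survey(simulation_config(seed = 2))
  mm <- compute_metric_matrix(sim$abundance, traits = sim$traits)
  rep <- screen_metrics(mm, sim$categories)
  flagged <- rep$metric[rep$sensitive %in% TRUE]
  planted <- planted_sensitive_metrics()
  expect_gt(mean(planted %in% flagged), 0.9)

  # preferences override the smallest-p rule inside each redundancy group
  prefs <- mindu_metric_names()
  rep2 <- screen_metrics(mm, sim$categories, preferences = prefs)
  cand <- as.data.frame(rep2)
  cand <- cand[cand$sensitive %in% TRUE & cand$seasonally_stable %in% TRUE &
                 !is.na(cand$redundancy_group), ]
  for (g in unique(cand$redundancy_group)) {
    members <- cand$metric[cand$redundancy_group == g]
    hit <- prefs[prefs %in% members]
    if (length(hit))
      expect_true(hit[1] %in% attr(rep2, "retained"))
  }
})
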