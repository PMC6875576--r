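test_that("thresholds derive by the inclusive quartile rule", {
  tt <- derive_thresholds(list(`Hem Abun` = c(7, 9, 12, 16.5, 20)),
                          c(`Hem Abun` = "decrease"))
  expect_equal(unlist(tt[1, c("min", "q25", "q50", "q75", "max")]),
               c(min = 7, q25 = 9, q50 = 12, q75 = 16.5, max = 20))

  # constant reference data collapse all five statistics
  tt <- derive_thresholds(list(m = rep(3.3, 6)), c(m = "increase"))
  expect_true(all(unlist(tt[1, c("min", "q25", "q50", "q75", "max")]) == 3.3))

  # random vectors agree with an independent sort-and-interpolate oracle
  set.seed(20)
  for (i in 1:20) {
    v <- rnorm(sample(4:30, 1))
    tt <- derive_thresholds(list(m = v), c(m = "increase"))
    expect_equal(unname(unlist(tt[1, c("min", "q25", "q50", "q75", "max")])),
                 oracle_quantile(v, c(0, .25, .5, .75, 1)),
                 tolerance = 1e-12)
  }

  expect_error(derive_thresholds(list(short = c(1, 2, 3)),
                                 c(short = "increase")), "short")
  expect_error(derive_thresholds(list(m = 1:5), c(other = "increase")),
               "direction")
})

test_that("banded 5/3/1 scoring reproduces every published band cell", {
  tt <- load_packaged_mindu()
  # (metric, value, expected score): three cells per metric, plus the
  # published worked examples and the band-edge equalities
  cases <- list(
    list("Hem Abun", 9, 5L), list("Hem Abun", 25, 5L),
    list("Hem Abun", 7, 3L), list("Hem Abun", 8, 3L),
    list("Hem Abun", 8.999, 3L), list("Hem Abun", 6.999, 1L),
    list("%Col + Hem", 10.60, 5L), list("%Col + Hem", 33, 5L),
    list("%Col + Hem", 9.68, 3L), list("%Col + Hem", 10.59, 3L),
    list("%Col + Hem", 9.67, 1L),
    list("%Chi + Oli", 60, 5L), list("%Chi + Oli", 67.59, 5L),
    list("%Chi + Oli", 67.60, 3L), list("%Chi + Oli", 73.12, 3L),
    list("%Chi + Oli", 73.13, 1L),
    list("Even Ind", 0.56, 5L), list("Even Ind", 0.77, 5L),
    list("Even Ind", 0.41, 3L), list("Even Ind", 0.5599, 3L),
    list("Even Ind", 0.40, 1L),
    list("Log VeL", 0.065, 5L), list("Log VeL", 0.2, 5L),
    list("Log VeL", 0.060, 3L), list("Log VeL", 0.0649, 3L),
    list("Log VeL", 0.0599, 1L))
  for (cs in cases)
    expect_equal(score_metric_value(cs[[2]], tt, metric = cs[[1]]),
                 cs[[3]], info = paste(cs[[1]], cs[[2]]))
  expect_true(is.na(score_metric_value(NA, tt, metric = "Hem Abun")))
})

test_that("scoring is monotone in the metric value", {
  set.seed(31)
  for (i in 1:20) {
    v <- sort(rnorm(8))
    q <- quantile_inclusive(v, c(0, .25, .5, .75, 1))
    for (dir in c("increase", "decrease")) {
      row <- as_threshold_table(data.frame(
        metric = "m", direction = dir, min = q[1], q25 = q[2],
        q50 = q[3], q75 = q[4], max = q[5]))
      grid <- seq(q[1] - 1, q[5] + 1, length.out = 60)
      sc <- vapply(grid, score_metric_value, integer(1), thresholds = row)
      if (dir == "increase") expect_true(all(diff(sc) <= 0))
      else expect_true(all(diff(sc) >= 0))
    }
  }
})

test_that("index aggregation covers exactly the attainable sums and bands", {
  r <- compute_index(setNames(rep(5L, 5), letters[1:5]))
  expect_equal(r$mindu, 25)
  expect_equal(r$wq_class, "B")
  expect_equal(r$label, "very good")

  r <- compute_index(setNames(rep(1L, 5), letters[1:5]))
  expect_equal(r$mindu, 5)
  expect_equal(r$wq_class, "F")
  expect_equal(r$label, "very poor")

  r <- compute_index(setNames(c(5L, 3L, 5L, 3L, 1L), letters[1:5]))
  expect_equal(r$mindu, 17)
  expect_equal(r$wq_class, "D")
  expect_equal(r$label, "fair")

  # attainable sums of five scores from {1,3,5}: the odd numbers 5..25;
  # each falls in exactly one band
  sums <- unique(rowSums(expand.grid(rep(list(c(1, 3, 5)), 5))))
  expect_setequal(sums, seq(5, 25, by = 2))
  bands <- mindu_class_bands()
  for (s in sums)
    expect_equal(sum(s >= bands$lo & s <= bands$hi), 1)

  # any missing score makes the sample unscorable
  r <- compute_index(setNames(c(5L, NA, 5L, 3L, 1L), letters[1:5]))
  expect_false(r$scorable)
  expect_true(is.na(r$mindu))
  expect_error(compute_index(setNames(c(5L, 4L, 5L, 3L, 1L), letters[1:5])),
               "1, 3 or 5")
})

test_that("the packaged MINDU table is exactly the published one", {
  tt <- load_packaged_mindu()
  expect_equal(tt$metric, c("Hem Abun", "%Col + Hem", "%Chi + Oli",
                            "Even Ind", "Log VeL"))
  expect_equal(tt$direction, c("decrease", "decrease", "increase",
                               "decrease", "decrease"))
  expect_equal(unname(unlist(tt[tt$metric == "Even Ind",
                                c("min", "q25", "q50", "q75", "max")])),
               c(0.41, 0.56, 0.61, 0.66, 0.77))
  expect_equal(unname(unlist(tt[tt$metric == "Log VeL",
                                c("min", "q25", "q50", "q75", "max")])),
               c(0.060, 0.065, 0.092, 0.145, 0.21))
  expect_equal(unname(unlist(tt[tt$metric == "Hem Abun",
                                c("min", "q25", "q50", "q75", "max")])),
               c(7, 9, 12, 16.5, 20))
})

test_that("survey scoring flags unscorable occasions and sums the rest", {
  sim <- simulate_survey(simulation_config(seed = 4, n_months = 3))
  res <- score_survey(sim$abundance, traits = sim$traits)
  expect_s3_class(res, "index_result")
  expect_equal(nrow(res), 11 * 3)
  ok <- res$scorable
  expect_true(all(res$mindu[ok] >= 5 & res$mindu[ok] <= 25))
  score_cols <- grep("^score: ", names(res), value = TRUE)
  expect_equal(length(score_cols), 5)
  expect_equal(res$mindu[ok],
               as.integer(rowSums(res[ok, score_cols])))
  expect_true(all(is.na(res$mindu[!ok])))

  # an occasion with zero individuals is unscorable, not zero-scored
  ab <- as.data.frame(sim$abundance)
  ab$count[ab$station == "LIS1" & ab$date == ab$date[1]] <- 0L
  res2 <- score_survey(as_abundance_table(ab), traits = sim$traits)
  expect_false(res2$scorable[res2$station == "LIS1" &
                               res2$date == ab$date[1]][1])

  expect_error(as_threshold_table(data.frame(
    metric = "m", direction = "increase", min = 5, q25 = 4, q50 = 6,
    q75 = 7, max = 8)), "non-monotone")
})
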