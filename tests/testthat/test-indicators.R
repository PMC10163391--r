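test_that("disparity ratio matches hand-worked cases", {
  expect_equal(disparity_ratio(c(a = 10, b = 10, c = 10)), 1.0)
  # min 10, mean of others (20 + 30) / 2 = 25 -> 2.5
  expect_equal(disparity_ratio(c(a = 10, b = 20, c = 30)), 2.5)
  expect_equal(disparity_ratio(7 * c(a = 10, b = 20, c = 30)), 2.5)
  # favorable outcome: reference is the best (max) group, still >= 1
  expect_equal(disparity_ratio(c(a = 90, b = 60, c = 60), adverse = FALSE),
               1.5)
})

test_that("disparity ratio is >= 1, equals 1 iff equal, and is scale invariant", {
  withr::local_seed(401)
  for (i in 1:300) {
    k <- sample(2:8, 1)
    rates <- runif(k, 0.5, 500)
    adverse <- i %% 2 == 0
    r <- disparity_ratio(rates, adverse = adverse)
    expect_gte(r, 1)
    expect_equal(disparity_ratio(rates * runif(1, 0.01, 50),
                                 adverse = adverse), r)
  }
  expect_equal(disparity_ratio(rep(3.7, 5)), 1)
})

test_that("a zero reference rate makes the ratio undefined", {
  expect_error(disparity_ratio(c(a = 0, b = 20, c = 30)), "undefined")
  expect_error(stratified_rates(c(0, 0, 0)), "positive")
  expect_error(stratified_rates(c(10)), "2 groups")
})

test_that("summary disparity maximizes over stratifications and names the winner", {
  per <- list(sex = c(f = 10, m = 12), race = c(a = 10, b = 20, c = 30))
  out <- summary_disparity(per)
  expect_equal(out$ratio, 2.5)
  expect_identical(out$stratification, "race")
  one <- summary_disparity(list(sex = c(f = 10, m = 12)))
  expect_equal(one$ratio, 1.2)
  eq <- summary_disparity(list(sex = c(f = 5, m = 5), age = c(a = 9, b = 9)))
  expect_equal(eq$ratio, 1.0)
  expect_error(summary_disparity(list(sex = c(f = 0, m = 3))), "sex")
})

test_that("trend arithmetic preserves sign and scale", {
  up <- trend(c("2015" = 100, "2019" = 150), 2015, 2019)
  expect_equal(up$absolute_change, 50)
  expect_equal(up$relative_change, 0.5)
  flat <- trend(c("2015" = 80, "2019" = 80), 2015, 2019)
  expect_equal(flat$absolute_change, 0)
  expect_equal(flat$relative_change, 0)
  down <- trend(c("2012" = 200, "2016" = 150), 2012, 2016)
  expect_equal(down$absolute_change, -50)
  expect_equal(down$relative_change, -0.25)
})

test_that("trend reversal negates the absolute change", {
  withr::local_seed(402)
  for (i in 1:50) {
    s <- setNames(runif(2, 1, 100), c("2012", "2016"))
    fwd <- trend(s, 2012, 2016)$absolute_change
    rev <- trend(setNames(rev(s), c("2012", "2016")), 2012,
                 2016)$absolute_change
    expect_equal(fwd, -rev)
  }
})

test_that("trend errors name missing years; zero start gives NA relative change", {
  expect_error(trend(c("2015" = 1), 2015, 2019), "2019")
  expect_error(trend(c("2015" = 1, "2019" = 2), 2019, 2015), "exceed")
  z <- trend(c("2015" = 0, "2019" = 4), 2015, 2019)
  expect_equal(z$absolute_change, 4)
  expect_true(is.na(z$relative_change))
})

test_that("innovation deficit is the [0,1] complement and an involution", {
  expect_equal(innovation_deficit(0.05), 0.95)
  expect_equal(innovation_deficit(0.09), 0.91)
  expect_equal(innovation_deficit(1.0), 0.0)
  s <- seq(0, 1, by = 0.05)
  expect_equal(innovation_deficit(innovation_deficit(s)), s)
  expect_error(innovation_deficit(1.2), "\\[0, 1\\]")
  expect_error(innovation_deficit(-0.1), "\\[0, 1\\]")
})
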