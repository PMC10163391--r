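test_that("vector and minmax normalization match hand computation", {
  m <- matrix(c(3, 4), ncol = 1)
  expect_equal(unname(topsis_normalize(m, "vector")[, 1]), c(0.6, 0.8))
  one <- matrix(5, ncol = 1)
  expect_equal(unname(topsis_normalize(one, "vector")[, 1]), 1.0)
  const <- matrix(c(2, 2, 2), ncol = 1)
  expect_equal(unname(topsis_normalize(const, "minmax")[, 1]), rep(0.5, 3))
  expect_error(topsis_normalize(matrix(c(0, 0), ncol = 1), "vector"),
               "degenerate")
})

test_that("reference points follow the direction flags componentwise", {
  v <- cbind(a = c(0.2, 0.8), b = c(0.3, 0.6))
  inc <- reference_points(v, c("gap_increasing", "gap_increasing"))
  expect_equal(unname(inc$a_best), c(0.2, 0.3))
  expect_equal(unname(inc$a_worst), c(0.8, 0.6))
  dec <- reference_points(v, c("gap_decreasing", "gap_decreasing"))
  expect_equal(unname(dec$a_best), c(0.8, 0.6))
  expect_equal(unname(dec$a_worst), c(0.2, 0.3))
  mix <- reference_points(v, c("gap_increasing", "gap_decreasing"))
  expect_equal(unname(mix$a_best), c(0.2, 0.6))
  expect_equal(unname(mix$a_worst), c(0.8, 0.3))
})

test_that("gap scores hit the endpoints and the worked 3x2 example", {
  dm <- decision_matrix(matrix(c(0, 1), ncol = 1), "gap_increasing")
  expect_equal(unname(gap_scores(dm, "minmax")$gap), c(0, 1))

  vals <- rbind(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  tr <- gap_scores(decision_matrix(vals, "gap_increasing"))
  expect_equal(unname(tr$gap[c("a", "c")]), c(0, 1))
  expect_equal(unname(tr$gap[["b"]]),
               topsis_oracle(vals, rep("gap_increasing", 2))[2],
               tolerance = 1e-12)
  expect_equal(unname(tr$gap[["b"]]), 0.5, tolerance = 0.02)
  expect_identical(tr$gap,
                   setNames(tr$d_best / (tr$d_best + tr$d_worst),
                            names(tr$gap)))
})

test_that("degenerate and undersized matrices follow the stated conventions", {
  same <- decision_matrix(matrix(c(4, 4, 4), ncol = 1), "gap_increasing")
  expect_equal(unname(gap_scores(same)$gap), rep(0.5, 3))
  expect_error(gap_scores(decision_matrix(matrix(1, 1, 1), "gap_increasing")),
               "at least 2")
  dup <- decision_matrix(rbind(c(1, 2), c(1, 2), c(3, 1)), "gap_increasing")
  g <- gap_scores(dup)$gap
  expect_equal(unname(g[1]), unname(g[2]))
})

test_that("gap scores match the brute-force oracle on random matrices", {
  withr::local_seed(403)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    m <- sample(1:6, 1)
    vals <- random_decision_values(n, m)
    dirs <- random_directions(m)
    w <- runif(m, 0.2, 3)
    norm <- if (i %% 2 == 0) "vector" else "minmax"
    g <- gap_scores(decision_matrix(vals, dirs, w), norm)$gap
    expect_equal(unname(g), topsis_oracle(vals, dirs, w, norm),
                 tolerance = 1e-12)
  }
})

test_that("weight rescaling, column rescaling and permutations leave scores invariant", {
  withr::local_seed(404)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    m <- sample(2:6, 1)
    vals <- random_decision_values(n, m)
    dirs <- random_directions(m)
    w <- runif(m, 0.2, 3)
    g <- gap_scores(decision_matrix(vals, dirs, w))$gap

    g_w <- gap_scores(decision_matrix(vals, dirs, w * runif(1, 0.01, 40)))$gap
    expect_equal(g, g_w, tolerance = 1e-12)

    scaled <- vals
    j <- sample(m, 1)
    scaled[, j] <- scaled[, j] * runif(1, 0.01, 40)
    g_c <- gap_scores(decision_matrix(scaled, dirs, w))$gap
    expect_equal(g, g_c, tolerance = 1e-12)

    p <- sample(n)
    g_p <- gap_scores(decision_matrix(vals[p, , drop = FALSE], dirs, w))$gap
    expect_equal(unname(g_p), unname(g[p]), tolerance = 1e-12)

    q <- sample(m)
    g_q <- gap_scores(decision_matrix(vals[, q, drop = FALSE], dirs[q],
                                      w[q]))$gap
    expect_equal(g, g_q, tolerance = 1e-12)
  }
})

test_that("flipping every direction maps G to 1 - G when reference points are unique", {
  withr::local_seed(405)
  flip <- c(gap_increasing = "gap_decreasing",
            gap_decreasing = "gap_increasing")
  for (i in 1:50) {
    n <- sample(3:8, 1)
    m <- sample(2:5, 1)
    vals <- random_decision_values(n, m)
    dirs <- random_directions(m)
    g <- gap_scores(decision_matrix(vals, dirs))$gap
    g_f <- gap_scores(decision_matrix(vals, unname(flip[dirs])))$gap
    expect_equal(unname(g_f), 1 - unname(g), tolerance = 1e-12)
  }
})

test_that("malformed decision matrices are rejected", {
  expect_error(decision_matrix(matrix(1:4, 2), c("up", "down")), "directions")
  expect_error(decision_matrix(matrix(1:4, 2), "gap_increasing",
                               weights = c(1, -1)), "positive")
  expect_error(decision_matrix(matrix(c(1, NA, 2, 3), 2), "gap_increasing"),
               "finite")
})
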