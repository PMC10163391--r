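test_that("generation is seed-deterministic and always validates", {
  spec <- synthetic_spec(seed = 501)
  t1 <- generate_metric_table(spec)
  t2 <- generate_metric_table(spec)
  expect_identical(t1$observations, t2$observations)
  expect_identical(nrow(validate_table(t1)), 0L)
  expect_identical(nrow(t1$conditions), 13L)
  expect_identical(nrow(t1$definitions), 23L)

  tiny <- generate_metric_table(synthetic_spec(n_conditions = 4, seed = 502))
  expect_identical(nrow(validate_table(tiny)), 0L)
  t3 <- generate_metric_table(synthetic_spec(seed = 503))
  expect_false(identical(t1$observations$value, t3$observations$value))
})

test_that("the roster mirrors the pilot: 16 innovation metrics in 6 categories", {
  roster <- pilot_metric_roster()
  innov <- roster[roster$domain == "innovation", ]
  expect_identical(nrow(innov), 16L)
  expect_identical(length(unique(innov$category)), 6L)
  expect_setequal(unique(roster$domain), c("burden", "cost", "innovation"))
})

test_that("innovation counts are integral and all values nonnegative", {
  tab <- generate_metric_table(synthetic_spec(seed = 504))
  roster <- pilot_metric_roster()
  counts <- roster$metric_id[roster$integer_valued]
  obs <- tab$observations
  cv <- obs$value[obs$metric_id %in% counts]
  expect_true(all(cv == round(cv)))
  expect_true(all(obs$value >= 0))
})

test_that("a planted gap condition separates from the population in every domain", {
  spec <- synthetic_spec(planted_gap = "cond_05", seed = 505)
  tab <- generate_metric_table(spec)
  obs <- tab$observations
  defs <- tab$definitions
  for (d in c("burden", "cost", "innovation")) {
    mets <- defs$metric_id[defs$domain == d & defs$kind == "cross_sectional"]
    sub <- obs[obs$metric_id %in% mets & is.na(obs$stratum), ]
    mu <- tapply(sub$value / stats::ave(sub$value, sub$metric_id),
                 sub$condition_id, mean)  # per-condition mean of scaled values
    planted <- mu[["cond_05"]]
    others <- median(mu[names(mu) != "cond_05"])
    if (d == "innovation") expect_lt(planted, others)
    else expect_gt(planted, others)
  }
})

test_that("generated strata recover the configured between-group ratio", {
  ratios <- c()
  for (s in 1:12) {
    spec <- synthetic_spec(seed = 600 + s, between_group_ratio = 2)
    tab <- generate_metric_table(spec)
    obs <- tab$observations
    sub <- obs[obs$metric_id == "mortality_stratified", ]
    for (cid in unique(sub$condition_id)) {
      rows <- sub[sub$condition_id == cid, ]
      strat <- sub("^([^:]*):.*$", "\\1", rows$stratum)
      for (st in unique(strat)) {
        r <- rows$value[strat == st]
        ratios <- c(ratios, disparity_ratio(r))
      }
    }
  }
  expect_gt(length(ratios), 400)
  expect_equal(mean(ratios), 2, tolerance = 0.1)
})

test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(n_conditions = 3), "at least 4")
  expect_error(synthetic_spec(planted_gap = "cond_99"), "not among")
  expect_error(synthetic_spec(planted_gap = "cond_01",
                              planted_paradox = "cond_01"), "distinct")
  expect_error(synthetic_spec(between_group_ratio = 0.5), ">= 1")
})

test_that("rank recovery is high for a strong planted effect (small replicate check)", {
  spec <- synthetic_spec(planted_gap = "cond_02", seed = 506)
  out <- planted_rank_recovery(spec, n_replicates = 20)
  expect_gte(out$recovery, 0.95)
  expect_identical(length(out$ranks), 20L)
  expect_error(planted_rank_recovery(synthetic_spec(seed = 1), 20),
               "planted_gap")
  expect_error(planted_rank_recovery(spec, 5), "20 replicates")
})

test_that("a planted paradox condition is annotated, not flagged, as an opportunity", {
  spec <- synthetic_spec(planted_paradox = "cond_04", seed = 507)
  res <- gap_pipeline(generate_metric_table(spec))
  row <- res$scores[res$scores$condition_id == "cond_04", ]
  expect_identical(row$cost_tier, "high")
  expect_identical(row$innovation_tier, "high")
  expect_false(row$opportunity_flag)
  expect_match(row$reason, "paradox")
})
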