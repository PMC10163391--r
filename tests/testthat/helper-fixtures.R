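# In-code fixtures: tiny metric tables with known structure.

# two conditions x three burden metrics at one year, no strata
toy_table <- function() {
  obs <- tibble::tibble(
    condition_id = rep(c("a", "b"), each = 3),
    metric_id = rep(c("mortality", "yld", "prevalence"), 2),
    year = 2019L,
    stratum = NA_character_,
    value = c(100, 300, 5000, 200, 600, 10000)
  )
  defs <- metric_definitions(c("mortality", "yld", "prevalence"),
                             rep("burden", 3), units = "per 100 000")
  cons <- tibble::tibble(condition_id = c("a", "b"),
                         name = c("Alpha", "Beta"), icd10_codes = "")
  metric_table(obs, cons, defs)
}

# n conditions with one metric per domain at the pilot reference years,
# values supplied per domain so domain scores are fully controlled
three_domain_table <- function(burden, cost, innovation) {
  n <- length(burden)
  ids <- sprintf("c%02d", seq_len(n))
  obs <- tibble::tibble(
    condition_id = rep(ids, 3),
    metric_id = rep(c("mortality", "total_spending", "patents_granted"),
                    each = n),
    year = rep(c(2019L, 2016L, 2019L), each = n),
    stratum = NA_character_,
    value = c(burden, cost, innovation)
  )
  defs <- metric_definitions(
    c("mortality", "total_spending", "patents_granted"),
    c("burden", "cost", "innovation"),
    units = c("per 100 000", "billion USD", "count")
  )
  metric_table(obs, conditions = NULL, definitions = defs)
}

expect_no_findings <- function(table) {
  testthat::expect_identical(nrow(validate_table(table)), 0L)
}
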