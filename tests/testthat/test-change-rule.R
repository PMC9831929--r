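test_that("interval change is followup minus reference per sector", {
  expect_equal(interval_change(flat_map(280), flat_map(280)), flat_map(0))
  expect_equal(interval_change(flat_map(280), flat_map(276)), flat_map(-4))
  ref <- flat_map(280)
  ref["C"] <- 250
  fol <- flat_map(280)
  fol["C"] <- 255
  d <- interval_change(ref, fol)
  expect_equal(unname(d["C"]), 5)
  expect_equal(unname(d["OT"]), 0)

  od <- make_scan(280, eye = "OD")
  os <- make_scan(280, eye = "OS_eye")
  expect_error(interval_change(od, os), "laterality")
})

test_that("the decision rule fires on >= tau in >= k contiguous sectors, both directions independently", {
  r <- apply_rule(flat_map(-5))
  expect_true(r$fires_thinning)
  expect_false(r$fires_thickening)
  expect_equal(r$max_neg_component, 9L)

  d <- flat_map(0)
  d[c("OS", "ON", "OI")] <- 4.0
  r <- apply_rule(d)
  expect_true(r$fires_thickening)
  expect_equal(r$max_pos_component, 3L)

  d <- flat_map(0)
  d[c("C", "II", "OT")] <- 6
  expect_false(apply_rule(d)$fires_thickening)

  # mixed directions can both fire
  d <- flat_map(0)
  d[c("IS", "IN", "II")] <- 5
  d[c("OS", "OT", "OI", "ON")] <- -5
  r <- apply_rule(d)
  expect_true(r$fires_thickening && r$fires_thinning)
})

test_that("swapping reference and followup negates diffs and mirrors the rule", {
  set.seed(11)
  for (i in 1:25) {
    a <- flat_map(280) + rnorm(9, 0, 3)
    b <- flat_map(280) + rnorm(9, 0, 3)
    d_ab <- interval_change(a, b)
    d_ba <- interval_change(b, a)
    expect_equal(d_ab, -d_ba)
    r_ab <- apply_rule(d_ab)
    r_ba <- apply_rule(d_ba)
    expect_equal(r_ab$fires_thickening, r_ba$fires_thinning)
    expect_equal(r_ab$max_pos_component, r_ba$max_neg_component)
  }
})

test_that("adding a constant to both scans leaves the rule result unchanged", {
  set.seed(12)
  a <- flat_map(280) + rnorm(9, 0, 3)
  b <- flat_map(280) + rnorm(9, 0, 3)
  r1 <- apply_rule(interval_change(a, b))
  r2 <- apply_rule(interval_change(a + 37, b + 37))
  expect_equal(r1[1:4], r2[1:4])
})

test_that("rule extremes behave as designed", {
  set.seed(13)
  noisy <- interval_change(flat_map(280), flat_map(280) + rnorm(9, 0, 1))
  # k = 1 with a vanishing threshold fires on any noisy pair
  r <- apply_rule(noisy, rule_params(tau = 1e-6, k = 1))
  expect_true(r$fires_thickening || r$fires_thinning)
  # k = 9 requires fully confluent directional change
  d <- flat_map(-6)
  d["C"] <- 0
  expect_false(apply_rule(d, rule_params(k = 9))$fires_thinning)
  expect_true(apply_rule(flat_map(-6), rule_params(k = 9))$fires_thinning)
})

test_that("rule parameters are validated", {
  expect_error(rule_params(tau = 0), "tau")
  expect_error(rule_params(k = 10))
  expect_error(rule_params(k = 1.5))
})

test_that("null calibration is zero for identical pairs and echoes the pair count", {
  pairs <- replicate(20, list(flat_map(280), flat_map(280)), simplify = FALSE)
  cal <- calibrate_null(pairs)
  expect_equal(cal$n_pairs, 20)
  expect_true(all(cal$freq$freq == 0))
  expect_equal(cal$p_at_rule, 0)

  many <- replicate(1530, list(flat_map(280), flat_map(280)), simplify = FALSE)
  expect_equal(calibrate_null(many)$n_pairs, 1530)

  expect_error(calibrate_null(list()), "empty")
})

test_that("calibration frequencies are monotone and match the enumeration oracle", {
  set.seed(99)
  n_pairs <- 10000
  sd_diff <- 1.02
  diffs <- matrix(rnorm(n_pairs * 9, 0, sd_diff), ncol = 9,
                  dimnames = list(NULL, sector_names))
  pairs <- lapply(seq_len(n_pairs), function(i) {
    list(flat_map(280), flat_map(280) + diffs[i, ])
  })
  cal <- calibrate_null(pairs)
  grid <- cal$freq

  # monotone non-increasing in tau at fixed k and in k at fixed tau
  by_k <- split(grid[order(grid$tau), ], grid$k[order(grid$tau)])
  expect_true(all(sapply(by_k, function(g) all(diff(g$freq) <= 0))))
  by_tau <- split(grid[order(grid$k), ], grid$tau[order(grid$k)])
  expect_true(all(sapply(by_tau, function(g) all(diff(g$freq) <= 0))))

  # independent straight-line oracle on the same pairs, within 3 MC SE
  for (cell in list(c(4, 3), c(2, 2), c(3, 5))) {
    tau <- cell[1]
    k <- cell[2]
    p_oracle <- oracle_null_frequency(diffs, tau, k)
    p_pkg <- grid$freq[grid$tau == tau & grid$k == k]
    se <- sqrt(max(p_oracle * (1 - p_oracle), 1e-9) / n_pairs)
    expect_lt(abs(p_pkg - p_oracle), 3 * se + 1e-12)
  }
})

test_that("replicate pairs are extracted per eye-encounter", {
  fx <- generate_cohort(small_config())
  pairs <- replicate_pairs(fx$scans)
  # two replicates per eye per encounter: one pair per eye-encounter
  expect_equal(length(pairs), nrow(fx$scans) / 2)
  expect_true(all(vapply(pairs, nrow, 1L) == 2))
})
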