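test_that("instrument registry matches the published scoring rules", {
  specs <- instrument_specs()
  # prorating minimum and treat-as-missing threshold are complementary for
  # single-scale instruments
  single <- c("pas", "stsc_a", "gad7", "calis_pv", "pos", "psoc_se", "camp",
              "rules", "motivation")
  for (nm in single) {
    sp <- specs[[nm]]
    expect_identical(sp$min_completed + sp$missing_ge, sp$n_items + 1L,
                     info = nm)
    expect_true(all(sp$reverse_items %in% seq_len(sp$n_items)), info = nm)
  }
  expect_equal(specs$pas$screen_cutoff, 34)
  expect_equal(specs$stsc_a$screen_cutoff, 30)
  expect_equal(specs$gad7$screen_cutoff, 8)
  expect_error(instrument_spec("nonexistent"), "unknown instrument")
})

test_that("totals, prorating and treat-as-missing follow the instrument rules", {
  # complete PAS
  full <- score_measure(rep(1, 28), "pas")
  expect_equal(full$total, 28)
  expect_false(full$prorated)
  # prorated PAS: 21 completed items of 2 -> mean 2 * 28 items
  pro <- score_measure(c(rep(2, 21), rep(NA, 7)), "pas")
  expect_equal(pro$total, 56)
  expect_true(pro$prorated)
  # 8 missing items -> measure missing
  expect_true(is.na(score_measure(c(rep(2, 20), rep(NA, 8)), "pas")$total))
  # reverse scoring: STSC-A items 3-6
  expect_equal(score_measure(rep(6, 7), "stsc_a")$total, 22)
  # CQ-P scores the first item only
  expect_equal(score_measure(c(5, 1, 1), "cq_p")$total, 5)
  expect_true(is.na(score_measure(c(NA, 7, 7), "cq_p")$total))
  # SDQ-E per-subscale prorating: two hyperactivity items missing leaves
  # three completed, so that subscale is prorated (all responses 1 score 1
  # after reversal since item range is 0-2): 1 * 5 + 5 = 10
  x <- rep(1, 10)
  x[c(1, 4)] <- NA
  sdq <- score_measure(x, "sdq_e")
  expect_true(sdq$prorated)
  expect_equal(sdq$total, 10)
  # three missing on one subscale -> measure missing
  x2 <- rep(1, 10)
  x2[c(1, 4, 6)] <- NA
  expect_true(is.na(score_measure(x2, "sdq_e")$total))
  # screening stage allows no missing items
  expect_true(is.na(score_measure(c(rep(1, 27), NA), "pas",
                                  screening = TRUE)$total))
  # out-of-range item
  expect_error(score_measure(c(rep(1, 27), 9), "pas"), "outside")
})

test_that("screening status flags and eligibility follow the cut-offs", {
  s <- screen_status(34, 7, 0)
  expect_true(s$child_anxiety && s$eligible)
  expect_false(s$behavioural_inhibition || s$parent_anxiety)
  s2 <- screen_status(33, 29, 7)
  expect_false(s2$eligible)
  s3 <- screen_status(0, 7, 8)
  expect_true(s3$parent_anxiety && s3$eligible)
  expect_false(s3$child_anxiety)
  expect_error(screen_status(NA, 7, 0), "complete")
})

test_that("household tie-breaking selects highest PAS, then highest STSC-A, then lowest id", {
  c1 <- data.frame(child_id = c(1, 2), pas = c(40, 35), stsc_a = c(10, 12))
  expect_equal(select_household_child(c1)$child_id, 1)
  c2 <- data.frame(child_id = c(1, 2), pas = c(36, 36), stsc_a = c(31, 28))
  expect_equal(select_household_child(c2)$child_id, 1)
  c3 <- data.frame(child_id = 7, pas = 36, stsc_a = 31)
  expect_equal(select_household_child(c3)$child_id, 7)
  c4 <- data.frame(child_id = c(9, 3), pas = c(36, 36), stsc_a = c(30, 30))
  expect_equal(select_household_child(c4)$child_id, 3)
  expect_error(select_household_child(data.frame()), "empty")
})

test_that("motivation categories and prorating follow the questionnaire rules", {
  expect_equal(as.character(categorise_motivation(18)), "ambivalent")
  expect_equal(as.character(categorise_motivation(19)), "partially motivated")
  expect_equal(as.character(categorise_motivation(23)), "partially motivated")
  expect_equal(as.character(categorise_motivation(24)), "motivated")
  expect_equal(as.character(categorise_motivation(30)), "motivated")
  expect_error(categorise_motivation(31), "out of range")
  # item 4 reverse scored; 5 completed items prorate by mean * 6
  m <- score_measure(c(3, 3, 3, NA, 3, 3), "motivation")
  expect_true(m$prorated)
  expect_equal(m$total, 3 * 6)
})

test_that("prorating leaves constant-response totals unchanged and within range", {
  set.seed(42)
  for (nm in c("pas", "stsc_a", "gad7", "calis_pv", "pos", "psoc_se",
               "camp", "rules", "motivation")) {
    sp <- instrument_spec(nm)
    for (val in c(sp$item_min, sp$item_max)) {
      # constant on the *scored* scale: reverse-scored items are entered
      # pre-inverted so every item contributes the same scored value
      x <- rep(val, sp$n_items)
      x[sp$reverse_items] <- sp$item_min + sp$item_max - val
      base <- score_measure(x, sp)$total
      for (k in seq_len(sp$missing_ge - 1)) {
        xm <- x
        xm[sample(sp$n_items, k)] <- NA
        tot <- score_measure(xm, sp)$total
        expect_equal(tot, base, info = sprintf("%s k=%d val=%g", nm, k, val))
        expect_gte(tot, sp$total_range[1])
        expect_lte(tot, sp$total_range[2])
      }
    }
  }
})

test_that("totals agree with a brute-force oracle on random complete responses", {
  set.seed(7)
  for (nm in names(instrument_specs())) {
    sp <- instrument_spec(nm)
    resp <- matrix(sample(sp$item_min:sp$item_max, 1000 * sp$n_items,
                          replace = TRUE), 1000, sp$n_items)
    got <- score_measure(resp, sp)$total
    want <- apply(resp, 1, oracle_total, spec = sp)
    expect_equal(got, want, info = nm)
  }
})
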