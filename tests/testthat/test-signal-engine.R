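test_that("the worked fourfold table reproduces all four statistics", {
  # frozen values computed independently by direct evaluation of the formulas
  s <- signal_stats(10, 90, 100, 9900)
  expect_equal(s$ror, 11)
  expect_equal(s$ror_low, 5.559515, tolerance = 1e-6)
  expect_equal(s$ror_high, 21.764489, tolerance = 1e-6)
  expect_equal(s$prr, 10)
  expect_equal(s$prr_low, 5.382154, tolerance = 1e-6)
  expect_equal(s$prr_high, 18.579922, tolerance = 1e-6)
  expect_equal(s$chi2, 74.447174, tolerance = 1e-6)
  expect_equal(s$ic, 3.19877986, tolerance = 1e-8)
  expect_equal(s$ic025, 2.19421598, tolerance = 1e-8)
  expect_equal(s$ebgm, 9.18181818, tolerance = 1e-8)
  expect_equal(s$ebgm05, 4.64058684, tolerance = 1e-8)
  expect_equal(s$ebgm95, 18.16705257, tolerance = 1e-8)
  expect_false(s$zero_cell_corrected)
})

test_that("a null table gives unit ratios, zero IC and zero chi-squared", {
  s <- signal_stats(5, 5, 5, 5)
  expect_equal(s$ror, 1)
  expect_equal(s$prr, 1)
  expect_equal(s$ebgm, 1)
  expect_equal(s$ic, 0)
  expect_equal(s$chi2, 0)
  # CI symmetric about 1 on the log scale
  expect_equal(log(s$ror_low), -log(s$ror_high))
})

test_that("2^IC equals EBGM to 1e-12 relative error on random tables", {
  set.seed(101)
  tb <- random_tables(2000)
  s <- signal_stats(tb$a, tb$b, tb$c, tb$d)
  expect_true(all(abs(2^s$ic - s$ebgm) <= 1e-12 * s$ebgm))
})

test_that("sign(ad - bc) dictates the ordering ROR vs PRR vs EBGM vs 1", {
  set.seed(202)
  tb <- random_tables(2000)
  s <- signal_stats(tb$a, tb$b, tb$c, tb$d)
  det <- tb$a * tb$d - tb$b * tb$c
  pos <- det > 0; neg <- det < 0; nul <- det == 0
  expect_true(all(s$ror[pos] > s$prr[pos] & s$prr[pos] > s$ebgm[pos] &
                    s$ebgm[pos] > 1))
  expect_true(all(s$ror[neg] < s$prr[neg] & s$prr[neg] < s$ebgm[neg] &
                    s$ebgm[neg] < 1))
  if (any(nul)) {
    expect_equal(s$ror[nul], rep(1, sum(nul)))
    expect_equal(s$ic[nul], rep(0, sum(nul)))
    expect_equal(s$chi2[nul], rep(0, sum(nul)))
  }
})

test_that("chi-squared matches the textbook Pearson statistic and is swap-invariant", {
  set.seed(303)
  tb <- random_tables(100)
  s <- signal_stats(tb$a, tb$b, tb$c, tb$d)
  for (i in seq_len(nrow(tb))) {
    m <- matrix(c(tb$a[i], tb$b[i], tb$c[i], tb$d[i]), 2, byrow = TRUE)
    ref <- suppressWarnings(stats::chisq.test(m, correct = FALSE)$statistic)
    expect_equal(s$chi2[i], unname(ref), tolerance = 1e-10)
  }
  swapped <- signal_stats(tb$d, tb$c, tb$b, tb$a)  # both rows and columns
  expect_equal(swapped$chi2, s$chi2, tolerance = 1e-12)
})

test_that("interval bounds bracket the point estimates", {
  set.seed(404)
  tb <- random_tables(500)
  s <- signal_stats(tb$a, tb$b, tb$c, tb$d)
  expect_true(all(s$ror_low <= s$ror & s$ror <= s$ror_high))
  expect_true(all(s$prr_low <= s$prr & s$prr <= s$prr_high))
  expect_true(all(s$ebgm05 <= s$ebgm & s$ebgm <= s$ebgm95))
  expect_true(all(s$ic025 <= s$ic))
  expect_true(all(s$chi2 >= 0))
})

test_that("false-positive rate of ror_low > 1 on simulated null tables stays within bound", {
  set.seed(505)
  n_sim <- 1000
  flags <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    # independence model: margins >= 50, cells drawn multinomially
    p_drug <- stats::runif(1, 0.05, 0.4)
    p_ev <- stats::runif(1, 0.05, 0.4)
    N <- sample(500:3000, 1)
    cells <- stats::rmultinom(1, N, c(p_drug * p_ev, p_drug * (1 - p_ev),
                                      (1 - p_drug) * p_ev,
                                      (1 - p_drug) * (1 - p_ev)))
    s <- signal_stats(cells[1], cells[2], cells[3], cells[4])
    flags[i] <- !is.na(s$ror_low) && s$ror_low > 1
  }
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / n_sim)
  expect_lte(mean(flags), bound)
})

test_that("zero-cell policy adds 0.5 to all cells only when b, c or d is zero", {
  s <- signal_stats(3, 0, 5, 100)
  expect_true(s$zero_cell_corrected)
  expect_equal(s$ror, (3.5 * 100.5) / (0.5 * 5.5))
  expect_true(is.finite(s$ror_high))
  s0 <- signal_stats(0, 10, 5, 100)
  expect_equal(s0$undefined_reason, "zero_a")
  expect_true(is.na(s0$ror))
  su <- signal_stats(3, 0, 5, 100, correct_zero = FALSE)
  expect_equal(su$undefined_reason, "zero_cell_uncorrected")
  expect_true(is.na(su$ror))
})

test_that("positivity rules apply the printed thresholds with strict/non-strict cuts", {
  # a = 2 with enormous ROR stays negative (frequency screen)
  s2 <- signal_stats(2, 1, 1, 10000)
  d2 <- classify_signal(s2)
  expect_false(d2$ror_positive)
  expect_false(d2$prr_positive)
  # the worked table passes everything
  s <- signal_stats(10, 90, 100, 9900)
  d <- classify_signal(s)
  expect_true(d$ror_positive && d$prr_positive && d$bcpnn_positive &&
                d$ebgm_positive && d$all_four)
  # IC025 exactly 0 is not positive (strict inequality)
  s$ic025 <- 0
  expect_false(classify_signal(s)$bcpnn_positive)
})

test_that("the all-four conjunction matches an independent rule-by-rule recheck", {
  set.seed(606)
  tb <- random_tables(100, max_cell = 50)
  s <- signal_stats(tb$a, tb$b, tb$c, tb$d)
  d <- classify_signal(s)
  manual <- (s$n_reported >= 3 & s$ror_low > 1) &
    (s$prr >= 2 & s$chi2 >= 4 & s$n_reported >= 3) &
    (s$n_reported >= 3 & s$ic025 > 0) &
    (s$n_reported >= 3 & s$ebgm05 > 2)
  expect_equal(d$all_four, manual)
  expect_equal(d$all_four, d$ror_positive & d$prr_positive &
                 d$bcpnn_positive & d$ebgm_positive)
})

test_that("single-table wrappers agree with the vectorized engine", {
  t <- two_by_two(10, 90, 100, 9900, event_name = "sopor",
                  drug_name = "lorazepam")
  expect_equal(compute_ror(t)$ror, 11)
  expect_equal(compute_prr_chi2(t)$prr, 10)
  expect_equal(compute_ebgm(t)$ebgm, 2^compute_ic(t)$ic, tolerance = 1e-14)
  expect_error(two_by_two(0, 0, 0, 0), "empty")
  expect_error(two_by_two(-1, 1, 1, 1), "non-negative")
})
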