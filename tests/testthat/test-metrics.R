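test_that("OM bias is the mean log10 deviation, antisymmetric in chosen/correct", {
  tr <- rbind(make_trials("s1", "addition", 10, 10),
              make_trials("s1", "subtraction", 10, 10))
  b <- om_bias(tr)
  expect_equal(b$bias_addition, 0)
  expect_equal(b$bias_subtraction, 0)
  expect_equal(b$om_difference, 0)

  tr2 <- rbind(make_trials("s1", "addition", 10, 20),
               make_trials("s1", "subtraction", 10, 20))
  expect_equal(om_bias(tr2)$bias_addition, log10(2), tolerance = 1e-12)

  # constructed two-operation fixture: om difference is the plain difference
  tr3 <- rbind(make_trials("s1", "addition", 100, 100 * 10^0.05),
               make_trials("s1", "subtraction", 100, 100 * 10^-0.02))
  b3 <- om_bias(tr3)
  expect_equal(b3$om_difference, 0.07, tolerance = 1e-10)

  # swapping chosen and correct negates the bias
  tr4 <- rbind(make_trials("s2", "addition", c(8, 10), c(10, 12)),
               make_trials("s2", "subtraction", c(8, 10), c(7, 8)))
  tr4_swapped <- tr4
  tr4_swapped$chosen <- tr4$correct
  tr4_swapped$correct <- tr4$chosen
  expect_equal(om_bias(tr4_swapped)$bias_addition, -om_bias(tr4)$bias_addition)
  expect_equal(om_bias(tr4_swapped)$om_difference, -om_bias(tr4)$om_difference)

  # a subject missing one operation is excluded with a warning
  tr5 <- rbind(tr4, make_trials("s3", "addition", 8, 8))
  expect_warning(b5 <- om_bias(tr5), "excluded")
  expect_identical(b5$subject, "s2")
})

test_that("CV profiles are zero for constant data and scale-invariant", {
  tr <- make_trials("s1", "addition", 10, 10)
  tr <- rbind(tr, tr, tr)
  cv <- cv_profile(tr)
  expect_equal(cv$cv, 0)

  set.seed(1)
  tr2 <- make_trials("s1", "addition", rep(10, 50), round(rnorm(50, 10, 2)))
  tr2k <- tr2
  tr2k$chosen <- tr2$chosen * 3
  tr2k$correct <- tr2$correct * 3
  expect_equal(cv_profile(tr2)$cv, cv_profile(tr2k)$cv, tolerance = 1e-12)
})

test_that("rank distributions sum to one and locate concentrated choices", {
  alts <- "4;5;6;7;8;10"
  # all mass at rank 2
  tr <- make_trials("s1", "addition", rep(8, 10), 5, alternatives = alts)
  rd <- rank_distribution(tr)
  expect_equal(rd$p[rd$rank == 2], 1)
  expect_equal(rd$asin_sqrt_p[rd$rank == 2], pi / 2, tolerance = 1e-12)
  expect_equal(sum(rd$p), 1)

  # uniform random choices approach 1/6 per rank
  set.seed(2)
  a <- c(4, 5, 6, 7, 8, 10)
  tr2 <- make_trials("s1", "addition", rep(8, 60000),
                     sample(a, 60000, replace = TRUE), alternatives = alts)
  rd2 <- rank_distribution(tr2)
  expect_true(all(abs(rd2$p - 1 / 6) < 0.01))

  # proportions sum to one in every cell of a mixed table
  tr3 <- rbind(make_trials("s1", "addition", rep(8, 20), sample(a, 20, TRUE),
                           range_flag = "low", alternatives = alts),
               make_trials("s1", "subtraction", rep(8, 20), sample(a, 20, TRUE),
                           range_flag = "high", alternatives = alts))
  rd3 <- rank_distribution(tr3)
  sums <- aggregate(p ~ task + range_flag, data = rd3, FUN = sum)
  expect_true(all(abs(sums$p - 1) < 1e-9))

  # rows with an off-list choice are rejected and counted
  tr4 <- make_trials("s1", "addition", c(8, 8), c(8, 9), alternatives = alts)
  expect_warning(rd4 <- rank_distribution(tr4), "rejected")
  expect_identical(attr(rd4, "n_rejected"), 1L)
  expect_equal(sum(rd4$n), 1)
})

test_that("memory regression recovers exact and least-squares lines", {
  tr <- make_trials("s1", "memorization", c(6, 19, 25), c(6, 19, 25))
  mr <- memory_regression(tr)
  expect_equal(mr$per_subject$intercept, 0, tolerance = 1e-12)
  expect_equal(mr$per_subject$slope, 1, tolerance = 1e-12)

  tr2 <- make_trials("s1", "memorization", c(6, 19, 25), c(8, 21, 27))
  mr2 <- memory_regression(tr2)
  expect_equal(mr2$per_subject$intercept, 2, tolerance = 1e-12)
  expect_equal(mr2$per_subject$slope, 1, tolerance = 1e-12)

  # three-point least squares fixture (closed form: b = 1794/1698)
  tr3 <- make_trials("s1", "memorization", c(6, 19, 25), c(7, 21, 27))
  mr3 <- memory_regression(tr3)
  expect_equal(mr3$per_subject$slope, 1794 / 1698, tolerance = 1e-10)
  expect_equal(mr3$per_subject$intercept, 3690 / 5094, tolerance = 1e-10)

  # a subject with a single shown numerosity is skipped
  tr4 <- rbind(tr3, make_trials("s2", "memorization", c(6, 6), c(7, 5)))
  expect_identical(memory_regression(tr4)$per_subject$subject, "s1")
})

test_that("cueing effects are z-based, shift-invariant and ratio-preserving", {
  # constant RTs: undefined SD handled as all-zero scores
  cue <- data.frame(subject_id = "s1", validity = rep(c("valid", "neutral", "invalid"), 4),
                    rt_ms = 500, response_correct = TRUE)
  eff <- cueing_effects(cue)
  expect_equal(eff$orienting, 0)
  expect_equal(eff$reorienting, 0)

  # adding a constant per subject changes nothing
  set.seed(3)
  cue2 <- data.frame(subject_id = "s1",
                     validity = rep(c("valid", "neutral", "invalid"), each = 20),
                     rt_ms = rnorm(60, rep(c(450, 480, 540), each = 20), 30),
                     response_correct = TRUE)
  cue2b <- cue2
  cue2b$rt_ms <- cue2$rt_ms + 250
  expect_equal(cueing_effects(cue2)$orienting, cueing_effects(cue2b)$orienting,
               tolerance = 1e-12)
  expect_equal(cueing_effects(cue2)$reorienting, cueing_effects(cue2b)$reorienting,
               tolerance = 1e-12)

  # generative recovery of the 1:2 orienting:reorienting ratio
  sub <- data.frame(subject_id = "s9", group = "child", rt_base = log(500),
                    rt_noise = 0.02, rt_orient = 30, rt_reorient = 60,
                    error_rate = 0)
  big <- simulate_cueing(sub, make_cueing_schedule(1700), seed = 8)
  eff3 <- cueing_effects(big)
  expect_gt(eff3$orienting, 0)
  expect_lt(eff3$reorienting, 0)
  expect_lt(abs(abs(eff3$reorienting) / eff3$orienting - 2), 0.2)

  # subjects with an empty condition are dropped with a warning
  cue4 <- rbind(cue2, data.frame(subject_id = "s2", validity = "valid",
                                 rt_ms = 400, response_correct = TRUE))
  expect_warning(eff4 <- cueing_effects(cue4), "excluded")
  expect_identical(eff4$subject, "s1")
})

test_that("correlation wraps the Pearson product-moment with its t-based p", {
  x <- c(1, 2, 3)
  expect_equal(correlate(x, x)$r, 1, tolerance = 1e-12)
  expect_equal(correlate(x, 2 * x)$r, 1, tolerance = 1e-12)
  ct <- correlate(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(ct$r, 0.8, tolerance = 1e-12)
  expect_equal(ct$p, cor.test(c(1, 2, 3, 4), c(1, 3, 2, 4))$p.value)
  # zero variance is reported as undefined, not an error
  flat <- correlate(c(1, 1, 1), c(1, 2, 3))
  expect_false(flat$defined)
  expect_true(is.na(flat$r))
  expect_error(correlate(c(1, 2), c(1, 2)), "3 complete pairs")
})

test_that("a default cohort yields regular adult OM and inverse child OM", {
  co <- simulate_cohort(n_per_group = 32, seed = 12)
  b <- om_bias(co$trials)
  gm <- tapply(b$om_difference, b$group, mean)
  expect_gt(gm[["adult"]], 0)
  expect_lt(gm[["child"]], 0)
})
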