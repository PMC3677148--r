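# hand-built draws object for the algebraic checks
fake_draws <- function(mu1, mu2, n = 5) {
  mk <- function(m) matrix(rep(m, each = n), n, 2,
                           dimnames = list(NULL, c("add", "sub")))
  sig <- matrix(rep(c(1, 0, 1), each = n), n, 3,
                dimnames = list(NULL, c("s11", "s12", "s22")))
  structure(list(mu = list(adult = mk(mu1), child = mk(mu2)),
                 sigma = list(adult = sig, child = sig),
                 groups = c("adult", "child"), n_iter = n, burn_in = 0,
                 thin = 1, seed = 0),
            class = "om_draws")
}

test_that("standardization pools groups and measurements and is invertible", {
  set.seed(5)
  sc <- data.frame(group = rep(c("a", "b"), each = 10),
                   bias_addition = rnorm(20, 0.05, 0.1),
                   bias_subtraction = rnorm(20, -0.02, 0.2))
  md <- standardize_scores(sc)
  all_vals <- do.call(rbind, md$y)
  expect_equal(mean(all_vals), 0, tolerance = 1e-12)
  expect_equal(sd(as.vector(all_vals)), 1, tolerance = 1e-12)
  # within-group contrasts keep their sign
  d_raw <- mean(sc$bias_addition[1:10]) - mean(sc$bias_subtraction[1:10])
  d_std <- mean(md$y[["a"]][, 1]) - mean(md$y[["a"]][, 2])
  expect_identical(sign(d_raw), sign(d_std))
  # recorded transform inverts to the input
  back <- all_vals * md$scale + md$center
  expect_equal(unname(back), unname(as.matrix(sc[, 2:3])), tolerance = 1e-12)
  expect_error(standardize_scores(data.frame(group = c("a", "a", "b", "b"),
                                             bias_addition = 1,
                                             bias_subtraction = 1)),
               "zero")
})

test_that("prior-only chains reproduce the configured priors", {
  pr <- gibbs_sample(list(g1 = matrix(numeric(0), 0, 2)),
                     n_iter = 22000, burn_in = 2000, seed = 31)
  # nearly flat normal prior on the means: SD sqrt(1e5) = 316.2
  expect_lt(abs(sd(pr$mu[[1]][, 1]) - sqrt(1e5)), 8)
  expect_lt(abs(sd(pr$mu[[1]][, 2]) - sqrt(1e5)), 8)
  expect_lt(abs(mean(pr$mu[[1]][, 1] > 0) - 0.5), 0.02)
  # inverse-Wishart(I, 2) marginals against an independent direct sampler
  set.seed(99)
  direct <- replicate(20000, {
    w <- stats::rWishart(1, df = 2, Sigma = diag(2))[, , 1]
    solve(w)[1, 1]
  })
  expect_lt(abs(median(pr$sigma[[1]][, "s11"]) - median(direct)), 0.3)
  expect_true(all(pr$sigma[[1]][, "s11"] > 0))
  # positive-definiteness of every retained draw
  dets <- pr$sigma[[1]][, "s11"] * pr$sigma[[1]][, "s22"] - pr$sigma[[1]][, "s12"]^2
  expect_true(all(dets > 0))
})

test_that("with a frozen covariance the mean draws match the conjugate posterior", {
  set.seed(17)
  sigma0 <- matrix(c(1, 0.3, 0.3, 0.8), 2)
  n <- 25
  y <- matrix(rnorm(2 * n), n, 2) %*% chol(sigma0)
  y <- sweep(y, 2, c(0.3, -0.2), "+")
  dr <- gibbs_sample(list(g = y), n_iter = 42000, burn_in = 2000, seed = 17,
                     fix_sigma = list(g = sigma0))
  N <- nrow(dr$mu[[1]])
  prec <- n * solve(sigma0) + diag(2) / 1e5
  V <- solve(prec)
  m <- V %*% (n * solve(sigma0) %*% colMeans(y))
  for (j in 1:2) {
    se <- sqrt(V[j, j] / N)
    expect_lt(abs(mean(dr$mu[[1]][, j]) - m[j]), 3 * se)
  }
  emp_cov <- cov(dr$mu[[1]])
  for (j in 1:2) for (k in 1:2) {
    se_cov <- sqrt((V[j, j] * V[k, k] + V[j, k]^2) / N)
    expect_lt(abs(emp_cov[j, k] - V[j, k]), 3 * se_cov)
  }
  # frozen sigma is returned untouched
  expect_true(all(dr$sigma[[1]][, "s11"] == sigma0[1, 1]))
})

test_that("a single-group fit at n = 200 recovers known means", {
  set.seed(23)
  y <- matrix(rnorm(400), 200, 2) + matrix(rep(c(0.5, -0.5), each = 200), 200, 2)
  dr <- gibbs_sample(list(g = y), n_iter = 22000, burn_in = 2000, seed = 23)
  expect_lt(abs(mean(dr$mu[[1]][, 1]) - 0.5), 0.1)
  expect_lt(abs(mean(dr$mu[[1]][, 2]) + 0.5), 0.1)
})

test_that("derived effects are exact iteration-wise functions of the means", {
  d <- derived_effects(fake_draws(c(1, 0.3), c(-0.1, 0.2)))
  expect_equal(unique(d$effects[, "effect_group1"]), 0.7)
  expect_equal(unique(d$effects[, "effect_group2"]), -0.3)
  expect_equal(unique(d$effects[, "interaction"]), 1.0)
  # identical means give all-zero effects
  d0 <- derived_effects(fake_draws(c(0.4, 0.4), c(0.4, 0.4)))
  expect_true(all(d0$effects == 0))
  # interaction identity holds draw-wise on a real chain
  set.seed(1)
  y <- list(a = matrix(rnorm(20), 10, 2), b = matrix(rnorm(20), 10, 2))
  dr <- derived_effects(gibbs_sample(y, n_iter = 2000, burn_in = 500, seed = 2))
  expect_equal(dr$effects[, "interaction"],
               dr$effects[, "effect_group1"] - dr$effects[, "effect_group2"],
               tolerance = 1e-14)
})

test_that("HDIs are the shortest intervals at the requested mass", {
  set.seed(41)
  z <- rnorm(1e6)
  h <- hdi(z, 0.95)
  expect_lt(abs(h[["lower"]] - qnorm(0.025)), 0.02)
  expect_lt(abs(h[["upper"]] - qnorm(0.975)), 0.02)
  # decreasing density: interval starts at the minimum
  e <- rexp(1e6)
  he <- hdi(e, 0.95)
  expect_lt(he[["lower"]], 0.001)
  expect_lt(abs(he[["upper"]] + log(0.05)), 0.03)
  expect_identical(unname(hdi(rep(3.5, 200), 0.9)), c(3.5, 3.5))
  expect_error(hdi(z, 1.2), "between 0 and 1")
})

test_that("sign probabilities are draw fractions above zero", {
  expect_identical(sign_probability(c(0.1, 2, 5)), 1)
  expect_identical(sign_probability(c(-1, -2)), 0)
  set.seed(43)
  expect_lt(abs(sign_probability(rnorm(1e6)) - 0.5), 0.002)
  expect_lt(abs(sign_probability(rnorm(1e6, 1, 1)) - pnorm(1)), 0.002)
  expect_error(sign_probability(numeric(0)), "empty")
})

test_that("posterior summaries have the joint-analysis layout", {
  d <- derived_effects(fake_draws(c(1, 0.3), c(-0.1, 0.2)))
  sm <- summarize_posterior(d, 0.95)
  expect_identical(nrow(sm), 13L)  # 4 means + 6 (co)variances + 3 effects
  expect_identical(sum(grepl("^mu_", sm$quantity)), 4L)
  expect_identical(sum(grepl("^var_|^cov_", sm$quantity)), 6L)
  # constant draw series: mean equals the constant, zero-width HDI
  row <- sm[sm$quantity == "effect_adult", ]
  expect_equal(row$mean, 0.7)
  expect_equal(row$hdi_lower, row$hdi_upper)
  expect_equal(row$p_positive, 1)
})

test_that("summaries are stable against a tenfold longer chain", {
  set.seed(47)
  sc <- simulate_bias_scores(c(0.226, -0.513), c(-0.034, 0.321), seed = 47)
  short <- om_bayes(x = sc[, c("group", "bias_addition", "bias_subtraction")],
                    standardize = FALSE, n_iter = 60000, burn_in = 10000, seed = 3)
  long <- om_bayes(x = sc[, c("group", "bias_addition", "bias_subtraction")],
                   standardize = FALSE, n_iter = 510000, burn_in = 10000, seed = 4)
  expect_lt(max(abs(summary(short)$mean - summary(long)$mean)), 0.01)
  expect_lt(max(abs(summary(short)$p_positive - summary(long)$p_positive)), 0.01)
})

test_that("95% HDIs cover true parameters at roughly nominal rate", {
  mu_a <- c(0.4, -0.4)
  mu_c <- c(-0.1, 0.3)
  truths <- c(mu_a, mu_c, 1, 0, 1, 1, 0, 1)  # means then vectorized covariances
  hits <- 0
  total <- 0
  for (s in 1:20) {
    sc <- simulate_bias_scores(mu_a, mu_c, n_per_group = 32, seed = 100 + s)
    fit <- om_bayes(x = sc[, c("group", "bias_addition", "bias_subtraction")],
                    standardize = FALSE, n_iter = 22000, burn_in = 2000, seed = s)
    sm <- summary(fit)
    par_rows <- sm[!grepl("^effect_|^interaction$", sm$quantity), ]
    expect_identical(nrow(par_rows), 10L)
    inside <- truths >= par_rows$hdi_lower & truths <= par_rows$hdi_upper
    hits <- hits + sum(inside)
    total <- total + length(inside)
  }
  expect_gt(hits / total, 0.9)
})

test_that("the sampler demands a seed and a sane burn-in", {
  y <- list(a = matrix(rnorm(20), 10, 2), b = matrix(rnorm(20), 10, 2))
  expect_error(gibbs_sample(y, n_iter = 100, burn_in = 10), "seed")
  expect_error(gibbs_sample(y, n_iter = 100, burn_in = 200, seed = 1), "burn_in")
  # same seed, same chain
  d1 <- gibbs_sample(y, n_iter = 1000, burn_in = 100, seed = 8)
  d2 <- gibbs_sample(y, n_iter = 1000, burn_in = 100, seed = 8)
  expect_identical(d1$mu, d2$mu)
  expect_identical(d1$sigma, d2$sigma)
})
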