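#' Priors for the heteroscedastic repeated-measures model
#'
#' Each mean component has an independent, nearly flat normal prior
#' `N(0, mean_prior_variance)`. Each group covariance matrix has an
#' inverse-Wishart prior with density proportional to
#' `|Sigma|^-(df + p + 1)/2 * exp(-tr(scale %*% solve(Sigma)) / 2)`
#' (p = 2), which is proper for `df > 1`; the defaults (identity scale,
#' 2 degrees of freedom) are as weak as propriety permits.
#'
#' @param mean_prior_variance Prior variance of each mean component.
#' @param wishart_scale 2x2 positive-definite scale matrix.
#' @param wishart_df Degrees of freedom (> 1).
#' @return List of class `om_priors`.
#' @export
om_priors <- function(mean_prior_variance = 1e5, wishart_scale = diag(2),
                      wishart_df = 2) {
  stopifnot(mean_prior_variance > 0, wishart_df > 1,
            is.matrix(wishart_scale), all(dim(wishart_scale) == 2))
  if (any(eigen(wishart_scale, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    stop("'wishart_scale' must be positive-definite")
  }
  structure(list(mean_prior_variance = mean_prior_variance,
                 wishart_scale = wishart_scale, wishart_df = wishart_df),
            class = "om_priors")
}

#' Pool-standardize bias scores for the joint model
#'
#' Subtracts the grand mean and divides by the grand standard deviation,
#' both computed over all `2 * (n_adult + n_child)` score values pooled
#' across groups and measurements. The affine transform is recorded so
#' results can be mapped back to the raw scale.
#'
#' @param scores Data frame with columns `group` (two levels) and the two
#'   measurement columns named in `measurements`.
#' @param measurements Names of the two score columns, addition first.
#' @return Object of class `om_model_data`: list with `y` (named list of
#'   n_k x 2 matrices, one per group), `groups`, `measurements`, `center`
#'   and `scale`.
#' @export
standardize_scores <- function(scores,
                               measurements = c("bias_addition", "bias_subtraction")) {
  stopifnot(all(c("group", measurements) %in% names(scores)))
  vals <- as.matrix(scores[, measurements])
  if (any(!is.finite(vals))) stop("scores must be finite")
  center <- mean(vals)
  scale <- stats::sd(as.vector(vals))
  if (scale == 0) stop("grand standard deviation is zero; cannot standardize")
  groups <- unique(as.character(scores$group))
  if (length(groups) != 2) stop("exactly two groups are required")
  y <- lapply(groups, function(g) {
    m <- (vals[scores$group == g, , drop = FALSE] - center) / scale
    if (nrow(m) < 2) stop("need at least 2 subjects per group")
    dimnames(m) <- list(NULL, measurements)
    m
  })
  names(y) <- groups
  structure(list(y = y, groups = groups, measurements = measurements,
                 center = center, scale = scale),
            class = "om_model_data")
}

#' Gibbs sampler for the two-group bivariate-normal model
#'
#' Alternates the conjugate full-conditional draws per group: the mean
#' vector given the covariance is bivariate normal with precision
#' `n_k * solve(Sigma_k) + I / mean_prior_variance`; the covariance given
#' the mean is inverse-Wishart with scale `wishart_scale + S_k` (`S_k` the
#' centered scatter matrix) and `wishart_df + n_k` degrees of freedom.
#' Groups are conditionally independent so each runs its own chain.
#'
#' @param data An `om_model_data` object (see [standardize_scores()]), or
#'   a named list of n x 2 matrices (possibly with zero rows for
#'   prior-only runs).
#' @param priors An [om_priors()] object.
#' @param n_iter Total iterations.
#' @param burn_in Iterations discarded from the front (`< n_iter`).
#' @param seed Integer seed (mandatory: chains must be reproducible).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param fix_sigma Optional named list of 2x2 matrices; when given for a
#'   group, its covariance is frozen at that value and only the mean is
#'   sampled (used for analytic cross-checks).
#' @return Object of class `om_draws`: per-group matrices of retained
#'   `mu` draws (columns: the two measurements) and `sigma` draws
#'   (columns `s11`, `s12`, `s22`), plus sampler metadata.
#' @export
gibbs_sample <- function(data, priors = om_priors(), n_iter = 600000,
                         burn_in = 100000, seed, thin = 1, fix_sigma = NULL) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(burn_in < n_iter, thin >= 1)
  y <- if (inherits(data, "om_model_data")) data$y else data
  stopifnot(is.list(y), length(names(y)) == length(y))
  set.seed(seed)
  jitters <- 0L
  draws <- lapply(names(y), function(g) {
    yk <- as.matrix(y[[g]])
    if (ncol(yk) != 2 && nrow(yk) > 0) stop("each group needs an n x 2 matrix")
    if (nrow(yk) == 0) yk <- matrix(numeric(0), 0, 2)
    fs <- !is.null(fix_sigma) && !is.null(fix_sigma[[g]])
    res <- .gibbs_chain_cpp(yk, as.integer(n_iter), as.integer(burn_in),
                            as.integer(thin), priors$mean_prior_variance,
                            priors$wishart_scale, priors$wishart_df,
                            fs, if (fs) fix_sigma[[g]] else diag(2))
    jitters <<- jitters + res$jitters
    colnames(res$mu) <- if (inherits(data, "om_model_data")) data$measurements
                        else c("m1", "m2")
    colnames(res$sigma) <- c("s11", "s12", "s22")
    res[c("mu", "sigma")]
  })
  names(draws) <- names(y)
  if (jitters > 0) {
    warning("numerically singular scale matrices were jittered ", jitters, " time(s)")
  }
  structure(list(mu = lapply(draws, `[[`, "mu"),
                 sigma = lapply(draws, `[[`, "sigma"),
                 groups = names(y), n_iter = n_iter, burn_in = burn_in,
                 thin = thin, seed = seed, priors = priors),
            class = "om_draws")
}

#' Append derived operation effects to posterior draws
#'
#' Per retained iteration: the adult operation effect (addition minus
#' subtraction mean in group 1), the child effect (same in group 2), and
#' their difference (the group-by-operation interaction).
#'
#' @param draws An `om_draws` object with exactly two groups.
#' @return The same object with an `effects` matrix (columns
#'   `effect_group1`, `effect_group2`, `interaction`, where group 1 is the
#'   first group in the data).
#' @export
derived_effects <- function(draws) {
  stopifnot(inherits(draws, "om_draws"), length(draws$mu) == 2)
  e1 <- draws$mu[[1]][, 1] - draws$mu[[1]][, 2]
  e2 <- draws$mu[[2]][, 1] - draws$mu[[2]][, 2]
  draws$effects <- cbind(effect_group1 = e1, effect_group2 = e2,
                         interaction = e1 - e2)
  draws
}

#' Highest-density interval of a draw series
#'
#' The shortest contiguous interval containing `ceiling(mass * N)` of the
#' sorted draws (exact for unimodal posteriors).
#'
#' @param x Numeric vector of draws (>= 100 for a meaningful interval).
#' @param mass Probability mass in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
hdi <- function(x, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1 || mass <= 0 || mass >= 1) {
    stop("'mass' must lie strictly between 0 and 1")
  }
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1])
}

#' Posterior probability that a quantity is positive
#'
#' @param x Numeric vector of draws.
#' @return Fraction of draws strictly greater than zero.
#' @export
sign_probability <- function(x) {
  if (length(x) == 0) stop("empty draw series")
  mean(x > 0)
}

# split-chain potential scale reduction factor
rhat_split <- function(x) {
  if (!all(is.finite(x))) return(NA_real_)
  n <- floor(length(x) / 2)
  h <- list(x[seq_len(n)], x[n + seq_len(n)])
  W <- mean(vapply(h, var, 0))
  B <- n * var(vapply(h, mean, 0))
  if (W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# effective sample size via the initial positive autocorrelation sequence
ess <- function(x) {
  n <- length(x)
  if (!all(is.finite(x))) return(NA_real_)
  if (var(x) == 0) return(n)
  m <- x - mean(x)
  nf <- stats::nextn(2 * n)
  f <- stats::fft(c(m, rep(0, nf - n)))
  ac <- Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)]
  ac <- ac / ac[1]
  s <- 0
  for (k in seq(2, min(n - 1, 1000), by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}

#' Convergence diagnostics for retained draws
#'
#' Split-chain potential scale reduction (each retained series split in
#' half) and effective sample size from the initial positive
#' autocorrelation sequence.
#'
#' @param draws An `om_draws` object.
#' @return Data frame with one row per monitored quantity: `quantity`,
#'   `rhat`, `ess`.
#' @export
mcmc_diagnostics <- function(draws) {
  series <- draw_series_list(draws)
  data.frame(quantity = names(series),
             rhat = vapply(series, rhat_split, 0),
             ess = vapply(series, ess, 0),
             row.names = NULL)
}

# flatten an om_draws object into a named list of series, Table-2 order:
# 4 means, 6 (co)variances, then derived effects when present
draw_series_list <- function(draws) {
  g <- draws$groups
  ms <- colnames(draws$mu[[1]])
  out <- list()
  for (k in 1:2) for (j in 1:2) {
    out[[paste0("mu_", ms[j], "_", g[k])]] <- draws$mu[[k]][, j]
  }
  for (k in 1:2) {
    out[[paste0("var_", g[k], "_", ms[1])]] <- draws$sigma[[k]][, "s11"]
    out[[paste0("cov_", g[k])]] <- draws$sigma[[k]][, "s12"]
    out[[paste0("var_", g[k], "_", ms[2])]] <- draws$sigma[[k]][, "s22"]
  }
  if (!is.null(draws$effects)) {
    out[[paste0("effect_", g[1])]] <- draws$effects[, 1]
    out[[paste0("effect_", g[2])]] <- draws$effects[, 2]
    out$interaction <- draws$effects[, 3]
  }
  out
}

#' Summarize posterior draws in the joint-analysis layout
#'
#' One row per model parameter (four means, six covariance entries) and,
#' when present, per derived effect: posterior mean, highest-density
#' interval at the requested mass, and the posterior probability of being
#' positive.
#'
#' @param draws An `om_draws` object (run [derived_effects()] first to
#'   include the operation effects).
#' @param mass HDI probability mass.
#' @return Data frame of class `om_posterior_summary` with columns
#'   `quantity`, `mean`, `hdi_lower`, `hdi_upper`, `p_positive`.
#' @export
summarize_posterior <- function(draws, mass = 0.95) {
  series <- draw_series_list(draws)
  out <- data.frame(
    quantity = names(series),
    mean = vapply(series, mean, 0),
    hdi_lower = vapply(series, function(s) hdi(s, mass)[["lower"]], 0),
    hdi_upper = vapply(series, function(s) hdi(s, mass)[["upper"]], 0),
    p_positive = vapply(series, sign_probability, 0),
    row.names = NULL
  )
  attr(out, "mass") <- mass
  class(out) <- c("om_posterior_summary", "data.frame")
  out
}

#' @export
print.om_posterior_summary <- function(x, digits = 3, ...) {
  mass <- attr(x, "mass")
  cat("Posterior summary (", format(100 * mass), "% HDI)\n\n", sep = "")
  y <- x
  class(y) <- "data.frame"
  y$mean <- round(y$mean, digits)
  y$hdi_lower <- round(y$hdi_lower, digits)
  y$hdi_upper <- round(y$hdi_upper, digits)
  y$p_positive <- round(y$p_positive, digits)
  print(y, row.names = FALSE, ...)
  invisible(x)
}
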