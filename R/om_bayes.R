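#' Fit the heteroscedastic Bayesian repeated-measures model
#'
#' The workhorse of the package: per-subject (addition, subtraction) bias
#' score pairs from two groups are modelled as bivariate normal with a
#' group-specific mean vector and a group-specific covariance matrix, so
#' neither homoscedasticity across groups nor across operations is
#' assumed. Nearly flat normal priors on the means and weak
#' inverse-Wishart priors on the covariances (see [om_priors()]) let the
#' data dominate. Posterior draws come from the conjugate Gibbs sampler
#' ([gibbs_sample()]); the operation effect per group and the
#' group-by-operation interaction are derived per iteration, and every
#' quantity is summarized by its posterior mean, highest-density interval
#' and sign probability.
#'
#' @param formula Model formula `cbind(add_col, sub_col) ~ group_col`,
#'   naming the two score columns (addition first) and the grouping
#'   factor. Alternatively pass `x` directly.
#' @param data Data frame holding the columns named in `formula`.
#' @param x Instead of a formula: a data frame with columns `group` plus
#'   the two measurement columns, or a ready-made `om_model_data` object.
#' @param standardize Pool-standardize the scores before fitting (the
#'   recorded transform is kept in the fit). Ignored for `om_model_data`
#'   input, which is assumed ready.
#' @param n_iter,burn_in,thin Chain settings; defaults run 600,000
#'   iterations and discard the first 100,000.
#' @param seed Integer seed (mandatory).
#' @param hdi_mass Probability mass of the reported HDIs.
#' @param priors An [om_priors()] object.
#' @return Object of class `om_bayes` with components `draws`
#'   (`om_draws`, including derived effects), `summary`
#'   (`om_posterior_summary`), `diagnostics`, `data` (the standardized
#'   `om_model_data`), `hdi_mass`, `seed` and `call`. Supports `print`,
#'   `summary`, `coef`, `confint`, `vcov`, `plot` and `simulate`.
#' @examples
#' scores <- simulate_bias_scores(c(0.23, -0.51), c(-0.03, 0.32), seed = 7)
#' fit <- om_bayes(cbind(bias_addition, bias_subtraction) ~ group,
#'                 data = scores, n_iter = 20000, burn_in = 5000, seed = 7)
#' summary(fit)
#' @export
om_bayes <- function(formula = NULL, data = NULL, x = NULL,
                     standardize = TRUE, n_iter = 600000, burn_in = 100000,
                     thin = 1, seed, hdi_mass = 0.95, priors = om_priors()) {
  if (missing(seed)) stop("'seed' is mandatory")
  cl <- match.call()
  if (!is.null(formula)) {
    mf <- stats::model.frame(formula, data)
    scores <- as.data.frame(mf[[1]])
    measurements <- colnames(mf[[1]])
    if (is.null(measurements) || length(measurements) != 2) {
      stop("the formula left-hand side must be cbind() of two score columns")
    }
    names(scores) <- measurements
    scores$group <- as.character(mf[[2]])
    x <- scores
  }
  if (is.null(x)) stop("supply either a formula with data, or 'x'")
  md <- if (inherits(x, "om_model_data")) {
    x
  } else if (standardize) {
    standardize_scores(x, measurements = setdiff(names(x), c("group", "subject")))
  } else {
    measurements <- setdiff(names(x), c("group", "subject"))
    groups <- unique(as.character(x$group))
    y <- lapply(groups, function(g) {
      m <- as.matrix(x[x$group == g, measurements])
      dimnames(m) <- list(NULL, measurements)
      m
    })
    names(y) <- groups
    structure(list(y = y, groups = groups, measurements = measurements,
                   center = 0, scale = 1), class = "om_model_data")
  }
  draws <- gibbs_sample(md, priors = priors, n_iter = n_iter,
                        burn_in = burn_in, seed = seed, thin = thin)
  draws <- derived_effects(draws)
  diag_ <- mcmc_diagnostics(draws)
  if (any(diag_$rhat > 1.01, na.rm = TRUE)) {
    warning("split-chain R-hat above 1.01 for: ",
            paste(diag_$quantity[diag_$rhat > 1.01], collapse = ", "))
  }
  if (any(diag_$ess < 400, na.rm = TRUE)) {
    warning("effective sample size below 400 for: ",
            paste(diag_$quantity[diag_$ess < 400], collapse = ", "))
  }
  structure(list(call = cl, data = md, draws = draws,
                 summary = summarize_posterior(draws, hdi_mass),
                 diagnostics = diag_, hdi_mass = hdi_mass, seed = seed,
                 priors = priors),
            class = "om_bayes")
}

#' @export
print.om_bayes <- function(x, ...) {
  n <- vapply(x$data$y, nrow, 0L)
  cat("Heteroscedastic Bayesian repeated-measures model\n")
  cat("Groups:", paste(sprintf("%s (n = %d)", names(n), n), collapse = ", "), "\n")
  cat("Measurements:", paste(x$data$measurements, collapse = ", "), "\n")
  kept <- nrow(x$draws$mu[[1]])
  cat(sprintf("Chain: %d iterations, %d burn-in, thin %d (%d retained), seed %d\n",
              x$draws$n_iter, x$draws$burn_in, x$draws$thin, kept, x$seed))
  eff <- x$summary[grepl("^effect_|^interaction$", x$summary$quantity), ]
  cat("\nOperation effects (standardized scale):\n")
  print(data.frame(quantity = eff$quantity, mean = round(eff$mean, 3),
                   p_positive = round(eff$p_positive, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
summary.om_bayes <- function(object, ...) object$summary

#' @export
coef.om_bayes <- function(object, ...) {
  m <- t(vapply(object$draws$mu, colMeans, numeric(2)))
  dimnames(m) <- list(object$data$groups, object$data$measurements)
  m
}

#' Posterior-mean covariance matrices per group
#'
#' @param object An `om_bayes` fit.
#' @param ... Unused.
#' @return Named list of 2x2 posterior-mean covariance matrices.
#' @export
vcov.om_bayes <- function(object, ...) {
  lapply(setNames(object$draws$sigma, object$data$groups), function(s) {
    m <- colMeans(s)
    matrix(c(m["s11"], m["s12"], m["s12"], m["s22"]), 2, 2,
           dimnames = list(object$data$measurements, object$data$measurements))
  })
}

#' Highest-density intervals of fitted quantities
#'
#' @param object An `om_bayes` fit.
#' @param parm Quantity names (rows of `summary(object)`); all by default.
#' @param level HDI mass.
#' @param ... Unused.
#' @return Matrix with `lower` and `upper` columns.
#' @export
confint.om_bayes <- function(object, parm, level = 0.95, ...) {
  series <- draw_series_list(object$draws)
  if (missing(parm)) parm <- names(series)
  out <- t(vapply(series[parm], hdi, numeric(2), mass = level))
  colnames(out) <- c("lower", "upper")
  out
}

#' Trace and density plots for an om_bayes fit
#'
#' @param x An `om_bayes` fit.
#' @param quantities Which monitored quantities to show (default: the
#'   three derived effects).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.om_bayes <- function(x, quantities = NULL, ...) {
  series <- draw_series_list(x$draws)
  if (is.null(quantities)) {
    quantities <- grep("^effect_|^interaction$", names(series), value = TRUE)
  }
  op <- graphics::par(mfrow = c(length(quantities), 2),
                      mar = c(3, 3, 2, 1), mgp = c(1.8, 0.6, 0))
  on.exit(graphics::par(op))
  for (q in quantities) {
    s <- series[[q]]
    graphics::plot(s, type = "l", col = "grey40", xlab = "iteration",
                   ylab = q, main = paste("trace:", q), ...)
    d <- stats::density(s)
    graphics::plot(d, main = paste("density:", q), xlab = q)
    h <- hdi(s, x$hdi_mass)
    graphics::abline(v = h, lty = 2)
  }
  invisible(x)
}

#' Posterior-predictive simulation of new subjects
#'
#' For each requested replicate, one retained posterior draw of
#' `(mu_k, Sigma_k)` is selected and `n_per_group` new subject score
#' pairs are drawn per group from the bivariate-normal data model.
#'
#' @param object An `om_bayes` fit.
#' @param nsim Number of replicate datasets.
#' @param seed Optional seed.
#' @param n_per_group Subjects per group per replicate (defaults to the
#'   fitted group sizes).
#' @param ... Unused.
#' @return List of `nsim` data frames shaped like the model input
#'   (columns `group` plus the two measurements, standardized scale).
#' @export
simulate.om_bayes <- function(object, nsim = 1, seed = NULL,
                              n_per_group = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n_kept <- nrow(object$draws$mu[[1]])
  sizes <- vapply(object$data$y, nrow, 0L)
  if (!is.null(n_per_group)) sizes[] <- n_per_group
  lapply(seq_len(nsim), function(r) {
    it <- sample.int(n_kept, 1)
    do.call(rbind, lapply(seq_along(object$data$groups), function(k) {
      g <- object$data$groups[k]
      mu <- object$draws$mu[[k]][it, ]
      s <- object$draws$sigma[[k]][it, ]
      sigma <- matrix(c(s["s11"], s["s12"], s["s12"], s["s22"]), 2, 2)
      z <- matrix(rnorm(2 * sizes[k]), sizes[k], 2) %*% chol(sigma)
      out <- data.frame(group = g, z[, 1] + mu[1], z[, 2] + mu[2],
                        stringsAsFactors = FALSE)
      names(out)[2:3] <- object$data$measurements
      out
    }))
  })
}
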