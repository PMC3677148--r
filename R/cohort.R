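#' Population parameters for a simulated group
#'
#' Describes the distribution from which per-subject generative parameters
#' are drawn. Operation biases are additive on the log10 scale of the
#' internal magnitude estimate (so a bias of `log10(1.2)` means outcomes
#' are over-estimated by 20\% on average); `weber` is the standard
#' deviation of the natural-log estimate noise, which under Weber's law
#' fixes the coefficient of variation at `sqrt(exp(weber^2) - 1)`.
#'
#' The defaults encode the qualitative group structure of the paradigm the
#' package emulates: adults over-estimate addition and under-estimate
#' subtraction (regular operational momentum), children show the reverse
#' (inverse OM) and are more variable throughout; cueing reaction times
#' carry an orienting benefit and a larger reorienting cost, with about 2\%
#' wrong-side errors; and across children the OM difference correlates
#' negatively with the reorienting cost parameter (children with smaller
#' costs show more regular OM).
#'
#' @param group `"adult"` or `"child"`.
#' @param ... Named overrides of any default component.
#' @return List of class `om_group_params`.
#' @export
group_params <- function(group = c("adult", "child"), ...) {
  group <- match.arg(group)
  p <- if (group == "adult") {
    list(group = "adult",
         bias_add_mean = 0.02, bias_add_sd = 0.05,
         bias_sub_mean = -0.05, bias_sub_sd = 0.05,
         bias_corr = -0.34,
         bias_mem_mean = 0.01, bias_mem_sd = 0.03,
         weber_mean = 0.15, weber_sd = 0.02,
         lapse_mean = 0.01, lapse_sd = 0.005,
         rt_base_mean = log(450), rt_base_sd = 0.12,
         rt_noise_mean = 0.15, rt_noise_sd = 0.03,
         rt_orient_mean = 25, rt_orient_sd = 8,
         rt_reorient_mean = 40, rt_reorient_sd = 15,
         error_rate_mean = 0.02, error_rate_sd = 0.01,
         rho_om_reorient = -0.6)
  } else {
    list(group = "child",
         bias_add_mean = 0.00, bias_add_sd = 0.09,
         bias_sub_mean = 0.03, bias_sub_sd = 0.09,
         bias_corr = 0.42,
         bias_mem_mean = 0.02, bias_mem_sd = 0.05,
         weber_mean = 0.25, weber_sd = 0.04,
         lapse_mean = 0.05, lapse_sd = 0.02,
         rt_base_mean = log(650), rt_base_sd = 0.15,
         rt_noise_mean = 0.25, rt_noise_sd = 0.05,
         rt_orient_mean = 30, rt_orient_sd = 10,
         rt_reorient_mean = 60, rt_reorient_sd = 40,
         error_rate_mean = 0.02, error_rate_sd = 0.01,
         rho_om_reorient = -0.6)
  }
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown group_params fields: ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  if (abs(p$bias_corr) >= 1 || abs(p$rho_om_reorient) > 1) {
    stop("correlations must lie in [-1, 1] (bias_corr strictly inside)")
  }
  structure(p, class = "om_group_params")
}

# one bivariate-normal draw matrix given means, sds, correlation
rbvn <- function(n, m1, s1, m2, s2, rho) {
  z1 <- rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  cbind(m1 + s1 * z1, m2 + s2 * z2)
}

#' Draw per-subject generative parameters from group distributions
#'
#' Operation biases are drawn jointly with the configured within-subject
#' correlation; the reorienting cost is drawn jointly with the
#' addition-minus-subtraction bias difference at correlation
#' `rho_om_reorient`. Dispersion parameters are truncated at small
#' positive floors, probabilities at \[0, 0.5\].
#'
#' @param params An [group_params()] object.
#' @param n Number of subjects.
#' @param id_offset Subject ids start at `id_offset + 1`.
#' @return Data frame, one row per subject, with all generative fields.
#' @export
draw_subjects <- function(params, n, id_offset = 0L) {
  stopifnot(inherits(params, "om_group_params"), n >= 1)
  b <- rbvn(n, params$bias_add_mean, params$bias_add_sd,
            params$bias_sub_mean, params$bias_sub_sd, params$bias_corr)
  om <- b[, 1] - b[, 2]
  om_sd <- sqrt(params$bias_add_sd^2 + params$bias_sub_sd^2 -
                  2 * params$bias_corr * params$bias_add_sd * params$bias_sub_sd)
  z_om <- if (om_sd > 0) (om - mean(om)) / stats::sd(om) else rep(0, n)
  if (n < 2) z_om <- rep(0, n)
  rho <- params$rho_om_reorient
  reor <- params$rt_reorient_mean + params$rt_reorient_sd *
    (rho * z_om + sqrt(1 - rho^2) * rnorm(n))
  data.frame(
    subject_id = paste0(substr(params$group, 1, 1), id_offset + seq_len(n)),
    group = params$group,
    bias_add = b[, 1],
    bias_sub = b[, 2],
    bias_mem = rnorm(n, params$bias_mem_mean, params$bias_mem_sd),
    weber = pmax(rnorm(n, params$weber_mean, params$weber_sd), 0.02),
    lapse = pmin(pmax(rnorm(n, params$lapse_mean, params$lapse_sd), 0), 0.5),
    rt_base = rnorm(n, params$rt_base_mean, params$rt_base_sd),
    rt_noise = pmax(rnorm(n, params$rt_noise_mean, params$rt_noise_sd), 0.01),
    rt_orient = rnorm(n, params$rt_orient_mean, params$rt_orient_sd),
    rt_reorient = reor,
    error_rate = pmin(pmax(rnorm(n, params$error_rate_mean, params$error_rate_sd), 0), 0.2),
    stringsAsFactors = FALSE
  )
}

#' Simulate choices among displayed alternatives
#'
#' The internal magnitude estimate is log-normally distributed around the
#' correct outcome: `log10(X) = log10(correct) + bias + (weber/ln 10) * Z`
#' with standard-normal `Z`. The subject picks the alternative closest to
#' the estimate on the log scale (ties go to the smaller value); with
#' probability `lapse` the choice is instead uniform over the
#' alternatives.
#'
#' @param correct Correct outcome (positive).
#' @param alternatives Numeric vector of displayed outcomes.
#' @param bias Log10-scale operation bias.
#' @param weber Natural-log-scale noise SD (> 0 allowed to be 0 for the
#'   deterministic case).
#' @param lapse Lapse probability.
#' @param n Number of independent choices to simulate.
#' @return Numeric vector of `n` chosen values.
#' @examples
#' simulate_choice(8, c(4, 5, 6, 7, 8, 10), bias = log10(1.2), weber = 0)  # 10
#' @export
simulate_choice <- function(correct, alternatives, bias = 0, weber = 0.15,
                            lapse = 0, n = 1) {
  stopifnot(correct > 0, all(alternatives > 0), weber >= 0,
            lapse >= 0, lapse < 1)
  alternatives <- sort(alternatives)
  la <- log(alternatives)
  lx <- log(correct) + bias * log(10) + weber * rnorm(n)
  idx <- vapply(lx, function(v) which.min(abs(la - v)), 0L)
  chosen <- alternatives[idx]
  if (lapse > 0) {
    flip <- runif(n) < lapse
    chosen[flip] <- sample(alternatives, sum(flip), replace = TRUE)
  }
  chosen
}

#' Simulate one subject's arithmetic session
#'
#' Applies the operation-specific bias (`bias_add`, `bias_sub`,
#' `bias_mem`) per trial of the test phase and draws a log-normal
#' response time per trial.
#'
#' @param subject One row of [draw_subjects()] output (data frame or list).
#' @param schedule A session schedule from [build_session_schedule()].
#' @param seed Optional seed; `NULL` continues the current RNG stream.
#' @return Data frame of trial records, one row per test trial.
#' @export
simulate_session <- function(subject, schedule, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- schedule[schedule$phase == "test", , drop = FALSE]
  alts <- alts_split(sc$alternatives)
  bias <- c(addition = subject$bias_add, subtraction = subject$bias_sub,
            memorization = subject$bias_mem)[sc$task]
  chosen <- numeric(nrow(sc))
  for (i in seq_len(nrow(sc))) {
    chosen[i] <- simulate_choice(sc$correct[i], alts[[i]], bias = bias[i],
                                 weber = subject$weber, lapse = subject$lapse)
  }
  data.frame(
    subject_id = subject$subject_id,
    group = subject$group,
    task = sc$task,
    operand1 = sc$operand1,
    operand2 = sc$operand2,
    correct = sc$correct,
    range_flag = sc$range_flag,
    area_mode = sc$area_mode,
    alternatives = sc$alternatives,
    chosen = chosen,
    rt_ms = exp(subject$rt_base + subject$rt_noise * rnorm(nrow(sc))),
    response_correct = chosen == sc$correct,
    stringsAsFactors = FALSE
  )
}

#' Simulate one subject's cueing session
#'
#' Reaction time is log-normal baseline plus additive condition effects:
#' the orienting benefit is subtracted on valid trials and the reorienting
#' cost added on invalid trials. The response lands on the wrong side with
#' probability `error_rate`.
#'
#' @inheritParams simulate_session
#' @param schedule A cueing schedule from [build_cueing_schedule()].
#' @return Data frame of cueing trial records (test phase only).
#' @export
simulate_cueing <- function(subject, schedule, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sc <- schedule[schedule$phase == "test", , drop = FALSE]
  shift <- ifelse(sc$validity == "valid", -subject$rt_orient,
                  ifelse(sc$validity == "invalid", subject$rt_reorient, 0))
  rt <- exp(subject$rt_base + subject$rt_noise * rnorm(nrow(sc))) + shift
  data.frame(
    subject_id = subject$subject_id,
    group = subject$group,
    task = "cueing",
    validity = sc$validity,
    cue = sc$cue,
    target_side = sc$target_side,
    soa_ms = sc$soa_ms,
    rt_ms = pmax(rt, 1),
    response_correct = runif(nrow(sc)) >= subject$error_rate,
    stringsAsFactors = FALSE
  )
}

#' Simulate a full two-group cohort
#'
#' Draws `n_per_group` adults and children, gives every subject its own
#' randomized session schedule, and runs the choice and cueing simulators.
#' As in the paradigm being emulated, only half of the children (rounded
#' up) complete the cueing task.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param seed Integer seed for the whole cohort.
#' @param adult,child [group_params()] objects.
#' @param cueing_fraction Fraction of children given the cueing task.
#' @return List with `trials` (arithmetic trial records), `cueing`
#'   (cueing trial records) and `truth` (the per-subject generative
#'   parameters, for recovery checks).
#' @export
simulate_cohort <- function(n_per_group = 32, seed = 1,
                            adult = group_params("adult"),
                            child = group_params("child"),
                            cueing_fraction = 0.5) {
  stopifnot(n_per_group >= 2)
  set.seed(seed)
  truth <- rbind(draw_subjects(adult, n_per_group),
                 draw_subjects(child, n_per_group))
  trials <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    sched <- build_session_schedule(seed = NULL)
    trials[[i]] <- simulate_session(truth[i, ], sched)
  }
  kids <- which(truth$group == "child")
  cue_ids <- kids[seq_len(ceiling(length(kids) * cueing_fraction))]
  cueing <- vector("list", length(cue_ids))
  for (j in seq_along(cue_ids)) {
    sched <- build_cueing_schedule(seed = NULL)
    cueing[[j]] <- simulate_cueing(truth[cue_ids[j], ], sched)
  }
  list(trials = do.call(rbind, trials),
       cueing = do.call(rbind, cueing),
       truth = truth)
}

#' Simulate standardized bias-score pairs for model recovery
#'
#' Draws per-subject (addition, subtraction) score pairs directly from the
#' bivariate-normal data model, one covariance matrix per group — the
#' ground-truth scenario for Gibbs-sampler recovery studies.
#'
#' @param mu_adult,mu_child Length-2 mean vectors (addition, subtraction).
#' @param sigma_adult,sigma_child 2x2 positive-definite covariance
#'   matrices.
#' @param n_per_group Subjects per group.
#' @param seed Optional integer seed.
#' @return Data frame with columns `subject`, `group`, `bias_addition`,
#'   `bias_subtraction`.
#' @export
simulate_bias_scores <- function(mu_adult, mu_child,
                                 sigma_adult = diag(2), sigma_child = diag(2),
                                 n_per_group = 32, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  draw <- function(mu, sigma, n, label, prefix) {
    ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("covariance matrix for ", label, " is not positive-definite")
    z <- matrix(rnorm(2 * n), n, 2) %*% chol(sigma)
    data.frame(subject = paste0(prefix, seq_len(n)), group = label,
               bias_addition = mu[1] + z[, 1],
               bias_subtraction = mu[2] + z[, 2],
               stringsAsFactors = FALSE)
  }
  rbind(draw(mu_adult, sigma_adult, n_per_group, "adult", "a"),
        draw(mu_child, sigma_child, n_per_group, "child", "c"))
}
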