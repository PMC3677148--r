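#' Per-subject operational-momentum bias
#'
#' The OM bias of a subject in an operation is the mean of
#' `log10(chosen) - log10(correct)` over that subject's trials; the OM
#' difference is the addition bias minus the subtraction bias (positive =
#' regular OM, negative = inverse OM).
#'
#' @param trials Trial records (arithmetic/memorization rows; cueing rows
#'   are ignored). Needs columns `subject_id`, `group`, `task`, `chosen`,
#'   `correct`.
#' @return Data frame with one row per subject: `subject`, `group`,
#'   `bias_addition`, `bias_subtraction`, `bias_memorization` (when
#'   present) and `om_difference`. Subjects missing an arithmetic
#'   operation are dropped with a warning.
#' @export
om_bias <- function(trials) {
  t <- trials[trials$task %in% c("addition", "subtraction", "memorization"), ]
  stopifnot(all(t$chosen > 0), all(t$correct > 0))
  t$dev <- log10(t$chosen) - log10(t$correct)
  agg <- stats::aggregate(dev ~ subject_id + group + task, data = t, FUN = mean)
  wide <- stats::reshape(agg, idvar = c("subject_id", "group"),
                         timevar = "task", direction = "wide")
  names(wide) <- sub("^dev\\.", "bias_", names(wide))
  names(wide)[names(wide) == "subject_id"] <- "subject"
  need <- c("bias_addition", "bias_subtraction")
  if (!all(need %in% names(wide))) {
    stop("trials must contain both addition and subtraction rows")
  }
  incomplete <- !complete.cases(wide[, need])
  if (any(incomplete)) {
    warning(sum(incomplete), " subject(s) lack trials in an arithmetic ",
            "operation and were excluded")
    wide <- wide[!incomplete, , drop = FALSE]
  }
  wide$om_difference <- wide$bias_addition - wide$bias_subtraction
  rownames(wide) <- NULL
  wide
}

#' Coefficient-of-variation profile across outcomes
#'
#' Under Weber's law the standard deviation of chosen values grows
#' proportionally with their mean, so the CV (SD / mean) is constant
#' across outcome magnitudes. By default the SD pools all trials of all
#' subjects within an operation-by-outcome cell; `by_subject = TRUE`
#' instead computes per-subject CVs and averages them.
#'
#' @param trials Trial records with `task`, `correct`, `chosen` (and
#'   `subject_id` for the per-subject variant).
#' @param by_subject Average per-subject CVs instead of pooling trials.
#' @return Data frame with columns `task`, `correct`, `n`, `mean`, `sd`,
#'   `cv`; empty cells are absent, single-trial cells have `NA` sd.
#' @export
cv_profile <- function(trials, by_subject = FALSE) {
  t <- trials[trials$task %in% c("addition", "subtraction", "memorization"), ]
  if (by_subject) {
    per <- stats::aggregate(chosen ~ subject_id + task + correct, data = t,
                            FUN = function(x) stats::sd(x) / mean(x))
    out <- stats::aggregate(chosen ~ task + correct, data = per, FUN = mean,
                            na.action = stats::na.omit)
    names(out)[names(out) == "chosen"] <- "cv"
    out$n <- stats::aggregate(chosen ~ task + correct, data = t, FUN = length)$chosen
    return(out[order(out$task, out$correct), ])
  }
  mean_ <- stats::aggregate(chosen ~ task + correct, data = t, FUN = mean)
  sd_ <- stats::aggregate(chosen ~ task + correct, data = t, FUN = stats::sd)
  n_ <- stats::aggregate(chosen ~ task + correct, data = t, FUN = length)
  out <- data.frame(task = mean_$task, correct = mean_$correct,
                    n = n_$chosen, mean = mean_$chosen, sd = sd_$chosen)
  out$cv <- out$sd / out$mean
  out[order(out$task, out$correct), ]
}

#' Choice-rank distributions by operation and range
#'
#' The rank of a choice is its position among the six displayed
#' alternatives sorted ascending (the correct outcome sits at rank 5 in
#' the low range and rank 2 in the high range). Proportions over ranks
#' are computed per operation-by-range cell, together with the
#' variance-stabilizing arcsine-square-root transform.
#'
#' @param trials Trial records with `task`, `range_flag`, `alternatives`
#'   (semicolon-joined) and `chosen`.
#' @return Data frame with `task`, `range_flag`, `rank`, `n`, `p`,
#'   `asin_sqrt_p`. Rows whose chosen value is not among the alternatives
#'   are rejected; their count is attached as attribute `n_rejected` (with
#'   a warning when non-zero).
#' @export
rank_distribution <- function(trials) {
  t <- trials[trials$task %in% c("addition", "subtraction", "memorization"), ]
  alts <- alts_split(t$alternatives)
  rank <- mapply(function(a, ch) {
    a <- sort(a)
    m <- match(ch, a)
    if (is.na(m)) NA_integer_ else m
  }, alts, t$chosen)
  bad <- is.na(rank)
  if (any(bad)) {
    warning(sum(bad), " trial(s) rejected: chosen value not among alternatives")
  }
  t <- t[!bad, , drop = FALSE]
  rank <- rank[!bad]
  cells <- unique(t[, c("task", "range_flag")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sel <- t$task == cells$task[i] & t$range_flag == cells$range_flag[i]
    counts <- tabulate(rank[sel], nbins = 6L)
    p <- counts / sum(counts)
    data.frame(task = cells$task[i], range_flag = cells$range_flag[i],
               rank = 1:6, n = counts, p = p, asin_sqrt_p = asin(sqrt(p)))
  }))
  rownames(out) <- NULL
  attr(out, "n_rejected") <- sum(bad)
  out
}

#' Per-subject regression of chosen on shown numerosity (memory trials)
#'
#' Fits `chosen = a + b * shown` by ordinary least squares for every
#' subject over the memorization trials, then tests the intercepts against
#' zero and the slopes against `null_slope` with one-sample t tests.
#'
#' @param trials Trial records containing memorization rows.
#' @param null_slope Null value for the group-level slope test (0 tests
#'   for any dependence on the shown value, 1 for deviation from
#'   identity).
#' @return List with `per_subject` (subject, intercept, slope),
#'   `t_intercept` and `t_slope` (`htest` objects). Subjects with fewer
#'   than two distinct shown numerosities are skipped.
#' @export
memory_regression <- function(trials, null_slope = 0) {
  t <- trials[trials$task == "memorization", ]
  if (nrow(t) == 0) stop("no memorization trials")
  per <- lapply(split(t, t$subject_id), function(d) {
    if (length(unique(d$correct)) < 2) return(NULL)
    cf <- coef(lm(chosen ~ correct, data = d))
    data.frame(subject = d$subject_id[1], intercept = cf[[1]], slope = cf[[2]])
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(per_subject = per,
       t_intercept = if (nrow(per) >= 2) t.test(per$intercept, mu = 0),
       t_slope = if (nrow(per) >= 2) t.test(per$slope, mu = null_slope))
}

#' Cueing orienting and reorienting effects
#'
#' Per subject, correct-trial reaction times are z-standardized (mean 0,
#' SD 1 within subject) before averaging by cue validity. The orienting
#' effect is the neutral-minus-valid difference (positive = benefit of a
#' valid cue); the reorienting effect is neutral minus invalid (negative
#' values = cost of an invalid cue, less negative = cheaper reorienting).
#'
#' @param cueing Cueing trial records with `subject_id`, `validity`,
#'   `rt_ms`, `response_correct`.
#' @return Data frame per subject: `subject`, condition means `z_valid`,
#'   `z_neutral`, `z_invalid`, and `orienting`, `reorienting`. Subjects
#'   with an empty condition are excluded with a warning.
#' @export
cueing_effects <- function(cueing) {
  t <- cueing[cueing$response_correct, , drop = FALSE]
  per <- lapply(split(t, t$subject_id), function(d) {
    if (!all(c("valid", "neutral", "invalid") %in% d$validity)) return(NULL)
    s <- stats::sd(d$rt_ms)
    z <- if (is.na(s) || s == 0) rep(0, nrow(d)) else (d$rt_ms - mean(d$rt_ms)) / s
    m <- tapply(z, d$validity, mean)
    data.frame(subject = d$subject_id[1],
               z_valid = m[["valid"]], z_neutral = m[["neutral"]],
               z_invalid = m[["invalid"]],
               orienting = m[["neutral"]] - m[["valid"]],
               reorienting = m[["neutral"]] - m[["invalid"]])
  })
  dropped <- sum(vapply(per, is.null, TRUE))
  if (dropped > 0) {
    warning(dropped, " subject(s) excluded: empty cueing condition")
  }
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Pearson correlation between two per-subject measures
#'
#' @param x,y Paired numeric vectors (>= 3 complete pairs).
#' @return List with `r`, `p` (two-sided, from the t transform), `n`, and
#'   `defined` (`FALSE` when either vector has zero variance, in which
#'   case `r` and `p` are `NA`).
#' @export
correlate <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, n = length(x), defined = FALSE))
  }
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x), defined = TRUE)
}
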