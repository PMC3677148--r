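#' @useDynLib opmom, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats coef cor lm median p.adjust pnorm qnorm rbinom rnorm
#'   runif sd setNames t.test var cor.test quantile simulate rchisq complete.cases
#' @importFrom utils read.csv write.csv head
NULL

# round half away from zero: the rounding convention that reproduces the
# printed deviant tables (e.g. 12.5 -> 13)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Geometric deviant series around a correct outcome
#'
#' Candidate outcomes are spaced geometrically from half to double the
#' correct result: `round(c * 2^(i/4))` for `i = -4, ..., 4`, rounding
#' half-integers away from zero. The fifth value (i = 0) is the correct
#' result itself.
#'
#' @param correct Correct outcome; a single integer >= 2.
#' @return Integer vector of 9 candidate outcomes, non-decreasing, with
#'   `values[5] == correct`.
#' @examples
#' deviant_series(8)   # 4 5 6 7 8 10 11 13 16
#' deviant_series(25)  # 13 15 18 21 25 30 35 42 50
#' @export
deviant_series <- function(correct) {
  if (length(correct) != 1L || !is.numeric(correct) || is.na(correct) ||
      correct != as.integer(correct) || correct < 2) {
    stop("'correct' must be a single integer >= 2")
  }
  correct <- as.integer(correct)
  as.integer(round_half_away(correct * 2^((-4:4) / 4)))
}

#' Resolve duplicate deviants by decrementing the smallest duplicate
#'
#' Integer rounding of a geometric series around a small outcome can
#' produce repeated candidate values. Repeatedly subtract one from a single
#' occurrence of the smallest duplicated value until all values are
#' distinct.
#'
#' @param deviants Non-decreasing integer vector (the candidate outcomes,
#'   usually excluding the correct one).
#' @return Sorted integer vector of the same length with all values
#'   distinct; every value is less than or equal to its input counterpart.
#' @examples
#' resolve_duplicates(c(3, 4, 4, 5, 7, 8, 10, 12))  # 2 3 4 5 7 8 10 12
#' @export
resolve_duplicates <- function(deviants) {
  if (is.unsorted(deviants)) stop("'deviants' must be sorted non-decreasing")
  x <- as.integer(deviants)
  repeat {
    tab <- table(x)
    dup <- as.integer(names(tab)[tab >= 2L])
    if (length(dup) == 0L) break
    v <- min(dup)
    if (v <= 1L) stop("cannot resolve duplicates: would decrement below 1")
    i <- which(x == v)[1L]
    x[i] <- x[i] - 1L
    x <- sort(x)
  }
  x
}

full_series <- function(correct) {
  s <- deviant_series(correct)
  dev <- resolve_duplicates(s[-5L])
  sort(c(dev, correct))
}

#' Select the displayed response range from a nine-value series
#'
#' Only six of the nine candidate outcomes appear on screen. The low range
#' shows the lower six (correct outcome is the fifth smallest), the high
#' range the upper six (correct outcome is the second smallest).
#'
#' @param series Nine distinct candidate outcomes, sorted ascending, with
#'   the correct outcome at position 5.
#' @param range_flag `"low"` or `"high"`.
#' @return List with `range_flag`, `alternatives` (6 integers) and
#'   `correct_rank` (5 for low, 2 for high).
#' @examples
#' select_range(deviant_series(8), "low")$alternatives   # 4 5 6 7 8 10
#' select_range(deviant_series(8), "high")$alternatives  # 7 8 10 11 13 16
#' @export
select_range <- function(series, range_flag = c("low", "high")) {
  range_flag <- match.arg(range_flag)
  if (length(series) != 9L || anyDuplicated(series) || is.unsorted(series)) {
    stop("'series' must be 9 distinct sorted values")
  }
  if (range_flag == "low") {
    list(range_flag = "low", alternatives = series[1:6], correct_rank = 5L)
  } else {
    list(range_flag = "high", alternatives = series[4:9], correct_rank = 2L)
  }
}

#' The full arithmetic/memorization problem set
#'
#' Eleven problems: four additions and four subtractions chosen so that
#' both operations share the outcome set \{8, 10, 19, 25\}, plus three
#' memorization problems (second operand zero) with outcomes 6, 19 and 25.
#' Each problem carries its nine-value deviant series; the series for
#' outcome 6 passes through [resolve_duplicates()] because integer rounding
#' collides there.
#'
#' @return Data frame with one row per problem: `operation`, `operand1`,
#'   `operand2`, `correct`, and a list column `series` of 9-value integer
#'   vectors.
#' @export
build_problem_table <- function() {
  ops <- rbind(
    data.frame(operation = "addition",
               operand1 = c(6L, 6L, 14L, 14L), operand2 = c(2L, 4L, 5L, 11L)),
    data.frame(operation = "subtraction",
               operand1 = c(16L, 16L, 32L, 32L), operand2 = c(8L, 6L, 13L, 7L)),
    data.frame(operation = "memorization",
               operand1 = c(6L, 19L, 25L), operand2 = 0L)
  )
  correct <- ifelse(ops$operation == "subtraction",
                    ops$operand1 - ops$operand2,
                    ops$operand1 + ops$operand2)
  tab <- cbind(ops, correct = as.integer(correct))
  tab$series <- I(lapply(tab$correct, full_series))
  tab
}

alts_join <- function(x) vapply(x, function(v) paste(v, collapse = ";"), "")
alts_split <- function(x) lapply(strsplit(as.character(x), ";", fixed = TRUE),
                                 as.numeric)

#' Build a randomized arithmetic session schedule
#'
#' The test phase crosses every problem with both response ranges and both
#' dot-area control modes (4 repetitions per problem), giving 44 trials:
#' 12 memorization, 16 addition, 16 subtraction. Trial order and the
#' assignment of the six alternatives to screen slots are randomized. The
#' training phase re-uses 8 randomly drawn trial configurations; test
#' responses are limited to 20 s, training responses are untimed.
#'
#' @param seed Integer seed; the schedule is reproducible from it. `NULL`
#'   uses the current RNG state.
#' @param problems Problem table, by default [build_problem_table()].
#' @return Data frame of trials with columns `trial_index`, `phase`,
#'   `task`, `operand1`, `operand2`, `correct`, `range_flag`, `area_mode`,
#'   `alternatives` (semicolon-joined), `correct_rank`, `slot_permutation`
#'   (semicolon-joined permutation of 1:6) and `response_limit_s`.
#' @export
build_session_schedule <- function(seed = NULL, problems = build_problem_table()) {
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(problem = seq_len(nrow(problems)),
                      range_flag = c("low", "high"),
                      area_mode = c("fixed_total_area", "fixed_dot_size"),
                      stringsAsFactors = FALSE)
  grid <- grid[sample.int(nrow(grid)), , drop = FALSE]
  p <- problems[grid$problem, ]
  rs <- Map(select_range, p$series, grid$range_flag)
  test <- data.frame(
    phase = "test",
    task = p$operation,
    operand1 = p$operand1,
    operand2 = p$operand2,
    correct = p$correct,
    range_flag = grid$range_flag,
    area_mode = grid$area_mode,
    alternatives = alts_join(lapply(rs, `[[`, "alternatives")),
    correct_rank = vapply(rs, `[[`, 0L, "correct_rank"),
    response_limit_s = 20,
    stringsAsFactors = FALSE
  )
  train <- test[sample.int(nrow(test), 8L), , drop = FALSE]
  train$phase <- "training"
  train$response_limit_s <- NA_real_
  out <- rbind(train, test)
  out$slot_permutation <- vapply(
    seq_len(nrow(out)), function(i) paste(sample.int(6L), collapse = ";"), "")
  out <- cbind(trial_index = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Build a randomized spatial-cueing (Posner) schedule
#'
#' Sixty test trials: 40 validly cued, 10 invalidly cued and 10 neutral
#' (bidirectional cue). Target side is balanced 50/50 within each validity
#' class and the two stimulus-onset asynchronies (200 and 800 ms) are
#' balanced within validity. Eight training trials precede the test.
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Data frame with columns `trial_index`, `phase`, `validity`,
#'   `cue`, `target_side`, `soa_ms`.
#' @export
build_cueing_schedule <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cell <- function(validity, n) {
    side <- rep(c("left", "right"), each = n / 2)
    # SOA balanced within validity; within side as evenly as 5 allows
    soa <- c(rep(c(200, 800), length.out = n / 2),
             rep(c(800, 200), length.out = n / 2))
    data.frame(validity = validity, target_side = side, soa_ms = soa,
               stringsAsFactors = FALSE)
  }
  test <- rbind(cell("valid", 40L), cell("invalid", 10L), cell("neutral", 10L))
  test$cue <- ifelse(test$validity == "neutral", "neutral",
                     ifelse(test$validity == "valid", test$target_side,
                            ifelse(test$target_side == "left", "right", "left")))
  test <- test[sample.int(nrow(test)), , drop = FALSE]
  test$phase <- "test"
  train <- rbind(cell("valid", 6L), cell("invalid", 2L)[1L, ], cell("neutral", 2L)[2L, ])
  train$cue <- ifelse(train$validity == "neutral", "neutral",
                      ifelse(train$validity == "valid", train$target_side,
                             ifelse(train$target_side == "left", "right", "left")))
  train <- train[sample.int(nrow(train)), , drop = FALSE]
  train$phase <- "training"
  out <- rbind(train, test)
  out <- cbind(trial_index = seq_len(nrow(out)),
               out[, c("phase", "validity", "cue", "target_side", "soa_ms")])
  rownames(out) <- NULL
  out
}

#' Generate a random non-overlapping dot array
#'
#' Places `n` circular dots uniformly at random in a rectangular field by
#' rejection sampling, with a minimum gap between dot rims and the field
#' border. Two area-control modes prevent continuous quantity from cueing
#' numerosity: `fixed_total_area` keeps the summed dot area constant across
#' numerosities (radius `sqrt(total_area / (n * pi))`), `fixed_dot_size`
#' keeps the individual radius constant (total area grows with `n`).
#'
#' @param n Number of dots (>= 1).
#' @param mode `"fixed_total_area"` or `"fixed_dot_size"`.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param field Field width and height in abstract pixels.
#' @param total_area Summed dot area in `fixed_total_area` mode.
#' @param radius Dot radius in `fixed_dot_size` mode.
#' @param gap Minimum rim-to-rim (and rim-to-border) distance.
#' @param max_attempts Placement attempts before giving up.
#' @return Object of class `dot_array`: list with `n`, `mode`,
#'   `field_size`, and `dots`, an `n x 3` matrix of (x, y, radius).
#' @export
generate_dot_array <- function(n, mode = c("fixed_total_area", "fixed_dot_size"),
                               seed = NULL, field = c(400, 400),
                               total_area = pi * 7^2 * 50, radius = 7,
                               gap = 2, max_attempts = 20000L) {
  mode <- match.arg(mode)
  if (length(n) != 1L || n < 1 || n != as.integer(n)) {
    stop("'n' must be a single positive integer")
  }
  if (!is.null(seed)) set.seed(seed)
  r <- if (mode == "fixed_total_area") sqrt(total_area / (n * pi)) else radius
  if (2 * (r + gap) >= min(field)) stop("field too small for the dot radius")
  xs <- ys <- numeric(0)
  attempts <- 0L
  while (length(xs) < n) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop("could not place ", n, " dots after ", max_attempts,
           " attempts; increase the field size")
    }
    x <- runif(1, r + gap, field[1] - r - gap)
    y <- runif(1, r + gap, field[2] - r - gap)
    if (length(xs) == 0 ||
        all((xs - x)^2 + (ys - y)^2 > (2 * r + gap)^2)) {
      xs <- c(xs, x)
      ys <- c(ys, y)
    }
  }
  structure(list(n = as.integer(n), mode = mode, field_size = field,
                 dots = cbind(x = xs, y = ys, r = rep(r, n))),
            class = "dot_array")
}

#' @export
print.dot_array <- function(x, ...) {
  cat("Dot array: n =", x$n, "| mode =", x$mode,
      "| field =", paste(x$field_size, collapse = " x "),
      "| total area =", format(sum(pi * x$dots[, "r"]^2), digits = 6), "\n")
  invisible(x)
}

#' Write a dot array as a JSON record
#'
#' @param x A `dot_array`.
#' @param path Output file path.
#' @export
write_dot_array <- function(x, path) {
  jsonlite::write_json(
    list(n = x$n, mode = x$mode, field_size = x$field_size,
         dots = unname(apply(x$dots, 1, as.numeric, simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
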