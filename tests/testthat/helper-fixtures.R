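# Printed problem set of the paradigm: 11 problems x 9 response
# alternatives (correct outcome in column 5). The first alternative of the
# outcome-19 series is a half-integer rounding tie in the printed source
# (9.5 shown as 9) and is flagged below.
printed_problem_table <- data.frame(
  operation = c(rep("addition", 4), rep("subtraction", 4), rep("memorization", 3)),
  operand1 = c(6, 6, 14, 14, 16, 16, 32, 32, 6, 19, 25),
  operand2 = c(2, 4, 5, 11, 8, 6, 13, 7, 0, 0, 0)
)
printed_series <- rbind(
  c(4, 5, 6, 7, 8, 10, 11, 13, 16),
  c(5, 6, 7, 8, 10, 12, 14, 17, 20),
  c(9, 11, 13, 16, 19, 23, 27, 32, 38),
  c(13, 15, 18, 21, 25, 30, 35, 42, 50),
  c(4, 5, 6, 7, 8, 10, 11, 13, 16),
  c(5, 6, 7, 8, 10, 12, 14, 17, 20),
  c(9, 11, 13, 16, 19, 23, 27, 32, 38),
  c(13, 15, 18, 21, 25, 30, 35, 42, 50),
  c(2, 3, 4, 5, 6, 7, 8, 10, 12),
  c(9, 11, 13, 16, 19, 23, 27, 32, 38),
  c(13, 15, 18, 21, 25, 30, 35, 42, 50)
)
# TRUE where the printed cell is the half-integer tie (9.5 -> 9)
printed_tie_cell <- matrix(FALSE, 11, 9)
printed_tie_cell[printed_series[, 5] == 19, 1] <- TRUE

# minimal trial-record constructor for metric tests
make_trials <- function(subject, task, correct, chosen,
                        group = "child", range_flag = "low",
                        alternatives = NULL) {
  n <- max(length(subject), length(task), length(correct), length(chosen))
  if (is.null(alternatives)) {
    alternatives <- vapply(rep_len(correct, n),
                           function(cc) paste(sort(unique(c(cc, chosen))), collapse = ";"),
                           "")
  }
  data.frame(subject_id = rep_len(subject, n), group = rep_len(group, n),
             task = rep_len(task, n), operand1 = rep_len(correct, n),
             operand2 = 0, correct = rep_len(correct, n),
             range_flag = rep_len(range_flag, n), area_mode = "fixed_dot_size",
             alternatives = rep_len(alternatives, n),
             chosen = rep_len(chosen, n), rt_ms = 500,
             response_correct = rep_len(correct, n) == rep_len(chosen, n),
             stringsAsFactors = FALSE)
}

# cueing schedule stub with n trials per validity condition
make_cueing_schedule <- function(n_per_condition) {
  data.frame(trial_index = seq_len(3 * n_per_condition), phase = "test",
             validity = rep(c("valid", "neutral", "invalid"), each = n_per_condition),
             cue = "left", target_side = "left", soa_ms = 200,
             stringsAsFactors = FALSE)
}
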