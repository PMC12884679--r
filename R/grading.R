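# AVR-based hypertensive retinopathy grading.
#
# The grade table anchors normal at AVR 0.667-0.75, mild at 0.5, moderate
# at 0.25 and malignant below 0.2; the interval rule centres the cut-points
# between adjacent anchors so every anchored value keeps its grade while
# the rule stays total on (0, Inf):
#   AVR >= 0.6          -> normal
#   0.4 <= AVR < 0.6    -> mild
#   0.2 <= AVR < 0.4    -> moderate
#   AVR < 0.2           -> malignant
# Bins are left-closed.  AVR above 0.75 is still graded normal but flagged
# as out of the tabulated range.

HR_RULE_VERSION <- "avr-interval-1"

#' Grade hypertensive retinopathy from the arteriovenous ratio
#'
#' @param avr arteriovenous ratio, must be positive.
#' @return an `hr_grade` list: `grade` (normal / mild / moderate /
#'   malignant), `avr`, `out_of_table` (TRUE when AVR > 0.75),
#'   `decision_rule`.
#' @export
grade_from_avr <- function(avr) {
  if (!is.finite(avr) || avr <= 0) stop("AVR must be a positive number")
  grade <- if (avr >= 0.6) "normal"
  else if (avr >= 0.4) "mild"
  else if (avr >= 0.2) "moderate"
  else "malignant"
  structure(list(grade = grade, avr = avr, out_of_table = avr > 0.75,
                 decision_rule = HR_RULE_VERSION),
            class = "hr_grade")
}

#' Binary normal / HR decision
#'
#' Any grade other than normal counts as hypertensive retinopathy.
#'
#' @param grade an `hr_grade` from [grade_from_avr()].
#' @return `"normal"` or `"HR"`.
#' @export
classify_binary <- function(grade) {
  stopifnot(inherits(grade, "hr_grade"))
  if (grade$grade == "normal") "normal" else "HR"
}

#' JSON-ready grading verdict
#'
#' @param avr arteriovenous ratio.
#' @return list with `avr`, `grade`, `binary`, `rule_version`,
#'   `out_of_table`.
#' @export
hr_verdict <- function(avr) {
  g <- grade_from_avr(avr)
  list(avr = avr, grade = g$grade, binary = classify_binary(g),
       rule_version = g$decision_rule, out_of_table = g$out_of_table)
}
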