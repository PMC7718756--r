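# Ordinal DFA color grading of kernels and lots.

#' DFA lightness thresholds
#'
#' Cut points on the L* axis separating the four ordinal DFA color classes
#' (1 = Extra Light, 2 = Light, 3 = Light Amber, 4 = Amber). The defaults
#' are midpoints between the L* values of adjacent chart patches
#' (77.5, 62.5, 47.5, 32.5), i.e. cuts at 70, 55 and 40.
#'
#' @param c1,c2,c3 strictly decreasing cut points in `[0, 100]`.
#' @return an object of class `dfa_thresholds`.
#' @export
dfa_thresholds <- function(c1 = 70, c2 = 55, c3 = 40) {
  cuts <- c(c1, c2, c3)
  if (any(diff(cuts) >= 0) || any(cuts < 0 | cuts > 100))
    stop("DFA cuts must be strictly decreasing within [0, 100]", call. = FALSE)
  structure(list(c1 = c1, c2 = c2, c3 = c3), class = "dfa_thresholds")
}

#' Classify kernels on the DFA scale from L*
#'
#' Class 1 when `L >= c1`, class 2 when `c2 <= L < c1`, class 3 when
#' `c3 <= L < c2`, else class 4. A kernel exactly on a boundary takes the
#' lighter class. The mapping is monotone: lower lightness never gives a
#' lighter class.
#'
#' @param L numeric vector of kernel L* values.
#' @param thresholds a [dfa_thresholds()].
#' @return integer vector of classes 1-4.
#' @export
classify_dfa <- function(L, thresholds = dfa_thresholds()) {
  stopifnot(inherits(thresholds, "dfa_thresholds"))
  as.integer(1L + (L < thresholds$c1) + (L < thresholds$c2) +
               (L < thresholds$c3))
}

.dfa_grades <- c("ELIT", "LITE", "LAMB", "AMBR")
.dfa_tolerance <- c(ELIT = 0.15, LITE = 0.15, LAMB = 0.15, AMBR = 0.10)

#' Grade a lot of kernels
#'
#' Commercial lot grading: a lot takes the lightest grade whose tolerance
#' for darker kernels is met — Extra Light, Light and Light Amber each
#' permit 15% of kernels darker than the grade, Amber permits 10%. A lot
#' exceeding the Amber tolerance is darker than Amber ("below-AMBR").
#'
#' @param classes integer vector of per-kernel DFA classes (1-4).
#' @return a list with `grade` (one of `ELIT, LITE, LAMB, AMBR,
#'   below-AMBR`) and `fraction_darker`, the offending fraction at the
#'   assigned grade.
#' @export
grade_lot <- function(classes) {
  if (!length(classes)) stop("cannot grade an empty lot", call. = FALSE)
  if (any(is.na(classes) | classes < 1))
    stop("classes must be positive DFA classes", call. = FALSE)
  for (g in 1:4) {
    frac <- mean(classes > g)
    if (frac <= .dfa_tolerance[g])
      return(list(grade = .dfa_grades[g], fraction_darker = frac))
  }
  list(grade = "below-AMBR", fraction_darker = mean(classes > 4))
}
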