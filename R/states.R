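#' @useDynLib bmidiab, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' BMI category labels
#'
#' The five BMI categories used throughout the package, in increasing order:
#' normal weight (BMI < 25 kg/m2), overweight (25-30), obesity class I
#' (30-35), class II (35-40) and class III (>= 40).
#' @export
BMI_CLASSES <- c("NW", "OW", "OB1", "OB2", "OB3")

#' Labels of the 10 living health states
#'
#' BMI categories without type 2 diabetes (states 1-5) followed by the same
#' categories with type 2 diabetes (states 6-10, suffix `_D`).
#' @export
STATE_LABELS <- c(BMI_CLASSES, paste0(BMI_CLASSES, "_D"))

#' The 10-state health-state space
#'
#' Five BMI categories crossed with type 2 diabetes status give 10 living
#' states. Direct transitions move one BMI category up or down (diabetes
#' status unchanged) or from non-diabetic to diabetic within a BMI category;
#' diabetes is absorbing (no remission).
#'
#' @return A data frame with columns `index` (1-10), `label`, `bmi_class`
#'   and `diabetic`.
#' @examples
#' state_space()
#' @export
state_space <- function() {
  data.frame(
    index = 1:10,
    label = STATE_LABELS,
    bmi_class = rep(BMI_CLASSES, 2),
    diabetic = rep(c(FALSE, TRUE), each = 5),
    stringsAsFactors = FALSE
  )
}

#' State index from BMI category and diabetes status
#'
#' @param bmi_class Character vector of BMI category labels (see
#'   [BMI_CLASSES]).
#' @param diabetic Logical (or 0/1) vector, recycled.
#' @return Integer state indices in 1..10.
#' @examples
#' state_index("OB2", diabetic = TRUE)
#' @export
state_index <- function(bmi_class, diabetic = FALSE) {
  i <- match(bmi_class, BMI_CLASSES)
  if (anyNA(i)) stop("unknown BMI class label")
  i + 5L * as.integer(as.logical(diabetic))
}

#' Allowed direct transitions between health states
#'
#' @return A 10x10 logical matrix; `TRUE` where a direct transition exists
#'   (adjacent BMI categories within a diabetes layer, or diabetes onset
#'   within a BMI category).
#' @export
allowed_transitions <- function() {
  A <- matrix(FALSE, 10, 10, dimnames = list(STATE_LABELS, STATE_LABELS))
  for (i in 1:4) {
    A[i, i + 1] <- TRUE; A[i + 1, i] <- TRUE          # non-diabetic layer
    A[i + 5, i + 6] <- TRUE; A[i + 6, i + 5] <- TRUE  # diabetic layer
  }
  for (i in 1:5) A[i, i + 5] <- TRUE                  # diabetes onset
  A
}
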