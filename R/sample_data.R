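#' Two-group diagnostic test sample
#'
#' Container for continuous diagnostic test results split into a diseased and
#' a nondiseased group, the common input of all three ROC estimators in this
#' package.
#'
#' @param diseased numeric vector of test results for diseased subjects.
#' @param nondiseased numeric vector of test results for nondiseased subjects.
#'
#' @return An object of class `"sample_data"`: a list with elements
#'   `diseased`, `nondiseased`, `n1` (diseased count) and `n0`
#'   (nondiseased count).
#'
#' @examples
#' s <- sample_data(rnorm(50, 1.5), rnorm(50))
#' s$n1
#' @export
sample_data <- function(diseased, nondiseased) {
  diseased <- as.numeric(diseased)
  nondiseased <- as.numeric(nondiseased)
  if (length(diseased) == 0L || length(nondiseased) == 0L) {
    stop("both groups must contain at least one test result", call. = FALSE)
  }
  if (!all(is.finite(diseased)) || !all(is.finite(nondiseased))) {
    stop("all test results must be finite", call. = FALSE)
  }
  structure(
    list(
      diseased = diseased,
      nondiseased = nondiseased,
      n1 = length(diseased),
      n0 = length(nondiseased)
    ),
    class = "sample_data"
  )
}

#' @export
print.sample_data <- function(x, ...) {
  cat("Diagnostic test sample: n1 =", x$n1, "diseased, n0 =", x$n0,
      "nondiseased\n")
  invisible(x)
}

# shared guard for the variance-bearing estimators
check_min_group_sizes <- function(sample, min = 2L) {
  if (sample$n1 < min || sample$n0 < min) {
    stop("each group needs at least ", min,
         " observations (got n1 = ", sample$n1, ", n0 = ", sample$n0, ")",
         call. = FALSE)
  }
  invisible(sample)
}
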