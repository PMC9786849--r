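#' Chi-square goodness-of-fit test for segregation ratios
#'
#' Tests observed phenotype-class counts against a Mendelian expected ratio
#' with Pearson's chi-square statistic, `df = k - 1`, without continuity
#' correction — the classical segregation test, e.g. a 3:1 wild-type to
#' mutant ratio for a monogenic recessive trait in an F2 or T1 family.
#'
#' @param observed Non-negative integer counts per phenotype class.
#' @param ratio Expected ratio, same length (e.g. `c(3, 1)`).
#' @param classes Optional class labels.
#'
#' @return A `seg_test` object with [generics::tidy()] and
#'   [generics::glance()] methods; printing shows the statistic and P value
#'   rounded to two decimals (full precision is retained).
#' @export
#' @examples
#' chi_square_gof(c(55, 15), c(3, 1))  # chi-square 0.48, P 0.49
#' chi_square_gof(c(94, 23), c(3, 1))  # chi-square 1.78, P 0.18
chi_square_gof <- function(observed, ratio, classes = NULL) {
  if (length(observed) != length(ratio)) {
    stop("observed and ratio must have equal length")
  }
  if (any(observed < 0)) stop("observed counts must be non-negative")
  if (sum(observed) <= 0) stop("total observed count must be positive")
  if (any(ratio <= 0)) stop("ratio entries must be positive")
  if (is.null(classes)) classes <- paste0("class", seq_along(observed))
  ht <- suppressWarnings(
    stats::chisq.test(observed, p = ratio, rescale.p = TRUE, correct = FALSE)
  )
  structure(list(classes = classes,
                 observed = observed,
                 ratio = ratio,
                 expected = sum(observed) * ratio / sum(ratio),
                 chi_square = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = ht$p.value),
            class = "seg_test")
}

#' @export
print.seg_test <- function(x, ...) {
  cat("Segregation chi-square goodness-of-fit\n")
  cat("  observed: ", paste(x$observed, collapse = ":"),
      "   expected ratio: ", paste(x$ratio, collapse = ":"), "\n", sep = "")
  cat(sprintf("  chi-square = %.2f, df = %d, P = %.2f\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

#' Tidy a segregation test
#'
#' @param x A [chi_square_gof()] result.
#' @param ... Unused.
#' @return `tidy()`: one row per phenotype class with observed and expected
#'   counts; `glance()`: a one-row tibble with `chi_square`, `df`,
#'   `p_value`.
#' @method tidy seg_test
#' @export
tidy.seg_test <- function(x, ...) {
  tibble::tibble(class = x$classes, observed = x$observed,
                 ratio = x$ratio, expected = x$expected)
}

#' @rdname tidy.seg_test
#' @method glance seg_test
#' @export
glance.seg_test <- function(x, ...) {
  tibble::tibble(chi_square = x$chi_square, df = x$df, p_value = x$p_value)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted P values controlling the FDR, the adjustment behind an
#' "FDR-adjusted P <= 0.05" differential-expression threshold.
#'
#' @param p Numeric vector of P values in [0, 1].
#' @return Adjusted P values, capped at 1.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03))
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}
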