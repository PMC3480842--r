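#' Hoel test statistics for peak-like coverage forms
#'
#' Model-free z statistics comparing independently measured Poisson counts by
#' a normalized linear contrast. At a location x with coverage C and flanking
#' coverages L = C(x - delta), R = C(x + delta), the three peak-form
#' hypotheses are: Form 1, the center exceeds the mean of both flanks
#' (2*lambda_x > lambda_left + lambda_right); Form 2, the center exceeds the
#' left flank only; Form 3, the right flank only. Each statistic is the
#' contrast divided by the square root of an unbiased estimate of its variance
#' under the corresponding null, and is approximately standard normal even at
#' low total counts:
#'
#' \deqn{z_1 = \frac{2C - L - R}{\sqrt{2(L + C + R)}}, \quad
#'       z_2 = \frac{C - L}{\sqrt{L + C}}, \quad
#'       z_3 = \frac{C - R}{\sqrt{R + C}}}
#'
#' When every count in the denominator is zero there is no evidence either
#' way and the statistic is defined as 0 (never `NaN`); the strict detection
#' condition z > min_z then correctly fails.
#'
#' @param c_left,c_center,c_right Non-negative counts (vectors recycle; a
#'   run-length encoded [S4Vectors::Rle] is also accepted, in which case an
#'   Rle is returned).
#' @return The z statistic(s), same shape as the inputs.
#' @examples
#' hoel_z1(0, 10, 0)          # 20 / sqrt(20)
#' hoel_z2(4, 9)              # 5 / sqrt(13)
#' hoel_z3(9, 4)
#' @seealso [hoel_z4()] for the control-based enrichment test,
#'   [nlp_from_z()] to convert to -log10 p-values.
#' @export
hoel_z1 <- function(c_left, c_center, c_right) {
  num <- 2 * c_center - c_left - c_right
  den <- 2 * (c_left + c_center + c_right)
  zero_guard(num / sqrt(den))
}

#' @rdname hoel_z1
#' @export
hoel_z2 <- function(c_left, c_center) {
  zero_guard((c_center - c_left) / sqrt(c_left + c_center))
}

#' @rdname hoel_z1
#' @export
hoel_z3 <- function(c_center, c_right) {
  zero_guard((c_center - c_right) / sqrt(c_right + c_center))
}

#' Enrichment test statistic against a control sample
#'
#' Tests local enrichment of ChIP coverage C over control coverage B given
#' the control/ChIP library-size ratio r, i.e. the hypothesis
#' r*lambda_x > mu_x:
#'
#' \deqn{z_4 = \frac{rC - B}{\sqrt{r(C + B)}}}
#'
#' The denominator is the square root of an unbiased variance estimate under
#' the null mu = r*lambda: Var(rC - B) = r^2 lambda + mu, which at the null
#' equals r (lambda + mu) = E[r (C + B)]. Zero total count maps to z = 0.
#'
#' @param chip,control Non-negative coverage counts (vectors or Rle).
#' @param ratio Control/ChIP library-size ratio r (> 0).
#' @return The z statistic(s).
#' @examples
#' hoel_z4(10, 2, 1)        # 8 / sqrt(12)
#' hoel_z4(5, 10, 2)        # 0: balanced after scaling
#' @export
hoel_z4 <- function(chip, control, ratio) {
  stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio > 0)
  zero_guard((ratio * chip - control) / sqrt(ratio * (chip + control)))
}

#' Local enrichment ratio
#'
#' Pseudo-count-stabilized ratio of library-scaled ChIP coverage to control
#' coverage at a location: `ER = (1 + r*C) / (1 + B)`. Used (at the region
#' center) by the min.er filter; the add-one stabilization keeps the ratio
#' finite and equal to 1 for doubly-empty locations.
#'
#' @inheritParams hoel_z4
#' @return Positive ratio(s).
#' @examples
#' enrichment_ratio(7, 3, 1)   # 2
#' enrichment_ratio(0, 9, 1)   # 0.1
#' @export
enrichment_ratio <- function(chip, control, ratio) {
  stopifnot(is.numeric(ratio), length(ratio) == 1L, ratio > 0)
  (1 + ratio * chip) / (1 + control)
}

#' Negative log10 p-value of an upper-tail standard-normal test
#'
#' Converts a z value to `-log10 P(Z > z)` using the log-scale normal
#' survival function, so that very large z (say z = 40) yields a large finite
#' NLP instead of underflowing to infinity.
#'
#' @param z Finite z value(s).
#' @return Non-negative NLP value(s), strictly increasing in `z`.
#' @examples
#' nlp_from_z(0)            # log10(2)
#' nlp_from_z(qnorm(0.9))   # 1
#' @export
nlp_from_z <- function(z) {
  -stats::pnorm(z, lower.tail = FALSE, log.p = TRUE) / log(10)
}

#' z cut-off from an upper-tail probability
#'
#' The standard-normal upper-tail quantile used as the default `min_z`:
#' `min_z_from_p(0.1)` is about 1.2816.
#'
#' @param p Upper-tail probability, strictly between 0 and 1.
#' @return The quantile `qnorm(1 - p)`.
#' @export
min_z_from_p <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie strictly between 0 and 1", call. = FALSE)
  }
  stats::qnorm(p, lower.tail = FALSE)
}

# Replace non-finite entries (0/0 from all-zero counts) by 0.
# Works on plain numerics and on S4Vectors::Rle.
zero_guard <- function(z) {
  if (inherits(z, "Rle")) {
    v <- S4Vectors::runValue(z)
    v[!is.finite(v)] <- 0
    S4Vectors::runValue(z) <- v
    z
  } else {
    z[!is.finite(z)] <- 0
    z
  }
}
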