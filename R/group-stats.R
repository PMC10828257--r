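#' Star thresholds in units of standard errors
#'
#' The condition-comparison scheme marks a difference of means by how many
#' standard errors it spans: below `z1` not significant, `[z1, z2)` one
#' star, `[z2, z3]` two stars, above `z3` three stars. Defaults 1.64, 2.33
#' and 2.83: the first two are the one-sided normal critical values for
#' p = 0.05 and p = 0.01 (to two decimals). Note that 2.83 does not quite
#' match the one-sided p < 0.002 often quoted with three stars (the 0.998
#' normal quantile is 2.878); the z thresholds are treated as authoritative.
#'
#' @param z1,z2,z3 Increasing positive thresholds.
#' @export
significance_thresholds <- function(z1 = 1.64, z2 = 2.33, z3 = 2.83) {
  if (!(0 < z1 && z1 < z2 && z2 < z3)) {
    stop_input("thresholds must satisfy 0 < z1 < z2 < z3")
  }
  structure(list(z1 = z1, z2 = z2, z3 = z3),
            class = "significance_thresholds")
}

#' Standard error of the mean across dishes
#'
#' Sample standard deviation (n - 1 denominator) divided by the square
#' root of the number of dishes.
#'
#' @param values At least two finite per-plate numbers.
#' @export
sem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || any(!is.finite(values))) {
    stop_input("sem needs >= 2 finite values")
  }
  sd(values) / sqrt(length(values))
}

#' One-sided p-value of a z score
#'
#' Upper-tail standard normal probability, `1 - pnorm(z)`.
#'
#' @param z Finite z score.
#' @export
z_to_one_sided_p <- function(z) {
  if (!is.finite(z)) stop_input("z must be finite")
  pnorm(z, lower.tail = FALSE)
}

#' Star label for an absolute z score
#'
#' Boundary handling follows the wording "less than" / "between" /
#' "greater than": `z < z1` is ns, `z1 <= z < z2` one star, `z2 <= z <= z3`
#' two stars, and three stars require strictly `z > z3`.
#'
#' @param z_abs Absolute difference in SE units (>= 0).
#' @param thresholds A [significance_thresholds()].
#' @return One of `"ns"`, `"*"`, `"**"`, `"***"`.
#' @export
assign_stars <- function(z_abs, thresholds = significance_thresholds()) {
  stopifnot(z_abs >= 0)
  if (z_abs < thresholds$z1) return("ns")
  if (z_abs < thresholds$z2) return("*")
  if (z_abs <= thresholds$z3) return("**")
  "***"
}

#' Compare two condition means by Gaussian error propagation
#'
#' The difference of means carries the propagated standard error
#' `sqrt(sem_a^2 + sem_b^2)`; the difference expressed in units of that
#' standard error (z) sets both the one-sided p-value and the star label.
#' The alternative is declared by `direction`: `"greater"` tests a > b,
#' `"less"` tests a < b. When the observed difference points away from the
#' alternative the comparison is not significant regardless of magnitude.
#'
#' @param mean_a,sem_a,mean_b,sem_b Group means and their standard errors
#'   (sems >= 0, not both 0).
#' @param direction `"greater"` or `"less"`.
#' @param thresholds A [significance_thresholds()].
#' @return A `comparison_result` list: `mean_diff`, `se_diff`, `z` (signed,
#'   a - b in SE units), `p_one_sided`, `stars`, `direction`, and
#'   `infinite_z` flagging a zero propagated error with unequal means.
#' @export
compare_groups <- function(mean_a, sem_a, mean_b, sem_b,
                           direction = c("greater", "less"),
                           thresholds = significance_thresholds()) {
  direction <- match.arg(direction)
  if (sem_a < 0 || sem_b < 0) stop_input("sems must be >= 0")
  mean_diff <- mean_a - mean_b
  se_diff <- sqrt(sem_a^2 + sem_b^2)
  infinite_z <- FALSE
  if (se_diff == 0) {
    if (mean_diff == 0) {
      z <- 0
    } else {
      infinite_z <- TRUE
      z <- sign(mean_diff) * Inf
    }
  } else {
    z <- mean_diff / se_diff
  }
  oriented <- if (direction == "greater") z else -z
  p <- if (is.infinite(oriented)) {
    if (oriented > 0) 0 else 1
  } else {
    z_to_one_sided_p(oriented)
  }
  stars <- if (oriented > 0) assign_stars(abs(z), thresholds) else "ns"
  structure(
    list(mean_diff = mean_diff, se_diff = se_diff, z = z,
         p_one_sided = p, stars = stars, direction = direction,
         infinite_z = infinite_z),
    class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("diff %.4g +/- %.4g SE, z = %.3f, one-sided p = %.4g [%s]\n",
              x$mean_diff, x$se_diff, x$z, x$p_one_sided, x$stars))
  invisible(x)
}
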