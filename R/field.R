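#' Elastic force-field parameters
#'
#' Describes one one-sided virtual spring: the field exerts an upward-resisting
#' force \eqn{F = k (y - y_0)} once the hand position `y` exceeds the field
#' boundary `y0`, and no force below it. The on/off transition is smoothed by a
#' C1 quadratic blend of half-width `w` (see [elastic_force()]). Catch trials
#' carry `is_catch = TRUE`: the rendered field is silently zeroed while the
#' scheduled (expected) `k` and `y0` are retained so that expected-field
#' quantities remain computable.
#'
#' @param k Stiffness, N/m. Must be >= 0.
#' @param y0 Field-onset (boundary) position, m above home.
#' @param w Smoothing half-width, m (default 1 mm).
#' @param is_catch Logical; catch trial (field silently disabled)?
#' @param target Target position, m; the nominal peak force is
#'   `F_max = k * (target - y0)`.
#'
#' @return An object of class `field_params`: a list with elements `k`, `y0`,
#'   `w`, `F_max`, `is_catch`, `target`.
#' @examples
#' fp <- field_params(k = 2800, y0 = 0.145)
#' fp$F_max  # 14 N at the 15-cm target
#' @export
field_params <- function(k, y0, w = 0.001, is_catch = FALSE, target = 0.15) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k < 0)
    stop("invalid field parameter: stiffness k must be a single number >= 0")
  if (!is.numeric(y0) || length(y0) != 1L || is.na(y0))
    stop("invalid field parameter: y0 must be a single number")
  if (w < 0) stop("invalid field parameter: smoothing half-width w must be >= 0")
  structure(
    list(k = k, y0 = y0, w = w, F_max = k * (target - y0),
         is_catch = isTRUE(is_catch), target = target),
    class = "field_params")
}

#' @export
print.field_params <- function(x, ...) {
  cat(sprintf("<field_params> k = %.4g N/m, y0 = %.4g cm, F_max = %.4g N%s\n",
              x$k, 100 * x$y0, x$F_max,
              if (x$is_catch) " [catch]" else ""))
  invisible(x)
}

#' Rendered elastic force at a position
#'
#' One-sided spring force with a C1 quadratic onset blend. Outside the field
#' (`y < y0 - w`) the force is zero; deep inside (`y > y0 + w`) it is
#' `k * (y - y0)`; on `[y0 - w, y0 + w]` the unique quadratic
#' `k (y - y0 + w)^2 / (4 w)` joins the two branches with continuous value and
#' slope, so the rendered force is continuously differentiable and monotone
#' non-decreasing in `y`. With `w = 0` the blend degenerates to the hinge
#' `k * max(y - y0, 0)`.
#'
#' For catch trials (`fp$is_catch`) the rendered force is identically zero;
#' use `expected = TRUE` to evaluate the scheduled (expected) field instead.
#'
#' @param y Position, m (vectorized).
#' @param fp A [field_params()] object.
#' @param expected Evaluate the scheduled field even on catch trials?
#' @return Force in N, same length as `y`.
#' @examples
#' fp <- field_params(k = 2800, y0 = 0.145, w = 0)
#' elastic_force(0.150, fp)  # 14 N
#' @export
elastic_force <- function(y, fp, expected = FALSE) {
  stopifnot(inherits(fp, "field_params"))
  if (fp$is_catch && !expected) return(rep(0, length(y)))
  k <- fp$k; y0 <- fp$y0; w <- fp$w
  if (w == 0) return(k * pmax(y - y0, 0))
  f <- numeric(length(y))
  lo <- y <= (y0 - w)
  hi <- y >= (y0 + w)
  mid <- !lo & !hi
  f[hi] <- k * (y[hi] - y0)
  f[mid] <- k * (y[mid] - y0 + w)^2 / (4 * w)
  f
}
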