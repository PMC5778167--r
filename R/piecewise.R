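#' Structural parameters of the piecewise-linear lesion model
#'
#' One lesion's longest-diameter time course is modelled as linear decay
#' from baseline until a switch point `sp` (days), then linear re-growth:
#' the re-growth phase is read as expansion of the treatment-resistant
#' clone. No sign restriction is placed on either slope: a lesion may grow
#' during the "decay" phase or shrink during "re-growth", and such
#' sign-anomalous lesions are reported downstream rather than excluded.
#'
#' @param bsl Baseline longest diameter, mm (> 0).
#' @param decay Slope before `sp`, mm/day (typically <= 0).
#' @param regrowth Slope after `sp`, mm/day (typically >= 0).
#' @param sp Switch point, days (> 0).
#' @return An object of class `piecewise_params`.
#' @export
#' @examples
#' p <- piecewise_params(bsl = 20, decay = -0.17, regrowth = 0.07, sp = 63)
#' predict_diameter(p, c(0, 42, 84, 147, 210))
piecewise_params <- function(bsl, decay, regrowth, sp) {
  stopifnot(is.numeric(bsl), is.numeric(decay), is.numeric(regrowth),
            is.numeric(sp), length(bsl) == 1L, length(decay) == 1L,
            length(regrowth) == 1L, length(sp) == 1L)
  if (!is.finite(bsl) || bsl <= 0) stop("baseline diameter `bsl` must be positive")
  if (!is.finite(sp) || sp <= 0) stop("switch point `sp` must be positive")
  structure(list(bsl = bsl, decay = decay, regrowth = regrowth, sp = sp),
            class = "piecewise_params")
}

#' @export
print.piecewise_params <- function(x, ...) {
  cat(sprintf(
    "piecewise lesion trajectory: bsl %.3g mm, decay %.4g mm/day, regrowth %.4g mm/day, switch day %g\n",
    x$bsl, x$decay, x$regrowth, x$sp))
  invisible(x)
}

#' Predict the structural (noise-free) diameter of a lesion
#'
#' Continuous parameterisation: `bsl + decay * t` for `t < sp` and
#' `bsl + decay * sp + regrowth * (t - sp)` for `t >= sp` (the boundary
#' `t = sp` belongs to the re-growth branch). Predictions may be negative;
#' clipping at 0 mm is the observation model's job ([observe_diameter()]),
#' so the fitting machinery stays linear-Gaussian.
#'
#' `form = "literal"` instead evaluates `bsl + decay * sp + regrowth * t`
#' after the switch — a parameterisation with a jump of size `regrowth * sp`
#' at `sp`, retained only for comparison with the continuous default.
#'
#' @param params A [piecewise_params()] object.
#' @param t Days since treatment start, non-negative. Vectorised.
#' @param form `"continuous"` (default) or `"literal"`.
#' @return Predicted longest diameters, mm (possibly negative).
#' @export
predict_diameter <- function(params, t, form = c("continuous", "literal")) {
  stopifnot(inherits(params, "piecewise_params"))
  form <- match.arg(form)
  if (any(!is.finite(t)) || any(t < 0)) stop("times must be non-negative")
  if (form == "continuous") {
    params$bsl + params$decay * pmin(t, params$sp) +
      params$regrowth * pmax(t - params$sp, 0)
  } else {
    ifelse(t < params$sp,
           params$bsl + params$decay * t,
           params$bsl + params$decay * params$sp + params$regrowth * t)
  }
}

#' Piecewise-linear design matrix at a fixed switch point
#'
#' Returns the 3-column basis `[1, min(t, sp), max(t - sp, 0)]` per time,
#' such that `design %*% c(bsl, decay, regrowth)` equals the continuous
#' piecewise prediction. This linearity in `(bsl, decay, regrowth)` at fixed
#' `sp` is what lets the mixed-model machinery treat the model as linear
#' apart from the log-normal baseline.
#'
#' @param times Days, sorted ascending (not enforced beyond a check).
#' @param sp Switch point, days (> 0).
#' @return Numeric matrix with columns `bsl`, `decay`, `regrowth`.
#' @export
piecewise_design <- function(times, sp) {
  if (!is.numeric(sp) || length(sp) != 1L || sp <= 0)
    stop("switch point `sp` must be a positive scalar")
  if (is.unsorted(times)) stop("`times` must be sorted ascending")
  cbind(bsl = rep(1, length(times)),
        decay = pmin(times, sp),
        regrowth = pmax(times - sp, 0))
}

#' Simulate a noisy observed diameter
#'
#' Adds independent Gaussian residual error to the structural prediction and
#' clips at 0 mm (a recorded longest diameter cannot be negative). Draws use
#' R's global RNG stream, so results are reproducible under `set.seed()`.
#'
#' @param params A [piecewise_params()] object.
#' @param t Days, vectorised.
#' @param residual_sd Residual SD in mm (>= 0).
#' @return Observed diameters, mm (>= 0), with attribute `clipped`: logical
#'   vector marking draws that were truncated at 0.
#' @export
observe_diameter <- function(params, t, residual_sd) {
  if (!is.numeric(residual_sd) || length(residual_sd) != 1L || residual_sd < 0)
    stop("`residual_sd` must be a non-negative scalar")
  mu <- predict_diameter(params, t)
  y <- mu + stats::rnorm(length(t), 0, residual_sd)
  clipped <- y < 0
  y[clipped] <- 0
  attr(y, "clipped") <- clipped
  y
}
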