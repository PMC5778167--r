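#' Growth-law parameters for the proliferating-rim model
#'
#' The structural model rests on a classical geometric argument: if tumour
#' growth is confined to an outer proliferating shell of constant thickness
#' `d_layer` whose cells double every `t_d` hours, the radius grows linearly
#' in time while the volume grows cubically. These parameters exist to make
#' that derivation executable and testable; the lesion-level analysis itself
#' works directly with linear diameter slopes.
#'
#' @param t_d Cell-cycle length in hours (> 0).
#' @param d_layer Thickness of the proliferating layer in mm (> 0).
#' @param R0 Initial radius in mm (>= 0).
#'
#' @return An object of class `growth_law_params`: a list with elements
#'   `t_d`, `a` (exponential rate `log(2)/t_d`, per hour), `d_layer`, `R0`
#'   and `thin_shell_ok` (FALSE when `d_layer >= R0`, flagging that the
#'   thin-shell assumption behind the linear law is violated).
#' @export
#' @examples
#' p <- growth_law_params(t_d = 24, d_layer = 0.1, R0 = 5)
#' radius_trajectory(p, times = c(0, 24, 48))
growth_law_params <- function(t_d, d_layer, R0) {
  stopifnot(is.numeric(t_d), length(t_d) == 1L,
            is.numeric(d_layer), length(d_layer) == 1L,
            is.numeric(R0), length(R0) == 1L)
  if (t_d <= 0) stop("cell-cycle length `t_d` must be positive")
  if (d_layer <= 0) stop("proliferating-layer thickness `d_layer` must be positive")
  if (R0 < 0) stop("initial radius `R0` must be non-negative")
  structure(
    list(t_d = t_d, a = growth_rate_from_doubling(t_d),
         d_layer = d_layer, R0 = R0,
         thin_shell_ok = d_layer < R0),
    class = "growth_law_params"
  )
}

#' @export
print.growth_law_params <- function(x, ...) {
  cat("Proliferating-rim growth law\n")
  cat(sprintf("  cell-cycle length t_d = %g h  (rate a = %.6g /h)\n", x$t_d, x$a))
  cat(sprintf("  layer thickness       = %g mm, initial radius R0 = %g mm\n",
              x$d_layer, x$R0))
  if (!x$thin_shell_ok)
    cat("  warning: layer thickness >= R0; thin-shell assumption violated\n")
  invisible(x)
}

#' Exponential growth rate from a cell-cycle length
#'
#' A population whose cells double every `t_d` hours grows as `exp(a t)`
#' with `a = log(2) / t_d`.
#'
#' @param t_d Cell-cycle (doubling) length in hours; must be positive.
#' @return Per-hour exponential rate.
#' @export
growth_rate_from_doubling <- function(t_d) {
  if (any(!is.finite(t_d)) || any(t_d <= 0))
    stop("doubling time must be positive and finite")
  log(2) / t_d
}

#' Volume of a thin proliferating shell
#'
#' Approximates the volume of a spherical shell of thickness `d_layer` at
#' radius `r` by surface area times thickness, `4 * pi * r^2 * d_layer`.
#' Accurate to relative order `d_layer / r`.
#'
#' @param r Radius in mm (> 0). Vectorised.
#' @param d_layer Shell thickness in mm (> 0).
#' @return Shell volume in mm^3.
#' @export
shell_volume <- function(r, d_layer) {
  if (any(!is.finite(r)) || any(r <= 0)) stop("radius must be positive")
  if (any(!is.finite(d_layer)) || any(d_layer <= 0))
    stop("layer thickness must be positive")
  4 * pi * r^2 * d_layer
}

#' Linear radius trajectory of the rim-growth model
#'
#' Solution of `dr/dt = a * d_layer` with `r(0) = R0`: the radius grows
#' linearly at rate `a * d_layer` (mm per hour), so the volume grows
#' cubically rather than exponentially.
#'
#' @param params A [growth_law_params()] object.
#' @param times Times in hours, non-negative. Vectorised.
#' @return Radii in mm at `times`.
#' @export
radius_trajectory <- function(params, times) {
  stopifnot(inherits(params, "growth_law_params"))
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be non-negative and finite")
  params$R0 + params$a * params$d_layer * times
}

#' Convert a radial growth rate to a diameter slope
#'
#' Lesion data are longest diameters; the mechanistic derivation is in
#' radius space. The diameter slope implied by the rim model is
#' `2 * a * d_layer` (mm per hour; multiply by 24 for mm/day).
#'
#' @param a Exponential cell growth rate, per hour.
#' @param d_layer Proliferating-layer thickness, mm.
#' @param per_day If TRUE (default) return mm/day, else mm/hour.
#' @return Diameter growth slope.
#' @export
diameter_slope <- function(a, d_layer, per_day = TRUE) {
  s <- 2 * a * d_layer
  if (per_day) s * 24 else s
}
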