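#' Marginal log-likelihood of the piecewise mixed-effects model
#'
#' Computes the log of the marginal likelihood of all observations,
#' integrating over the random effects. The normal slope effects integrate
#' out analytically into the per-unit covariance; the lesion-level
#' log-baseline deviations enter the mean non-linearly (through
#' `exp(lbsl_pop + b)`) and are integrated numerically: by a Laplace
#' approximation around the joint mode (`method = "laplace"`, the compiled
#' default), or by adaptive Gauss-Hermite quadrature (`method = "ghq"`, a
#' pure-R oracle backend feasible for units with at most 4 lesions).
#' The likelihood factorises over units (patients, or lesions under the
#' `lesion_only` hierarchy), and per-unit contributions are returned.
#'
#' @param cohort A [lesion_cohort()].
#' @param spec A [lesion_model_spec()].
#' @param theta Named parameter vector: fixed effects `lbsl_pop` (baseline
#'   on the log-mm scale), `decay_pop`, `regrowth_pop` (mm/day), and one
#'   `log_sd_*` entry per random-effect term plus `log_sd_resid` (SDs are
#'   log-parameterised, hence strictly positive; see
#'   `lesionkinetics:::theta_names`).
#' @param method `"agq"` (nested adaptive quadrature, the compiled default),
#'   `"laplace"` (the same scheme restricted to one mode-centred node per
#'   dimension — a Laplace-type approximation, cheapest), or `"ghq"` (the
#'   pure-R dense oracle).
#' @param ghq_points Nodes per dimension for `"ghq"` (default 31).
#' @param agq_inner,agq_outer Nodes for the inner (log-baseline) and outer
#'   (patient-effect) adaptive rules of `"agq"`.
#' @return Scalar log-likelihood with attribute `unit_loglik` (per-unit
#'   contributions). `NaN` (with a warning) if the inner mode search fails.
#' @export
marginal_loglik <- function(cohort, spec, theta,
                            method = c("agq", "laplace", "ghq"),
                            ghq_points = 31L,
                            agq_inner = 15L, agq_outer = 9L) {
  method <- match.arg(method)
  theta <- check_theta(theta, spec)
  pd <- prepare_pw_data(cohort, spec)
  sds <- theta_to_sds(theta, spec)
  if (method == "ghq") {
    res <- ghq_loglik(pd, sds, as.integer(ghq_points))
    return(structure(res$loglik, unit_loglik = res$unit_loglik))
  }
  if (method == "laplace") { agq_inner <- 1L; agq_outer <- 1L }
  res <- pw_loglik_cpp(pd$y, pd$x1, pd$x2, pd$lesion_ptr, pd$unit_les_ptr,
                       sds$beta0, sds$d_pop, sds$g_pop, sds$sd_b,
                       sds$sd_pd, sds$sd_pg, sds$sd_ld, sds$sd_lg,
                       sds$sd_e, as.integer(agq_inner), as.integer(agq_outer),
                       FALSE)
  if (!res$converged) {
    warning("inner mode-finding failed to converge; returning NaN")
    return(structure(NaN, unit_loglik = NULL))
  }
  structure(res$loglik, unit_loglik = res$unit_loglik)
}
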