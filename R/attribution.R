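#' @title Energy-balance attribution
#' @description Converts background-corrected albedo and latent-heat
#'   changes into equivalent LST changes through the first-order Taylor
#'   expansion of upward long-wave radiation, with sensible heat as the
#'   residual: ΔT = ΔT_α + ΔT_LE + ΔT_H.
#' @name attribution
NULL

#' Energy-balance inputs
#'
#' @param emissivity Broadband surface emissivity in (0, 1].
#' @param lst_ref Reference LST (K): the target pixel's pre-loss baseline
#'   mean.
#' @param sw_down Pre-loss mean downwelling shortwave radiation (W m-2).
#' @param lambda_v Latent heat of vaporization (J kg-1), default 2.45e6.
#' @return List of class `eb_inputs`; includes the derived Taylor
#'   `sensitivity` (K per W m-2).
#' @export
eb_inputs <- function(emissivity = 0.97, lst_ref, sw_down,
                      lambda_v = 2.45e6) {
  if (emissivity <= 0 || emissivity > 1) stop("emissivity must be in (0,1]")
  if (lst_ref <= 0) stop("reference LST must be positive")
  if (sw_down < 0) stop("sw_down must be >= 0")
  structure(list(emissivity = emissivity, lst_ref = lst_ref,
                 sw_down = sw_down, lambda_v = lambda_v,
                 sensitivity = taylor_sensitivity(emissivity, lst_ref)),
            class = "eb_inputs")
}

#' Taylor-expansion sensitivity of LST to a radiative perturbation
#'
#' First-order expansion of upward long-wave radiation εσT^4 gives
#' \deqn{\partial T / \partial R = 1 / (4 \varepsilon \sigma T^3)}
#' in K per W m-2.
#'
#' @param emissivity Broadband emissivity in (0, 1].
#' @param lst_ref Reference LST (K).
#' @return Sensitivity in K/(W m-2).
#' @examples
#' taylor_sensitivity(1, 300)    # 0.1633
#' taylor_sensitivity(0.97, 300) # 0.1684
#' @export
taylor_sensitivity <- function(emissivity, lst_ref) {
  if (any(lst_ref <= 0)) stop("reference LST must be positive")
  if (any(emissivity <= 0 | emissivity > 1))
    stop("emissivity must be in (0,1]")
  1 / (4 * emissivity * SIGMA_SB * lst_ref^3)
}

#' Convert an evapotranspiration change to a latent-heat flux change
#'
#' 1 mm of water over 10 days is 1 kg m-2 over 864000 s, so
#' \eqn{\Delta LE = \Delta ET \cdot \lambda_v / 864000} W m-2.
#'
#' @param d_et ET change in mm per 10 days.
#' @param lambda_v Latent heat of vaporization (J kg-1).
#' @return Latent-heat flux change in W m-2.
#' @examples
#' et_to_le(10) # 28.36 W m-2
#' @export
et_to_le <- function(d_et, lambda_v = 2.45e6) {
  d_et * lambda_v / 864000
}

#' Equivalent LST change from an albedo or latent-heat change
#'
#' Albedo: ΔT = sensitivity x (-SW_down x Δα); latent heat:
#' ΔT = sensitivity x (-ΔLE). Positive albedo changes cool; reduced latent
#' heat warms.
#'
#' @param delta Numeric series of Δα (unitless) or ΔLE (W m-2).
#' @param inputs An [eb_inputs()] object.
#' @param kind `"albedo"` or `"latent"`.
#' @return Equivalent LST change series (K).
#' @export
equivalent_dT <- function(delta, inputs, kind = c("albedo", "latent")) {
  kind <- match.arg(kind)
  stopifnot(inherits(inputs, "eb_inputs"))
  if (kind == "albedo") inputs$sensitivity * (-inputs$sw_down * delta)
  else inputs$sensitivity * (-delta)
}

#' Energy-balance attribution of a paired sample's response
#'
#' Applies the trend and seasonal response machinery to the albedo and ET
#' decompositions of the same paired pixels, converts the resulting Δα and
#' ΔLE changes into equivalent LST changes, and closes the budget with
#' sensible heat as the residual (never estimated from data):
#' ΔT_H = ΔT - ΔT_α - ΔT_LE, and likewise for the monthly seasonal terms.
#'
#' @param response A [response_metrics()] result for the LST pairs.
#' @param albedo_target,albedo_backgrounds Albedo decompositions of the
#'   target and background pixels (same machinery as LST).
#' @param et_target,et_backgrounds ET decompositions (mm/10 days).
#' @param window,period The sample's [loss_window()] and [study_period()].
#' @param inputs An [eb_inputs()] object.
#' @param distances,weighting Background combination, as in
#'   [delta_trend_series()].
#' @return List of class `attribution_series`: yearly `dT_alpha`, `dT_le`,
#'   `dT_h` aligned to `response$delta_t`, monthly `dS_alpha`, `dS_le`,
#'   `dS_h`, and the `sensitivity` used.
#' @export
attribute <- function(response, albedo_target, albedo_backgrounds,
                      et_target, et_backgrounds, window, period, inputs,
                      distances = NULL, weighting = c("mean", "idw")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(response, "response_metrics"))
  d_alpha <- delta_trend_series(albedo_target, albedo_backgrounds, window,
                                period, distances, weighting)
  d_et <- delta_trend_series(et_target, et_backgrounds, window, period,
                             distances, weighting)
  dT_alpha <- equivalent_dT(d_alpha$dT, inputs, "albedo")
  dT_le <- equivalent_dT(et_to_le(d_et$dT, inputs$lambda_v), inputs,
                         "latent")
  dT <- response$delta_t$dT
  s_alpha <- delta_seasonal(albedo_target, albedo_backgrounds, window,
                            distances, weighting)
  s_et <- delta_seasonal(et_target, et_backgrounds, window, distances,
                         weighting)
  dS_alpha <- equivalent_dT(s_alpha$dS, inputs, "albedo")
  dS_le <- equivalent_dT(et_to_le(s_et$dS, inputs$lambda_v), inputs,
                         "latent")
  dS <- response$delta_s$dS
  structure(
    list(year = response$delta_t$year,
         dT = dT, dT_alpha = dT_alpha, dT_le = dT_le,
         dT_h = dT - dT_alpha - dT_le,
         month = response$delta_s$month,
         dS = dS, dS_alpha = dS_alpha, dS_le = dS_le,
         dS_h = dS - dS_alpha - dS_le,
         sensitivity = inputs$sensitivity),
    class = "attribution_series")
}
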