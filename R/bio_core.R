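#' Nutrient limitation factor
#'
#' Michaelis-Menten limitation of phytoplankton growth by nitrate,
#' `f(N) = N / (K_N + N)`. Dimensionless, in `[0, 1)`, monotone increasing,
#' equal to 1/2 at `N = K_N`.
#'
#' @param N Nitrate concentration (mmol N m^-3); scalar or array, all >= 0.
#' @param p A [bio_params()] set.
#' @return Limitation factor, same shape as `N`.
#' @examples
#' nutrient_limitation(0.5, bio_params())  # 0.5 at half saturation
#' @export
nutrient_limitation <- function(N, p = bio_params()) {
  if (any(N < 0)) stop("nutrient_limitation: N must be >= 0", call. = FALSE)
  N / (p$K_N + N)
}

#' Light limitation factor
#'
#' Saturating-exponential light response `f(I) = 1 - exp(-alpha_I I)`:
#' zero in the dark, initial slope `alpha_I`, saturating to 1 at high
#' irradiance. The response is injected behind this single function; an
#' alternative form can be selected with `form` without touching callers.
#'
#' @param I Photosynthetically available radiation (W m^-2), >= 0.
#' @param p A [bio_params()] set.
#' @param form Response shape; only `"exp_saturating"` is provided.
#' @return Limitation factor in `[0, 1]`, same shape as `I`.
#' @examples
#' light_limitation(40, bio_params())  # approximately 0.699
#' @export
light_limitation <- function(I, p = bio_params(), form = "exp_saturating") {
  form <- match.arg(form)
  if (any(I < 0)) stop("light_limitation: I must be >= 0", call. = FALSE)
  1 - exp(-p$alpha_I * I)
}

#' Irradiance profile through a phytoplankton column
#'
#' Downward attenuation of surface irradiance by water and by plankton
#' self-shading: `I(z) = I_s exp(-integral_0^z (k_w + k_b P) dz')`,
#' evaluated at layer midpoints with midpoint-rule attenuation (half the
#' local layer's contribution plus the full contribution of all layers
#' above). Strictly decreasing with depth for non-negative `P`.
#'
#' @param P_column Phytoplankton concentrations per layer, surface first
#'   (mmol N m^-3).
#' @param layer_thickness Layer thicknesses (m), positive; scalar or one
#'   value per layer.
#' @param p A [bio_params()] set.
#' @return Irradiance (W m^-2) at each layer midpoint.
#' @examples
#' # pure water, 20 m: I = I_s * exp(-k_w * 20)
#' light_profile(c(0, 0), c(20, 20), bio_params())
#' @export
light_profile <- function(P_column, layer_thickness, p = bio_params()) {
  if (any(P_column < 0))
    stop("light_profile: P must be >= 0", call. = FALSE)
  n <- length(P_column)
  dz <- rep_len(layer_thickness, n)
  if (any(dz <= 0))
    stop("light_profile: layer thicknesses must be positive", call. = FALSE)
  k <- (p$k_w + p$k_b * P_column) * dz
  att <- cumsum(k) - k / 2  # attenuation down to each layer midpoint
  p$I_s * exp(-att)
}

#' Zooplankton grazing on phytoplankton and detritus
#'
#' Shared-saturation (Michaelis-Menten on total preferred food) grazing:
#' `G_P = r_Z Z a1 P / (K_Z + a1 P + a2 D)` and analogously
#' `G_D = r_Z Z a2 D / (K_Z + a1 P + a2 D)`. Total specific grazing
#' `(G_P + G_D)/Z` saturates at `r_Z`; grazing is linear in `Z` at fixed
#' food.
#'
#' @param P,D,Z Concentrations (mmol N m^-3), all >= 0; scalars or arrays
#'   of a common shape.
#' @param p A [bio_params()] set.
#' @param form Grazing shape; only `"shared_saturation"` is provided.
#' @return List with components `G_P` and `G_D` (mmol N m^-3 day^-1).
#' @examples
#' grazing(P = 1, D = 0.5, Z = 1, p = bio_params())
#' @export
grazing <- function(P, D, Z, p = bio_params(), form = "shared_saturation") {
  form <- match.arg(form)
  if (any(P < 0) || any(D < 0) || any(Z < 0))
    stop("grazing: P, D, Z must be >= 0", call. = FALSE)
  den <- p$K_Z + p$a1 * P + p$a2 * D
  list(G_P = p$r_Z * Z * p$a1 * P / den,
       G_D = p$r_Z * Z * p$a2 * D / den)
}

#' Detritus sinking velocity
#'
#' Concentration-dependent sinking speed
#' `w_D = w_Dmax D / (S_D + D)` (m day^-1): detritus sinks faster at
#' higher concentrations, saturating at `w_Dmax`.
#'
#' @param D Detritus concentration (mmol N m^-3), >= 0.
#' @param p A [bio_params()] set.
#' @return Sinking speed (m day^-1), same shape as `D`.
#' @examples
#' sinking_velocity(0.2, bio_params())  # half of w_Dmax
#' @export
sinking_velocity <- function(D, p = bio_params()) {
  if (any(D < 0)) stop("sinking_velocity: D must be >= 0", call. = FALSE)
  p$w_Dmax * D / (p$S_D + D)
}

#' Biological source-sink tendencies of the NPZD compartments
#'
#' Local (per-cell) rates of change from uptake, grazing, mortality,
#' excretion, and remineralization:
#' \deqn{dP = r_P f(N) f(I) P - G_P - m_P P}
#' \deqn{dZ = \gamma (G_P + G_D) - \mu_Z Z - m_Z Z^2}
#' \deqn{dN = -r_P f(N) f(I) P + \mu_Z Z + \epsilon D}
#' \deqn{dD = m_P P + (1-\gamma)(G_P + G_D) + \beta m_Z Z^2 - G_D - \epsilon D}
#' The tendencies close the nitrogen budget exactly:
#' `dN + dP + dZ + dD = -(1 - beta) m_Z Z^2`, the permanent loss to
#' unresolved higher predators. Sinking is handled by transport, not here.
#'
#' @param state Named list or vector with elements `N`, `P`, `Z`, `D`
#'   (mmol N m^-3), scalars or arrays of a common shape, all >= 0.
#' @param I Irradiance (W m^-2), >= 0.
#' @param p A [bio_params()] set.
#' @param fluxes If `TRUE`, attach the individual process fluxes as an
#'   attribute `"fluxes"` (uptake, G_P, G_D, mortalities, excretion,
#'   remineralization).
#' @return List with components `dN`, `dP`, `dZ`, `dD`
#'   (mmol N m^-3 day^-1).
#' @examples
#' source_terms(list(N = 1, P = 1, Z = 1, D = 1), I = 40)
#' @export
source_terms <- function(state, I, p = bio_params(), fluxes = FALSE) {
  N <- state$N; P <- state$P; Z <- state$Z; D <- state$D
  if (any(I < 0)) stop("source_terms: I must be >= 0", call. = FALSE)
  fN <- nutrient_limitation(N, p)
  fI <- light_limitation(I, p)
  U  <- p$r_P * fN * fI * P
  G  <- grazing(P, D, Z, p)
  MP <- p$m_P * P
  MZ <- p$m_Z * Z^2
  EX <- p$mu_Z * Z
  RM <- p$eps * D
  out <- list(
    dN = -U + EX + RM,
    dP = U - G$G_P - MP,
    dZ = p$gamma * (G$G_P + G$G_D) - EX - MZ,
    dD = MP + (1 - p$gamma) * (G$G_P + G$G_D) + p$beta * MZ - G$G_D - RM)
  if (fluxes)
    attr(out, "fluxes") <- list(uptake = U, G_P = G$G_P, G_D = G$G_D,
                                mort_P = MP, mort_Z = MZ, excretion = EX,
                                remin = RM)
  out
}
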