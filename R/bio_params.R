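#' Biological parameter set for the NPZD model
#'
#' Constructs the parameter set of the four-compartment nitrogen-based
#' plankton model (nutrient N, phytoplankton P, zooplankton Z, detritus D).
#' Defaults are the winter Alboran Sea calibration: a single diatom-like
#' phytoplankton group adapted to high-nutrient, low-light conditions, with
#' temperature effects folded into a reduced maximum growth rate rather than
#' an explicit temperature response.
#'
#' All rates are expressed per day; concentrations in mmol N m^-3.
#'
#' @param r_P Maximum phytoplankton growth rate (day^-1).
#' @param m_P Phytoplankton linear mortality rate (day^-1).
#' @param m_Z Quadratic zooplankton mortality coefficient
#'   (day^-1 (mmol N m^-3)^-1). Represents natural mortality plus predation
#'   by unresolved higher trophic levels (model closure).
#' @param mu_Z Zooplankton excretion rate (day^-1).
#' @param gamma Assimilation efficiency of grazing (dimensionless, 0-1).
#' @param beta Fraction of quadratic zooplankton mortality recycled to
#'   detritus; the remaining (1 - beta) is permanently removed from the
#'   modelled nitrogen pool (higher-predator export).
#' @param eps Detritus remineralization rate (day^-1).
#' @param K_N Half-saturation constant for nitrate uptake (mmol N m^-3).
#' @param alpha_I Initial slope of the light limitation curve ((W m^-2)^-1).
#' @param k_w Background light extinction coefficient (m^-1).
#' @param k_b Biogenic (self-shading) extinction coefficient
#'   (mmol N^-1 m^2).
#' @param I_s Surface photosynthetically available radiation (W m^-2);
#'   the winter-mean value, half of the short-wave flux.
#' @param r_Z Maximum zooplankton grazing rate (day^-1).
#' @param K_Z Half-saturation constant of zooplankton grazing
#'   (mmol N m^-3).
#' @param a1 Food preference of zooplankton for phytoplankton
#'   (dimensionless, 0-1).
#' @param a2 Food preference of zooplankton for detritus
#'   (dimensionless, 0-1).
#' @param S_D Half-saturation constant of the detritus sinking-speed curve
#'   (mmol N m^-3).
#' @param w_Dmax Maximum detritus sinking velocity (m day^-1).
#'
#' @return An object of class `bio_params`: a named list of the 18
#'   constants, validated.
#' @examples
#' p <- bio_params()
#' p$r_P
#' bio_params(r_P = 1.0)$r_P
#' @export
bio_params <- function(r_P = 1.3, m_P = 0.06, m_Z = 0.10, mu_Z = 0.05,
                       gamma = 0.7, beta = 0.5, eps = 0.25, K_N = 0.5,
                       alpha_I = 0.03, k_w = 0.05, k_b = 0.04, I_s = 40,
                       r_Z = 0.5, K_Z = 0.5, a1 = 1.0, a2 = 0.5,
                       S_D = 0.2, w_Dmax = 8.0) {
  p <- list(r_P = r_P, m_P = m_P, m_Z = m_Z, mu_Z = mu_Z, gamma = gamma,
            beta = beta, eps = eps, K_N = K_N, alpha_I = alpha_I,
            k_w = k_w, k_b = k_b, I_s = I_s, r_Z = r_Z, K_Z = K_Z,
            a1 = a1, a2 = a2, S_D = S_D, w_Dmax = w_Dmax)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("bio_params: '", nm, "' must be a finite numeric scalar",
           call. = FALSE)
    if (v < 0)
      stop("bio_params: '", nm, "' must be non-negative", call. = FALSE)
  }
  for (nm in c("gamma", "beta", "a1", "a2")) {
    if (p[[nm]] > 1)
      stop("bio_params: '", nm, "' must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "bio_params")
}

#' @export
print.bio_params <- function(x, ...) {
  cat("NPZD biological parameters (rates day^-1, conc. mmol N m^-3):\n")
  v <- unlist(x)
  print(v)
  invisible(x)
}

# Vector of parameters in the fixed order expected by the C++ kernel.
bio_params_vector <- function(p) {
  stopifnot(inherits(p, "bio_params"))
  unlist(p[c("r_P", "m_P", "m_Z", "mu_Z", "gamma", "beta", "eps", "K_N",
             "alpha_I", "k_w", "k_b", "I_s", "r_Z", "K_Z", "a1", "a2",
             "S_D", "w_Dmax")])
}
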