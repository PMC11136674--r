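# Generalized plate model of leaf optical properties.
#
# A leaf is modelled as a pile of N identical absorbing plates separated by
# N-1 air gaps. Per wavelength:
#   * the per-layer absorption coefficient k is the concentration-weighted
#     sum of constituent specific absorption coefficients divided by N;
#   * the isotropic-beam transmission factor through one plate thickness is
#     theta(k) = (1-k) exp(-k) + k^2 E1(k) (exponential integral);
#   * interface reflectivities come from unpolarized Fresnel coefficients
#     averaged over an incidence cone (40 deg for the leaf's upper surface,
#     90 deg for internal diffuse incidence);
#   * the top plate and a substack of N-1 inner plates are combined with
#     the Stokes solution of the multiple-reflection system, with
#     non-integer N handled through fractional exponents.

#' Leaf biochemistry for the plate model
#'
#' @param N_layers Effective number of elementary layers (>= 1, may be
#'   fractional).
#' @param chlorophyll,carotenoids,anthocyanins Pigment contents, ug cm-2.
#' @param water_ewt Equivalent water thickness, g cm-2.
#' @param dry_mass_lma Leaf dry mass per area, g cm-2 (mode `"D"`).
#' @param protein,cbc Protein and carbon-based-constituent contents, g cm-2
#'   (mode `"PRO"`, where they replace `dry_mass_lma`).
#' @return An object of class `crt_leaf_biochem`.
#' @export
leaf_biochemistry <- function(N_layers = 1.5, chlorophyll = 40,
                              carotenoids = 10, anthocyanins = 1,
                              water_ewt = 0.015, dry_mass_lma = 0.009,
                              protein = 0, cbc = 0) {
  vals <- c(chlorophyll, carotenoids, anthocyanins, water_ewt,
            dry_mass_lma, protein, cbc)
  if (any(vals < 0)) stop("constituent concentrations must be >= 0")
  if (N_layers < 1) stop("N_layers must be >= 1")
  structure(list(N_layers = N_layers, chlorophyll = chlorophyll,
                 carotenoids = carotenoids, anthocyanins = anthocyanins,
                 water_ewt = water_ewt, dry_mass_lma = dry_mass_lma,
                 protein = protein, cbc = cbc),
            class = "crt_leaf_biochem")
}

#' Per-layer absorption coefficient spectrum
#'
#' `k(lambda) = sum_i C_i K_i(lambda) / N_layers`. In mode `"D"` the dry
#' matter term uses `dry_mass_lma`; in mode `"PRO"` it is replaced by the
#' protein and carbon-based-constituent terms.
#'
#' @param bio A [leaf_biochemistry()].
#' @param tables Coefficient tables (see
#'   [synthetic_prospect_coefficients()]).
#' @param mode `"D"` or `"PRO"`.
#' @return A `crt_spectrum` of dimensionless per-layer absorption.
#' @export
layer_absorption <- function(bio, tables = synthetic_prospect_coefficients(),
                             mode = c("D", "PRO")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bio, "crt_leaf_biochem"))
  validate_absorption_tables(tables)
  k <- bio$chlorophyll * tables$k_chl +
    bio$carotenoids * tables$k_car +
    bio$anthocyanins * tables$k_anth +
    bio$water_ewt * tables$k_water
  k <- k + if (mode == "D") bio$dry_mass_lma * tables$k_dry
           else bio$protein * tables$k_protein + bio$cbc * tables$k_cbc
  spectrum(tables$wavelength_nm, k / bio$N_layers)
}

# Isotropic-beam transmission factor through one plate: theta(k).
# theta(0) = 1; decreasing in k.
absorption_factor <- function(k) {
  out <- numeric(length(k))
  z <- k <= 0
  out[z] <- 1
  kp <- k[!z]
  if (length(kp)) out[!z] <- (1 - kp) * exp(-kp) + kp^2 * pracma::expint(kp)
  pmin(pmax(out, 0), 1)
}

# Unpolarized Fresnel transmittance air -> medium n at incidence theta (rad).
fresnel_t <- function(theta, n) {
  ct <- cos(theta)
  st <- sin(theta)
  stt <- st / n
  ctt <- sqrt(pmax(0, 1 - stt^2))
  rs <- ((ct - n * ctt) / (ct + n * ctt))^2
  rp <- ((n * ct - ctt) / (n * ct + ctt))^2
  1 - (rs + rp) / 2
}

#' Interface transmissivity averaged over an incidence cone
#'
#' Average of the unpolarized Fresnel transmittance from air into a medium
#' of refractive index `n`, weighted by the projected solid angle over
#' incidence angles `0..alpha_deg` (fixed 64-point Gauss-Legendre
#' quadrature). `alpha_deg = 90` gives the diffuse (hemispherical) average
#' used for internal interfaces.
#'
#' @param alpha_deg Maximum incidence angle, degrees, in (0, 90].
#' @param n Refractive index (vectorized), > 1.
#' @return Average transmissivity in `[0,1]`.
#' @export
tav_interface <- function(alpha_deg, n) {
  if (alpha_deg <= 0 || alpha_deg > 90) stop("alpha_deg must be in (0, 90]")
  if (any(n <= 1)) stop("refractive index must be > 1")
  a <- alpha_deg * pi / 180
  gl <- pracma::gaussLegendre(64, 0, a)
  # weight sin(t)cos(t) dt, normalized by sin^2(a)/2
  num <- rep(0, length(n))
  for (i in seq_along(gl$x)) {
    th <- gl$x[i]
    num <- num + gl$w[i] * fresnel_t(th, n) * sin(th) * cos(th)
  }
  num / (sin(a)^2 / 2)
}

#' Reflectance and transmittance of a single plate
#'
#' One absorbing plate with Fresnel interfaces: radiation enters the top
#' interface through an incidence cone of half-angle `alpha_deg` and
#' traverses the plate as an isotropic beam; internal reflections use the
#' diffuse (90 deg) interface averages.
#'
#' @param k Per-layer absorption (vectorized over wavelength), >= 0.
#' @param n_refr Refractive index (same length or scalar), > 1.
#' @param alpha_deg Incidence cone half-angle, degrees; 40 for the upper
#'   leaf surface, 90 for plates inside the stack.
#' @return `list(R1=, T1=)`, each in `[0,1]` with `R1 + T1 <= 1`.
#' @export
plate_rt <- function(k, n_refr, alpha_deg = 40) {
  if (any(k < 0)) stop("absorption k must be >= 0")
  theta <- absorption_factor(k)
  talf <- tav_interface(alpha_deg, n_refr)
  ralf <- 1 - talf
  t12 <- tav_interface(90, n_refr)
  t21 <- t12 / n_refr^2
  r21 <- 1 - t21
  denom <- 1 - r21^2 * theta^2
  T1 <- talf * theta * t21 / denom
  R1 <- ralf + r21 * theta * T1
  if (any(R1 < -1e-12 | R1 > 1 + 1e-12 | T1 < -1e-12 | T1 > 1 + 1e-12 |
          R1 + T1 > 1 + 1e-9)) {
    stop("plate model produced non-physical reflectance/transmittance")
  }
  list(R1 = pmin(pmax(R1, 0), 1), T1 = pmin(pmax(T1, 0), 1))
}

#' Stack of N identical plates (Stokes system)
#'
#' Reflectance and transmittance of a pile of `N_layers` identical plates
#' (air gaps between plates), each with single-plate values `(R1, T1)`.
#' Non-integer `N_layers` uses the standard fractional-exponent form of the
#' Stokes solution.
#'
#' @param R1,T1 Single-plate reflectance/transmittance (vectorized).
#' @param N_layers Number of plates, >= 0 (0 returns the empty stack:
#'   R = 0, T = 1).
#' @return `list(R=, T=)`.
#' @export
stack_layers <- function(R1, T1, N_layers) {
  if (N_layers < 0) stop("N_layers must be >= 0")
  if (any(R1 < 0 | T1 < 0)) stop("R1 and T1 must be >= 0")
  if (any(R1 + T1 > 1 + 1e-9)) stop("degenerate input: R1 + T1 > 1")
  m <- length(R1)
  if (length(T1) != m) stop("R1 and T1 length mismatch")
  R <- numeric(m); Tt <- numeric(m)
  if (N_layers == 0) return(list(R = R, T = rep(1, m)))

  cons <- abs(R1 + T1 - 1) < 1e-12 & R1 > 0   # conservative (non-absorbing)
  zr <- R1 <= 1e-14                            # non-reflecting
  zt <- T1 <= 1e-14 & !zr                      # opaque
  gen <- !(cons | zr | zt)

  # non-reflecting: plain attenuation
  R[zr] <- 0
  Tt[zr] <- T1[zr]^N_layers
  # opaque: only the first surface reflects
  R[zt] <- R1[zt]
  Tt[zt] <- 0
  # conservative limit of the Stokes solution
  if (any(cons)) {
    r <- R1[cons]
    R[cons] <- N_layers * r / (1 + (N_layers - 1) * r)
    Tt[cons] <- (1 - r) / (1 + (N_layers - 1) * r)
  }
  if (any(gen)) {
    r <- R1[gen]; t <- T1[gen]
    D <- sqrt(pmax(0, (1 + r + t) * (1 + r - t) * (1 - r + t) * (1 - r - t)))
    a <- (1 + r^2 - t^2 + D) / (2 * r)
    b <- (1 - r^2 + t^2 + D) / (2 * t)
    bN <- b^N_layers
    bN2 <- bN^2
    a2 <- a^2
    denom <- a2 * bN2 - 1
    R[gen] <- a * (bN2 - 1) / denom
    Tt[gen] <- bN * (a2 - 1) / denom
  }
  if (any(R < -1e-12 | Tt < -1e-12 | R + Tt > 1 + 1e-9)) {
    stop("layer stacking produced non-physical values")
  }
  list(R = pmin(pmax(R, 0), 1), T = pmin(pmax(Tt, 0), 1))
}

#' Leaf reflectance and transmittance spectra from biochemistry
#'
#' Full 400--2500 nm hemispherical reflectance and transmittance of a leaf,
#' composed per wavelength from [layer_absorption()], [plate_rt()] (top
#' plate at `alpha_deg`, inner plates at 90 deg) and [stack_layers()] for
#' the `N_layers - 1` inner plates.
#'
#' @inheritParams layer_absorption
#' @param alpha_deg Incidence cone half-angle for the upper leaf surface.
#' @return `list(rho=, tau=)` of `crt_spectrum` objects.
#' @export
prospect <- function(bio, tables = synthetic_prospect_coefficients(),
                     mode = c("D", "PRO"), alpha_deg = 40) {
  mode <- match.arg(mode)
  kspec <- layer_absorption(bio, tables, mode)
  k <- kspec$values
  n <- tables$n
  top <- plate_rt(k, n, alpha_deg)
  inner <- plate_rt(k, n, 90)
  sub <- stack_layers(inner$R1, inner$T1, bio$N_layers - 1)
  denom <- 1 - sub$R * inner$R1
  rho <- top$R1 + top$T1 * sub$R * inner$T1 / denom
  tau <- top$T1 * sub$T / denom
  list(rho = spectrum(tables$wavelength_nm, pmin(pmax(rho, 0), 1)),
       tau = spectrum(tables$wavelength_nm, pmin(pmax(tau, 0), 1)))
}
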