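# Synthetic absorption / refractive-index tables for the leaf plate model.
#
# These tables are SYNTHETIC: they are generated programmatically to emulate
# the qualitative shape of published leaf-optics calibrations (pigment
# absorption in the visible, water bands near 1450 and 1940 nm, dry-matter /
# protein / carbon-based-constituent features in the SWIR, refractive index
# decreasing slowly from ~1.52 to ~1.40), not copied from any published
# coefficient set. All structural guarantees of the plate model
# (conservation, monotonicity, limits) hold for any physically plausible
# table; tests that compare against a reference implementation use these
# same tables on both sides.

gauss_bump <- function(wl, center, width, height) {
  height * exp(-((wl - center) / width)^2)
}

#' Synthetic leaf-optics coefficient tables
#'
#' Per-wavelength refractive index `n` and specific absorption coefficients
#' for each leaf constituent on the 400--2500 nm grid at 1-nm spacing.
#' Units match the biochemistry inputs of [leaf_biochemistry()]:
#' cm2 ug-1 for pigments (chlorophyll, carotenoids, anthocyanins) and
#' cm2 g-1 for water, dry mass, protein and carbon-based constituents.
#'
#' The tables are synthetic (see source comments); swap in measured tables
#' with the same column layout to reproduce a published calibration.
#'
#' @return A data.frame with columns `wavelength_nm`, `n`, `k_chl`, `k_car`,
#'   `k_anth`, `k_water`, `k_dry`, `k_protein`, `k_cbc`.
#' @export
synthetic_prospect_coefficients <- function() {
  wl <- as.numeric(crt_grid())
  n <- 1.52 - 0.12 * (wl - 400) / 2100 +
    0.015 * exp(-((wl - 1900) / 220)^2)  # mild dispersion near the water band

  k_chl <- gauss_bump(wl, 430, 28, 0.055) + gauss_bump(wl, 680, 22, 0.045) +
    gauss_bump(wl, 620, 60, 0.012) + gauss_bump(wl, 460, 40, 0.020)
  k_chl[wl > 760] <- 0

  k_car <- gauss_bump(wl, 450, 32, 0.060) + gauss_bump(wl, 480, 25, 0.045)
  k_car[wl > 560] <- 0

  k_anth <- gauss_bump(wl, 545, 35, 0.040)
  k_anth[wl > 650] <- 0

  k_water <- gauss_bump(wl, 1200, 45, 4) + gauss_bump(wl, 1450, 45, 30) +
    gauss_bump(wl, 1940, 60, 110) + gauss_bump(wl, 2500, 180, 45) +
    gauss_bump(wl, 980, 30, 0.6)
  k_water[wl < 900] <- 0

  k_dry <- 1.2 + gauss_bump(wl, 1730, 60, 14) + gauss_bump(wl, 2100, 80, 26) +
    gauss_bump(wl, 2300, 90, 30)

  k_protein <- 0.8 + gauss_bump(wl, 2055, 55, 40) + gauss_bump(wl, 2170, 50, 35)
  k_cbc <- 1.0 + gauss_bump(wl, 1730, 55, 22) + gauss_bump(wl, 2270, 70, 38) +
    gauss_bump(wl, 2100, 70, 18)

  data.frame(wavelength_nm = wl, n = n, k_chl = k_chl, k_car = k_car,
             k_anth = k_anth, k_water = k_water, k_dry = k_dry,
             k_protein = k_protein, k_cbc = k_cbc)
}

#' Read / write coefficient tables as delimited text
#'
#' Tab-separated with a header line; columns as in
#' [synthetic_prospect_coefficients()].
#' @param path File path.
#' @export
read_absorption_tables <- function(path) {
  d <- utils::read.table(path, header = TRUE, comment.char = "#")
  validate_absorption_tables(d)
  d
}

#' @param tables Coefficient data.frame.
#' @rdname read_absorption_tables
#' @export
write_absorption_tables <- function(tables, path) {
  utils::write.table(tables, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_absorption_tables <- function(tables) {
  need <- c("wavelength_nm", "n", "k_chl", "k_car", "k_anth", "k_water",
            "k_dry", "k_protein", "k_cbc")
  if (!all(need %in% names(tables))) {
    stop("coefficient tables missing columns: ",
         paste(setdiff(need, names(tables)), collapse = ", "))
  }
  if (any(tables$n <= 1)) stop("refractive index must be > 1")
  kk <- as.matrix(tables[, setdiff(need, c("wavelength_nm", "n"))])
  if (any(kk < 0)) stop("absorption coefficients must be >= 0")
  if (min(tables$wavelength_nm) > 400 || max(tables$wavelength_nm) < 2500) {
    stop("tables must cover 400-2500 nm")
  }
  invisible(tables)
}
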