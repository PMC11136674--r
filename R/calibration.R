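# Camera spectral response calibration from a color target.
#
# A real camera images a reference color board under a known illuminant in
# open surroundings; each patch's normalized image value then equals its
# camera-weighted reflectivity rho_o. Given the patch reflectance spectra
# and the illuminant, the effective per-channel response C_lambda is
# recovered by bounded least squares on the patch values over a smooth
# non-negative bump basis. The same machinery runs in "no-target" mode by
# supplying user-chosen patch values instead of measured ones, which
# designs a new simulated camera response without a physical camera.

#' Reference color target
#'
#' @param patches Named list of patch reflectance spectra (`crt_spectrum`,
#'   values in `[0,1]`; transmissivity is taken as 0).
#' @return An object of class `crt_color_target`.
#' @export
color_target <- function(patches) {
  if (length(patches) < 3L) {
    stop("a meaningful color target needs >= 3 spectrally distinct patches")
  }
  if (is.null(names(patches)) || any(!nzchar(names(patches)))) {
    stop("patches must be named")
  }
  for (p in patches) {
    stopifnot(is_spectrum(p))
    if (any(p$values > 1)) stop("patch reflectance must be <= 1")
  }
  structure(list(patches = patches), class = "crt_color_target")
}

#' Synthetic 18-patch color board
#'
#' Smooth, spectrally diverse reflectance patches built from Gaussian
#' mixtures over 400--750 nm: saturated hues, pastels and a gray ramp,
#' emulating the layout of a commercial color calibration card.
#'
#' @param seed Seed for the mixture draws.
#' @param n_patches Number of patches.
#' @return A [color_target()].
#' @export
synthetic_color_board <- function(seed = 42L, n_patches = 18L) {
  wl <- seq(400, 750, by = 5)
  with_seed(seed, {
    patches <- list()
    n_gray <- max(2L, n_patches %/% 6L)
    grays <- seq(0.05, 0.95, length.out = n_gray)
    for (i in seq_len(n_gray)) {
      patches[[sprintf("gray_%02d", i)]] <- spectrum(wl, rep(grays[i], length(wl)))
    }
    for (i in seq_len(n_patches - n_gray)) {
      base <- stats::runif(1, 0.02, 0.15)
      k <- sample(1:3, 1)
      v <- rep(base, length(wl))
      for (j in seq_len(k)) {
        v <- v + stats::runif(1, 0.2, 0.8) *
          exp(-((wl - stats::runif(1, 410, 740)) / stats::runif(1, 25, 90))^2)
      }
      patches[[sprintf("hue_%02d", i)]] <- spectrum(wl, pmin(v, 1))
    }
    color_target(patches)
  })
}

#' Predicted patch image values
#'
#' The model-side of the calibration: per patch and channel, the
#' camera-weighted reflectivity `rho_o` under illuminant `S` for the
#' channel's band and response.
#'
#' @param target A [color_target()].
#' @param S Illuminant spectrum.
#' @param responses Named list (per channel) of response spectra, or
#'   `NULL` entries for full sensitivity.
#' @param bands Named list (per channel) of [waveband()].
#' @return Matrix `patches x channels`.
#' @export
predict_patch_values <- function(target, S, responses, bands) {
  stopifnot(inherits(target, "crt_color_target"))
  channels <- names(bands)
  out <- matrix(0, length(target$patches), length(channels),
                dimnames = list(names(target$patches), channels))
  zero_tau <- constant_spectrum(0)
  for (ch in channels) {
    for (i in seq_along(target$patches)) {
      out[i, ch] <- band_camera_props(target$patches[[i]], zero_tau,
                                      responses[[ch]], S, bands[[ch]])$rho_o
    }
  }
  out
}

#' Response model: smooth non-negative bump basis
#'
#' `n_basis` Gaussian bumps with centers spread across `range`, normalized
#' pointwise to a partition of unity so any coefficient vector in `[0,1]`
#' reconstructs a response in `[0,1]` by construction. Smoothness is
#' encouraged by a squared second-difference penalty on the coefficients.
#'
#' @param n_basis Bumps per channel.
#' @param range Wavelength range covered, nm.
#' @param smoothness Penalty weight.
#' @param step Evaluation grid step, nm.
#' @return An object of class `crt_response_model` with the basis matrix.
#' @export
response_model <- function(n_basis = 12L, range = c(400, 750),
                           smoothness = 1e-3, step = 2) {
  wl <- seq(range[1], range[2], by = step)
  centers <- seq(range[1], range[2], length.out = n_basis)
  sigma <- diff(centers[1:2])
  B <- sapply(centers, function(c0) exp(-((wl - c0) / sigma)^2))
  B <- B / rowSums(B)   # partition of unity
  structure(list(wavelengths_nm = wl, basis = B, centers = centers,
                 n_basis = as.integer(n_basis), smoothness = smoothness),
            class = "crt_response_model")
}

#' Reconstruct a response spectrum from model coefficients
#'
#' @param model A [response_model()].
#' @param coef Coefficient vector in `[0,1]`.
#' @return A `crt_spectrum`.
#' @export
response_from_coef <- function(model, coef) {
  stopifnot(length(coef) == model$n_basis)
  spectrum(model$wavelengths_nm,
           pmin(pmax(as.numeric(model$basis %*% coef), 0), 1))
}

#' Fit the effective camera spectral response
#'
#' Box-constrained least squares per channel: minimize the squared error
#' between predicted patch values (rho_o of each patch through the
#' candidate response) and the measured values, plus
#' `smoothness * sum(diff(coef, differences = 2)^2)`. The predicted values
#' are linear in the coefficients, so the quadratic objective is solved by
#' L-BFGS-B with analytic gradients from a deterministic start.
#'
#' @param measured Matrix `patches x channels` of observed normalized image
#'   values in `[0,1]` (rows matching `target`).
#' @param target A [color_target()].
#' @param S Illuminant spectrum.
#' @param bands Named per-channel list of [waveband()].
#' @param model A [response_model()].
#' @param seed Seed (jitters the start; the quadratic problem makes the
#'   solution start-independent in practice).
#' @return An object of class `crt_response_fit`: per-channel `coef`,
#'   `responses` (spectra), fitted `predicted` values, `r2`, and
#'   per-channel optimizer diagnostics.
#' @export
fit_response <- function(measured, target, S, bands,
                         model = response_model(), seed = 1L) {
  stopifnot(inherits(target, "crt_color_target"))
  measured <- as.matrix(measured)
  if (any(!is.finite(measured)) || any(measured < 0 | measured > 1)) {
    stop("measured values must be finite and in [0,1]")
  }
  np <- length(target$patches)
  if (nrow(measured) != np) stop("measured rows must match target patches")
  channels <- names(bands)
  if (is.null(channels)) stop("bands must be a named per-channel list")
  if (np < model$n_basis) {
    warning("fewer patches than basis functions; regularization dominates")
  }
  # design matrix per channel: A[i, j] = rho_o of patch i through bump j
  zero_tau <- constant_spectrum(0)
  design <- function(ch) {
    A <- matrix(0, np, model$n_basis)
    for (j in seq_len(model$n_basis)) {
      Bj <- spectrum(model$wavelengths_nm, model$basis[, j])
      for (i in seq_len(np)) {
        A[i, j] <- band_camera_props(target$patches[[i]], zero_tau, Bj, S,
                                     bands[[ch]])$rho_o
      }
    }
    A
  }
  # spectrally identical patches make the fit non-identifiable
  pv <- sapply(target$patches, function(p) {
    spec_at(p, model$wavelengths_nm)
  })
  if (max(stats::dist(t(pv))) < 1e-9) {
    warning("all patches are spectrally identical; response is not identifiable")
  }
  D2 <- diff(diag(model$n_basis), differences = 2)
  P <- model$smoothness * crossprod(D2)
  fits <- list()
  for (ch in channels) {
    A <- design(ch)
    m <- measured[, ch]
    obj <- function(x) sum((A %*% x - m)^2) + drop(t(x) %*% P %*% x)
    grad <- function(x) as.numeric(2 * crossprod(A, A %*% x - m) + 2 * P %*% x)
    x0 <- with_seed(stream_seed(seed, 1L, match(ch, channels)),
                    stats::runif(model$n_basis, 0.3, 0.7))
    opt <- stats::optim(x0, obj, grad, method = "L-BFGS-B",
                        lower = rep(0, model$n_basis),
                        upper = rep(1, model$n_basis),
                        control = list(maxit = 500, factr = 1e4))
    if (opt$convergence != 0 && opt$convergence != 1) {
      stop("response fit failed for channel ", ch, ": ", opt$message)
    }
    fits[[ch]] <- opt
  }
  coefs <- lapply(fits, function(f) f$par)
  responses <- lapply(coefs, function(cf) response_from_coef(model, cf))
  predicted <- predict_patch_values(target, S, responses, bands)
  structure(list(coef = coefs, responses = responses, predicted = predicted,
                 measured = measured,
                 r2 = calibration_r2(measured, predicted),
                 model = model, diagnostics = fits),
            class = "crt_response_fit")
}

#' @export
print.crt_response_fit <- function(x, ...) {
  cat(sprintf("<crt_response_fit> %d channels, patch-value R^2 = %.4f\n",
              length(x$coef), x$r2))
  invisible(x)
}

#' Coefficient of determination for calibrated patch values
#'
#' R^2 across all patch x channel values:
#' `1 - sum((m - p)^2) / sum((m - mean(m))^2)`.
#'
#' @param measured,predicted Matching numeric matrices or vectors.
#' @return R^2 (can be negative for a fit worse than the mean).
#' @export
calibration_r2 <- function(measured, predicted) {
  m <- as.numeric(measured); p <- as.numeric(predicted)
  if (length(m) != length(p)) stop("measured and predicted sizes differ")
  if (length(m) < 2L) stop("need at least 2 values for R^2")
  ss_tot <- sum((m - mean(m))^2)
  if (ss_tot == 0) {
    return(if (sum((m - p)^2) == 0) 1 else -Inf)
  }
  1 - sum((m - p)^2) / ss_tot
}
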