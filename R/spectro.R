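#' Fit a pKa from a pH titration of the anionic band
#'
#' Least-squares fit of the single-site Henderson-Hasselbalch form
#' `A(pH) = A_an / (1 + 10^(pKa - pH))`, optionally with an additive
#' acid-limb baseline. The absorbance of the anionic chromophore band rises
#' with pH; the pKa is the pH of half-maximal absorbance.
#'
#' @param curve a `titration_curve` or data frame with columns `pH` and
#'   `absorbance`.
#' @param baseline fit an additive baseline term.
#' @return an object of class `pka_fit` with `pKa`, its standard error and
#'   the fitted plateau `a_max`.
#' @export
fit_pka <- function(curve, baseline = FALSE) {
  df <- as.data.frame(curve)
  if (!all(c("pH", "absorbance") %in% names(df))) {
    stop("curve must have columns pH and absorbance")
  }
  if (nrow(df) < 5) stop("need at least 5 titration points")
  a <- df$absorbance; ph <- df$pH
  amax0 <- max(a)
  if (amax0 <= 0 || (max(a) - min(a)) < 0.2 * amax0 || min(a) > 0.5 * amax0) {
    stop("no protonation transition within the pH range")
  }
  # init pKa: pH where the curve crosses half of the plateau
  half <- amax0 / 2
  i <- which(a >= half)[1]
  pka0 <- if (i > 1) {
    ph[i - 1] + (half - a[i - 1]) / (a[i] - a[i - 1]) * (ph[i] - ph[i - 1])
  } else ph[1]
  fml <- if (baseline) absorbance ~ b + a_max / (1 + 10^(pKa - pH))
         else absorbance ~ a_max / (1 + 10^(pKa - pH))
  start <- list(a_max = amax0, pKa = pka0)
  if (baseline) start$b <- min(a)
  fit <- tryCatch(
    minpack.lm::nlsLM(fml, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("pKa fit failed: ", conditionMessage(e),
                             call. = FALSE))
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (cf[["pKa"]] < min(ph) || cf[["pKa"]] > max(ph)) {
    stop("fitted pKa falls outside the titrated pH range")
  }
  structure(list(pKa = cf[["pKa"]], se = se[["pKa"]],
                 a_max = cf[["a_max"]],
                 baseline = if (baseline) cf[["b"]] else 0,
                 data = df, nls = fit),
            class = "pka_fit")
}

#' @export
print.pka_fit <- function(x, ...) {
  cat(sprintf("Henderson-Hasselbalch fit: pKa = %.3f +/- %.3f (A_an = %.3g)\n",
              x$pKa, x$se, x$a_max))
  invisible(x)
}

#' @export
coef.pka_fit <- function(object, ...) {
  c(pKa = object$pKa, a_max = object$a_max)
}

#' @export
predict.pka_fit <- function(object, newdata = NULL, ...) {
  ph <- if (is.null(newdata)) object$data$pH
        else if (is.numeric(newdata)) newdata
        else newdata$pH
  object$baseline + object$a_max / (1 + 10^(object$pKa - ph))
}

#' @export
plot.pka_fit <- function(x, ...) {
  graphics::plot(x$data$pH, x$data$absorbance, pch = 16,
                 xlab = "pH", ylab = "absorbance (a.u.)",
                 main = "anionic-band titration", ...)
  ph <- seq(min(x$data$pH), max(x$data$pH), length.out = 200)
  graphics::lines(ph, predict(x, ph), col = 2, lwd = 2)
  graphics::abline(v = x$pKa, lty = 2)
  invisible(x)
}

#' Extinction coefficient of the red form from paired absorbance changes
#'
#' Photoconversion consumes the green band and produces the red band;
#' assuming no photodestruction, the red-form extinction coefficient is the
#' ratio of the red-band absorbance increase to the green-band decrease,
#' multiplied by the green-form extinction coefficient:
#' `eps_R = (dA_R / |dA_G|) * eps_G`.
#'
#' @param pair a `spectrum_pair` (see [gen_spectra_pair()]) or list with
#'   `delta_green` (< 0) and `delta_red` (>= 0).
#' @param eps_green green-form extinction coefficient (any unit; the result
#'   is in the same unit).
#' @return the red-form extinction coefficient.
#' @export
epsilon_red <- function(pair, eps_green) {
  dg <- pair$delta_green; dr <- pair$delta_red
  if (is.null(dg) || is.null(dr)) {
    stop("pair must provide delta_green and delta_red")
  }
  if (dg >= 0) stop("delta_green must be negative")
  if (dr < 0) stop("delta_red must be >= 0")
  if (eps_green <= 0) stop("eps_green must be positive")
  (dr / abs(dg)) * eps_green
}

#' Relative fluorescence quantum yield from dilution series
#'
#' For each dilution series the area under the corrected emission spectrum
#' is regressed on the absorbance at the excitation wavelength through the
#' origin (zero absorbance implies zero emission); the quantum yield is the
#' reference yield scaled by the ratio of the slopes.
#'
#' @param sample_series data frame with columns `absorbance`, `area`
#'   (>= 3 dilutions, absorbance not exceeding 0.1).
#' @param ref_series same, for the reference fluorophore.
#' @param phi_ref quantum yield of the reference.
#' @return the sample quantum yield.
#' @export
relative_qy <- function(sample_series, ref_series, phi_ref) {
  slope <- function(df, what) {
    if (!all(c("absorbance", "area") %in% names(df))) {
      stop(what, " must have columns absorbance and area")
    }
    if (nrow(df) < 3) stop(what, " needs at least 3 dilutions")
    if (any(df$absorbance > 0.1)) {
      warning(what, ": absorbance exceeds 0.1; inner-filter bias likely")
    }
    unname(stats::coef(stats::lm(area ~ 0 + absorbance, data = df))[1])
  }
  s_ref <- slope(ref_series, "ref_series")
  if (s_ref <= 0) stop("reference slope must be positive")
  s_sam <- slope(sample_series, "sample_series")
  phi <- phi_ref * s_sam / s_ref
  if (phi > 1) warning("estimated quantum yield exceeds 1; check inputs")
  phi
}
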