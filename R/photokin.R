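#' Construct a fluorescence decay trace
#'
#' @param time_s sampling times (s), strictly increasing.
#' @param intensity fluorescence intensity (a.u.).
#' @param variant optional variant label.
#' @param form optional `"green"` or `"red"`.
#' @return an object of class `decay_trace` (a data frame).
#' @export
decay_trace <- function(time_s, intensity, variant = NULL, form = NULL) {
  if (length(time_s) != length(intensity)) {
    stop("time_s and intensity must have the same length")
  }
  if (is.unsorted(time_s, strictly = TRUE)) {
    stop("time_s must be strictly increasing")
  }
  if (!all(is.finite(intensity))) stop("intensity must be finite")
  structure(data.frame(time_s = time_s, intensity = intensity),
            variant = variant, form = form,
            class = c("decay_trace", "data.frame"))
}

#' Read a decay trace (or cycles of traces) from CSV
#'
#' Expects columns `time_s`, `intensity` and optionally `cycle`; with a
#' `cycle` column a list of per-cycle traces is returned.
#'
#' @param path CSV file.
#' @return a `decay_trace`, or a list of them when cycles are present.
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "intensity") %in% names(df))) {
    stop("trace CSV must have columns time_s, intensity")
  }
  if ("cycle" %in% names(df) && length(unique(df$cycle)) > 1) {
    return(lapply(split(df, df$cycle), function(d) {
      tr <- decay_trace(d$time_s, d$intensity)
      attr(tr, "cycle") <- d$cycle[1]
      tr
    }))
  }
  decay_trace(df$time_s, df$intensity)
}

.as_trace <- function(trace) {
  if (inherits(trace, "decay_trace")) return(trace)
  if (is.data.frame(trace) && all(c("time_s", "intensity") %in% names(trace))) {
    return(decay_trace(trace$time_s, trace$intensity))
  }
  stop("expected a decay_trace or a data frame with time_s and intensity")
}

#' Fit the mono-exponential off-switching model
#'
#' Nonlinear least-squares fit of `I(t) = A * exp(-k * t) + c`
#' (Levenberg-Marquardt). Starting values follow the usual scheme:
#' `c0 = min(I)`, `k0` from a log-linear regression of `I - c0` over the
#' upper part of the decay, `A0 = I(0) - c0`. A trace whose trend is
#' increasing is rejected, and a fitted window shorter than `1/k` triggers
#' a warning since the plateau is then unconstrained.
#'
#' @param trace a `decay_trace` (or data frame with `time_s`, `intensity`).
#' @return an object of class `monoexp_fit` with coefficients `A`, `k`, `c`,
#'   their standard errors, and the residual RMS.
#' @export
fit_monoexp <- function(trace) {
  tr <- .as_trace(trace)
  t <- tr$time_s; I <- tr$intensity
  if (length(t) < 5) stop("need at least 5 points")
  if (unname(stats::coef(stats::lm(I ~ t))[2]) > 0) {
    stop("trace is increasing; expected an on-to-off decay")
  }
  c0 <- min(I)
  y <- I - c0
  sel <- y > 0.05 * max(y)
  k0 <- tryCatch({
    sl <- unname(stats::coef(stats::lm(log(y[sel]) ~ t[sel]))[2])
    if (is.finite(sl) && sl < 0) -sl else 1 / diff(range(t))
  }, error = function(e) 1 / diff(range(t)))
  A0 <- max(I[1] - c0, 1e-6 * max(abs(I), 1))
  df <- data.frame(t = t, I = I)
  fit <- tryCatch(
    minpack.lm::nlsLM(I ~ A * exp(-k * t) + c, data = df,
                      start = list(A = A0, k = k0, c = c0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) {
      stop("mono-exponential fit failed to converge: ",
           conditionMessage(e),
           sprintf(" [starts A=%.3g k=%.3g c=%.3g, n=%d]", A0, k0, c0,
                   length(t)),
           call. = FALSE)
    })
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  if (cf[["k"]] <= 0) stop("fitted rate is non-positive")
  if (diff(range(t)) < 1 / cf[["k"]]) {
    warning("trace spans less than 1/k of decay; parameters poorly constrained")
  }
  structure(list(coefficients = c(A = cf[["A"]], k = cf[["k"]], c = cf[["c"]]),
                 se = c(A = se[["A"]], k = se[["k"]], c = se[["c"]]),
                 sigma = sqrt(mean(stats::residuals(fit)^2)),
                 data = tr, nls = fit,
                 variant = attr(tr, "variant"), form = attr(tr, "form")),
            class = "monoexp_fit")
}

#' @export
coef.monoexp_fit <- function(object, ...) object$coefficients

#' @export
print.monoexp_fit <- function(x, ...) {
  cf <- x$coefficients
  cat(sprintf(
    "mono-exponential fit: I(t) = A exp(-k t) + c\n  A = %.4g +/- %.2g\n  k = %.4g +/- %.2g 1/s\n  c = %.4g +/- %.2g\n  residual RMS %.3g (n = %d)\n",
    cf["A"], x$se["A"], cf["k"], x$se["k"], cf["c"], x$se["c"],
    x$sigma, nrow(x$data)))
  invisible(x)
}

#' @export
summary.monoexp_fit <- function(object, ...) {
  out <- list(coefficients = cbind(Estimate = object$coefficients,
                                   `Std. Error` = object$se),
              sigma = object$sigma, n = nrow(object$data),
              switching_contrast = switching_contrast(object))
  class(out) <- "summary.monoexp_fit"
  out
}

#' @export
print.summary.monoexp_fit <- function(x, ...) {
  print(round(x$coefficients, 6))
  cat(sprintf("residual RMS %.3g on %d points; switching contrast %.1f%%\n",
              x$sigma, x$n, x$switching_contrast))
  invisible(x)
}

#' @export
predict.monoexp_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_s
       else if (is.numeric(newdata)) newdata
       else newdata$time_s
  cf <- object$coefficients
  cf["A"] * exp(-cf["k"] * t) + cf["c"]
}

#' @export
residuals.monoexp_fit <- function(object, ...) {
  object$data$intensity - predict(object)
}

#' @export
fitted.monoexp_fit <- function(object, ...) predict(object)

#' @export
plot.monoexp_fit <- function(x, ...) {
  graphics::plot(x$data$time_s, x$data$intensity, pch = 16, cex = 0.5,
                 xlab = "time (s)", ylab = "intensity (a.u.)",
                 main = "on-to-off photoswitching", ...)
  ts <- seq(min(x$data$time_s), max(x$data$time_s), length.out = 300)
  graphics::lines(ts, predict(x, ts), col = 2, lwd = 2)
  invisible(x)
}

#' Simulate traces from a fitted mono-exponential model
#' @param object a `monoexp_fit`.
#' @param nsim number of traces.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `decay_trace` objects with the fit's residual RMS as noise.
#' @export
simulate.monoexp_fit <- function(object, nsim = 1, seed = NULL, ...) {
  cf <- object$coefficients
  t <- object$data$time_s
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    decay_trace(t, cf["A"] * exp(-cf["k"] * t) + cf["c"] +
                  stats::rnorm(length(t), 0, object$sigma))
  }))
}

#' Switching contrast of a fitted decay
#'
#' `SC = 100 * A / (A + c)`: the percent drop from the fitted initial
#' intensity `A + c` to the plateau `c`.
#'
#' @param fit a `monoexp_fit`, or a named vector/list with `A` and `c`.
#' @return switching contrast in percent.
#' @export
switching_contrast <- function(fit) {
  cf <- if (inherits(fit, "monoexp_fit")) fit$coefficients
        else unlist(fit)
  A <- cf[["A"]]; c <- cf[["c"]]
  if (A + c <= 0) stop("A + c must be positive")
  100 * A / (A + c)
}

#' Fold change between two off-switching rates
#'
#' @param fit_a,fit_b `monoexp_fit` objects (numerator / denominator).
#' @return list with `ratio` (`k_a / k_b`), its propagated standard error,
#'   and the nearest-integer `rounded` value.
#' @export
rate_fold_change <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "monoexp_fit"), inherits(fit_b, "monoexp_fit"))
  ka <- fit_a$coefficients[["k"]]; kb <- fit_b$coefficients[["k"]]
  if (kb <= 0) stop("denominator rate must be positive")
  ratio <- ka / kb
  rel <- sqrt((fit_a$se[["k"]] / ka)^2 + (fit_b$se[["k"]] / kb)^2)
  list(ratio = ratio, se = ratio * rel, rounded = round(ratio))
}

#' Multi-cycle photostability
#'
#' Fits each cycle's decay, takes the fitted initial intensity `A + c` per
#' cycle, and regresses its logarithm on the cycle index; the per-cycle
#' loss factor is `exp(slope)`. Cycles whose fit fails are flagged and
#' excluded from the regression.
#'
#' @param traces list of `decay_trace` objects (>= 2 cycles).
#' @return an object of class `photostability` with `per_cycle` (data frame
#'   of cycle, A, k, c, initial, ok) and `loss_factor`.
#' @export
cycle_photostability <- function(traces) {
  if (!is.list(traces) || length(traces) < 2) {
    stop("need at least 2 cycles")
  }
  rows <- lapply(seq_along(traces), function(m) {
    f <- tryCatch(fit_monoexp(traces[[m]]), error = function(e) NULL)
    if (is.null(f)) {
      data.frame(cycle = m, A = NA, k = NA, c = NA, initial = NA, ok = FALSE)
    } else {
      cf <- f$coefficients
      data.frame(cycle = m, A = cf[["A"]], k = cf[["k"]], c = cf[["c"]],
                 initial = cf[["A"]] + cf[["c"]], ok = TRUE)
    }
  })
  per_cycle <- do.call(rbind, rows)
  ok <- per_cycle$ok & per_cycle$initial > 0
  if (sum(ok) < 2) {
    loss <- NA_real_
    warning("fewer than 2 usable cycle fits; loss factor undefined")
  } else {
    sl <- stats::coef(stats::lm(log(initial) ~ cycle,
                                data = per_cycle[ok, ]))[["cycle"]]
    loss <- exp(sl)
  }
  structure(list(per_cycle = per_cycle, loss_factor = loss,
                 n_failed = sum(!per_cycle$ok)),
            class = "photostability")
}

#' @export
print.photostability <- function(x, ...) {
  cat(sprintf("photostability over %d cycles: per-cycle loss factor %.3f%s\n",
              nrow(x$per_cycle), x$loss_factor,
              if (x$n_failed) sprintf(" (%d cycle fit(s) failed)", x$n_failed)
              else ""))
  invisible(x)
}
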