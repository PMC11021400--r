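#' Bond-length-alternation time series
#'
#' BLA is the difference between the two C-C bond lengths of the chromophore
#' methine bridge: `BLA(t) = d(C_imid, C_bridge) - d(C_bridge, C_phenol)`.
#' With this sign convention the phenolic-predominant resonance form gives
#' BLA > 0.
#'
#' @param traj a `trajectory`.
#' @param triplet atom names of the bridge triplet, in the order
#'   (imidazolinone-side C, bridge C, phenol-side C); either a character
#'   vector of three atom names unique in the trajectory, or a list
#'   `list(residue = <index>, atoms = <character(3)>)`.
#' @return an object of class `bla_series`: numeric per-frame BLA (Angstrom).
#' @export
compute_bla <- function(traj, triplet) {
  stopifnot(inherits(traj, "trajectory"))
  m <- traj$atom_meta
  if (is.list(triplet)) {
    atoms <- triplet$atoms
    sel <- which(m$residue_index == triplet$residue)
  } else {
    atoms <- triplet
    sel <- seq_len(nrow(m))
  }
  if (length(atoms) != 3) stop("triplet must name exactly three atoms")
  idx <- vapply(atoms, function(a) {
    hit <- sel[m$name[sel] == a]
    if (length(hit) == 0) stop("atom '", a, "' not found")
    if (length(hit) > 1) stop("atom name '", a, "' is ambiguous")
    hit
  }, integer(1))
  d <- function(i, j) {
    sqrt((traj$coords[, i, 1] - traj$coords[, j, 1])^2 +
         (traj$coords[, i, 2] - traj$coords[, j, 2])^2 +
         (traj$coords[, i, 3] - traj$coords[, j, 3])^2)
  }
  bla <- d(idx[1], idx[2]) - d(idx[2], idx[3])
  structure(bla, triplet = atoms, class = "bla_series")
}

#' @export
print.bla_series <- function(x, ...) {
  cat(sprintf("bla_series: %d frames, mean %.4f A, sd %.4f A (triplet %s)\n",
              length(x), mean(x), stats::sd(x),
              paste(attr(x, "triplet"), collapse = "-")))
  invisible(x)
}

# one EM run for a K-component 1-D Gaussian mixture; returns NULL on collapse
.gmm_em <- function(x, w, mu, sigma, max_iter, tol) {
  n <- length(x)
  K <- length(w)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    logd <- vapply(seq_len(K),
                   function(k) log(w[k]) + stats::dnorm(x, mu[k], sigma[k],
                                                        log = TRUE),
                   numeric(n))
    mx <- apply(logd, 1, max)
    if (any(!is.finite(mx))) return(NULL)
    lse <- mx + log(rowSums(exp(logd - mx)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    r <- exp(logd - lse)                       # responsibilities n x K
    nk <- colSums(r)
    if (any(nk < 1e-8)) return(NULL)
    w <- nk / n
    mu <- colSums(r * x) / nk
    sigma <- sqrt(colSums(r * (outer(x, mu, "-"))^2) / nk)
    if (any(sigma < 1e-8)) return(NULL)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) break
    ll_old <- ll
  }
  list(weights = w, means = mu, sds = sigma, logLik = ll,
       ll_trace = ll_trace, iterations = it)
}

#' Fit a three-component Gaussian mixture by EM
#'
#' Expectation-maximisation to convergence (log-likelihood change below
#' `tol` or `max_iter` iterations), restarted from quantile-based and
#' perturbed initialisations; the best run by final log-likelihood is
#' returned with components sorted by mean.
#'
#' @param samples numeric sample vector (>= 30 values recommended).
#' @param n_restarts number of EM restarts.
#' @param seed integer seed for the initialisation perturbations.
#' @param max_iter maximum EM iterations per restart.
#' @param tol convergence tolerance on the log-likelihood change.
#' @return an object of class `gmm3_fit` with `weights`, `means`, `sds`,
#'   `logLik` and the per-iteration `ll_trace` of the winning run.
#' @export
fit_gmm3 <- function(samples, n_restarts = 8, seed = NULL,
                     max_iter = 500, tol = 1e-8) {
  x <- as.numeric(samples)
  K <- 3L
  if (length(x) < K) stop("fewer samples than mixture components")
  if (length(x) < 30) warning("fewer than 30 samples; fit may be unstable")
  if (stats::sd(x) < 1e-12) {
    stop("degenerate input: all samples (nearly) identical")
  }
  base_mu <- as.numeric(stats::quantile(x, c(1, 3, 5) / 6))
  base_sd <- rep(stats::sd(x) / 2, K)
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      mu <- if (r == 1) base_mu else
        base_mu + stats::rnorm(K, 0, stats::sd(x) / 4)
      fit <- .gmm_em(x, rep(1 / K, K), mu, base_sd, max_iter, tol)
      if (!is.null(fit) &&
          (is.null(best) || fit$logLik > best$logLik)) best <- fit
    }
  })
  if (is.null(best)) stop("EM failed to produce a non-degenerate fit")
  ord <- order(best$means)
  structure(list(weights = best$weights[ord], means = best$means[ord],
                 sds = best$sds[ord], logLik = best$logLik,
                 ll_trace = best$ll_trace, n = length(x),
                 iterations = best$iterations),
            class = "gmm3_fit")
}

#' @export
print.gmm3_fit <- function(x, ...) {
  cat("3-component Gaussian mixture (EM)\n")
  print(round(coef(x), 4))
  cat(sprintf("log-likelihood %.3f (n = %d, %d iterations)\n",
              x$logLik, x$n, x$iterations))
  invisible(x)
}

#' @export
coef.gmm3_fit <- function(object, ...) {
  rbind(weight = object$weights, mean = object$means, sd = object$sds)
}

#' @export
logLik.gmm3_fit <- function(object, ...) {
  structure(object$logLik, df = 8, nobs = object$n, class = "logLik")
}

#' @export
plot.gmm3_fit <- function(x, samples = NULL, breaks = NULL, ...) {
  if (!is.null(samples)) {
    if (is.null(breaks)) {
      breaks <- seq(min(samples) - 0.005, max(samples) + 0.005, by = 0.005)
    }
    graphics::hist(samples, breaks = breaks, freq = FALSE,
                   main = "Gaussian mixture fit", xlab = "BLA (A)", ...)
    xs <- seq(min(samples), max(samples), length.out = 400)
  } else {
    xs <- seq(min(x$means - 4 * x$sds), max(x$means + 4 * x$sds),
              length.out = 400)
    graphics::plot(NA, xlim = range(xs), ylim = c(0, NA_real_),
                   xlab = "BLA (A)", ylab = "density",
                   main = "Gaussian mixture fit", ...)
  }
  dens <- rowSums(vapply(1:3, function(k) {
    x$weights[k] * stats::dnorm(xs, x$means[k], x$sds[k])
  }, numeric(length(xs))))
  graphics::lines(xs, dens, lwd = 2)
  for (k in 1:3) {
    graphics::lines(xs, x$weights[k] * stats::dnorm(xs, x$means[k], x$sds[k]),
                    lty = 2)
  }
  invisible(x)
}

#' Posterior component responsibilities
#' @param object a `gmm3_fit`.
#' @param newdata numeric sample vector.
#' @param ... unused.
#' @return `length(newdata) x 3` matrix of posterior probabilities.
#' @export
predict.gmm3_fit <- function(object, newdata, ...) {
  logd <- vapply(1:3, function(k) {
    log(object$weights[k]) +
      stats::dnorm(newdata, object$means[k], object$sds[k], log = TRUE)
  }, numeric(length(newdata)))
  mx <- apply(logd, 1, max)
  r <- exp(logd - (mx + log(rowSums(exp(logd - mx)))))
  colnames(r) <- paste0("comp", 1:3)
  r
}

#' Weight and mean of the right-most mixture component
#'
#' The component with the largest mean tracks the phenolic-predominant
#' resonance form (BLA > 0); its weight is the quantity compared across
#' variants. Ties in mean are broken towards the larger weight.
#'
#' @param fit a `gmm3_fit`.
#' @return named numeric `c(weight, mean)`.
#' @export
rightmost_component <- function(fit) {
  stopifnot(inherits(fit, "gmm3_fit"))
  mx <- max(fit$means)
  cand <- which(abs(fit$means - mx) < 1e-12)
  if (length(cand) > 1L) cand <- cand[which.max(fit$weights[cand])]
  c(weight = unname(fit$weights[cand]), mean = unname(fit$means[cand]))
}
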