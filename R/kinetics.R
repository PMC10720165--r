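#' Fixed relaxation times for the three-site model
#'
#' T1 values (s) are fixed during fitting to stabilize the two-parameter
#' rate estimation: 30 s (pyruvate), 25 s (lactate), 20 s (bicarbonate).
#'
#' @param pyruvate,lactate,bicarbonate longitudinal relaxation times (s).
#' @return Named numeric vector of class `"hp_relax"`.
#' @export
relaxation_times <- function(pyruvate = 30, lactate = 25, bicarbonate = 20) {
  x <- c(pyruvate = pyruvate, lactate = lactate, bicarbonate = bicarbonate)
  if (any(x <= 0)) stop("T1 values must be strictly positive", call. = FALSE)
  structure(x, class = c("hp_relax", "numeric"))
}

#' Flip-angle schedule of the metabolite-specific acquisition
#'
#' One excitation per slice per metabolite per frame (2D multislice), with
#' 20 degrees for pyruvate and 30 degrees for lactate and bicarbonate, so
#' the per-frame magnetization loss is a single `cos(theta)` factor per
#' metabolite.
#'
#' @param times strictly increasing frame times (s); default 30 frames at
#'   3.6 s spacing (3 heartbeats at 50 bpm).
#' @param pyruvate,lactate,bicarbonate excitation flip angles (degrees, in
#'   (0, 90)).
#' @return Object of class `"hp_flips"`: list with `times` and `theta`
#'   (radians, named).
#' @export
flip_schedule <- function(times = seq(0, by = 3.6, length.out = 30),
                          pyruvate = 20, lactate = 30, bicarbonate = 30) {
  th <- c(pyruvate = pyruvate, lactate = lactate, bicarbonate = bicarbonate)
  if (any(th <= 0 | th >= 90)) {
    stop("flip angles must lie strictly between 0 and 90 degrees",
         call. = FALSE)
  }
  if (length(times) < 1 || any(diff(times) <= 0)) {
    stop("frame times must be strictly increasing", call. = FALSE)
  }
  structure(list(times = times, theta = deg2rad(th), theta_deg = th),
            class = "hp_flips")
}

#' Kinetic conversion rates
#'
#' @param k_pl,k_pb apparent first-order pyruvate-to-lactate and
#'   pyruvate-to-bicarbonate conversion rates (s^-1). Finite, otherwise
#'   unconstrained: fits may legitimately return small negative values in
#'   noise, which must be preserved for unbiased group statistics.
#' @return Named numeric vector `c(k_pl, k_pb)`.
#' @export
kinetic_rates <- function(k_pl, k_pb) {
  x <- c(k_pl = unname(k_pl), k_pb = unname(k_pb))
  if (any(!is.finite(x))) stop("rates must be finite", call. = FALSE)
  x
}

# Closed-form convolution of the inter-frame pyruvate magnetization against
# exp(-(t_{i+1} - t)/T1_X). Pyruvate is modeled mono-exponentially between
# its frame endpoints (p0 just after the excitation at frame i, p1 just
# before frame i+1); if either endpoint is <= 0 (possible in signed noise)
# the curve is taken flat at the clamped endpoint mean.
interframe_conv <- function(p0, p1, dt, t1x) {
  if (p0 > 0 && p1 > 0) {
    rho <- log(p0 / p1) / dt
    d <- 1 / t1x - rho
    if (abs(d) < 1e-12) {
      p0 * exp(-dt / t1x) * dt
    } else {
      p0 * exp(-dt / t1x) * (exp(d * dt) - 1) / d
    }
  } else {
    pbar <- max((p0 + p1) / 2, 0)
    pbar * t1x * (1 - exp(-dt / t1x))
  }
}

#' Predict lactate and bicarbonate signals from measured pyruvate
#'
#' The "inputless" formulation of the uni-directional three-site model: the
#' measured pyruvate signal itself serves as the precursor input, so no
#' arterial input function is assumed. The longitudinal pyruvate
#' magnetization at each frame is recovered from the signal via
#' `M_P(i+) = (S_P(i)/sin(theta_P)) * cos(theta_P)`, modeled
#' mono-exponentially between frame endpoints, and each product pool X
#' follows the discrete recursion
#' `M_X(i+1-) = M_X(i+) * exp(-dt/T1_X) + k_PX * C_i`, where `C_i` is the
#' closed-form convolution of the inter-frame pyruvate against
#' `exp(-(t_{i+1}-t)/T1_X)`. Signals are `S_X(i) = M_X(i-) * sin(theta_X)`.
#'
#' @param s_pyr measured (phased, real-valued) pyruvate signal per frame.
#' @param rates [kinetic_rates()] or named vector with `k_pl`, `k_pb`.
#' @param relax [relaxation_times()].
#' @param flips [flip_schedule()] whose `times` match `length(s_pyr)`.
#' @param initial initial longitudinal magnetizations
#'   `c(lactate = , bicarbonate = )` at the first frame (pre-excitation).
#' @return Matrix `n_frames x 2` with columns `lactate`, `bicarbonate`
#'   (transverse signals). Attribute `"mz"` holds the longitudinal
#'   magnetizations; attribute `"zero_input"` flags an all-zero pyruvate
#'   input (the prediction is then identically the decaying initial pools).
#' @export
predict_inputless <- function(s_pyr, rates, relax = relaxation_times(),
                              flips = flip_schedule(),
                              initial = c(lactate = 0, bicarbonate = 0)) {
  n <- length(s_pyr)
  if (length(flips$times) != n) {
    stop("flip schedule and pyruvate signal disagree in length", call. = FALSE)
  }
  th <- flips$theta
  dtv <- diff(flips$times)
  kx <- c(rates[["k_pl"]], rates[["k_pb"]])
  t1 <- c(relax[["lactate"]], relax[["bicarbonate"]])
  mp_minus <- s_pyr / sin(th[["pyruvate"]])
  mp_plus <- mp_minus * cos(th[["pyruvate"]])
  mz <- matrix(0, n, 2, dimnames = list(NULL, c("lactate", "bicarbonate")))
  mz[1, ] <- c(initial[["lactate"]], initial[["bicarbonate"]])
  cth <- c(cos(th[["lactate"]]), cos(th[["bicarbonate"]]))
  for (i in seq_len(n - 1)) {
    dt <- dtv[i]
    dec <- exp(-dt / t1)
    conv <- c(interframe_conv(mp_plus[i], mp_minus[i + 1], dt, t1[1]),
              interframe_conv(mp_plus[i], mp_minus[i + 1], dt, t1[2]))
    mz[i + 1, ] <- mz[i, ] * cth * dec + kx * conv
  }
  sig <- sweep(mz, 2, c(sin(th[["lactate"]]), sin(th[["bicarbonate"]])), `*`)
  attr(sig, "mz") <- mz
  attr(sig, "zero_input") <- all(s_pyr == 0)
  sig
}

# Pyruvate longitudinal magnetization at frame times driven by an input
# curve u(t), with per-frame excitation losses and effective decay
# lambda = 1/T1_P + k_PL + k_PB. The inter-frame delivery integral is
# evaluated by composite Simpson quadrature.
simulate_pyruvate <- function(u, times, rates, relax = relaxation_times(),
                              theta_p = deg2rad(20), n_sub = 64, m0 = 0) {
  lambda <- 1 / relax[["pyruvate"]] + rates[["k_pl"]] + rates[["k_pb"]]
  n <- length(times)
  mz_minus <- numeric(n)
  mz_minus[1] <- m0
  for (i in seq_len(n - 1)) {
    dt <- times[i + 1] - times[i]
    tau <- seq(0, dt, length.out = n_sub + 1)
    w <- u(times[i] + tau) * exp(-lambda * (dt - tau))
    h <- dt / n_sub
    integ <- h / 3 * (w[1] + w[n_sub + 1] +
                        4 * sum(w[seq(2, n_sub, 2)]) +
                        2 * sum(w[seq(3, n_sub - 1, 2)]))
    mz_minus[i + 1] <- mz_minus[i] * cos(theta_p) * exp(-lambda * dt) + integ
  }
  mz_minus
}

#' Forward-model metabolite timecourses
#'
#' Generates pyruvate, lactate and bicarbonate signal curves for one voxel
#' or region. The precursor can be given either as an input-function
#' delivery curve `u(t)` (a function of time, e.g. a [gamma_variate()]
#' bolus), from which the pyruvate magnetization is integrated with
#' excitation and T1 losses and effective decay `1/T1_P + k_PL + k_PB`, or
#' directly as a measured pyruvate signal vector. Lactate and bicarbonate
#' then follow the [predict_inputless()] recursion, so feeding the model's
#' own pyruvate output back with the generating rates reproduces its
#' product curves exactly.
#'
#' @param input function of time (delivery curve, magnetization units per
#'   second) or numeric vector (pyruvate signal at frame times).
#' @param rates,relax,flips,initial see [predict_inputless()].
#' @param n_sub quadrature subintervals per frame for the input integral.
#' @param initial_pyruvate pyruvate longitudinal magnetization at the first
#'   frame (pre-excitation); only used with a function input.
#' @return Object of class `"hp_timecourses"`: matrix `n_frames x 3` with
#'   columns `pyruvate`, `lactate`, `bicarbonate`, with attributes `times`
#'   and `"mz"`.
#' @examples
#' aif <- aif_model()
#' tc <- hp_forward_model(function(t) gamma_variate(t, aif),
#'                        kinetic_rates(0.02, 0.01))
#' head(tc)
#' @export
hp_forward_model <- function(input, rates, relax = relaxation_times(),
                             flips = flip_schedule(),
                             initial = c(lactate = 0, bicarbonate = 0),
                             n_sub = 64, initial_pyruvate = 0) {
  if (is.function(input)) {
    mz_p <- simulate_pyruvate(input, flips$times, rates, relax,
                              flips$theta[["pyruvate"]], n_sub,
                              m0 = initial_pyruvate)
    s_p <- mz_p * sin(flips$theta[["pyruvate"]])
  } else {
    s_p <- as.numeric(input)
  }
  lb <- predict_inputless(s_p, rates, relax, flips, initial)
  out <- cbind(pyruvate = s_p, lactate = lb[, "lactate"],
               bicarbonate = lb[, "bicarbonate"])
  attr(out, "mz") <- attr(lb, "mz")
  attr(out, "times") <- flips$times
  class(out) <- c("hp_timecourses", class(out))
  out
}

#' Fit kPL and kPB by inputless least squares
#'
#' The central estimator: minimizes the summed squared residuals of the
#' lactate and bicarbonate signal predictions driven by the measured
#' pyruvate signal, over the two conversion rates, by Levenberg-Marquardt
#' least squares ([minpack.lm::nls.lm]). The parameters are unconstrained
#' (noise can legitimately push them slightly negative), T1 values are
#' fixed, and the initial lactate/bicarbonate magnetizations are taken
#' from the first measured frame (used as-is, signed). With uni-directional
#' conversion the two sub-problems are separable, so the joint fit
#' coincides with per-metabolite fits.
#'
#' @param s_pyr,s_lac,s_bic phased, real-valued signal timecourses (equal
#'   length, >= 3 frames). Alternatively pass an `"hp_timecourses"` matrix
#'   as `s_pyr` and leave the others `NULL`.
#' @param relax [relaxation_times()].
#' @param flips [flip_schedule()].
#' @param start starting rates for the local optimizer (s^-1).
#' @param ... passed to [minpack.lm::nls.lm] control.
#' @return Object of class `"hp_kinfit"`: coefficients `k_pl`, `k_pb`,
#'   residual sum of squares, fitted curves, convergence flag. Never throws
#'   on non-convergence; the best iterate is flagged instead.
#' @examples
#' tc <- hp_forward_model(function(t) gamma_variate(t, aif_model()),
#'                        kinetic_rates(0.02, 0.01))
#' fit <- fit_kinetics(tc)
#' coef(fit)
#' @export
fit_kinetics <- function(s_pyr, s_lac = NULL, s_bic = NULL,
                         relax = relaxation_times(),
                         flips = flip_schedule(),
                         start = c(k_pl = 0.01, k_pb = 0.005), ...) {
  if (inherits(s_pyr, "hp_timecourses") ||
      (is.matrix(s_pyr) && is.null(s_lac))) {
    tc <- s_pyr
    s_lac <- tc[, "lactate"]
    s_bic <- tc[, "bicarbonate"]
    s_pyr <- tc[, "pyruvate"]
  }
  n <- length(s_pyr)
  if (n < 3 || length(s_lac) != n || length(s_bic) != n) {
    stop("need three equal-length timecourses with at least 3 frames",
         call. = FALSE)
  }
  if (length(flips$times) != n) {
    flips <- flip_schedule(times = flips$times[seq_len(n)],
                           pyruvate = flips$theta_deg[["pyruvate"]],
                           lactate = flips$theta_deg[["lactate"]],
                           bicarbonate = flips$theta_deg[["bicarbonate"]])
  }
  initial <- c(lactate = s_lac[1] / sin(flips$theta[["lactate"]]),
               bicarbonate = s_bic[1] / sin(flips$theta[["bicarbonate"]]))
  obs <- c(s_lac, s_bic)
  resid_fun <- function(p) {
    pred <- predict_inputless(s_pyr, c(k_pl = p[1], k_pb = p[2]),
                              relax, flips, initial)
    c(pred[, "lactate"], pred[, "bicarbonate"]) - obs
  }
  fit <- minpack.lm::nls.lm(par = unname(start), fn = resid_fun, ...)
  rates <- kinetic_rates(fit$par[1], fit$par[2])
  pred <- predict_inputless(s_pyr, rates, relax, flips, initial)
  structure(
    list(coefficients = rates,
         rss = sum(fit$fvec^2),
         fitted = cbind(lactate = pred[, "lactate"],
                        bicarbonate = pred[, "bicarbonate"]),
         observed = cbind(pyruvate = s_pyr, lactate = s_lac,
                          bicarbonate = s_bic),
         initial = initial,
         converged = fit$info %in% 1:4,
         info = fit$info, message = fit$message,
         relax = relax, flips = flips),
    class = "hp_kinfit"
  )
}

#' @export
print.hp_kinfit <- function(x, ...) {
  cat("Inputless three-site kinetic fit\n")
  cat(sprintf("  k_PL = %.5f s^-1, k_PB = %.5f s^-1\n",
              x$coefficients[["k_pl"]], x$coefficients[["k_pb"]]))
  cat(sprintf("  RSS = %.4g over %d frames%s\n", x$rss, nrow(x$observed),
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
coef.hp_kinfit <- function(object, ...) object$coefficients

#' @export
fitted.hp_kinfit <- function(object, ...) object$fitted

#' @export
residuals.hp_kinfit <- function(object, ...) {
  object$observed[, c("lactate", "bicarbonate")] - object$fitted
}

#' @export
deviance.hp_kinfit <- function(object, ...) object$rss

#' @export
summary.hp_kinfit <- function(object, ...) {
  res <- residuals(object)
  out <- list(coefficients = coef(object), rss = object$rss,
              sigma = sqrt(object$rss / max(1, length(res) - 2)),
              converged = object$converged, n_frames = nrow(object$observed))
  class(out) <- "summary.hp_kinfit"
  out
}

#' @export
print.summary.hp_kinfit <- function(x, ...) {
  cat("Inputless three-site kinetic fit (", x$n_frames, "frames )\n")
  print(x$coefficients)
  cat(sprintf("Residual sum of squares: %.4g (sigma %.4g)\n", x$rss, x$sigma))
  if (!x$converged) cat("Warning: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
predict.hp_kinfit <- function(object, newdata = NULL, ...) {
  s_pyr <- if (is.null(newdata)) object$observed[, "pyruvate"] else newdata
  initial <- if (is.null(newdata)) object$initial else c(lactate = 0, bicarbonate = 0)
  predict_inputless(s_pyr, coef(object), object$relax, object$flips, initial)
}

#' @export
simulate.hp_kinfit <- function(object, nsim = 1, seed = NULL, ...) {
  s <- summary(object)
  with_seed(seed, {
    replicate(nsim, {
      object$fitted + matrix(rnorm(length(object$fitted), sd = s$sigma),
                             nrow(object$fitted))
    }, simplify = FALSE)
  })
}

#' @export
plot.hp_kinfit <- function(x, ...) {
  t <- x$flips$times
  obs <- x$observed
  op <- par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  matplot(t, cbind(obs[, "lactate"], x$fitted[, "lactate"]),
          type = c("p", "l"), pch = 1, lty = 1, col = c("gray40", "red3"),
          xlab = "time (s)", ylab = "signal", main = "lactate")
  matplot(t, cbind(obs[, "bicarbonate"], x$fitted[, "bicarbonate"]),
          type = c("p", "l"), pch = 1, lty = 1, col = c("gray40", "blue3"),
          xlab = "time (s)", ylab = "signal", main = "bicarbonate")
  invisible(x)
}

#' Voxelwise kPL/kPB rate maps
#'
#' Runs [fit_kinetics()] in every voxel of `mask` on phased, real-valued
#' dynamic images. Voxels outside the mask (and any statistic computed
#' from them) carry the `NA` sentinel and are excluded from all summaries.
#'
#' @param images named list with elements `pyruvate`, `lactate`,
#'   `bicarbonate`, each a real array `(ny, nx, n_slices, n_frames)`.
#' @param mask logical array `(ny, nx, n_slices)`.
#' @param relax,flips,start see [fit_kinetics()].
#' @return Object of class `"hp_rate_maps"`: list of arrays `k_pl`, `k_pb`,
#'   `rss`, `converged` (NA outside the mask).
#' @export
fit_rate_maps <- function(images, mask, relax = relaxation_times(),
                          flips = flip_schedule(),
                          start = c(k_pl = 0.01, k_pb = 0.005)) {
  d <- dim(images$pyruvate)
  if (!all(dim(mask) == d[1:3])) {
    stop("mask must match the image grid", call. = FALSE)
  }
  k_pl <- array(NA_real_, d[1:3])
  k_pb <- array(NA_real_, d[1:3])
  rss <- array(NA_real_, d[1:3])
  conv <- array(NA, d[1:3])
  vox <- which(mask)
  if (!length(vox)) {
    warning("empty mask: returning all-NA rate maps")
  }
  nvox <- prod(d[1:3])
  mp <- matrix(images$pyruvate, nvox)
  ml <- matrix(images$lactate, nvox)
  mb <- matrix(images$bicarbonate, nvox)
  for (v in vox) {
    f <- fit_kinetics(mp[v, ], ml[v, ], mb[v, ], relax, flips, start)
    k_pl[v] <- f$coefficients[["k_pl"]]
    k_pb[v] <- f$coefficients[["k_pb"]]
    rss[v] <- f$rss
    conv[v] <- f$converged
  }
  structure(list(k_pl = k_pl, k_pb = k_pb, rss = rss, converged = conv,
                 n_fitted = length(vox)),
            class = "hp_rate_maps")
}

#' @export
print.hp_rate_maps <- function(x, ...) {
  cat("Voxelwise kinetic rate maps:", x$n_fitted, "voxels fitted\n")
  if (x$n_fitted) {
    cat(sprintf("  k_PL: median %.4f s^-1 | k_PB: median %.4f s^-1\n",
                median(x$k_pl, na.rm = TRUE), median(x$k_pb, na.rm = TRUE)))
  }
  invisible(x)
}
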