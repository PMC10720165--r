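# Independent brute-force implementation of the discrete recursion used as
# an oracle: plain loops, no shared code path with predict_inputless.
brute_force_recursion <- function(s_pyr, k_pl, k_pb,
                                  t1 = c(30, 25, 20),
                                  th = c(20, 30, 30) * pi / 180,
                                  dt = 3.6, init = c(0, 0), h = NULL) {
  n <- length(s_pyr)
  mp_minus <- s_pyr / sin(th[1])
  mp_plus <- mp_minus * cos(th[1])
  ml <- init[1]; mb <- init[2]
  L <- numeric(n); B <- numeric(n)
  L[1] <- ml * sin(th[2]); B[1] <- mb * sin(th[3])
  for (i in seq_len(n - 1)) {
    p0 <- mp_plus[i]; p1 <- mp_minus[i + 1]
    if (p0 > 0 && p1 > 0) {
      rho <- log(p0 / p1) / dt
      pfun <- function(tau) p0 * exp(-rho * tau)
    } else {
      pbar <- max((p0 + p1) / 2, 0)
      pfun <- function(tau) rep(pbar, length(tau))
    }
    ml <- ml * cos(th[2]); mb <- mb * cos(th[3])
    if (is.null(h)) {
      # exact integral of pfun against the T1 decay kernel by quadrature
      cl <- integrate(function(tau) pfun(tau) * exp(-(dt - tau) / t1[2]),
                      0, dt, rel.tol = 1e-12)$value
      cb <- integrate(function(tau) pfun(tau) * exp(-(dt - tau) / t1[3]),
                      0, dt, rel.tol = 1e-12)$value
      ml <- ml * exp(-dt / t1[2]) + k_pl * cl
      mb <- mb * exp(-dt / t1[3]) + k_pb * cb
    } else {
      # fine-step Euler integration of dM_X/dt = k_PX P(t) - M_X/T1_X
      nst <- round(dt / h)
      tau <- (seq_len(nst) - 1) * h
      pv <- pfun(tau)
      for (s in seq_len(nst)) {
        ml <- ml + h * (k_pl * pv[s] - ml / t1[2])
        mb <- mb + h * (k_pb * pv[s] - mb / t1[3])
      }
    }
    L[i + 1] <- ml * sin(th[2]); B[i + 1] <- mb * sin(th[3])
  }
  cbind(lactate = L, bicarbonate = B)
}

test_that("zero rates and zero initial pools give identically zero products", {
  tc <- hp_forward_model(function(t) gamma_variate(t, aif_model()),
                         kinetic_rates(0, 0))
  expect_true(all(tc[, "lactate"] == 0))
  expect_true(all(tc[, "bicarbonate"] == 0))
  expect_gt(max(tc[, "pyruvate"]), 0)
})

test_that("input-free pyruvate decay matches the closed form to machine precision", {
  flips <- flip_schedule()
  tc <- hp_forward_model(function(t) numeric(length(t)), kinetic_rates(0, 0),
                         flips = flips, initial_pyruvate = 3)
  n <- 0:29
  closed <- 3 * cos(deg2rad_test(20))^n * exp(-n * 3.6 / 30) * sin(deg2rad_test(20))
  expect_equal(unclass(tc[, "pyruvate"]), closed, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("forward model agrees with a 1 ms fine-step ODE oracle within 0.5%", {
  tc <- hp_forward_model(function(t) gamma_variate(t, aif_model()),
                         kinetic_rates(0.02, 0.01))
  orc <- brute_force_recursion(tc[, "pyruvate"], 0.02, 0.01, h = 1e-3)
  for (m in c("lactate", "bicarbonate")) {
    rel <- max(abs(tc[, m] - orc[, m])) / max(abs(tc[, m]))
    expect_lt(rel, 0.005)
  }
})

test_that("the recursion halves its error against the continuous solution when the frame interval halves", {
  skip_if_not_installed("deSolve")
  # near-zero flip angles isolate the inter-frame discretization error
  aif <- aif_model()
  rates <- kinetic_rates(0.02, 0.01)
  err_at <- function(dt) {
    nt <- ceiling(108 / dt)
    flips <- flip_schedule(times = seq(0, by = dt, length.out = nt),
                           pyruvate = 1e-3, lactate = 1e-3, bicarbonate = 1e-3)
    tc <- hp_forward_model(function(t) gamma_variate(t, aif), rates,
                           flips = flips, n_sub = 256)
    sol <- deSolve::ode(
      y = c(P = 0, L = 0), times = flips$times,
      func = function(t, y, p) {
        list(c(gamma_variate(t, aif) - (1 / 30 + 0.03) * y[1],
               0.02 * y[1] - y[2] / 25))
      }, rtol = 1e-10, atol = 1e-12)
    max(abs(tc[, "lactate"] / sin(deg2rad_test(1e-3)) - sol[, "L"])) /
      max(sol[, "L"])
  }
  e1 <- err_at(3.6)
  e2 <- err_at(1.8)
  expect_lt(e2, e1)
  expect_gt(e1 / e2, 1.5)   # at least first-order convergence
})

test_that("feeding the forward model's pyruvate back reproduces its products exactly", {
  tc <- hp_forward_model(function(t) gamma_variate(t, aif_model()),
                         kinetic_rates(0.017, 0.008))
  pred <- predict_inputless(tc[, "pyruvate"], kinetic_rates(0.017, 0.008))
  expect_equal(unclass(pred[, "lactate"]), unclass(tc[, "lactate"]),
               tolerance = 1e-14, ignore_attr = TRUE)
  expect_equal(unclass(pred[, "bicarbonate"]), unclass(tc[, "bicarbonate"]),
               tolerance = 1e-14, ignore_attr = TRUE)
})

test_that("the inputless prediction is linear in the pyruvate signal", {
  set.seed(5)
  sp <- abs(rnorm(30))
  p1 <- predict_inputless(sp, kinetic_rates(0.03, 0.01))
  p2 <- predict_inputless(4.2 * sp, kinetic_rates(0.03, 0.01))
  expect_equal(4.2 * unclass(p1), unclass(p2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("the closed-form recursion matches brute-force quadrature on random inputs", {
  set.seed(17)
  for (rep in 1:5) {
    sp <- abs(rnorm(30, sd = 2))
    sp[sample(30, 3)] <- 0   # exercise the flat fallback
    pred <- predict_inputless(sp, kinetic_rates(0.03, 0.012),
                              initial = c(lactate = 0.2, bicarbonate = -0.1))
    orc <- brute_force_recursion(sp, 0.03, 0.012,
                                 init = c(0.2, -0.1))
    expect_equal(unclass(pred), orc, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("noiseless rates are recovered within 1e-3 and null signals fit to zero", {
  tc <- hp_forward_model(function(t) gamma_variate(t, aif_model()),
                         kinetic_rates(0.02, 0.01))
  fit <- fit_kinetics(tc)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[["k_pl"]] - 0.02), 1e-3)
  expect_lt(abs(coef(fit)[["k_pb"]] - 0.01), 1e-3)
  expect_lt(fit$rss, 1e-12)

  null_fit <- fit_kinetics(tc[, "pyruvate"], numeric(30), numeric(30))
  expect_lt(abs(coef(null_fit)[["k_pl"]]), 1e-8)
  expect_lt(abs(coef(null_fit)[["k_pb"]]), 1e-8)
})

test_that("hp_kinfit methods are coherent", {
  tc <- hp_forward_model(function(t) gamma_variate(t, aif_model()),
                         kinetic_rates(0.02, 0.01))
  fit <- fit_kinetics(tc)
  expect_named(coef(fit), c("k_pl", "k_pb"))
  expect_equal(dim(fitted(fit)), c(30L, 2L))
  expect_equal(unname(residuals(fit)[, 1]),
               unname(tc[, "lactate"] - fitted(fit)[, "lactate"]))
  expect_equal(deviance(fit), fit$rss)
  pr <- predict(fit)
  expect_equal(unclass(pr[, "lactate"]), unclass(fitted(fit)[, "lactate"]),
               ignore_attr = TRUE)
  s <- summary(fit)
  expect_s3_class(s, "summary.hp_kinfit")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_output(print(fit), "k_PL")
})

test_that("rate estimates are invariant to the lactate flip angle", {
  aif <- aif_model()
  rates <- kinetic_rates(0.02, 0.01)
  tcs <- lapply(c(15, 30), function(th_l) {
    flips <- flip_schedule(lactate = th_l)
    list(tc = hp_forward_model(function(t) gamma_variate(t, aif), rates,
                               flips = flips),
         flips = flips)
  })
  # the measured lactate really does depend on its flip angle ...
  expect_gt(max(abs(tcs[[1]]$tc[, "lactate"] - tcs[[2]]$tc[, "lactate"])), 0)
  # ... yet the model's flip-loss correction recovers the same rate
  k <- vapply(tcs, function(x)
    coef(fit_kinetics(x$tc, flips = x$flips))[["k_pl"]], 0)
  expect_lt(abs(k[1] - k[2]) / k[1], 0.01)
})

test_that("rate maps recover uniform myocardial rates and respect the mask", {
  st <- small_study(noise = FALSE)
  geom <- small_geometry()
  cb <- combine_study(st, maps = st$truth$sensitivities)
  myo <- geom$labels >= 3
  # restrict to one slice for speed
  myo[, , c(1, 3)] <- FALSE
  maps <- fit_rate_maps(cb$images, myo, flips = protocol_flips(st$protocol))
  expect_equal(mean(maps$k_pl[myo]), 0.02, tolerance = 0.02)
  expect_equal(mean(maps$k_pb[myo]), 0.01, tolerance = 0.02)
  expect_true(all(is.na(maps$k_pl[!myo])))

  expect_warning(empty <- fit_rate_maps(cb$images, array(FALSE, dim(myo))),
                 "empty mask")
  expect_true(all(is.na(empty$k_pl)))
})

test_that("a fed render with multiplier > 1 yields strictly larger myocardial kPB", {
  kin <- tissue_kinetics(fed_k_pb_mult = 2)
  fa <- small_study(state = "fasted", noise = FALSE, kinetics = kin)
  fe <- small_study(state = "fed", noise = FALSE, kinetics = kin)
  geom <- small_geometry()
  myo <- geom$labels >= 3
  myo[, , c(1, 3)] <- FALSE
  k_fa <- fit_rate_maps(combine_study(fa, maps = fa$truth$sensitivities)$images,
                        myo, flips = protocol_flips(fa$protocol))
  k_fe <- fit_rate_maps(combine_study(fe, maps = fe$truth$sensitivities)$images,
                        myo, flips = protocol_flips(fe$protocol))
  expect_gt(mean(k_fe$k_pb[myo]), mean(k_fa$k_pb[myo]))
})

test_that("schedule and input validation errors are raised", {
  expect_error(flip_schedule(times = c(0, 3.6, 3.6)), "increasing")
  expect_error(flip_schedule(pyruvate = 95), "between")
  expect_error(relaxation_times(pyruvate = -1), "positive")
  expect_error(fit_kinetics(1:2, 1:2, 1:2), "3 frames")
  # all-zero pyruvate is flagged via diagnostics, not an exception
  pred <- predict_inputless(numeric(30), kinetic_rates(0.02, 0.01))
  expect_true(attr(pred, "zero_input"))
  expect_true(all(pred == 0))
})
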