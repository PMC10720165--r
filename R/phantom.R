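#' Tissue kinetics specification for the phantom
#'
#' Ground-truth conversion rates for the myocardium, per AHA segment, with
#' fed-state multipliers. Absolute myocardial rates in this phantom are set
#' to values typical of the hyperpolarized cardiac literature (kPL around
#' 0.02 s^-1, kPB around 0.01 s^-1 fasted); the fed state multiplies kPB
#' strongly (PDH activation by insulin) and kPL moderately.
#'
#' @param k_pl,k_pb fasted myocardial rates (s^-1), scalar or length-16
#'   per-segment vectors.
#' @param fed_k_pl_mult,fed_k_pb_mult fed-state multipliers (>= 0).
#' @param myo_uptake myocardial pyruvate delivery amplitude relative to the
#'   blood input (perfusion/uptake fraction).
#' @return Object of class `"hp_kinetics_spec"`.
#' @export
tissue_kinetics <- function(k_pl = 0.02, k_pb = 0.01,
                            fed_k_pl_mult = 1.3, fed_k_pb_mult = 2.0,
                            myo_uptake = 0.15) {
  k_pl <- rep_len(k_pl, 16)
  k_pb <- rep_len(k_pb, 16)
  if (any(k_pl < 0) || any(k_pb < 0)) {
    stop("rates must be nonnegative", call. = FALSE)
  }
  if (fed_k_pl_mult < 0 || fed_k_pb_mult < 0) {
    stop("fed multipliers must be nonnegative", call. = FALSE)
  }
  structure(list(k_pl = k_pl, k_pb = k_pb,
                 fed_k_pl_mult = fed_k_pl_mult,
                 fed_k_pb_mult = fed_k_pb_mult,
                 myo_uptake = myo_uptake),
            class = "hp_kinetics_spec")
}

# Segment rates in a given state.
state_rates <- function(kinetics, state) {
  fed <- identical(state, "fed")
  list(k_pl = kinetics$k_pl * if (fed) kinetics$fed_k_pl_mult else 1,
       k_pb = kinetics$k_pb * if (fed) kinetics$fed_k_pb_mult else 1)
}

#' Receive coil array model
#'
#' A paddle-style array: channels centered on an anterior arc outside the
#' imaged region, each with a smooth rational-falloff magnitude and a weak
#' linear phase ramp. The root-sum-of-squares of the sensitivities is
#' strictly positive over the grid, with an anterior/septal bias mimicking
#' a surface receive array.
#'
#' @param n_channels number of receive channels.
#' @param sigma per-channel complex Gaussian noise standard deviation
#'   (image units; identity noise covariance). The default puts the
#'   myocardial pyruvate AUC-SNR of the rendered phantom in the
#'   few-hundred range -- the regime in which the SNR-200 quantification
#'   mask retains the myocardium -- with blood-pool SNR roughly tenfold
#'   higher and background AUC-SNR of order one.
#' @return Object of class `"hp_coils"`.
#' @export
coil_array <- function(n_channels = 8, sigma = 0.001) {
  structure(list(n_channels = n_channels, sigma = sigma),
            class = "hp_coils")
}

#' Complex sensitivity fields of a coil array over a phantom grid
#'
#' @param coils an [coil_array()].
#' @param geometry an [build_geometry()] geometry.
#' @return Complex array `(ny, nx, n_slices, n_channels)`.
#' @export
make_sensitivities <- function(coils, geometry) {
  d <- geometry$dims
  nc <- coils$n_channels
  ny <- d[["ny"]]; nx <- d[["nx"]]; ns <- d[["n_slices"]]
  row <- matrix(seq_len(ny), ny, nx)
  col <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  # channel centers on an anterior (top of image) arc
  ang <- deg2rad(seq(20, 160, length.out = nc))
  rad <- 0.75 * max(ny, nx)
  width <- 0.6 * max(ny, nx)
  sens <- array(0i, c(ny, nx, ns, nc))
  for (ch in seq_len(nc)) {
    ccx <- cx + rad * cos(ang[ch])
    ccy <- cy - rad * sin(ang[ch])          # anterior = low row index
    dist2 <- (row - ccy)^2 + (col - ccx)^2
    mag <- 1 / (1 + dist2 / width^2)
    ph <- 0.02 * ((col - cx) * cos(ang[ch]) - (row - cy) * sin(ang[ch])) +
      2 * pi * (ch - 1) / nc
    plane <- mag * exp(1i * ph)
    for (s in seq_len(ns)) sens[, , s, ch] <- plane
  }
  sens
}

#' Acquisition protocol of the dynamic multi-metabolite scan
#'
#' Defaults mirror the cardiac protocol this pipeline targets: 30 dynamic
#' frames at one frame per 3 heartbeats (~3.6 s), 5 short-axis slices,
#' 20 degree pyruvate / 30 degree lactate and bicarbonate excitations, 6 mm
#' in-plane pyruvate and 12 mm lactate/bicarbonate resolution, 21 mm slices,
#' a 22 ms spiral readout, and a (pyruvate, lactate, bicarbonate) metabolite
#' ordering within each frame.
#'
#' @param n_frames,frame_dt number of dynamic frames and frame interval (s).
#' @param n_slices number of slices.
#' @param flip_pyruvate,flip_lactate,flip_bicarbonate flip angles (degrees).
#' @param res_mm named in-plane resolutions (mm).
#' @param slice_mm slice thickness (mm).
#' @param readout_ms spiral readout duration (ms).
#' @param seed random seed for rendering.
#' @return Object of class `"hp_protocol"`.
#' @export
acquisition_protocol <- function(n_frames = 30, frame_dt = 3.6, n_slices = 5,
                                 flip_pyruvate = 20, flip_lactate = 30,
                                 flip_bicarbonate = 30,
                                 res_mm = c(pyruvate = 6, lactate = 12,
                                            bicarbonate = 12),
                                 slice_mm = 21, readout_ms = 22, seed = 1L) {
  if (frame_dt <= 0 || n_frames < 1) {
    stop("need frame_dt > 0 and n_frames >= 1", call. = FALSE)
  }
  structure(list(n_frames = n_frames, frame_dt = frame_dt,
                 n_slices = n_slices,
                 flip = c(pyruvate = flip_pyruvate, lactate = flip_lactate,
                          bicarbonate = flip_bicarbonate),
                 res_mm = res_mm, slice_mm = slice_mm,
                 readout_ms = readout_ms,
                 order = c("pyruvate", "lactate", "bicarbonate"),
                 seed = seed),
            class = "hp_protocol")
}

#' @export
print.hp_protocol <- function(x, ...) {
  cat(sprintf("Acquisition: %d frames x %.1f s, %d slices, flips %s deg\n",
              x$n_frames, x$frame_dt, x$n_slices,
              paste(x$flip, collapse = "/")))
  invisible(x)
}

# Flip schedule implied by a protocol.
protocol_flips <- function(protocol) {
  flip_schedule(times = seq(0, by = protocol$frame_dt,
                            length.out = protocol$n_frames),
                pyruvate = protocol$flip[["pyruvate"]],
                lactate = protocol$flip[["lactate"]],
                bicarbonate = protocol$flip[["bicarbonate"]])
}

#' Noiseless metabolite timecourses per phantom region
#'
#' Blood pools convert pyruvate to lactate at the (small) blood LDH rate
#' and produce no bicarbonate; each myocardial segment converts at its own
#' kPL/kPB. The myocardial pyruvate delivery is the blood input delayed by
#' the transit plus perfusion delay and scaled by the uptake fraction.
#'
#' @param kinetics [tissue_kinetics()].
#' @param aif [aif_model()].
#' @param protocol [acquisition_protocol()].
#' @param state `"fasted"` or `"fed"`.
#' @return List of 18 `"hp_timecourses"` keyed by region code (as
#'   character): `"1"` RV blood, `"2"` LV blood, `"3"`..`"18"` myocardial
#'   AHA segments 1-16.
#' @export
region_timecourses <- function(kinetics, aif, protocol,
                               state = c("fasted", "fed")) {
  state <- match.arg(state)
  flips <- protocol_flips(protocol)
  relax <- relaxation_times()
  blood_rates <- kinetic_rates(aif$k_pl_blood, 0)
  rates <- state_rates(kinetics, state)
  out <- vector("list", 18)
  names(out) <- as.character(1:18)
  out[["1"]] <- hp_forward_model(function(t) gamma_variate(t, aif),
                                 blood_rates, relax, flips)
  out[["2"]] <- hp_forward_model(
    function(t) gamma_variate(t, aif, delay = aif$transit_delay),
    blood_rates, relax, flips)
  myo_delay <- aif$transit_delay + aif$perfusion_delay
  for (s in 1:16) {
    out[[as.character(s + 2)]] <- hp_forward_model(
      function(t) kinetics$myo_uptake * gamma_variate(t, aif, delay = myo_delay),
      kinetic_rates(rates$k_pl[s], rates$k_pb[s]), relax, flips)
  }
  out
}

#' Render a synthetic dynamic multi-channel study
#'
#' Produces complex multi-channel dynamic images for the three metabolites:
#' region timecourses painted into the label map, multiplied by the coil
#' sensitivities and a smooth per-voxel constant phase field, with lactate
#' and bicarbonate rendered at 2x coarser in-plane resolution (2x2 in-plane
#' block averaging before noise, preserving AUC sums) and complex Gaussian
#' noise added per channel. Rendering with the same seed is bit-identical;
#' a noiseless render is exactly zero in background voxels.
#'
#' @param geometry [build_geometry()].
#' @param kinetics [tissue_kinetics()].
#' @param aif [aif_model()].
#' @param coils [coil_array()].
#' @param protocol [acquisition_protocol()].
#' @param state `"fasted"` or `"fed"`.
#' @param noise add complex Gaussian noise?
#' @param phase_offsets apply the smooth per-voxel phase field?
#' @param seed seed for the phase field and noise; defaults to
#'   `protocol$seed`.
#' @return Object of class `"hp_study"`: list with `images` (named list of
#'   complex arrays `(ny, nx, n_slices, n_frames, n_channels)`), `protocol`,
#'   `state`, `seed`, and `truth` (ground-truth rate maps, label map,
#'   region curves, phase field, sensitivities, noise sigma).
#' @export
render_dynamic_study <- function(geometry, kinetics = tissue_kinetics(),
                                 aif = aif_model(), coils = coil_array(),
                                 protocol = acquisition_protocol(),
                                 state = c("fasted", "fed"),
                                 noise = TRUE, phase_offsets = TRUE,
                                 seed = NULL) {
  state <- match.arg(state)
  if (is.null(seed)) seed <- protocol$seed
  d <- geometry$dims
  ny <- d[["ny"]]; nx <- d[["nx"]]; ns <- d[["n_slices"]]
  nt <- protocol$n_frames
  nc <- coils$n_channels
  if (ns != protocol$n_slices) {
    stop("geometry and protocol disagree on the number of slices",
         call. = FALSE)
  }
  curves <- region_timecourses(kinetics, aif, protocol, state)
  # region code -> curve row lookup (row 1 = background, zero signal)
  lut <- matrix(0, 19, 3 * nt)
  for (code in 1:18) {
    lut[code + 1, ] <- as.vector(curves[[as.character(code)]][, 1:3])
  }
  labvec <- as.integer(geometry$labels)
  base <- lut[labvec + 1L, , drop = FALSE]   # nvox x (3 nt)
  nvox <- ny * nx * ns
  sens <- make_sensitivities(coils, geometry)
  sens_m <- array(sens, c(nvox, nc))
  rates <- state_rates(kinetics, state)
  truth_kpl <- array(0, d)
  truth_kpb <- array(0, d)
  truth_kpl[geometry$labels %in% 1:2] <- aif$k_pl_blood
  for (s in 1:16) {
    truth_kpl[geometry$labels == s + 2L] <- rates$k_pl[s]
    truth_kpb[geometry$labels == s + 2L] <- rates$k_pb[s]
  }
  with_seed(seed, {
    phase <- if (phase_offsets) smooth_phase_field(ny, nx, ns) else array(0, d)
    ph_fac <- exp(1i * as.vector(phase))
    images <- vector("list", 3)
    names(images) <- c("pyruvate", "lactate", "bicarbonate")
    for (m in 1:3) {
      bm <- base[, (m - 1) * nt + seq_len(nt), drop = FALSE] * ph_fac
      arr <- array(0i, c(ny, nx, ns, nt, nc))
      for (ch in seq_len(nc)) {
        arr[, , , , ch] <- array(bm * sens_m[, ch], c(ny, nx, ns, nt))
      }
      if (m > 1) arr <- block_average_2x2(arr)
      if (noise) {
        arr <- arr + complex(real = rnorm(length(arr), sd = coils$sigma),
                             imaginary = rnorm(length(arr), sd = coils$sigma))
        arr <- array(arr, c(ny, nx, ns, nt, nc))
      }
      images[[m]] <- arr
    }
    structure(
      list(images = images, protocol = protocol, state = state, seed = seed,
           truth = list(k_pl = truth_kpl, k_pb = truth_kpb,
                        labels = geometry$labels, curves = curves,
                        phase = phase, sensitivities = sens,
                        sigma = if (noise) coils$sigma else 0,
                        aif = aif, kinetics = kinetics)),
      class = "hp_study"
    )
  })
}

#' @export
print.hp_study <- function(x, ...) {
  d <- dim(x$images$pyruvate)
  cat(sprintf("Synthetic dynamic study (%s): %d x %d x %d, %d frames, %d channels, seed %d\n",
              x$state, d[1], d[2], d[3], d[4], d[5], x$seed))
  invisible(x)
}

# Smooth low-order per-voxel phase field (constant over the time series),
# drawn from the active RNG stream.
smooth_phase_field <- function(ny, nx, ns) {
  row <- matrix(seq_len(ny) / ny, ny, nx)
  col <- matrix(seq_len(nx) / nx, ny, nx, byrow = TRUE)
  out <- array(0, c(ny, nx, ns))
  for (s in seq_len(ns)) {
    f <- stats::runif(2, 0.3, 1.2)
    a <- stats::runif(3, -0.8, 0.8)
    out[, , s] <- a[1] + a[2] * sin(2 * pi * f[1] * row + a[3]) +
      a[3] * cos(2 * pi * f[2] * col - a[1])
  }
  out
}

#' Combine and phase a rendered study into real-valued dynamics
#'
#' Convenience wrapper over the reconstruction-side operations for studies
#' already in image space: Roemer-combines the channels (by default with
#' sensitivities estimated from the pyruvate channel AUCs) and applies the
#' per-voxel constant-phase correction, returning the signed real-valued
#' dynamic images used by all quantification.
#'
#' @param study an [render_dynamic_study()] study.
#' @param maps optional sensitivity maps; default estimates them from the
#'   study's pyruvate data via [estimate_sensitivities()].
#' @return List with `images` (named list of real arrays
#'   `(ny, nx, n_slices, n_frames)`), `phase` (per-metabolite phase maps)
#'   and `maps`.
#' @export
combine_study <- function(study, maps = NULL) {
  d <- dim(study$images$pyruvate)
  nt <- d[4]; nc <- d[5]
  if (is.null(maps)) {
    pyr_auc <- array(0i, c(d[1], d[2], d[3], nc))
    for (ch in seq_len(nc)) {
      pyr_auc[, , , ch] <- apply(study$images$pyruvate[, , , , ch, drop = FALSE],
                                 1:3, sum)
    }
    maps <- estimate_sensitivities(pyr_auc)
  }
  out <- list()
  phase <- list()
  for (m in names(study$images)) {
    comb <- array(0i, d[1:4])
    for (f in seq_len(nt)) {
      comb[, , , f] <- roemer_combine(
        array(study$images[[m]][, , , f, ], c(d[1:3], nc)), maps)
    }
    pc <- phase_correct(comb)
    out[[m]] <- pc$real
    phase[[m]] <- pc$phase
  }
  list(images = out, phase = phase, maps = maps)
}

#' Generate a paired fasted/fed synthetic cohort
#'
#' Draws per-subject ground-truth rates and blood glucose values and builds
#' the paired study specifications for a fed/fasted crossover: each subject
#' is scanned fasted and again after a glucose load, with the fed kPB (and,
#' more weakly, kPL) scaled up in proportion to the subject's glucose
#' increment. One subject can be designated a non-responder (no glucose
#' rise, rates unchanged), emulating the occasional volunteer whose glucose
#' challenge fails to raise insulin-driven PDH flux.
#'
#' Studies are returned as lazy specifications (a rendered 8-channel study
#' is large); materialize any of them with [render_cohort_study()].
#'
#' @param n_subjects number of subjects (>= 2).
#' @param effect list with `k_pb_multiplier` and `k_pl_multiplier`: the
#'   fed/fasted rate ratio of a full responder.
#' @param nonresponder index of the non-responder subject, or `NULL`.
#' @param seed cohort seed.
#' @param geometry,kinetics,aif,coils,protocol shared phantom components;
#'   `kinetics` supplies the population-mean rates.
#' @param subject_cv lognormal coefficient of variation of per-subject
#'   fasted rates.
#' @return Object of class `"hp_cohort"`: `subjects` (per-subject kinetics
#'   and glucose), `manifest` (data frame: subject, state, glucose, k_pl,
#'   k_pb ground-truth myocardial means, seed), and the shared components.
#' @export
generate_paired_cohort <- function(n_subjects = 5,
                                   effect = list(k_pb_multiplier = 2,
                                                 k_pl_multiplier = 1.3),
                                   nonresponder = 4, seed = 1,
                                   geometry = NULL,
                                   kinetics = tissue_kinetics(),
                                   aif = aif_model(),
                                   coils = coil_array(),
                                   protocol = acquisition_protocol(),
                                   subject_cv = 0.2) {
  if (n_subjects < 2) stop("need at least 2 subjects", call. = FALSE)
  if (is.null(geometry)) geometry <- build_geometry()
  glu_ref <- 38   # reference glucose increment (mg/dL) of a full responder
  with_seed(seed, {
    subjects <- vector("list", n_subjects)
    rows <- list()
    for (i in seq_len(n_subjects)) {
      nr <- !is.null(nonresponder) && i == nonresponder
      sdlog <- sqrt(log(1 + subject_cv^2))
      kpl_i <- stats::rlnorm(1, log(mean(kinetics$k_pl)) - sdlog^2 / 2, sdlog)
      kpb_i <- stats::rlnorm(1, log(mean(kinetics$k_pb)) - sdlog^2 / 2, sdlog)
      glu_fast <- round(rnorm(1, 70, 8))
      inc <- if (nr) max(0, round(rnorm(1, 2, 1))) else round(rnorm(1, glu_ref, 5))
      mult_pb <- if (nr) 1 else 1 + (effect$k_pb_multiplier - 1) * inc / glu_ref
      mult_pl <- if (nr) 1 else 1 + (effect$k_pl_multiplier - 1) * inc / glu_ref
      kin_i <- tissue_kinetics(k_pl = kpl_i, k_pb = kpb_i,
                               fed_k_pl_mult = mult_pl,
                               fed_k_pb_mult = mult_pb,
                               myo_uptake = kinetics$myo_uptake)
      subjects[[i]] <- list(id = sprintf("S%02d", i), kinetics = kin_i,
                            glucose_fasted = glu_fast,
                            glucose_fed = glu_fast + inc,
                            nonresponder = nr)
      for (st in c("fasted", "fed")) {
        r <- state_rates(kin_i, st)
        rows[[length(rows) + 1]] <- data.frame(
          subject = subjects[[i]]$id, state = st,
          glucose = if (st == "fed") glu_fast + inc else glu_fast,
          k_pl = mean(r$k_pl), k_pb = mean(r$k_pb),
          seed = seed * 1000L + i * 10L + (st == "fed"))
      }
    }
    structure(list(subjects = subjects, manifest = do.call(rbind, rows),
                   effect = effect, nonresponder = nonresponder, seed = seed,
                   geometry = geometry, aif = aif, coils = coils,
                   protocol = protocol),
              class = "hp_cohort")
  })
}

#' @export
print.hp_cohort <- function(x, ...) {
  cat(sprintf("Paired fasted/fed cohort: %d subjects, %d studies (seed %d)\n",
              length(x$subjects), nrow(x$manifest), x$seed))
  print(x$manifest[, c("subject", "state", "glucose", "k_pl", "k_pb")],
        row.names = FALSE)
  invisible(x)
}

#' Materialize one cohort study
#'
#' @param cohort an [generate_paired_cohort()] cohort.
#' @param subject subject index.
#' @param state `"fasted"` or `"fed"`.
#' @param ... passed to [render_dynamic_study()] (e.g. `noise = FALSE`).
#' @return An `"hp_study"`.
#' @export
render_cohort_study <- function(cohort, subject, state = c("fasted", "fed"),
                                ...) {
  state <- match.arg(state)
  sub <- cohort$subjects[[subject]]
  row <- cohort$manifest[cohort$manifest$subject == sub$id &
                           cohort$manifest$state == state, ]
  render_dynamic_study(cohort$geometry, sub$kinetics, cohort$aif,
                       cohort$coils, cohort$protocol, state = state,
                       seed = row$seed, ...)
}
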