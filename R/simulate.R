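#' Invert the pendulum step-length relation
#'
#' Solves `L = K_I * 2 * sqrt(2 * W_h * H - H^2)` for the vertical excursion,
#' taking the smaller root `H = W_h - sqrt(W_h^2 - (L / (2 K_I))^2)` (the
#' physically relevant branch for small excursions). [step_length()] applied
#' to the result returns `L` to numerical precision.
#'
#' @param L step length in metres, in `[0, 2 * K_I * W_h)`.
#' @param cfg a [pendulum_config()].
#' @return Vertical excursion `H` in metres.
#' @export
invert_pendulum <- function(L, cfg = pendulum_config()) {
  stopifnot(inherits(cfg, "pendulum_config"))
  if (any(L < 0 | L >= 2 * cfg$K_I * cfg$W_h)) {
    stop("domain error: L must lie in [0, 2 * K_I * W_h)", call. = FALSE)
  }
  r <- L / (2 * cfg$K_I)
  cfg$W_h - sqrt(cfg$W_h^2 - r^2)
}

#' Specification of one synthetic walk
#'
#' Parameters of a simulated straight walk: per-step durations and lengths
#' are drawn from truncated normals (floors 0.25 s and 0.05 m), the sensor's
#' vertical displacement is built as one raised-cosine arc per step whose
#' excursion is the pendulum inverse of the drawn step length, and the
#' acceleration is the exact second derivative of that closed-form
#' displacement plus gravity, static tilt and optional white noise.
#'
#' @param n_steps number of steps (at least 3).
#' @param step_time_mean,step_time_sd per-step duration distribution (s).
#' @param step_length_mean,step_length_sd per-step length distribution (m);
#'   the mean must be pendulum-invertible (`< 2 * K_I * W_h`).
#' @param cfg a [pendulum_config()].
#' @param fs sampling rate in Hz (default 100 for numerically clean tests;
#'   use 32 to match the wearable device).
#' @param noise_sigma_rel additive Gaussian noise standard deviation as a
#'   fraction of the dynamic signal RMS.
#' @param tilt_deg static pitch of the sensor in degrees (rotates gravity
#'   into the AP channel).
#' @param roll_deg static roll in degrees (ML channel).
#' @param pad_s still standing time prepended and appended (s).
#' @param seed integer seed.
#' @return An object of class `walk_spec`.
#' @export
walk_spec <- function(n_steps = 16, step_time_mean = 0.55,
                      step_time_sd = 0.02, step_length_mean = 0.37,
                      step_length_sd = 0.01, cfg = pendulum_config(),
                      fs = 100, noise_sigma_rel = 0, tilt_deg = 0,
                      roll_deg = 0, pad_s = 0.5, seed = 1L) {
  if (n_steps < 3L) stop("parameter error: n_steps must be at least 3",
                         call. = FALSE)
  if (step_length_mean >= 2 * cfg$K_I * cfg$W_h) {
    stop("domain error: step_length_mean not pendulum-invertible",
         call. = FALSE)
  }
  if (fs <= 0 || noise_sigma_rel < 0 || pad_s < 0) {
    stop("parameter error: invalid walk specification", call. = FALSE)
  }
  structure(as.list(environment()), class = "walk_spec")
}

#' Simulate one ground-truth-annotated walk
#'
#' Generates the triaxial recording implied by a [walk_spec()] together with
#' its true initial-contact times (the minima of the closed-form
#' displacement, i.e. the step boundaries) and the true gait parameters
#' computed directly from the drawn step durations and lengths (so all
#' parameter identities hold exactly).
#'
#' Within step `i` of duration `T_i` and excursion `H_i`, the sensor height
#' is `h(t) = (H_i / 2) * (1 - cos(2 pi t / T_i))`: minimal at the step
#' boundaries (heel strikes) and maximal at mid-stance, mimicking the vault
#' over the stance leg. The vertical acceleration is its exact second
#' derivative; gravity (1 g) is added, the static tilt rotates part of it
#' into the AP/ML channels, and seeded white noise is added to all three
#' channels.
#'
#' @param spec a [walk_spec()].
#' @return An object of class `annotated_walk`: list with `recording`
#'   ([triaxial_recording()]), `truth_events` ([gait_events()]),
#'   `truth_params` (`gait_parameters`) and `spec`.
#' @export
simulate_walk <- function(spec) {
  stopifnot(inherits(spec, "walk_spec"))
  local_seed(spec$seed, {
    cfg <- spec$cfg
    lmax <- 2 * cfg$K_I * cfg$W_h
    Ts <- rtnorm(spec$n_steps, spec$step_time_mean, spec$step_time_sd,
                 lower = 0.25)
    Ls <- rtnorm(spec$n_steps, spec$step_length_mean, spec$step_length_sd,
                 lower = 0.05, upper = 0.95 * lmax)
    Hs <- invert_pendulum(Ls, cfg)

    bounds <- spec$pad_s + c(0, cumsum(Ts))   # true IC times
    dur <- bounds[length(bounds)] + spec$pad_s
    t <- seq(0, dur, by = 1 / spec$fs)

    step_of <- findInterval(t, bounds)
    inside <- step_of >= 1L & step_of <= spec$n_steps & t < bounds[length(bounds)]
    a_dyn <- numeric(length(t))
    idx <- which(inside)
    si <- step_of[idx]
    om <- 2 * pi / Ts[si]
    a_dyn[idx] <- (Hs[si] / 2) * om^2 * cos(om * (t[idx] - bounds[si]))

    # gait initiation/termination transients: continue the outer steps'
    # cosine into the pads under a Gaussian decay so the acceleration is
    # continuous (and locally symmetric) at the first and last heel strike,
    # as in a smooth weight-shift into and out of steady walking; the
    # transient lies outside every IC-to-IC window, so truth parameters are
    # unaffected
    pre <- which(t < bounds[1L])
    if (length(pre) > 0L) {
      om1 <- 2 * pi / Ts[1L]
      dt1 <- t[pre] - bounds[1L]
      a_dyn[pre] <- (Hs[1L] / 2) * om1^2 * cos(om1 * dt1) *
        exp(-dt1^2 / (2 * (0.25 * Ts[1L])^2))
    }
    post <- which(t >= bounds[length(bounds)])
    if (length(post) > 0L) {
      nL <- spec$n_steps
      omn <- 2 * pi / Ts[nL]
      dtn <- t[post] - bounds[length(bounds)]
      a_dyn[post] <- (Hs[nL] / 2) * omn^2 * cos(omn * dtn) *
        exp(-dtn^2 / (2 * (0.25 * Ts[nL])^2))
    }

    # sensor frame: gravity plus dynamics on V, rotated by the static tilt
    v0 <- 1 + a_dyn / G_MS2
    th <- spec$tilt_deg * pi / 180
    ph <- spec$roll_deg * pi / 180
    ap <- sin(th) * v0
    v1 <- cos(th) * v0
    ml <- sin(ph) * v1
    v2 <- cos(ph) * v1

    if (spec$noise_sigma_rel > 0) {
      sig <- spec$noise_sigma_rel * sqrt(mean(a_dyn^2)) / G_MS2
      ml <- ml + rnorm(length(t), 0, sig)
      ap <- ap + rnorm(length(t), 0, sig)
      v2 <- v2 + rnorm(length(t), 0, sig)
    }

    rec <- triaxial_recording(spec$subject_id %||% "sim", spec$leg %||% "left",
                              t, acc_ml = ml, acc_ap = ap, acc_v = v2,
                              fs = spec$fs)
    truth_events <- gait_events(rec$subject_id, rec$leg, bounds,
                                method_params = list(source = "simulator"))
    st <- Ts
    strt <- Ts[-1] + Ts[-length(Ts)]
    truth_params <- structure(
      list(subject_id = rec$subject_id, leg = rec$leg,
           step_time_s = mean(st), stride_time_s = mean(strt),
           step_length_m = mean(Ls), stride_length_m = 2 * mean(Ls),
           walking_speed_mps = mean(Ls) / mean(st),
           n_steps = spec$n_steps,
           per_step = data.frame(index = seq_along(Ts),
                                 ic_start = bounds[-length(bounds)],
                                 ic_end = bounds[-1], step_time = Ts,
                                 H = Hs, step_length = Ls),
           config = unclass(cfg)),
      class = "gait_parameters")
    structure(list(recording = rec, truth_events = truth_events,
                   truth_params = truth_params, spec = spec),
              class = "annotated_walk")
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Group-level simulator presets. The healthy-older-group (HOG) values follow
# the reference motion-capture means (step time ~0.55 s, step length 0.37 m);
# the PD preset shortens step length by the separation factor, with walking
# speed following through the length/time ratio. Between-subject and
# within-walk spreads are modest, as expected for age-matched cohorts walking
# a short fixed track at comfortable pace.
cohort_presets <- function(separation = 0.85) {
  list(
    HOG = list(step_time_mean = 0.55, step_length_mean = 0.37,
               between_time_sd = 0.03, between_length_sd = 0.025,
               within_time_sd = 0.02, within_length_sd = 0.01),
    PD = list(step_time_mean = 0.55, step_length_mean = 0.37 * separation,
              between_time_sd = 0.03, between_length_sd = 0.025,
              within_time_sd = 0.02, within_length_sd = 0.01)
  )
}

#' Simulate a two-group cohort with ground truth
#'
#' Draws per-subject mean step time and step length from group-level
#' distributions (PD step length shortened by `separation`; speed follows),
#' simulates one annotated walk per subject per leg, and builds a subject
#' metadata table with demographics drawn from normal approximations of the
#' two cohorts (PD: age 70.6 +/- 9.5, UPDRS-III 20.9 +/- 12.3, H&Y
#' 2.1 +/- 0.74, disease duration 35.5 +/- 27.1 months; HOG: age 69.4 +/-
#' 7.4, UPDRS-III and duration 0).
#'
#' @param n_pd,n_hog subjects per group (at least 1 each).
#' @param separation multiplicative PD step-length factor (1 = no group
#'   difference; default 0.85).
#' @param noise_sigma_rel,fs,n_steps,tilt_deg passed to each [walk_spec()].
#' @param cfg a [pendulum_config()].
#' @param seed integer seed controlling every draw.
#' @return An object of class `gait_cohort`: list with `walks` (named list
#'   of `annotated_walk`, keys `<subject>_<leg>`), `subjects` (metadata
#'   data.frame) and `truth` (data.frame of true per-leg parameters).
#' @export
simulate_cohort <- function(n_pd = 48, n_hog = 40, separation = 0.85,
                            noise_sigma_rel = 0.03, fs = 100, n_steps = 16,
                            tilt_deg = 0, cfg = pendulum_config(), seed = 1L) {
  if (n_pd < 1L || n_hog < 1L) {
    stop("parameter error: need at least 1 subject per group", call. = FALSE)
  }
  presets <- cohort_presets(separation)
  local_seed(seed, {
    groups <- c(rep("PD", n_pd), rep("HOG", n_hog))
    ids <- sprintf("S%03d", seq_along(groups))
    walks <- list()
    truth <- list()
    subj <- list()
    for (i in seq_along(ids)) {
      g <- groups[i]
      p <- presets[[g]]
      mu_t <- rtnorm(1, p$step_time_mean, p$between_time_sd, lower = 0.3)
      mu_l <- rtnorm(1, p$step_length_mean, p$between_length_sd,
                     lower = 0.08, upper = 0.9 * 2 * cfg$K_I * cfg$W_h)
      for (leg in c("left", "right")) {
        ws <- walk_spec(n_steps = n_steps, step_time_mean = mu_t,
                        step_time_sd = p$within_time_sd,
                        step_length_mean = mu_l,
                        step_length_sd = p$within_length_sd, cfg = cfg,
                        fs = fs, noise_sigma_rel = noise_sigma_rel,
                        tilt_deg = tilt_deg,
                        seed = sample.int(.Machine$integer.max, 1))
        ws$subject_id <- ids[i]
        ws$leg <- leg
        aw <- simulate_walk(ws)
        walks[[paste0(ids[i], "_", leg)]] <- aw
        truth[[length(truth) + 1L]] <- as.data.frame(aw$truth_params)
      }
      if (g == "PD") {
        subj[[i]] <- data.frame(
          subject_id = ids[i], group = "PD",
          sex = sample(c("M", "F"), 1, prob = c(25, 23)),
          age = round(rnorm(1, 70.61, 9.51), 1),
          updrs3 = round(rtnorm(1, 20.9, 12.31, lower = 1)),
          hy_stage = round(rtnorm(1, 2.10, 0.74, lower = 0.5, upper = 5) * 2) / 2,
          disease_duration = round(rtnorm(1, 35.49, 27.07, lower = 1)),
          tug = round(rtnorm(1, 20.87, 15.78, lower = 5), 1),
          tinetti_gait = round(rtnorm(1, 9.86, 2.56, lower = 0, upper = 12)))
      } else {
        subj[[i]] <- data.frame(
          subject_id = ids[i], group = "HOG",
          sex = sample(c("M", "F"), 1, prob = c(22, 18)),
          age = round(rnorm(1, 69.36, 7.42), 1),
          updrs3 = 0, hy_stage = NA_real_, disease_duration = 0,
          tug = NA_real_, tinetti_gait = NA_real_)
      }
    }
    structure(list(walks = walks,
                   subjects = validate_subject_table(do.call(rbind, subj)),
                   truth = do.call(rbind, truth), seed = seed,
                   separation = separation),
              class = "gait_cohort")
  })
}

#' @export
print.gait_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat(sprintf("<gait_cohort> %d subjects (%d PD, %d HOG), %d recordings\n",
              nrow(x$subjects), tab[["PD"]], tab[["HOG"]], length(x$walks)))
  invisible(x)
}
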