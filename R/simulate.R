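#' Simulation configuration for synthetic arousal cohorts
#'
#' Bundles every tunable of the synthetic-data generator with defaults that
#' mirror the study conditions of the 7 T resting-state analysis the pipeline
#' implements: TR = 0.586 s, 400 cortical parcels, roughly 2.5 phasic events
#' per 10-min run and type, an anterior-to-posterior travelling wave at
#' 0.13 m/s, modular correlation structure whose between-module coupling
#' rises for 10 TR after LC-type events, and post-event displacement variance
#' scaled by 2 (LC, landscape flattening) and 0.5 (BNM, deepening).
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_time time points per subject (> 100).
#' @param n_parcels number of cortical parcels.
#' @param tr_seconds repetition time in seconds.
#' @param burst_rate_per_min expected phasic bursts per minute, applied to
#'   each event type (`lc`, `bnm`, `joint`) independently.
#' @param burst_amplitude_sd burst amplitude in units of the noise s.d.
#' @param wave_velocity_m_per_s travelling-wave propagation speed.
#' @param wave_direction unit vector in MNI space along which the wave
#'   travels; the default `c(0, -1, 0)` is anterior-to-posterior.
#' @param wave_amplitude_sd peak amplitude of the per-parcel wave response,
#'   in noise-s.d. units.
#' @param n_modules number of planted cortical modules.
#' @param within_corr,between_corr_base,between_corr_post_event planted
#'   correlations: within-module, between-module at rest, and between-module
#'   during the post-event integration window.
#' @param integration_window number of TRs after an LC-type event during
#'   which between-module coupling is elevated.
#' @param noise_band passband (Hz) of the synthetic BOLD noise.
#' @param spectral_exponent in-band power-law exponent of the noise
#'   spectrum (power ~ 1/f^exponent); 2 mirrors the low-frequency dominance
#'   of resting BOLD.
#' @param channel_corr shared-variance correlation between the LC and BNM
#'   noise floors (the nuclei are heavily interconnected and share global
#'   and vascular fluctuations); it also sets the noise variance of the
#'   LC-BNM contrast to `2 (1 - channel_corr)`.
#' @param mix_nuisance mixing weight of the fourth-ventricle nuisance channel
#'   into the observed LC series (exercises residualisation).
#' @param post_event_var_scale named list of displacement-variance factors
#'   applied to the cortical signal in the `landscape_window` after events of
#'   each type; values > 1 flatten the energy landscape, < 1 deepen it.
#' @param landscape_window number of post-event TRs over which displacement
#'   variance is scaled (the landscape's lag horizon).
#' @param min_event_gap minimum separation between any two events, in TR;
#'   the default keeps 21-TR analysis windows disjoint.
#' @param boundary events are kept away from the first/last `boundary` TRs.
#' @param seed integer seed; all subject-level randomness derives from it.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 12, n_time = 1000, n_parcels = 400,
                       tr_seconds = 0.586,
                       burst_rate_per_min = 0.25,
                       burst_amplitude_sd = 3,
                       wave_velocity_m_per_s = 0.13,
                       wave_direction = c(0, -1, 0),
                       wave_amplitude_sd = 3,
                       n_modules = 4,
                       within_corr = 0.6,
                       between_corr_base = 0.05,
                       between_corr_post_event = 0.3,
                       integration_window = 10,
                       noise_band = c(0.01, 0.15),
                       spectral_exponent = 2,
                       channel_corr = 0.7,
                       mix_nuisance = 0.4,
                       post_event_var_scale = list(lc = 2, bnm = 0.5, joint = 1),
                       landscape_window = 15,
                       min_event_gap = 21,
                       boundary = 20,
                       seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects), n_time = as.integer(n_time),
              n_parcels = as.integer(n_parcels), tr_seconds = tr_seconds,
              burst_rate_per_min = burst_rate_per_min,
              burst_amplitude_sd = burst_amplitude_sd,
              wave_velocity_m_per_s = wave_velocity_m_per_s,
              wave_direction = wave_direction / sqrt(sum(wave_direction^2)),
              wave_amplitude_sd = wave_amplitude_sd,
              n_modules = as.integer(n_modules),
              within_corr = within_corr,
              between_corr_base = between_corr_base,
              between_corr_post_event = between_corr_post_event,
              integration_window = as.integer(integration_window),
              noise_band = noise_band,
              spectral_exponent = spectral_exponent,
              channel_corr = channel_corr,
              mix_nuisance = mix_nuisance,
              post_event_var_scale = post_event_var_scale,
              landscape_window = as.integer(landscape_window),
              min_event_gap = as.integer(min_event_gap),
              boundary = as.integer(boundary),
              seed = as.integer(seed))
  if (cfg$n_time <= 100) stop("'n_time' must exceed 100", call. = FALSE)
  stopifnot_scalar_positive(cfg$tr_seconds, "tr_seconds")
  if (cfg$burst_amplitude_sd < 0) stop("burst amplitudes must be positive", call. = FALSE)
  if (cfg$within_corr < cfg$between_corr_post_event ||
      cfg$within_corr + cfg$between_corr_post_event > 1 + 1e-12) {
    # weights below require 1 - a(t)^2 - b^2 >= 0 with b^2 = within - base
    stop("infeasible correlation targets: need between_post <= within and within + between_post <= 1",
         call. = FALSE)
  }
  if (cfg$between_corr_base > cfg$between_corr_post_event) {
    stop("infeasible correlation targets: base between-module correlation exceeds post-event level",
         call. = FALSE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Band-limited Gaussian noise via frequency-domain synthesis: complex
# Gaussian coefficients with power ~ 1/f^exponent on the exact DFT bins
# inside the passband, zero elsewhere, then inverse transform.  Guarantees
# the band limits with no filter transients; the series is z-scored
# afterwards.  The default exponent 2 mirrors the low-frequency dominance
# of resting-state BOLD spectra.
band_noise <- function(n_time, tr_seconds, band, exponent = 2) {
  nf <- floor(n_time / 2)
  f <- (1:nf) / (n_time * tr_seconds)
  keep <- which(f >= band[1] & f <= band[2])
  if (length(keep) == 0) stop("no DFT bins inside the noise band", call. = FALSE)
  spec <- complex(real = rep(0, n_time))
  amp <- f[keep]^(-exponent / 2)
  z <- amp * complex(real = stats::rnorm(length(keep)),
                     imaginary = stats::rnorm(length(keep)))
  spec[1 + keep] <- z
  spec[n_time + 1 - keep] <- Conj(z)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n_time
  zscore(x)
}

# MNI-like parcel grid: parcels on a 3D lattice spanning typical cortical
# extents (x +-70 mm splits hemispheres, y spans 140 mm anterior-posterior,
# z 100 mm), module labels interleaved so modules are not confounded with
# the wave axis.
parcel_grid <- function(n_parcels, n_modules) {
  nz <- max(1L, round(n_parcels^(1 / 3) / 1.6))
  nxy <- ceiling(sqrt(n_parcels / nz))
  g <- expand.grid(x = seq(-70, 70, length.out = nxy),
                   y = seq(-90, 50, length.out = nxy),
                   z = seq(-40, 60, length.out = nz))
  g <- g[seq_len(n_parcels), , drop = FALSE]
  data.frame(parcel_id = paste0("P", seq_len(n_parcels)),
             x_mm = g$x, y_mm = g$y, z_mm = g$z,
             hemisphere = ifelse(g$x < 0, "L", "R"),
             network_label = paste0("M", (seq_len(n_parcels) - 1L) %% n_modules + 1L),
             stringsAsFactors = FALSE)
}

# Poisson event trains per type, merged and thinned to the minimum gap so
# analysis windows never overlap.
draw_events <- function(cfg) {
  minutes <- cfg$n_time * cfg$tr_seconds / 60
  lo <- cfg$boundary + 1L
  hi <- cfg$n_time - cfg$boundary - cfg$min_event_gap
  ev <- do.call(rbind, lapply(c("lc", "bnm", "joint"), function(ty) {
    n <- stats::rpois(1, cfg$burst_rate_per_min * minutes)
    if (n == 0 || hi < lo) return(NULL)
    data.frame(type = ty, t0 = sort(sample(lo:hi, min(n, hi - lo + 1L))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(ev) || nrow(ev) == 0) {
    return(data.frame(type = character(), t0 = integer(), stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$t0), , drop = FALSE]
  keep <- rep(TRUE, nrow(ev))
  last <- -Inf
  for (i in seq_len(nrow(ev))) {
    if (ev$t0[i] - last < cfg$min_event_gap) keep[i] <- FALSE else last <- ev$t0[i]
  }
  ev <- ev[keep, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Generate one synthetic subject
#'
#' Builds a cortical parcel matrix (band-limited noise + planted modular
#' correlation structure + HRF-convolved travelling-wave responses locked to
#' LC-type events), the two subcortical arousal channels (noise +
#' HRF-convolved bursts at the ground-truth onsets, with a fourth-ventricle
#' nuisance channel partially mixed into the observed LC series), and the
#' ground truth needed to score every downstream stage.
#'
#' @param cfg a [sim_config()].
#' @param subject_seed integer seed for this subject's realisation.
#' @return list with elements `cortex` (T x R matrix), `subcort`
#'   (data.frame: `lc`, `bnm`, `ventricle`, `pontine`), `parcels`
#'   (metadata data.frame) and `truth` (list: `events`, `velocity`,
#'   `modules`, `integration`, `delay_range_s`).
#' @export
generate_subject <- function(cfg, subject_seed) {
  withr::with_seed(as.integer(subject_seed), generate_subject_impl(cfg))
}

generate_subject_impl <- function(cfg) {
  Tn <- cfg$n_time; R <- cfg$n_parcels
  parcels <- parcel_grid(R, cfg$n_modules)
  modules <- as.integer(sub("^M", "", parcels$network_label))
  events <- draw_events(cfg)
  tr <- cfg$tr_seconds
  noise <- function() band_noise(Tn, tr, cfg$noise_band, cfg$spectral_exponent)

  # --- subcortical channels -------------------------------------------------
  # Burst amplitudes are defined on the conditioned (band-passed) series, so
  # the injected kernel is rescaled by the band-pass peak attenuation.
  kernel <- double_gamma_hrf(tr, 30) / bandpass_peak_gain(tr)
  impulse_response <- function(t0s) {
    x <- numeric(Tn)
    for (t0 in t0s) {
      idx <- t0:min(Tn, t0 + length(kernel) - 1L)
      x[idx] <- x[idx] + cfg$burst_amplitude_sd * kernel[seq_along(idx)]
    }
    x
  }
  lc_events <- events$t0[events$type %in% c("lc", "joint")]
  bnm_events <- events$t0[events$type %in% c("bnm", "joint")]
  ventricle <- noise()
  pontine <- noise()
  shared <- noise()
  rho <- cfg$channel_corr
  lc_clean <- sqrt(rho) * shared + sqrt(1 - rho) * noise() + impulse_response(lc_events)
  bnm_clean <- sqrt(rho) * shared + sqrt(1 - rho) * noise() + impulse_response(bnm_events)
  lc_obs <- lc_clean + cfg$mix_nuisance * ventricle + cfg$mix_nuisance / 2 * pontine
  bnm_obs <- bnm_clean + cfg$mix_nuisance / 4 * ventricle

  # --- cortical matrix ------------------------------------------------------
  glob <- noise()
  mods <- vapply(seq_len(cfg$n_modules), function(k) noise(),
                 numeric(Tn))
  # time-varying between-module coupling: a(t)^2 rises after LC-type events.
  # The rise is delayed by the HRF peak lag: the coupling here shapes BOLD
  # correlations directly, and the BOLD expression of a neural gain change
  # is haemodynamically delayed just like the subcortical burst response
  # (so measured integration follows the arousal contrast, not vice versa).
  hrf_lag <- which.max(kernel) - 1L
  a2 <- rep(cfg$between_corr_base, Tn)
  for (t0 in lc_events) {
    idx <- (t0 + hrf_lag):min(Tn, t0 + hrf_lag + cfg$integration_window - 1L)
    a2[idx] <- cfg$between_corr_post_event
  }
  b2 <- cfg$within_corr - cfg$between_corr_base
  a_t <- sqrt(a2); b <- sqrt(b2); c_t <- sqrt(pmax(0, 1 - a2 - b2))
  cortex <- matrix(0, Tn, R)
  for (i in seq_len(R)) {
    cortex[, i] <- a_t * glob + b * mods[, modules[i]] +
      c_t * noise()
  }

  # --- travelling wave ------------------------------------------------------
  # onset delay per parcel = distance along the propagation axis / velocity
  proj <- as.matrix(parcels[, c("x_mm", "y_mm", "z_mm")]) %*% cfg$wave_direction
  delay_s <- (proj - min(proj)) / (cfg$wave_velocity_m_per_s * 1000)
  tpk <- seq(0, 30, by = 0.01)
  peak_val <- max(double_gamma_eval(tpk))
  t_grid <- (seq_len(Tn) - 1L) * tr
  for (t0 in lc_events) {
    onset_s <- (t0 - 1L) * tr
    for (i in seq_len(R)) {
      tt <- t_grid - onset_s - delay_s[i]
      sel <- which(tt >= 0 & tt <= 30)
      if (length(sel)) {
        cortex[sel, i] <- cortex[sel, i] +
          cfg$wave_amplitude_sd * double_gamma_eval(tt[sel]) / peak_val
      }
    }
  }

  # --- post-event displacement-variance scaling (landscape ground truth) ---
  for (j in seq_len(nrow(events))) {
    sc <- cfg$post_event_var_scale[[events$type[j]]]
    if (is.null(sc) || sc == 1) next
    t0 <- events$t0[j]
    idx <- (t0 + 1L):min(Tn, t0 + cfg$landscape_window)
    base <- cortex[t0, ]
    cortex[idx, ] <- matrix(base, length(idx), R, byrow = TRUE) +
      sqrt(sc) * (cortex[idx, , drop = FALSE] -
                    matrix(base, length(idx), R, byrow = TRUE))
  }

  list(cortex = cortex,
       subcort = data.frame(lc = lc_obs, bnm = bnm_obs,
                            ventricle = ventricle, pontine = pontine),
       parcels = parcels,
       truth = list(events = events,
                    velocity = cfg$wave_velocity_m_per_s,
                    modules = modules,
                    integration = a2,
                    delay_range_s = range(delay_s)))
}

#' Generate a synthetic cohort
#'
#' Derives per-subject seeds deterministically from `cfg$seed`, generates
#' every subject, and either returns the cohort in memory or writes it to
#' disk (TSV matrices + YAML manifest readable by [load_cohort()]).
#'
#' @param cfg a [sim_config()].
#' @param out_dir optional directory; when given, all subject files, parcel
#'   metadata, ground truth and a manifest are written there.
#' @return list with `cohort` (a `cohort_store`) and `truth` (per-subject
#'   ground-truth list); when `out_dir` is given, also `manifest` (path).
#' @export
generate_cohort <- function(cfg, out_dir = NULL) {
  seeds <- derive_seeds(cfg$seed, cfg$n_subjects)
  ids <- sprintf("sub-%02d", seq_len(cfg$n_subjects))
  subs <- lapply(seq_len(cfg$n_subjects), function(i) generate_subject(cfg, seeds[i]))
  names(subs) <- ids
  cohort <- new_cohort_store(
    subjects = lapply(subs, function(s) list(cortex = s$cortex, subcort = s$subcort)),
    parcels = subs[[1]]$parcels, tr_seconds = cfg$tr_seconds)
  truth <- lapply(subs, `[[`, "truth")
  out <- list(cohort = cohort, truth = truth)
  if (!is.null(out_dir)) {
    out$manifest <- write_cohort(cohort, out_dir, truth = truth)
  }
  out
}

#' Ground-truth events as a phasic event set
#'
#' Wraps the generator's true burst onsets in the same container the
#' detector produces, so downstream stages (landscapes, nulls, waves) can
#' be run against ground truth independently of detector performance.
#'
#' @param truth the `truth` element returned by [generate_cohort()].
#' @param n_time per-subject series length.
#' @return a `phasic_events` object with types mapped to `"LC-BNM"`
#'   (`lc`), `"BNM-LC"` (`bnm`) and `"LC+BNM"` (`joint`).
#' @export
truth_event_set <- function(truth, n_time) {
  te <- truth_events(truth)
  map <- c(lc = "LC-BNM", bnm = "BNM-LC", joint = "LC+BNM")
  events <- data.frame(subject = te$subject,
                       type = if (nrow(te)) unname(map[te$type]) else character(),
                       t0 = te$t0,
                       accel_value = rep(NA_real_, nrow(te)),
                       sustain_peak = rep(NA_real_, nrow(te)),
                       stringsAsFactors = FALSE)
  lens <- as.list(stats::setNames(rep(as.integer(n_time), length(truth)),
                                  names(truth)))
  structure(list(events = events, accel_sd = NA_real_, sustain_sd = NA_real_,
                 sustain_window = 10, boundary = 20, series_lengths = lens),
            class = "phasic_events")
}

#' Cohort-wide ground-truth event table
#'
#' @param truth the `truth` element returned by [generate_cohort()].
#' @return data.frame with columns `subject`, `t0`, `type`.
#' @export
truth_events <- function(truth) {
  out <- do.call(rbind, lapply(names(truth), function(id) {
    ev <- truth[[id]]$events
    if (nrow(ev) == 0) return(NULL)
    data.frame(subject = id, t0 = ev$t0, type = ev$type, stringsAsFactors = FALSE)
  }))
  if (is.null(out)) {
    out <- data.frame(subject = character(), t0 = integer(), type = character(),
                      stringsAsFactors = FALSE)
  }
  out
}
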