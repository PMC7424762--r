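#' Parameters for simulating an iGluSnFR fluorescence trace
#'
#' Defaults describe a single-plane ventral-nerve-cord recording: ~5.4 min of
#' acquisition at 0.92 frames/s, spontaneous glutamate release at a couple of
#' events per minute, transient amplitudes around 0.5 dF/F (an order of
#' magnitude above the per-frame noise), and about a third of events arriving
#' as multi-peak bursts.
#'
#' @param n_frames number of frames (>= 2).
#' @param frame_rate_hz acquisition rate, frames/s.
#' @param baseline_f0 baseline fluorescence, arbitrary units.
#' @param event_rate_per_min expected glutamate events per minute.
#' @param amplitude_mean,amplitude_sd normal distribution of per-peak
#'   amplitudes, dF/F units (draws are truncated to be positive).
#' @param burst_prob probability an event is a multi-peak burst.
#' @param subpeaks_range integer pair: min/max peaks per burst (each >= 2).
#' @param decay_tau_s exponential decay time constant of a transient, seconds.
#' @param rise_frames frames of linear rise from onset to peak.
#' @param burst_gap_frames frames between the end of one subpeak's rise and
#'   the start of the next subpeak's rise within a burst; small values keep
#'   inter-peak troughs well above the onset baseline so that the burst is
#'   one continuous transient.
#' @param noise_sd i.i.d. Gaussian per-frame noise, dF/F units.
#' @param bleach_rate per-frame multiplicative photobleaching (0 = none).
#' @param seed integer seed; identical parameters + seed give bit-identical
#'   output.
#' @return A validated parameter list of class `trace_sim_params`.
#' @export
trace_sim_params <- function(n_frames = 300L, frame_rate_hz = 0.92,
                             baseline_f0 = 100, event_rate_per_min = 2,
                             amplitude_mean = 0.5, amplitude_sd = 0.1,
                             burst_prob = 0.3, subpeaks_range = c(2L, 4L),
                             decay_tau_s = 3, rise_frames = 2L,
                             burst_gap_frames = 1L,
                             noise_sd = 0.02, bleach_rate = 0, seed = 1L) {
  p <- list(n_frames = as.integer(n_frames), frame_rate_hz = frame_rate_hz,
            baseline_f0 = baseline_f0,
            event_rate_per_min = event_rate_per_min,
            amplitude_mean = amplitude_mean, amplitude_sd = amplitude_sd,
            burst_prob = burst_prob,
            subpeaks_range = as.integer(subpeaks_range),
            decay_tau_s = decay_tau_s, rise_frames = as.integer(rise_frames),
            burst_gap_frames = as.integer(burst_gap_frames),
            noise_sd = noise_sd, bleach_rate = bleach_rate,
            seed = as.integer(seed))
  if (p$n_frames < 2L) stop("n_frames must be >= 2", call. = FALSE)
  if (p$frame_rate_hz <= 0) stop("frame_rate_hz must be > 0", call. = FALSE)
  if (p$baseline_f0 <= 0) stop("baseline_f0 must be > 0", call. = FALSE)
  if (p$event_rate_per_min < 0) stop("event_rate_per_min must be >= 0", call. = FALSE)
  if (p$amplitude_mean <= 0) stop("amplitude_mean must be > 0", call. = FALSE)
  if (p$amplitude_sd < 0) stop("amplitude_sd must be >= 0", call. = FALSE)
  if (p$burst_prob < 0 || p$burst_prob > 1) stop("burst_prob must be in [0,1]", call. = FALSE)
  if (length(p$subpeaks_range) != 2L || any(p$subpeaks_range < 2L) ||
      p$subpeaks_range[1L] > p$subpeaks_range[2L]) {
    stop("subpeaks_range must be an increasing pair of counts >= 2", call. = FALSE)
  }
  if (p$decay_tau_s <= 0) stop("decay_tau_s must be > 0", call. = FALSE)
  if (p$rise_frames < 1L) stop("rise_frames must be >= 1", call. = FALSE)
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p$bleach_rate < 0 || p$bleach_rate >= 1) stop("bleach_rate must be in [0,1)", call. = FALSE)
  class(p) <- "trace_sim_params"
  p
}

# transient kernel: linear rise over rise_frames, then exponential decay.
# onset is 1-based; returns the kernel evaluated on frames 1..n.
.transient_kernel <- function(n, onset, amplitude, rise_frames, decay_tau_s,
                              frame_rate_hz) {
  t <- seq_len(n)
  dt <- 1 / frame_rate_hz
  out <- numeric(n)
  rising <- t >= onset & t <= onset + rise_frames
  out[rising] <- amplitude * (t[rising] - onset) / rise_frames
  falling <- t > onset + rise_frames
  out[falling] <- amplitude *
    exp(-(t[falling] - onset - rise_frames) * dt / decay_tau_s)
  out
}

#' Simulate a fluorescence trace with ground-truth glutamate events
#'
#' Generates a raw fluorescence trace
#' `F_t = baseline_f0 * (1 - bleach_rate)^t * (1 + e_t) + baseline_f0 * noise`,
#' where `e_t` sums transient kernels (linear rise, exponential decay) and the
#' noise is i.i.d. Gaussian in dF/F units. Event onsets follow a Poisson
#' process thinned to a minimum separation of one rise plus four decay time
#' constants, so each ground-truth event corresponds to one well-separated
#' transient; bursts are `>= 2` overlapping kernels spaced closely enough that
#' inter-peak troughs stay high above the onset baseline. The effective event
#' rate is therefore slightly below nominal at high rates.
#'
#' Ground truth records, per event, the onset frame and the local maxima
#' (frames and dF/F values) of that event's noiseless component, so detector
#' recovery can be scored without reference to the detector itself.
#'
#' @param params a [trace_sim_params()] list.
#' @param roi_id,animal_id,condition labels stamped on the trace.
#' @return List with `trace` (a [fluorescence_trace]) and `events`, a data
#'   frame with one row per ground-truth event: `onset_frame` (0-based),
#'   `n_peaks`, `is_burst`, and list columns `peak_frames` (0-based) and
#'   `peak_amplitudes` (noiseless dF/F at those frames).
#' @export
simulate_trace <- function(params, roi_id = "roi1", animal_id = "animal1",
                           condition = "control") {
  stopifnot(inherits(params, "trace_sim_params"))
  set.seed(params$seed)
  n <- params$n_frames
  duration_min <- n / params$frame_rate_hz / 60
  n_events <- stats::rpois(1L, params$event_rate_per_min * duration_min)
  min_gap <- params$rise_frames +
    ceiling(4 * params$decay_tau_s * params$frame_rate_hz)

  draw_amp <- function(k) {
    a <- stats::rnorm(k, params$amplitude_mean, params$amplitude_sd)
    for (i in seq_len(25L)) {
      bad <- a <= 0
      if (!any(bad)) break
      a[bad] <- stats::rnorm(sum(bad), params$amplitude_mean,
                             params$amplitude_sd)
    }
    pmax(a, 1e-3)
  }

  e <- numeric(n)
  ev <- list()
  if (n_events > 0L) {
    onsets <- sort(sample.int(n, n_events, replace = TRUE))
    # thin to enforce separation from the previous *kept* event
    keep <- logical(length(onsets))
    last <- -Inf
    for (i in seq_along(onsets)) {
      keep[i] <- onsets[i] - last >= min_gap
      if (keep[i]) last <- onsets[i]
    }
    onsets <- onsets[keep]
    for (o in onsets) {
      is_burst <- stats::runif(1L) < params$burst_prob
      k <- if (is_burst) {
        sample(seq(params$subpeaks_range[1L], params$subpeaks_range[2L]), 1L)
      } else 1L
      amps <- draw_amp(k)
      spacing <- params$rise_frames + params$burst_gap_frames
      sub_onsets <- o + (seq_len(k) - 1L) * spacing
      comp <- numeric(n)
      for (s in seq_len(k)) {
        comp <- comp + .transient_kernel(n, sub_onsets[s], amps[s],
                                        params$rise_frames,
                                        params$decay_tau_s,
                                        params$frame_rate_hz)
      }
      # ground truth: local maxima of this event's noiseless component
      ext <- .local_extrema(comp)
      pk <- ext$max_frames
      pk <- pk[comp[pk] > 0]
      if (length(pk) == 0L) next   # event landed entirely past the last frame
      e <- e + comp
      ev[[length(ev) + 1L]] <- list(
        onset_frame = o - 1L,
        peak_frames = pk - 1L,
        peak_amplitudes = comp[pk],
        n_peaks = length(pk),
        is_burst = length(pk) >= 2L
      )
    }
  }

  bleach <- (1 - params$bleach_rate)^(seq_len(n) - 1L)
  noise <- if (params$noise_sd > 0) {
    stats::rnorm(n, 0, params$noise_sd)
  } else numeric(n)
  samples <- params$baseline_f0 * bleach * (1 + e) +
    params$baseline_f0 * noise

  events <- if (length(ev)) {
    d <- data.frame(
      onset_frame = vapply(ev, `[[`, 1L, "onset_frame"),
      n_peaks = vapply(ev, `[[`, 1L, "n_peaks"),
      is_burst = vapply(ev, `[[`, TRUE, "is_burst")
    )
    d$peak_frames <- lapply(ev, `[[`, "peak_frames")
    d$peak_amplitudes <- lapply(ev, `[[`, "peak_amplitudes")
    d
  } else {
    d <- data.frame(onset_frame = integer(), n_peaks = integer(),
                    is_burst = logical())
    d$peak_frames <- list()
    d$peak_amplitudes <- list()
    d
  }
  list(
    trace = fluorescence_trace(samples, params$frame_rate_hz,
                               roi_id = roi_id, animal_id = animal_id,
                               condition = condition),
    events = events
  )
}

#' Parameters for simulating a survival cohort
#'
#' Emulates the 2x2 genotype-by-induction lifespan design: each fly's death
#' day is drawn from a proportional-hazards Weibull family,
#' `S(t) = exp(-HR * (t / baseline_scale)^shape)`, with the group hazard
#' ratio `HR = genotype_hr^[alt genotype] * induction_hr^[induced] *
#' interaction_hr^[alt genotype & induced]`. The default shape of 4 gives
#' the sigmoidal survivorship typical of fly cohorts; `baseline_scale = 75`
#' days puts the reference median near 68 days at 25 degrees C. Days are
#' continuous (the few-times-weekly scoring interval is not emulated).
#'
#' @param n_per_group flies per genotype-by-induction cell (cohorts of
#'   130-150 females per condition are typical; default 150).
#' @param genotypes,inductions two labels each; the second level carries
#'   `genotype_hr` / `induction_hr`.
#' @param baseline_scale Weibull scale of the reference cell, days.
#' @param shape Weibull shape (> 0); 1 gives exponential lifetimes.
#' @param genotype_hr,induction_hr,interaction_hr positive hazard ratios.
#' @param censor_day optional right-censoring day applied to all flies.
#' @param seed integer seed.
#' @return A validated parameter list of class `survival_sim_params`.
#' @export
survival_sim_params <- function(n_per_group = 150L,
                                genotypes = c("AB42", "AB42_lap"),
                                inductions = c("RU0", "RU200"),
                                baseline_scale = 75, shape = 4,
                                genotype_hr = 1, induction_hr = 1,
                                interaction_hr = 1, censor_day = NULL,
                                seed = 1L) {
  p <- list(n_per_group = as.integer(n_per_group),
            genotypes = as.character(genotypes),
            inductions = as.character(inductions),
            baseline_scale = baseline_scale, shape = shape,
            genotype_hr = genotype_hr, induction_hr = induction_hr,
            interaction_hr = interaction_hr, censor_day = censor_day,
            seed = as.integer(seed))
  if (p$n_per_group < 1L) stop("n_per_group must be >= 1", call. = FALSE)
  if (length(p$genotypes) != 2L || length(p$inductions) != 2L ||
      anyDuplicated(p$genotypes) || anyDuplicated(p$inductions)) {
    stop("need exactly two distinct genotype and induction labels",
         call. = FALSE)
  }
  if (p$baseline_scale <= 0 || p$shape <= 0) {
    stop("baseline_scale and shape must be > 0", call. = FALSE)
  }
  if (any(c(p$genotype_hr, p$induction_hr, p$interaction_hr) <= 0)) {
    stop("hazard ratios must be > 0", call. = FALSE)
  }
  if (!is.null(p$censor_day) && p$censor_day <= 0) {
    stop("censor_day must be > 0", call. = FALSE)
  }
  class(p) <- "survival_sim_params"
  p
}

#' Simulate a 2x2 genotype-by-induction survival cohort
#'
#' @param params a [survival_sim_params()] list.
#' @return Data frame with one row per fly: `fly_id`, `genotype`,
#'   `induction`, `day` (> 0), `censored` (logical).
#' @seealso [weibull_median()] for the closed-form group median.
#' @export
simulate_survival <- function(params) {
  stopifnot(inherits(params, "survival_sim_params"))
  set.seed(params$seed)
  cells <- expand.grid(genotype = params$genotypes,
                       induction = params$inductions,
                       stringsAsFactors = FALSE)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    alt_geno <- cells$genotype[i] == params$genotypes[2L]
    induced <- cells$induction[i] == params$inductions[2L]
    hr <- params$genotype_hr^alt_geno * params$induction_hr^induced *
      params$interaction_hr^(alt_geno && induced)
    u <- stats::runif(params$n_per_group)
    day <- params$baseline_scale * (-log(u) / hr)^(1 / params$shape)
    censored <- rep(FALSE, params$n_per_group)
    if (!is.null(params$censor_day)) {
      censored <- day > params$censor_day
      day <- pmin(day, params$censor_day)
    }
    out[[i]] <- data.frame(
      fly_id = sprintf("%s_%s_%03d", cells$genotype[i], cells$induction[i],
                       seq_len(params$n_per_group)),
      genotype = cells$genotype[i], induction = cells$induction[i],
      day = day, censored = censored, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Closed-form median lifespan of a simulated group
#'
#' Median of the proportional-hazards Weibull family used by
#' [simulate_survival()]: `scale * (log(2) / hr)^(1 / shape)`.
#'
#' @param scale,shape Weibull parameters.
#' @param hr group hazard ratio.
#' @export
weibull_median <- function(scale, shape, hr = 1) {
  scale * (log(2) / hr)^(1 / shape)
}

#' Parameters for simulating climbing (negative geotaxis) trials
#'
#' Each trial places `n_flies` into the top / middle / bottom zones of the
#' climbing chamber by a single trinomial draw. Defaults emulate one chamber
#' of 50 flies.
#'
#' @param n_flies flies per trial (>= 1).
#' @param p_top,p_middle,p_bottom zone probabilities, summing to 1.
#' @param n_trials number of independent trials.
#' @param seed integer seed.
#' @export
climbing_sim_params <- function(n_flies = 50L, p_top = 1 / 3,
                                p_middle = 1 / 3, p_bottom = 1 / 3,
                                n_trials = 1L, seed = 1L) {
  p <- list(n_flies = as.integer(n_flies), p_top = p_top,
            p_middle = p_middle, p_bottom = p_bottom,
            n_trials = as.integer(n_trials), seed = as.integer(seed))
  if (p$n_flies < 1L) stop("n_flies must be >= 1", call. = FALSE)
  if (p$n_trials < 1L) stop("n_trials must be >= 1", call. = FALSE)
  probs <- c(p$p_top, p$p_middle, p$p_bottom)
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-12) {
    stop("p_top, p_middle, p_bottom must be >= 0 and sum to 1",
         call. = FALSE)
  }
  class(p) <- "climbing_sim_params"
  p
}

#' Simulate trinomial climbing counts
#'
#' @param params a [climbing_sim_params()] list.
#' @return Data frame with one row per trial: `trial`, `n_top`, `n_middle`,
#'   `n_bottom`.
#' @export
simulate_climbing <- function(params) {
  stopifnot(inherits(params, "climbing_sim_params"))
  set.seed(params$seed)
  draws <- stats::rmultinom(params$n_trials, params$n_flies,
                            c(params$p_top, params$p_middle, params$p_bottom))
  data.frame(trial = seq_len(params$n_trials),
             n_top = draws[1L, ], n_middle = draws[2L, ],
             n_bottom = draws[3L, ])
}

#' Parameters for simulating a confocal image stack
#'
#' Each slice is `background_intensity + roi_intensity * mask`, translated by
#' a random integer jitter of at most `jitter_px` pixels per axis (slice 1 is
#' the unjittered reference), plus i.i.d. Gaussian noise. True shifts are
#' returned so registration can be scored.
#'
#' @param n_slices number of Z slices.
#' @param height,width image size in pixels.
#' @param roi_mask logical `height x width` matrix marking the ROI.
#' @param roi_intensity,background_intensity non-negative; ROI must be at
#'   least as bright as the background.
#' @param noise_sd Gaussian pixel noise.
#' @param jitter_px maximum per-slice integer translation.
#' @param seed integer seed.
#' @export
stack_sim_params <- function(n_slices = 10L, height = 32L, width = 32L,
                             roi_mask = NULL, roi_intensity = 100,
                             background_intensity = 10, noise_sd = 0,
                             jitter_px = 0L, seed = 1L) {
  if (is.null(roi_mask)) {
    roi_mask <- matrix(FALSE, height, width)
    rows <- seq(max(1L, height %/% 3L), min(height, 2L * height %/% 3L))
    cols <- seq(max(1L, width %/% 3L), min(width, 2L * width %/% 3L))
    roi_mask[rows, cols] <- TRUE
  }
  p <- list(n_slices = as.integer(n_slices), height = as.integer(height),
            width = as.integer(width), roi_mask = roi_mask,
            roi_intensity = roi_intensity,
            background_intensity = background_intensity,
            noise_sd = noise_sd, jitter_px = as.integer(jitter_px),
            seed = as.integer(seed))
  if (p$n_slices < 1L) stop("n_slices must be >= 1", call. = FALSE)
  if (!is.matrix(p$roi_mask) || !is.logical(p$roi_mask) ||
      !all(dim(p$roi_mask) == c(p$height, p$width))) {
    stop("roi_mask must be a logical height x width matrix", call. = FALSE)
  }
  if (!any(p$roi_mask)) stop("roi_mask must contain >= 1 TRUE pixel", call. = FALSE)
  if (p$roi_intensity < 0 || p$background_intensity < 0) {
    stop("intensities must be >= 0", call. = FALSE)
  }
  if (p$background_intensity > p$roi_intensity) {
    stop("background_intensity must not exceed roi_intensity", call. = FALSE)
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (p$jitter_px < 0) stop("jitter_px must be >= 0", call. = FALSE)
  if (p$jitter_px >= min(p$height, p$width)) {
    stop("jitter_px must be smaller than the image", call. = FALSE)
  }
  class(p) <- "stack_sim_params"
  p
}

#' Simulate a jittered confocal stack with known shifts
#'
#' @param params a [stack_sim_params()] list.
#' @return List with `stack` (numeric `n_slices x height x width` array) and
#'   `shifts`, a data frame of the true per-slice integer translations
#'   (`slice`, `dy`, `dx`; slice 1 is always (0, 0)).
#' @export
simulate_stack <- function(params) {
  stopifnot(inherits(params, "stack_sim_params"))
  set.seed(params$seed)
  base <- params$background_intensity +
    params$roi_intensity * params$roi_mask
  stack <- array(0, dim = c(params$n_slices, params$height, params$width))
  dy <- dx <- integer(params$n_slices)
  if (params$n_slices > 1L && params$jitter_px > 0L) {
    j <- params$jitter_px
    dy[-1L] <- sample.int(2L * j + 1L, params$n_slices - 1L,
                          replace = TRUE) - j - 1L
    dx[-1L] <- sample.int(2L * j + 1L, params$n_slices - 1L,
                          replace = TRUE) - j - 1L
  }
  for (s in seq_len(params$n_slices)) {
    img <- translate_image(base, dy[s], dx[s])
    if (params$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, params$noise_sd),
                          nrow(img))
    }
    stack[s, , ] <- img
  }
  list(stack = stack,
       shifts = data.frame(slice = seq_len(params$n_slices), dy = dy,
                           dx = dx))
}
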