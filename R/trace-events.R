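#' Fluorescence trace container
#'
#' Bundles a raw per-ROI fluorescence time series (arbitrary units) with its
#' acquisition frame rate and identifying labels. This is the unit of input
#' for the glutamate-event pipeline: one trace per ROI per animal.
#'
#' @param samples numeric vector of raw fluorescence samples, all finite and
#'   positive (a zero or negative sample means the trace was background
#'   subtracted past its baseline and cannot be normalized).
#' @param frame_rate_hz acquisition rate in frames per second. Default 0.92,
#'   the single-plane ventral-nerve-cord acquisition rate used for iGluSnFR
#'   imaging of L2 larvae.
#' @param roi_id,animal_id,condition character labels carried through to
#'   summaries.
#' @return An object of class `fluorescence_trace`.
#' @export
fluorescence_trace <- function(samples, frame_rate_hz = 0.92,
                               roi_id = "roi1", animal_id = "animal1",
                               condition = "control") {
  samples <- as.numeric(samples)
  if (length(samples) < 2L) {
    stop("a fluorescence trace needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(samples))) {
    stop("fluorescence samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(frame_rate_hz) || length(frame_rate_hz) != 1L ||
      frame_rate_hz <= 0) {
    stop("frame_rate_hz must be a single positive number", call. = FALSE)
  }
  structure(
    list(samples = samples, frame_rate_hz = frame_rate_hz,
         roi_id = as.character(roi_id), animal_id = as.character(animal_id),
         condition = as.character(condition)),
    class = "fluorescence_trace"
  )
}

#' @export
print.fluorescence_trace <- function(x, ...) {
  cat(sprintf(
    "<fluorescence_trace> %d frames @ %.3g Hz (%.1f s), roi=%s animal=%s condition=%s\n",
    length(x$samples), x$frame_rate_hz,
    length(x$samples) / x$frame_rate_hz,
    x$roi_id, x$animal_id, x$condition))
  invisible(x)
}

#' Normalize a fluorescence trace to dF/F
#'
#' Converts raw fluorescence to the dimensionless change relative to baseline,
#' dF/F = (F_t - F0) / F0, where F0 is the minimal fluorescence intensity
#' recorded over the whole trace. With this convention the trace attains
#' exactly 0 at its minimum and detection thresholds are comparable across
#' ROIs and acquisition settings.
#'
#' F0 is taken per trace (per ROI), so each ROI is normalized to its own
#' quietest moment; this makes the downstream detection invariant to
#' multiplying the raw trace by any positive gain.
#'
#' @param trace a [fluorescence_trace], or a bare numeric vector of raw
#'   samples (then `frame_rate_hz` applies).
#' @param frame_rate_hz frame rate used when `trace` is a bare vector.
#' @return An object of class `dff_trace`: list with `dff` (numeric vector),
#'   `f0` (the minimum raw fluorescence) and `frame_rate_hz`.
#' @examples
#' compute_dff(c(5, 5, 5, 5))$dff      # all zero
#' compute_dff(c(2, 4))$dff            # 0, 1
#' @export
compute_dff <- function(trace, frame_rate_hz = 0.92) {
  if (inherits(trace, "fluorescence_trace")) {
    samples <- trace$samples
    frame_rate_hz <- trace$frame_rate_hz
  } else {
    samples <- as.numeric(trace)
  }
  if (length(samples) < 2L || any(!is.finite(samples))) {
    stop("need >= 2 finite fluorescence samples", call. = FALSE)
  }
  f0 <- min(samples)
  if (f0 <= 0) {
    stop("non-positive baseline: min(samples) must be > 0 for dF/F ",
         "(trace looks background-subtracted to or below zero)",
         call. = FALSE)
  }
  structure(
    list(dff = (samples - f0) / f0, f0 = f0, frame_rate_hz = frame_rate_hz),
    class = "dff_trace"
  )
}

#' @export
print.dff_trace <- function(x, ...) {
  cat(sprintf("<dff_trace> %d frames @ %.3g Hz, F0 = %.4g, max dF/F = %.3g\n",
              length(x$dff), x$frame_rate_hz, x$f0, max(x$dff)))
  invisible(x)
}

# Local extrema on a discrete trace with plateaus collapsed to their first
# frame. Endpoints count: the first frame is a maximum (minimum) if the next
# distinct value is lower (higher), symmetrically for the last frame.
# Returns 1-based frame indices.
.local_extrema <- function(x) {
  n <- length(x)
  keep <- c(TRUE, x[-1L] != x[-n])
  idx <- which(keep)            # first frame of each constant run
  v <- x[idx]
  m <- length(v)
  is_max <- logical(m)
  is_min <- logical(m)
  if (m >= 2L) {
    is_max[1L] <- v[1L] > v[2L]
    is_min[1L] <- v[1L] < v[2L]
    is_max[m] <- v[m] > v[m - 1L]
    is_min[m] <- v[m] < v[m - 1L]
    if (m >= 3L) {
      i <- 2L:(m - 1L)
      # runs are distinct from both neighbours, so > on one side implies
      # a genuine extremum when also > on the other
      is_max[i] <- v[i] > v[i - 1L] & v[i] > v[i + 1L]
      is_min[i] <- v[i] < v[i - 1L] & v[i] < v[i + 1L]
    }
  }
  list(max_frames = idx[is_max], min_frames = idx[is_min])
}

# Core detector on a numeric dF/F vector. Returns a list of transients with
# 1-based frame indices; the exported wrapper converts to 0-based.
.detect_core <- function(x, thr, band) {
  n <- length(x)
  ext <- .local_extrema(x)
  peak_ok <- logical(n)
  peak_ok[ext$max_frames] <- TRUE
  peak_ok <- peak_ok & x > thr
  out <- vector("list", 8L)
  k <- 0L
  i <- 1L
  while (i <= n) {
    rel <- which(peak_ok[i:n])
    if (length(rel) == 0L) break
    p <- i - 1L + rel[1L]
    # onset: first frame of the maximal non-decreasing run ending at the
    # first peak. When the signal rose from below threshold this run
    # contains the threshold crossing (any dip above threshold before p
    # would itself be a peak), so it starts at the first frame of the
    # rising phase; it stays well defined when the signal never dropped
    # below threshold beforehand (e.g. on the tail of the previous event).
    onset <- p
    while (onset > 1L && x[onset - 1L] <= x[onset]) onset <- onset - 1L
    peaks <- p
    offset <- n
    j <- p + 1L
    closed <- FALSE
    while (j <= n) {
      if (x[j] - x[onset] <= band) {
        offset <- j
        closed <- TRUE
        break
      }
      if (peak_ok[j]) peaks <- c(peaks, j)
      j <- j + 1L
    }
    k <- k + 1L
    out[[k]] <- list(onset = onset, peaks = peaks, offset = offset,
                     truncated = peaks[length(peaks)] == n)
    if (!closed) break          # ran into the final frame; nothing follows
    i <- offset                 # next transient may share the offset frame
  }
  if (k == 0L) list() else out[seq_len(k)]
}

#' Detect glutamate transients in a dF/F trace
#'
#' Segments a dF/F trace into discrete glutamate release transients. A
#' candidate peak is any local maximum exceeding `event_threshold`
#' (dF/F > 0.1 by default). Each transient's onset is the first frame of the
#' maximal monotone non-decreasing run rising into its first peak — the
#' first frame of the rising phase; when the signal rose from below
#' threshold this run contains the threshold crossing. Scanning forward
#' from a peak, the
#' transient ends at the first frame whose dF/F has fallen back to within
#' `offset_band` (default 0.2) of the value at the onset frame — on a falling
#' signal that frame is where the trace bottoms back into the onset band —
#' or at the final frame if it never returns. Peaks with no qualifying
#' offset between them belong to one continuous transient: two or more such
#' peaks constitute a burst, and only the highest peak is scored as the
#' transient's amplitude.
#'
#' Plateaus are collapsed to their first frame when locating extrema. A
#' transient still rising at the final frame is closed there and flagged
#' `truncated`; truncated transients count towards event rates but are
#' excluded from amplitude means since their peak is unobserved. All frame
#' indices in the result are 0-based.
#'
#' @param dff a [dff_trace] (from [compute_dff()]) or bare numeric dF/F
#'   vector.
#' @param event_threshold dF/F value a local maximum must exceed to count as
#'   a glutamate event. Default 0.1.
#' @param offset_band how close (in absolute dF/F) the falling signal must
#'   return to its onset value for a local minimum to terminate the
#'   transient. Default 0.2.
#' @return A data frame of class `glut_transients`, one row per transient:
#'   `onset_frame`, `offset_frame`, `scored_peak_frame`, `scored_amplitude`,
#'   `n_peaks`, `is_burst`, `truncated`, plus list columns `peak_frames` and
#'   `peak_values`. Zero rows when nothing crosses threshold.
#' @examples
#' detect_transients(c(0, 0.05, 0.3, 0.05, 0))     # one single-peak event
#' detect_transients(c(0, 0.3, 0.25, 0.4, 0.02))   # one burst, scored 0.4
#' detect_transients(c(0, 0.3, 0.05, 0.4, 0.02))   # two single events
#' @export
detect_transients <- function(dff, event_threshold = 0.1, offset_band = 0.2) {
  x <- if (inherits(dff, "dff_trace")) dff$dff else as.numeric(dff)
  if (length(x) < 2L || any(!is.finite(x))) {
    stop("dff must hold >= 2 finite values", call. = FALSE)
  }
  if (event_threshold <= 0 || offset_band <= 0) {
    stop("event_threshold and offset_band must be > 0", call. = FALSE)
  }
  tr <- .detect_core(x, event_threshold, offset_band)
  if (length(tr) == 0L) {
    res <- data.frame(onset_frame = integer(), offset_frame = integer(),
                      scored_peak_frame = integer(),
                      scored_amplitude = numeric(), n_peaks = integer(),
                      is_burst = logical(), truncated = logical())
    res$peak_frames <- list()
    res$peak_values <- list()
  } else {
    pk_fr <- lapply(tr, function(t) t$peaks - 1L)
    pk_v <- lapply(tr, function(t) x[t$peaks])
    best <- vapply(seq_along(tr), function(i) which.max(pk_v[[i]]), 1L)
    res <- data.frame(
      onset_frame = vapply(tr, function(t) t$onset - 1L, 1L),
      offset_frame = vapply(tr, function(t) t$offset - 1L, 1L),
      scored_peak_frame = vapply(seq_along(tr),
                                 function(i) pk_fr[[i]][best[i]], 1L),
      scored_amplitude = vapply(seq_along(tr),
                                function(i) pk_v[[i]][best[i]], 1.0),
      n_peaks = vapply(pk_fr, length, 1L),
      is_burst = vapply(pk_fr, function(p) length(p) >= 2L, TRUE),
      truncated = vapply(tr, function(t) isTRUE(t$truncated), TRUE)
    )
    res$peak_frames <- pk_fr
    res$peak_values <- pk_v
  }
  class(res) <- c("glut_transients", "data.frame")
  attr(res, "n_frames") <- length(x)
  attr(res, "event_threshold") <- event_threshold
  attr(res, "offset_band") <- offset_band
  if (inherits(dff, "dff_trace")) {
    attr(res, "frame_rate_hz") <- dff$frame_rate_hz
  }
  res
}

#' @export
print.glut_transients <- function(x, ...) {
  cat(sprintf("<glut_transients> %d transient(s) (%d burst(s)) over %d frames\n",
              nrow(x), sum(x$is_burst), attr(x, "n_frames")))
  if (nrow(x) > 0L) {
    print.data.frame(x[, c("onset_frame", "scored_peak_frame", "offset_frame",
                           "scored_amplitude", "n_peaks", "is_burst",
                           "truncated")], row.names = FALSE, ...)
  }
  invisible(x)
}

#' Optional moving-average smoothing of a dF/F trace
#'
#' A centred moving-average filter for noisy traces. Detection runs on raw
#' dF/F by default (no smoothing or detrending); this helper is provided for
#' exploratory use only.
#'
#' @param x numeric vector or [dff_trace].
#' @param window odd window length in frames; 1 returns the input unchanged.
#' @return Same shape as the input.
#' @export
smooth_trace <- function(x, window = 1L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop("window must be a positive odd integer", call. = FALSE)
  }
  if (window == 1L) return(x)
  sm <- function(v) {
    out <- as.numeric(stats::filter(v, rep(1 / window, window), sides = 2))
    half <- (window - 1L) %/% 2L
    n <- length(v)
    out[seq_len(half)] <- v[seq_len(half)]        # edges left unfiltered
    out[(n - half + 1L):n] <- v[(n - half + 1L):n]
    out
  }
  if (inherits(x, "dff_trace")) {
    x$dff <- sm(x$dff)
    x
  } else {
    sm(as.numeric(x))
  }
}

#' Summarize detected transients for one trace
#'
#' Produces the per-ROI summary used for figure-style quantification: number
#' of transients, event rate per minute over the trace duration, and mean
#' scored amplitude. Truncated transients (still rising at the final frame)
#' contribute to counts and rates but not to the amplitude mean, because
#' their true peak is unobserved. By default the amplitude mean pools
#' single events and burst maxima (`amplitude_mode = "all"`); set
#' `amplitude_mode = "bursts"` to average over bursts only.
#'
#' @param transients a `glut_transients` data frame from
#'   [detect_transients()].
#' @param dff the [dff_trace] the transients came from (supplies duration
#'   and frame rate); alternatively pass `n_frames` and `frame_rate_hz`.
#' @param n_frames,frame_rate_hz trace length and rate, used when `dff` is
#'   missing.
#' @param amplitude_mode `"all"` (default) or `"bursts"`.
#' @param roi_id,animal_id,condition labels copied into the summary row.
#' @return A one-row data frame: labels, `n_transients`, `n_bursts`,
#'   `mean_amplitude` (NA when no scoreable transient), `events_per_min`,
#'   `n_frames`, `frame_rate_hz`.
#' @export
summarize_trace <- function(transients, dff = NULL, n_frames = NULL,
                            frame_rate_hz = NULL,
                            amplitude_mode = c("all", "bursts"),
                            roi_id = "roi1", animal_id = "animal1",
                            condition = "control") {
  amplitude_mode <- match.arg(amplitude_mode)
  if (!is.null(dff) && inherits(dff, "dff_trace")) {
    n_frames <- length(dff$dff)
    frame_rate_hz <- dff$frame_rate_hz
  }
  if (is.null(n_frames)) n_frames <- attr(transients, "n_frames")
  if (is.null(frame_rate_hz)) frame_rate_hz <- attr(transients, "frame_rate_hz")
  if (is.null(frame_rate_hz) || !is.numeric(frame_rate_hz) ||
      frame_rate_hz <= 0) {
    stop("frame_rate_hz must be a positive number", call. = FALSE)
  }
  duration_min <- n_frames / frame_rate_hz / 60
  scoreable <- !transients$truncated
  if (amplitude_mode == "bursts") scoreable <- scoreable & transients$is_burst
  amps <- transients$scored_amplitude[scoreable]
  data.frame(
    roi_id = roi_id, animal_id = animal_id, condition = condition,
    n_transients = nrow(transients),
    n_bursts = sum(transients$is_burst),
    mean_amplitude = if (length(amps)) mean(amps) else NA_real_,
    events_per_min = nrow(transients) / duration_min,
    n_frames = n_frames,
    frame_rate_hz = frame_rate_hz,
    stringsAsFactors = FALSE
  )
}

#' Aggregate ROI summaries to one row per animal
#'
#' Collapses ROI-level trace summaries to the per-animal values that enter
#' the cross-condition comparison (amplitudes and event counts are plotted
#' and tested as means per animal). The amplitude is the mean of the ROI
#' mean amplitudes; the event rate pools all transients over the animal's
#' total recorded time.
#'
#' @param summaries data frame of rows from [summarize_trace()].
#' @return Data frame with one row per animal: `animal_id`, `condition`,
#'   `mean_amplitude`, `events_per_min`, `n_transients`, `n_rois`.
#' @export
aggregate_by_animal <- function(summaries) {
  req <- c("roi_id", "animal_id", "condition", "n_transients",
           "mean_amplitude", "events_per_min", "n_frames", "frame_rate_hz")
  if (!all(req %in% names(summaries))) {
    stop("summaries must contain columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(summaries$animal_id, summaries$roi_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (animal_id, roi_id) rows: ambiguous which trace is which",
         call. = FALSE)
  }
  cond <- tapply(summaries$condition, summaries$animal_id,
                 function(v) unique(v))
  if (any(lengths(cond) > 1L)) {
    stop("an animal appears under more than one condition", call. = FALSE)
  }
  split_rows <- split(summaries, summaries$animal_id)
  out <- do.call(rbind, lapply(split_rows, function(d) {
    total_min <- sum(d$n_frames / d$frame_rate_hz) / 60
    data.frame(
      animal_id = d$animal_id[1L],
      condition = d$condition[1L],
      mean_amplitude = if (all(is.na(d$mean_amplitude))) NA_real_
                       else mean(d$mean_amplitude, na.rm = TRUE),
      events_per_min = sum(d$n_transients) / total_min,
      n_transients = sum(d$n_transients),
      n_rois = nrow(d),
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}
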