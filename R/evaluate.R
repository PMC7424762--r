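#' Score detector recovery against simulated ground truth
#'
#' Greedily matches ground-truth event onsets to detected transient onsets
#' (earliest first, one-to-one, within `tol_frames`) and reports onset
#' recall and precision plus the amplitude agreement of matched pairs. The
#' ground-truth amplitude of an event is the largest dF/F among its
#' noiseless component peaks, mirroring highest-peak scoring.
#'
#' @param events ground-truth event table from [simulate_trace()] (or a
#'   list of them, pooled).
#' @param transients detected `glut_transients` (or a list of them, matched
#'   elementwise with `events`).
#' @param tol_frames onset matching tolerance in frames (default 2).
#' @return List with `recall`, `precision`, `n_true`, `n_detected`,
#'   `amplitude_relative_bias` (mean of (detected - true)/true over matched
#'   pairs; NA when nothing matched) and the `matched` pair table.
#' @export
score_event_recovery <- function(events, transients, tol_frames = 2L) {
  if (is.data.frame(events)) events <- list(events)
  if (!is.list(transients) || inherits(transients, "data.frame")) {
    transients <- list(transients)
  }
  stopifnot(length(events) == length(transients))
  n_true <- 0L
  n_det <- 0L
  n_match <- 0L
  amp_true <- numeric()
  amp_det <- numeric()
  for (i in seq_along(events)) {
    ev <- events[[i]]
    tr <- transients[[i]]
    n_true <- n_true + nrow(ev)
    n_det <- n_det + nrow(tr)
    if (nrow(ev) == 0L || nrow(tr) == 0L) next
    used <- logical(nrow(tr))
    for (e in seq_len(nrow(ev))) {
      gap <- abs(tr$onset_frame - ev$onset_frame[e])
      gap[used] <- NA
      j <- which.min(gap)
      if (length(j) && !is.na(gap[j]) && gap[j] <= tol_frames) {
        used[j] <- TRUE
        n_match <- n_match + 1L
        amp_true <- c(amp_true, max(ev$peak_amplitudes[[e]]))
        amp_det <- c(amp_det, tr$scored_amplitude[j])
      }
    }
  }
  list(
    recall = if (n_true) n_match / n_true else NA_real_,
    precision = if (n_det) n_match / n_det else NA_real_,
    n_true = n_true, n_detected = n_det,
    amplitude_relative_bias = if (n_match) {
      mean((amp_det - amp_true) / amp_true)
    } else NA_real_,
    matched = data.frame(amp_true = amp_true, amp_det = amp_det)
  )
}
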