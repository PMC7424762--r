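#' Write fluorescence traces to a long-format CSV
#'
#' Columns: `frame` (0-based), `roi_id`, `animal_id`, `condition`,
#' `fluorescence`.
#'
#' @param traces a [fluorescence_trace] or list of them.
#' @param path output CSV path.
#' @export
write_traces_csv <- function(traces, path) {
  if (inherits(traces, "fluorescence_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(frame = seq_along(tr$samples) - 1L, roi_id = tr$roi_id,
               animal_id = tr$animal_id, condition = tr$condition,
               fluorescence = tr$samples,
               frame_rate_hz = tr$frame_rate_hz, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read fluorescence traces from a long-format CSV
#'
#' @param path CSV written by [write_traces_csv()] (or any CSV with columns
#'   `frame`, `roi_id`, `animal_id`, `condition`, `fluorescence`, and
#'   optionally `frame_rate_hz`).
#' @param frame_rate_hz fallback frame rate when the file carries none.
#' @return List of [fluorescence_trace] objects, one per (animal, roi).
#' @export
read_traces_csv <- function(path, frame_rate_hz = 0.92) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("frame", "roi_id", "animal_id", "condition", "fluorescence")
  if (!all(req %in% names(d))) {
    stop("trace CSV needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  key <- paste(d$animal_id, d$roi_id, sep = "\r")
  lapply(split(d, key), function(g) {
    g <- g[order(g$frame), ]
    fr <- if ("frame_rate_hz" %in% names(g)) g$frame_rate_hz[1L] else frame_rate_hz
    fluorescence_trace(g$fluorescence, fr, roi_id = g$roi_id[1L],
                       animal_id = g$animal_id[1L],
                       condition = g$condition[1L])
  })
}

#' Write detected transients to CSV
#'
#' List columns (`peak_frames`, `peak_values`) are flattened with `;`
#' separators.
#'
#' @param transients a `glut_transients` data frame (extra label columns are
#'   preserved).
#' @param path output CSV path.
#' @export
write_transients_csv <- function(transients, path) {
  d <- as.data.frame(transients)
  for (col in c("peak_frames", "peak_values")) {
    if (col %in% names(d)) {
      d[[col]] <- vapply(d[[col]], paste, "", collapse = ";")
    }
  }
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read or write survival records
#'
#' The CSV schema is one row per fly: `fly_id`, `genotype`, `induction`,
#' `day`, `censored` (0/1).
#'
#' @param records data frame of survival records.
#' @param path CSV path.
#' @export
write_survival_csv <- function(records, path) {
  d <- records
  d$censored <- as.integer(as.logical(d$censored))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_survival_csv
#' @export
read_survival_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$censored <- as.logical(d$censored)
  .check_survival_records(d)
  d
}

#' Read or write climbing counts
#'
#' Schema: one row per trial with `timepoint`, `genotype`, `induction`,
#' `n_top`, `n_middle`, `n_bottom` (label columns optional on read).
#'
#' @param counts data frame of climbing counts.
#' @param path CSV path.
#' @export
write_climbing_csv <- function(counts, path) {
  utils::write.csv(counts, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climbing_csv
#' @export
read_climbing_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("n_top", "n_middle", "n_bottom") %in% names(d))) {
    stop("climbing CSV needs n_top, n_middle, n_bottom columns",
         call. = FALSE)
  }
  d
}
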