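#' Translate an image by an integer shift, zero-filling exposed pixels
#'
#' @param img numeric matrix.
#' @param dy,dx integer shift in rows (down positive) and columns (right
#'   positive).
#' @param fill value for pixels shifted in from outside the frame.
#' @return Matrix of the same size.
#' @export
translate_image <- function(img, dy, dx, fill = 0) {
  h <- nrow(img)
  w <- ncol(img)
  dy <- as.integer(dy)
  dx <- as.integer(dx)
  if (abs(dy) >= h || abs(dx) >= w) {
    return(matrix(fill, h, w))
  }
  out <- matrix(fill, h, w)
  src_r <- max(1L, 1L - dy):min(h, h - dy)
  src_c <- max(1L, 1L - dx):min(w, w - dx)
  out[src_r + dy, src_c + dx] <- img[src_r, src_c]
  out
}

#' Rigid integer-shift registration of an image stack
#'
#' Aligns every slice to the first by the integer translation (at most
#' `max_shift` pixels per axis) maximizing the cross-correlation (sum of
#' products) with the first slice. Ties are broken towards the smallest
#' shift, so identical slices register at (0, 0). Pixels shifted in from
#' outside the frame are zero-filled; in-frame pixel values are never
#' altered. This is deliberately plain rigid registration for desk-scale
#' fixtures, not a re-implementation of subpixel motion-correction tools.
#'
#' @param stack numeric `n_slices x height x width` array.
#' @param max_shift maximum absolute shift searched per axis.
#' @return List with `stack` (registered array) and `shifts`, a data frame
#'   (`slice`, `dy`, `dx`) of the estimated displacement of each original
#'   slice relative to the first (registration applies the inverse).
#' @export
register_frames <- function(stack, max_shift = 3L) {
  stopifnot(length(dim(stack)) == 3L)
  max_shift <- as.integer(max_shift)
  if (max_shift < 0L) stop("max_shift must be >= 0", call. = FALSE)
  h <- dim(stack)[2L]
  w <- dim(stack)[3L]
  if (max_shift >= min(h, w)) {
    stop("max_shift must be smaller than the image", call. = FALSE)
  }
  n <- dim(stack)[1L]
  ref <- stack[1L, , ]
  cand <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  cand <- cand[order(abs(cand$dy) + abs(cand$dx), abs(cand$dy),
                     abs(cand$dx)), , drop = FALSE]
  out <- stack
  dy <- dx <- integer(n)
  for (s in seq_len(n)[-1L]) {
    img <- stack[s, , ]
    best <- -Inf
    bi <- 1L
    for (i in seq_len(nrow(cand))) {
      # score the hypothesis that this slice is displaced by (dy, dx):
      # undo it and correlate with the reference
      sc <- sum(translate_image(img, -cand$dy[i], -cand$dx[i]) * ref)
      if (sc > best) {
        best <- sc
        bi <- i
      }
    }
    dy[s] <- cand$dy[bi]
    dx[s] <- cand$dx[bi]
    out[s, , ] <- translate_image(img, -dy[s], -dx[s])
  }
  list(stack = out,
       shifts = data.frame(slice = seq_len(n), dy = dy, dx = dx))
}

#' Maximum-intensity projection of a Z-stack
#'
#' @param stack numeric `n_slices x height x width` array.
#' @return `height x width` matrix, `out[r, c] = max_s stack[s, r, c]`.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(length(dim(stack)) == 3L)
  apply(stack, c(2L, 3L), max)
}

#' Harmonize background levels across images
#'
#' Estimates each image's background as a low percentile of its intensity
#' histogram (type-1 empirical quantile, so the level is an actual pixel
#' value), subtracts it, and clips at zero. After harmonization all images
#' share background level 0, emulating per-experiment threshold matching so
#' that intensities are comparable across samples. Idempotent whenever the
#' background fraction of pixels is at least the chosen percentile.
#'
#' @param images a list of numeric matrices (or a single matrix).
#' @param percentile background percentile in (0, 50); default 5.
#' @return List of harmonized images with attribute `background_levels`
#'   giving the level subtracted from each.
#' @export
harmonize_background <- function(images, percentile = 5) {
  if (is.matrix(images)) images <- list(images)
  if (!is.list(images) || length(images) == 0L) {
    stop("images must be a non-empty list of matrices", call. = FALSE)
  }
  if (percentile <= 0 || percentile >= 50) {
    stop("percentile must be in (0, 50)", call. = FALSE)
  }
  bg <- vapply(images, function(img) {
    stats::quantile(img, percentile / 100, type = 1, names = FALSE)
  }, 1.0)
  out <- mapply(function(img, b) pmax(img - b, 0), images, bg,
                SIMPLIFY = FALSE)
  attr(out, "background_levels") <- bg
  out
}

#' Mean ROI fluorescence of a stack
#'
#' Measures the mean fluorescence intensity inside the ROI on every slice
#' and averages the per-slice means into one value per ROI, as done for NMJ
#' immunofluorescence quantification.
#'
#' @param stack numeric `n_slices x height x width` array (a single matrix
#'   is treated as a one-slice stack).
#' @param mask logical `height x width` matrix with at least one TRUE pixel.
#' @param label ROI label carried into the result.
#' @param background_level background subtracted upstream (recorded, not
#'   applied here); NA when unknown.
#' @return Object of class `roi_quant`: list with `label`,
#'   `per_slice_means`, `overall_mean`, `background_level`.
#' @export
roi_mean_intensity <- function(stack, mask, label = "roi",
                               background_level = NA_real_) {
  if (is.matrix(stack)) {
    stack <- array(stack, dim = c(1L, nrow(stack), ncol(stack)))
  }
  stopifnot(length(dim(stack)) == 3L)
  if (!is.matrix(mask) || !is.logical(mask) ||
      !all(dim(mask) == dim(stack)[2:3])) {
    stop("mask must be a logical matrix matching slice dimensions",
         call. = FALSE)
  }
  if (!any(mask)) stop("mask must contain >= 1 TRUE pixel", call. = FALSE)
  per_slice <- apply(stack, 1L, function(sl) mean(sl[mask]))
  structure(
    list(label = as.character(label), per_slice_means = as.numeric(per_slice),
         overall_mean = mean(per_slice),
         background_level = background_level),
    class = "roi_quant"
  )
}

#' @export
print.roi_quant <- function(x, ...) {
  cat(sprintf("<roi_quant> %s: overall mean %.4g over %d slice(s)\n",
              x$label, x$overall_mean, length(x$per_slice_means)))
  invisible(x)
}

#' Read a multi-page TIFF as a numeric stack
#'
#' @param path TIFF file path.
#' @return `n_slices x height x width` array, intensities as stored
#'   (the tiff format scales integer samples to [0, 1]).
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  h <- nrow(pages[[1L]])
  w <- ncol(pages[[1L]])
  stack <- array(0, dim = c(length(pages), h, w))
  for (s in seq_along(pages)) stack[s, , ] <- pages[[s]]
  stack
}

#' Write a numeric stack as a multi-page 16-bit TIFF
#'
#' Intensities are scaled by `scale` into [0, 1] before writing (TIFF
#' integer samples are stored normalized); read back with
#' [read_stack_tiff()] and multiply by `scale` to recover intensities to
#' 16-bit precision.
#'
#' @param stack `n_slices x height x width` array.
#' @param path output path.
#' @param scale intensity mapped to full scale; defaults to `max(stack)`.
#' @return `scale`, invisibly.
#' @export
write_stack_tiff <- function(stack, path, scale = NULL) {
  stopifnot(length(dim(stack)) == 3L)
  if (is.null(scale)) scale <- max(stack, 1e-12)
  pages <- lapply(seq_len(dim(stack)[1L]), function(s) {
    pmin(pmax(stack[s, , ] / scale, 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(scale)
}
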