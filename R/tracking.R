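#' Threshold a frame into a pixel mask
#'
#' Applies the brightness threshold to a grayscale frame and restricts the
#' result to the tube span. The returned mask stores, for every flagged
#' pixel, its lengthwise coordinate `x` as a 0-based column offset from the
#' odorant end, plus the total count `M` and the tube length `L` in pixels
#' — the quantities entering the CoM and avoidance-index statistics.
#'
#' Pixels outside the tube span are never flagged. With
#' `polarity = "bright_flies"` only pixels strictly above the level are
#' flagged; with `"dark_flies"`, strictly below. A frame whose flies sit on
#' the wrong side of the threshold for the chosen polarity simply yields an
#' empty mask (M = 0); downstream statistics treat that as missing.
#'
#' @param frame Numeric matrix (rows = transverse, columns = along tube).
#' @param spec A [threshold_spec()].
#' @param geometry A [tube_geometry()]; must lie within the frame.
#' @return A `pixel_mask` object: list with `flags` (logical matrix, frame
#'   shape), `x` (integer 0-based offsets from the odorant end, one per
#'   flagged pixel), `M`, and `geometry`.
#' @examples
#' fr <- matrix(0, 5, 20); fr[3, 15] <- 1
#' m <- threshold_frame(fr, threshold_spec(level = 0.5), tube_geometry(1, 20))
#' m$M
#' @export
threshold_frame <- function(frame, spec, geometry) {
  if (!is.matrix(frame) || !is.numeric(frame) || ncol(frame) < 2) {
    ft_abort("`frame` must be a numeric matrix with at least 2 columns.",
             "flytube_bad_frame")
  }
  if (!all(is.finite(frame))) {
    ft_abort("Frame intensities must be finite.", "flytube_bad_frame")
  }
  if (!inherits(spec, "threshold_spec")) {
    ft_abort("`spec` must be a threshold_spec().", "flytube_bad_argument")
  }
  if (!inherits(geometry, "tube_geometry")) {
    ft_abort("`geometry` must be a tube_geometry().", "flytube_bad_argument")
  }
  if (geometry$c1 > ncol(frame)) {
    ft_abort("Tube geometry extends beyond the frame.", "flytube_bad_geometry")
  }
  level <- if (spec$mode == "otsu") .otsu_level(frame) else spec$level
  flags <- if (spec$polarity == "bright_flies") frame > level else frame < level
  # never flag outside the tube span
  keep <- seq(geometry$c0, geometry$c1)
  flags[, setdiff(seq_len(ncol(frame)), keep)] <- FALSE
  new_pixel_mask(flags, geometry)
}

.otsu_level <- function(frame) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    ft_abort("Otsu mode requires the EBImage package; use a fixed level instead.",
             "flytube_missing_dependency")
  }
  rng <- range(frame)
  if (rng[1] == rng[2]) return(rng[1])
  EBImage::otsu(EBImage::Image((frame - rng[1]) / (rng[2] - rng[1]))) *
    (rng[2] - rng[1]) + rng[1]
}

new_pixel_mask <- function(flags, geometry) {
  cols <- which(flags, arr.ind = TRUE)[, "col"]
  x <- if (geometry$odorant_end == "left") {
    cols - geometry$c0
  } else {
    geometry$c1 - cols
  }
  structure(
    list(flags = flags, x = as.integer(unname(x)),
         M = length(x), geometry = geometry),
    class = "pixel_mask"
  )
}

#' Build a pixel mask directly from per-column counts
#'
#' Convenience constructor for synthetic masks: `counts[i]` above-threshold
#' pixels are placed in the i-th tube column (offset i-1 from the odorant
#' end). Useful for testing the statistics against hand-built
#' distributions without going through an image.
#'
#' @param counts Non-negative integer vector, one entry per tube column,
#'   ordered from the odorant end.
#' @return A `pixel_mask` whose tube length equals `length(counts)`.
#' @examples
#' compute_com(mask_from_counts(c(0, 0, 3))) # all mass in the far column
#' @export
mask_from_counts <- function(counts) {
  if (!is.numeric(counts) || length(counts) < 2 || any(counts < 0) ||
      any(counts != round(counts))) {
    ft_abort("`counts` must be >= 2 non-negative integer column counts.",
             "flytube_bad_argument")
  }
  W <- length(counts)
  H <- max(max(counts), 1)
  flags <- matrix(FALSE, H, W)
  for (j in seq_len(W)) if (counts[j] > 0) flags[seq_len(counts[j]), j] <- TRUE
  new_pixel_mask(flags, tube_geometry(1, W, "left"))
}

#' Build a single-pixel-per-fly mask from normalized positions
#'
#' Maps normalized tube coordinates (0 = odorant end, 1 = far end) onto a
#' tube of `W` pixel columns — position p goes to the column with 0-based
#' offset `round(p * (W - 1))` — and flags one pixel per fly. This is the
#' point-mass rasterization used to connect position-based patterns (e.g.
#' [canonical_positions()]) to the pixel-level statistics.
#'
#' @param positions Numeric vector in \[0, 1\], or a `canonical_pattern`.
#' @param W Number of tube columns (pixels).
#' @return A `pixel_mask`.
#' @examples
#' compute_com(mask_from_positions(c(0.5, 0.5), W = 101))
#' @export
mask_from_positions <- function(positions, W = 501) {
  if (inherits(positions, "canonical_pattern")) positions <- positions$positions
  if (!is.numeric(positions) || length(positions) < 1 ||
      any(!is.finite(positions)) || any(positions < 0 | positions > 1)) {
    ft_abort("`positions` must be finite values in [0, 1].", "flytube_bad_argument")
  }
  assert_scalar_number(W, "W")
  if (W < 2 || W != round(W)) {
    ft_abort("`W` must be an integer >= 2.", "flytube_bad_argument")
  }
  offsets <- round(positions * (W - 1))
  counts <- tabulate(offsets + 1L, nbins = W)
  mask_from_counts(counts)
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d flagged pixels, tube L = %d px, odorant at %s end\n",
              x$M, x$geometry$L, x$geometry$odorant_end))
  invisible(x)
}

#' Normalized center of mass of a pixel mask
#'
#' The per-frame tracking statistic: the mean lengthwise coordinate of all
#' above-threshold pixels, measured from the odorant end and normalized so
#' that 0 means all mass in the odorant-end column, 1 all mass in the
#' farthest column, and a homogeneous occupancy of every column gives
#' exactly 0.5. Values above 0.5 indicate aversion.
#'
#' Writing `x_n` for the 0-based column offset of flagged pixel n and `L`
#' for the tube length in pixels, the statistic is
#' \deqn{\mathrm{CoM} = \frac{\sum_n x_n}{M\,(L - 1)}.}
#' The `L - 1` denominator (maximal attainable offset) rather than `L` is
#' what makes the anchor values 0, 0.5 and 1 exact at any tube width; the
#' two normalizations differ by O(1/L).
#'
#' @param mask A `pixel_mask`.
#' @return A single number in \[0, 1\], or `NA` (with a warning) for an
#'   empty mask — an empty frame is missing data, never silently 0.
#' @examples
#' compute_com(mask_from_counts(c(1, 1, 1, 1, 1))) # 0.5
#' @export
compute_com <- function(mask) {
  if (!inherits(mask, "pixel_mask")) {
    ft_abort("`mask` must be a pixel_mask.", "flytube_bad_argument")
  }
  if (mask$M == 0) {
    warn("Empty mask (M = 0): CoM is missing for this frame.",
         class = "flytube_empty_mask")
    return(NA_real_)
  }
  sum(mask$x) / (mask$M * (mask$geometry$L - 1))
}

#' Avoidance index of a pixel mask
#'
#' Bisects the tube at its midpoint and computes
#' \deqn{\mathrm{A.I.} = \frac{N_{\mathrm{odorant\ half}} - N_{\mathrm{solvent\ half}}}{M},}
#' counting above-threshold pixels as a proxy for flies. Under this
#' formula (implemented verbatim) avoidance of the odorant gives
#' *negative* values; set `flip_sign = TRUE` to report avoidance as
#' positive instead. For an odd tube width the single middle column
#' belongs to neither half but still counts in the denominator.
#'
#' @param mask A `pixel_mask`.
#' @param flip_sign Report solvent-half excess (avoidance) as positive.
#' @return A number in \[-1, 1\], or `NA` for an empty mask.
#' @examples
#' compute_ai(mask_from_counts(c(3, 0, 0, 0, 1))) # (3 - 1) / 4
#' @export
compute_ai <- function(mask, flip_sign = FALSE) {
  if (!inherits(mask, "pixel_mask")) {
    ft_abort("`mask` must be a pixel_mask.", "flytube_bad_argument")
  }
  if (mask$M == 0) {
    warn("Empty mask (M = 0): AI is missing for this frame.",
         class = "flytube_empty_mask")
    return(NA_real_)
  }
  L <- mask$geometry$L
  if (L %% 2 == 0) {
    n_odor <- sum(mask$x <= L / 2 - 1)
    n_solv <- sum(mask$x >= L / 2)
  } else {
    mid <- (L - 1) / 2
    n_odor <- sum(mask$x < mid)
    n_solv <- sum(mask$x > mid)
  }
  ai <- (n_odor - n_solv) / mask$M
  if (flip_sign) -ai else ai
}

new_com_series <- function(df, cadence_s) {
  structure(df, cadence_s = cadence_s,
            class = c("com_series", class(tibble::tibble())))
}

#' Track a stack of frames
#'
#' Thresholds every frame and computes the per-frame CoM and avoidance
#' index, timestamped from the capture rate. Frames in which no pixel
#' crosses the threshold are carried as missing values (never imputed) and
#' are excluded from window averages downstream.
#'
#' @param frames A list of numeric matrices, or a 3-D array with frames
#'   along the third dimension, all sharing one geometry.
#' @param spec A [threshold_spec()].
#' @param geometry A [tube_geometry()].
#' @param fps Capture rate in frames/second (default 1); frame i is
#'   timestamped (i - 1)/fps.
#' @param flip_sign Passed to [compute_ai()].
#' @return A `com_series` tibble: columns `frame`, `time_s`, `com`, `ai`,
#'   `n_pixels`, with a `cadence_s` attribute.
#' @examples
#' fr <- matrix(0, 4, 11); fr[2, 3] <- 1
#' track_stack(list(fr, fr), threshold_spec(level = 0.5), tube_geometry(1, 11))
#' @export
track_stack <- function(frames, spec, geometry, fps = 1, flip_sign = FALSE) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    frames <- lapply(seq_len(dim(frames)[3]), function(i) frames[, , i])
  }
  if (!is.list(frames) || length(frames) == 0) {
    ft_abort("`frames` must be a non-empty list of matrices (or 3-D array).",
             "flytube_empty_stack")
  }
  assert_scalar_number(fps, "fps")
  rows <- purrr::map(frames, function(fr) {
    mask <- threshold_frame(fr, spec, geometry)
    if (mask$M == 0) {
      c(com = NA_real_, ai = NA_real_, n_pixels = 0)
    } else {
      c(com = compute_com(mask), ai = compute_ai(mask, flip_sign = flip_sign),
        n_pixels = mask$M)
    }
  })
  res <- dplyr::bind_rows(rows)
  new_com_series(
    tibble::tibble(
      frame = seq_along(frames),
      time_s = (seq_along(frames) - 1) / fps,
      com = res$com,
      ai = res$ai,
      n_pixels = as.integer(res$n_pixels)
    ),
    cadence_s = 1 / fps
  )
}
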