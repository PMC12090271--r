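#' Render trajectories into synthetic video frames
#'
#' Rasterizes a 1-D trajectory into grayscale frames emulating the
#' near-infrared video of the assay: each fly is drawn as a filled disc of
#' radius `fly_radius_px` centered at the pixel column its position maps to
#' (position x maps to 0-based column offset `round(x / L * (W - 1))`
#' within the tube span, W = tube width in pixels, clamped so the whole
#' disc stays inside the span), at a random transverse row. Gaussian noise
#' is added and clipped so that it can never cross the midpoint between
#' background and fly intensity, keeping the rendering faithful to a
#' fixed-threshold segmentation.
#'
#' Two guarantees make the rendering invertible by column-count tracking:
#' every disc is drawn in full (the clamp keeps each fly's pixel centroid
#' within `fly_radius_px` of its true position), and flies whose columns
#' come within one disc diameter of each other are placed on transverse
#' rows separated by more than a diameter, so discs never overlap and each
#' fly always contributes the same pixel weight. If more flies crowd one
#' lengthwise neighborhood than the frame height can separate, rendering
#' is rejected with a diagnostic (increase `height_px`).
#'
#' The dynamics are one-dimensional; the transverse row placement is
#' cosmetic and does not enter any statistic.
#'
#' @param traj A `fly_trajectory` from [simulate_trajectories()].
#' @param geometry A [tube_geometry()] giving the tube span in the frame.
#' @param height_px Frame height in pixels. Default 40.
#' @param width_px Frame width in pixels; defaults to the tube span end
#'   `geometry$c1` (tube flush with the frame edge).
#' @param fly_radius_px Fly disc radius in pixels. Default 2.
#' @param fly_intensity,background Grayscale levels in \[0, 1\]. Flies must
#'   be distinguishable from the background given the intended threshold
#'   (midway between the two): the function rejects settings where the
#'   noise could flip pixels across it.
#' @param noise_sd Gaussian noise SD. Default 0.02.
#' @param seed Integer seed for row placement and noise.
#' @return A list of `height_px` x `width_px` numeric matrices in \[0, 1\],
#'   one per frame.
#' @examples
#' traj <- simulate_trajectories(assay_sim_config(n_flies = 3, duration_s = 5, seed = 2))
#' frames <- render_frames(traj, tube_geometry(1, 150), seed = 2)
#' length(frames)
#' @export
render_frames <- function(traj, geometry,
                          height_px = 40, width_px = NULL,
                          fly_radius_px = 2,
                          fly_intensity = 1, background = 0,
                          noise_sd = 0.02, seed = 1L) {
  if (!inherits(traj, "fly_trajectory")) {
    ft_abort("`traj` must be a fly_trajectory.", "flytube_bad_argument")
  }
  if (!inherits(geometry, "tube_geometry")) {
    ft_abort("`geometry` must be a tube_geometry().", "flytube_bad_argument")
  }
  if (is.null(width_px)) width_px <- geometry$c1
  if (geometry$c1 > width_px) {
    ft_abort("Tube geometry extends beyond the frame width.", "flytube_bad_geometry")
  }
  margin <- abs(fly_intensity - background) / 2
  if (margin == 0 || noise_sd * 4 >= margin) {
    ft_abort(
      paste("Flies are indistinguishable from background: |fly_intensity -",
            "background| must exceed 8 * noise_sd so no noisy pixel can",
            "cross the midpoint threshold."),
      "flytube_bad_render"
    )
  }
  L_mm <- attr(traj, "tube_length_mm")
  times <- attr(traj, "times")
  pos <- unclass(traj)
  n <- nrow(pos)
  W_tube <- geometry$L
  r <- fly_radius_px
  if (W_tube < 2 * r + 1) {
    ft_abort("Tube span is narrower than one fly disc; shrink fly_radius_px.",
             "flytube_bad_render")
  }
  if (height_px < 2 * r + 2) {
    ft_abort("Frame height cannot hold one fly disc; increase height_px.",
             "flytube_bad_render")
  }
  # transverse rows spaced > one disc diameter apart, for occlusion-free
  # placement of flies sharing a lengthwise neighborhood
  slot_rows <- seq(1 + r, height_px - r, by = 2 * r + 1)
  free_rows <- seq(1 + r, height_px - r)
  set.seed(seed + 1L) # rendering substream, offset from the trajectory seed
  dy <- -r:r
  disc <- which(outer(dy^2, dy^2, "+") <= r^2, arr.ind = TRUE)
  lapply(seq_len(ncol(pos)), function(f) {
    fr <- matrix(background, height_px, width_px)
    if (n > 0) {
      offs <- pmin(pmax(round(pos[, f] / L_mm * (W_tube - 1)), r),
                   W_tube - 1 - r)
      cols <- if (geometry$odorant_end == "left") {
        geometry$c0 + offs
      } else {
        geometry$c1 - offs
      }
      rows <- .place_rows(cols, r, slot_rows, free_rows)
      for (i in seq_len(n)) {
        rr <- rows[i] + dy[disc[, 1]]
        cc <- cols[i] + dy[disc[, 2]]
        fr[cbind(rr, cc)] <- fly_intensity
      }
    }
    if (noise_sd > 0) {
      # clipped to < half the fly/background contrast, so no pixel can
      # cross the midpoint threshold
      noise <- matrix(rnorm(length(fr), 0, noise_sd), nrow(fr))
      fr <- fr + pmin(pmax(noise, -margin * 0.99), margin * 0.99)
    }
    pmin(pmax(fr, 0), 1)
  })
}

# Assign transverse rows so that flies whose columns are within one disc
# diameter of each other never share disc rows. Flies are grouped into
# column-adjacency clusters; clusters draw distinct spaced rows, singletons
# draw any row that keeps the disc inside the frame.
.place_rows <- function(cols, r, slot_rows, free_rows) {
  n <- length(cols)
  rows <- integer(n)
  ord <- order(cols)
  cluster <- cumsum(c(1, diff(cols[ord]) > 2 * r))
  for (idx in split(ord, cluster)) {
    m <- length(idx)
    if (m == 1) {
      rows[idx] <- free_rows[sample.int(length(free_rows), 1)]
    } else {
      if (m > length(slot_rows)) {
        ft_abort(
          paste("Too many flies share a lengthwise neighborhood to place",
                "without occlusion; increase height_px."),
          "flytube_bad_render"
        )
      }
      rows[idx] <- slot_rows[sample.int(length(slot_rows), m)]
    }
  }
  rows
}

#' Write a frame stack as a multi-page TIFF
#'
#' @param frames List of numeric matrices in \[0, 1\].
#' @param path Output file.
#' @param bits_per_sample 8 (default) or 16.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(frames, path, bits_per_sample = 8) {
  if (!is.list(frames) || length(frames) == 0) {
    ft_abort("`frames` must be a non-empty list of matrices.", "flytube_empty_stack")
  }
  tiff::writeTIFF(frames, path, bits.per.sample = bits_per_sample,
                  compression = "none")
  invisible(path)
}

#' Read a frame stack
#'
#' Reads either a multi-page TIFF file or a directory of single-frame PNG
#' images (sorted by file name). Color images are converted to grayscale by
#' channel averaging.
#'
#' @param path A `.tif`/`.tiff` file or a directory of `.png` frames.
#' @return A list of numeric matrices in \[0, 1\].
#' @export
read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) {
      ft_abort("No .png frames found in directory.", "flytube_empty_stack")
    }
    frames <- lapply(files, function(f) .to_gray(png::readPNG(f)))
  } else {
    if (!file.exists(path)) {
      ft_abort(sprintf("No such file: %s", path), "flytube_io_error")
    }
    frames <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    frames <- lapply(frames, .to_gray)
  }
  frames
}

.to_gray <- function(img) {
  if (length(dim(img)) == 3) {
    n_ch <- min(dim(img)[3], 3) # drop alpha
    img <- apply(img[, , seq_len(n_ch), drop = FALSE], c(1, 2), mean)
  }
  img
}
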