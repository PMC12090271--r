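#' Tube geometry within a video frame
#'
#' Describes where the assay tube lies in the image and which end carries
#' the odorant cap. Columns are indexed from 1 (R convention); the tube
#' occupies columns `c0` to `c1` inclusive, so its length in pixels is
#' `L = c1 - c0 + 1`.
#'
#' @param c0,c1 First and last column of the tube span (1-based, inclusive).
#' @param odorant_end `"left"` if the odorant cap is at the low-column end
#'   of the image, `"right"` if at the high-column end. All lengthwise
#'   coordinates are measured from the odorant end, so this flag flips the
#'   image orientation for the statistics.
#' @return A `tube_geometry` object.
#' @examples
#' tube_geometry(1, 500, "left")
#' @export
tube_geometry <- function(c0, c1, odorant_end = c("left", "right")) {
  assert_scalar_number(c0, "c0")
  assert_scalar_number(c1, "c1")
  odorant_end <- match.arg(odorant_end)
  if (c0 != round(c0) || c1 != round(c1) || c0 < 1 || c1 <= c0) {
    ft_abort("Need integer columns with c1 > c0 >= 1 (tube length >= 2 px).",
             "flytube_bad_geometry")
  }
  structure(
    list(c0 = as.integer(c0), c1 = as.integer(c1),
         odorant_end = odorant_end,
         L = as.integer(c1 - c0 + 1)),
    class = "tube_geometry"
  )
}

#' @export
print.tube_geometry <- function(x, ...) {
  cat(sprintf("<tube_geometry> columns %d..%d (L = %d px), odorant at %s end\n",
              x$c0, x$c1, x$L, x$odorant_end))
  invisible(x)
}

#' Brightness-threshold specification
#'
#' Flies are segmented from the background by a preset brightness
#' threshold. `mode = "fixed"` uses the given `level` on the image's
#' intensity scale; `mode = "otsu"` derives the level per frame with Otsu's
#' method (requires the EBImage package; offered as a convenience, the
#' fixed preset level is the default workflow). `polarity` states whether
#' flies are brighter or darker than the background; with
#' `"bright_flies"` pixels strictly above the level are flagged, with
#' `"dark_flies"` pixels strictly below it.
#'
#' @param mode `"fixed"` or `"otsu"`.
#' @param level Threshold level (required for `mode = "fixed"`), on the
#'   same scale as the frame intensities.
#' @param polarity `"bright_flies"` or `"dark_flies"`.
#' @return A `threshold_spec` object.
#' @examples
#' threshold_spec(level = 0.5)
#' @export
threshold_spec <- function(mode = c("fixed", "otsu"), level = NULL,
                           polarity = c("bright_flies", "dark_flies")) {
  mode <- match.arg(mode)
  polarity <- match.arg(polarity)
  if (mode == "fixed") {
    if (is.null(level)) {
      ft_abort("Fixed-threshold mode needs a `level`.", "flytube_bad_threshold")
    }
    assert_scalar_number(level, "level")
  }
  structure(list(mode = mode, level = level, polarity = polarity),
            class = "threshold_spec")
}
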