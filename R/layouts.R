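#' Screen layouts for the three paradigms
#'
#' A trial layout bundles the screen geometry a trial was presented on: screen
#' size, the central fixation point, the AOI rectangles (half-open,
#' `[x_min, x_max) x [y_min, y_max)`, origin at the top-left corner, y growing
#' downward), the true midline(s) separating the AOIs, and per-trial event
#' metadata (response time, chosen/novel/target AOI, target-word onset).
#'
#' `cascade_layout()` places two square face images left and right of a
#' vertical midline; `novelty_layout()` does the same with larger picture
#' AOIs; `vwp_layout()` centers one image in each screen quadrant, separated
#' by both a vertical and a horizontal midline.
#'
#' @param screen_w,screen_h Screen size in pixels.
#' @param image_w,image_h Stimulus image size in pixels (the AOI rectangle).
#' @param gap_px Horizontal gap between the two lateral images, in pixels.
#' @param fixation_ms Duration of the central fixation cross, ms.
#' @return A `trial_layout` list with fields `screen_w`, `screen_h`, `fix_x`,
#'   `fix_y`, `fixation_ms`, `aois` (tibble with `label`, `x_min`, `x_max`,
#'   `y_min`, `y_max`), `midline_x` and (four-AOI layouts only) `midline_y`.
#' @examples
#' lay <- cascade_layout()
#' lay$aois
#' @export
cascade_layout <- function(screen_w = 1280, screen_h = 720,
                           image_w = 173, image_h = 173,
                           gap_px = 295, fixation_ms = 2000) {
  cx <- screen_w / 2
  cy <- screen_h / 2
  aois <- tibble(
    label = c("left", "right"),
    x_min = c(cx - gap_px / 2 - image_w, cx + gap_px / 2),
    x_max = c(cx - gap_px / 2, cx + gap_px / 2 + image_w),
    y_min = cy - image_h / 2,
    y_max = cy + image_h / 2
  )
  new_trial_layout(screen_w, screen_h, fixation_ms, aois,
                   midline_x = cx, midline_y = NA_real_)
}

#' @rdname cascade_layout
#' @export
novelty_layout <- function(screen_w = 1280, screen_h = 720,
                           image_w = 472, image_h = 331,
                           gap_px = 295, fixation_ms = 2000) {
  cx <- screen_w / 2
  cy <- screen_h / 2
  aois <- tibble(
    label = c("left", "right"),
    x_min = c(cx - gap_px / 2 - image_w, cx + gap_px / 2),
    x_max = c(cx - gap_px / 2, cx + gap_px / 2 + image_w),
    y_min = cy - image_h / 2,
    y_max = cy + image_h / 2
  )
  new_trial_layout(screen_w, screen_h, fixation_ms, aois,
                   midline_x = cx, midline_y = NA_real_)
}

#' @rdname cascade_layout
#' @export
vwp_layout <- function(screen_w = 1280, screen_h = 720,
                       image_w = 265, image_h = 189, fixation_ms = 2000) {
  qx <- c(screen_w / 4, 3 * screen_w / 4)
  qy <- c(screen_h / 4, 3 * screen_h / 4)
  aois <- tibble(
    label = c("top_left", "top_right", "bottom_left", "bottom_right"),
    x_min = rep(qx, 2) - image_w / 2,
    x_max = rep(qx, 2) + image_w / 2,
    y_min = rep(qy, each = 2) - image_h / 2,
    y_max = rep(qy, each = 2) + image_h / 2
  )
  new_trial_layout(screen_w, screen_h, fixation_ms, aois,
                   midline_x = screen_w / 2, midline_y = screen_h / 2)
}

new_trial_layout <- function(screen_w, screen_h, fixation_ms, aois,
                             midline_x, midline_y) {
  layout <- structure(
    list(
      screen_w = screen_w, screen_h = screen_h,
      fix_x = screen_w / 2, fix_y = screen_h / 2,
      fixation_ms = fixation_ms,
      aois = aois,
      midline_x = midline_x, midline_y = midline_y
    ),
    class = "trial_layout"
  )
  validate_layout(layout)
  layout
}

#' Validate a trial layout
#'
#' Checks that AOI rectangles are non-empty, pairwise disjoint and inside the
#' screen, that midlines lie within the screen, and that the fixation
#' duration is positive.
#'
#' @param layout A `trial_layout`.
#' @return The layout, invisibly; errors if invalid.
#' @export
validate_layout <- function(layout) {
  a <- layout$aois
  stopifnot(
    layout$screen_w > 0, layout$screen_h > 0,
    layout$fixation_ms > 0,
    all(a$x_min < a$x_max), all(a$y_min < a$y_max),
    all(a$x_min >= 0), all(a$x_max <= layout$screen_w),
    all(a$y_min >= 0), all(a$y_max <= layout$screen_h)
  )
  if (layout$midline_x < 0 || layout$midline_x > layout$screen_w)
    stop("midline_x outside screen")
  if (!is.na(layout$midline_y) &&
      (layout$midline_y < 0 || layout$midline_y > layout$screen_h))
    stop("midline_y outside screen")
  n <- nrow(a)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      overlap_x <- a$x_min[i] < a$x_max[j] && a$x_min[j] < a$x_max[i]
      overlap_y <- a$y_min[i] < a$y_max[j] && a$y_min[j] < a$y_max[i]
      if (overlap_x && overlap_y)
        stop("AOI rectangles '", a$label[i], "' and '", a$label[j],
             "' overlap")
    }
  }
  invisible(layout)
}

#' @export
print.trial_layout <- function(x, ...) {
  cat(sprintf("<trial_layout> %d x %d px screen, %d AOIs, fixation %g ms\n",
              x$screen_w, x$screen_h, nrow(x$aois), x$fixation_ms))
  print(x$aois)
  invisible(x)
}
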