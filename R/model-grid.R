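#' Spatial grid for the normalization model
#'
#' The model is computed on a one-dimensional spatial axis (in model
#' arbitrary units, a.u.) crossed with a small number of motion-direction
#' channels. The grid is symmetric about zero so that centered stimuli are
#' represented without bias, and it carries a guard margin: stimuli whose
#' outer edge intrudes into the guard would suffer boundary truncation of
#' the suppressive pool, so they are rejected.
#'
#' @param half_width Half-extent of the axis in a.u.; positions span
#'   `[-half_width, half_width]`.
#' @param spacing Distance between adjacent samples (a.u.). Must divide
#'   `2 * half_width` into at least 63 intervals (>= 64 samples).
#' @param n_directions Number of motion-direction channels (default 2:
#'   left and right).
#' @param guard Guard margin in a.u. kept free of stimulus energy at each
#'   end of the axis (typically `3 * suppress_width`).
#' @param allow_small Permit grids with fewer than 64 samples. Production
#'   grids must have at least 64 samples; tiny grids are only meaningful
#'   for oracle cross-checks against brute-force implementations.
#' @return An object of class `spatial_grid` with fields `positions`,
#'   `spacing`, `n_directions`, `guard`.
#' @export
spatial_grid <- function(half_width, spacing, n_directions = 2L, guard = 0,
                         allow_small = FALSE) {
  stopifnot(spacing > 0, half_width > 0, n_directions >= 1, guard >= 0)
  n_half <- round(half_width / spacing)
  positions <- seq(-n_half, n_half) * spacing
  if (length(positions) < 64 && !allow_small) {
    stop("spatial_grid: fewer than 64 samples; reduce `spacing` or enlarge `half_width`")
  }
  structure(
    list(positions = positions, spacing = spacing,
         n_directions = as.integer(n_directions), guard = guard),
    class = "spatial_grid"
  )
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("<spatial_grid> %d samples in [%.3g, %.3g] a.u., spacing %.3g, %d direction channels, guard %.3g\n",
              length(x$positions), min(x$positions), max(x$positions),
              x$spacing, x$n_directions, x$guard))
  invisible(x)
}

#' Default grid sized to a stimulus set
#'
#' Builds a grid whose total extent is at least four times the largest
#' stimulus extent plus six suppressive widths, so that convolution
#' boundary effects are negligible (zero padding beyond the guard).
#'
#' @param max_extent_au Largest stimulus outer extent (full width, a.u.).
#' @param suppress_width Suppressive pool width sigma_s (a.u.).
#' @param spacing Sample spacing in a.u. (default 0.25).
#' @param n_directions Number of direction channels.
#' @return A [spatial_grid()].
#' @export
default_grid <- function(max_extent_au, suppress_width, spacing = 0.25,
                         n_directions = 2L) {
  half_width <- (4 * max_extent_au + 6 * suppress_width) / 2
  spatial_grid(half_width, spacing, n_directions,
               guard = 3 * suppress_width)
}

#' Stimulus specification
#'
#' A drifting-grating stimulus is idealized as a contrast-weighted
#' indicator over a spatial interval on one direction channel. An optional
#' surround adds a symmetric annulus (two flanking bars in 1-D) at a gap
#' from the center stimulus, on its own direction channel.
#'
#' @param extent Full width of the center stimulus (a.u.).
#' @param contrast Michelson contrast in `[0, 1]`.
#' @param center Stimulus center position (a.u., default 0).
#' @param direction `"left"` or `"right"`.
#' @param surround Optional list with fields `gap` (a.u., > 0),
#'   `outer_extent` (a.u., distance from center to the outer edge of the
#'   surround), `direction`, and optionally `contrast` (defaults to the
#'   center contrast).
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(extent, contrast, center = 0, direction = "left",
                          surround = NULL) {
  stopifnot(extent > 0, contrast >= 0, contrast <= 1)
  direction <- match.arg(direction, c("left", "right"))
  if (!is.null(surround)) {
    stopifnot(is.list(surround), surround$gap > 0)
    surround$direction <- match.arg(surround$direction, c("left", "right"))
    if (is.null(surround$contrast)) surround$contrast <- contrast
    if (surround$outer_extent <= extent / 2 + surround$gap) {
      stop("surround outer_extent must exceed extent/2 + gap")
    }
  }
  structure(list(center = center, extent = extent, contrast = contrast,
                 direction = direction, surround = surround),
            class = "stimulus_spec")
}

dir_index <- function(direction) match(direction, c("left", "right"))

#' Discretize a stimulus onto the grid
#'
#' Produces the stimulus drive image: contrast at grid positions inside
#' the stimulus interval on the stimulus's direction channel, zero
#' elsewhere. A surround, if present, contributes its contrast over the
#' annulus `[center + extent/2 + gap, center +/- outer_extent]` mirrored on
#' both sides, on the surround's direction channel.
#'
#' @param stim A [stimulus_spec()].
#' @param grid A [spatial_grid()].
#' @return A numeric matrix, space x direction.
#' @export
build_stimulus_drive <- function(stim, grid) {
  stopifnot(inherits(stim, "stimulus_spec"), inherits(grid, "spatial_grid"))
  pos <- grid$positions
  outer_edge <- abs(stim$center) + stim$extent / 2
  if (!is.null(stim$surround)) {
    outer_edge <- max(outer_edge, abs(stim$center) + stim$surround$outer_extent)
  }
  limit <- max(pos) - grid$guard
  if (outer_edge > limit) {
    stop(sprintf(
      "stimulus outer edge at %.3g a.u. exceeds the grid guard margin (|x| <= %.3g a.u.)",
      outer_edge, limit))
  }
  drive <- matrix(0, nrow = length(pos), ncol = grid$n_directions)
  in_center <- pos >= stim$center - stim$extent / 2 &
    pos <= stim$center + stim$extent / 2
  drive[in_center, dir_index(stim$direction)] <- stim$contrast
  if (!is.null(stim$surround)) {
    s <- stim$surround
    d <- abs(pos - stim$center)
    in_ann <- d >= stim$extent / 2 + s$gap & d <= s$outer_extent
    j <- dir_index(s$direction)
    drive[in_ann, j] <- pmax(drive[in_ann, j], s$contrast)
  }
  drive
}
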