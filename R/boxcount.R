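#' Count occupied boxes at one box size
#'
#' Tiles the volume with grid-aligned cubes of side `r` voxels, anchored at
#' the array origin and stacked side by side (partial boxes at the far
#' faces included, so the tiling covers the whole object), and counts the
#' boxes containing at least one filled voxel.
#'
#' @param volume a `voxel_volume` (or 3D logical array).
#' @param r positive integer box side in voxels.
#' @return Nonnegative integer count of occupied boxes.
#' @export
count_boxes <- function(volume, r) {
  grid <- if (inherits(volume, "voxel_volume")) volume$grid else volume
  if (length(dim(grid)) != 3L) stop("volume must be 3D")
  r <- check_count(r, "r")
  idx <- which(grid, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0L)
  b <- (idx - 1L) %/% r
  nb <- ceiling(dim(grid) / r)
  code <- b[, 1] + nb[1] * (b[, 2] + nb[2] * b[, 3])
  length(unique(code))
}

#' Box-count series over a schedule of box sizes
#'
#' Computes the occupied-box count N(r) for every integer box size from
#' `r_max` down to `r_min` (defaults 10 down to 2, giving 9 points).
#'
#' @inheritParams count_boxes
#' @param r_max,r_min integer endpoints of the (decreasing) schedule.
#' @return A data.frame of class `boxcount_series` with columns `r` and
#'   `N`, ordered by decreasing `r`.
#' @export
boxcount_series <- function(volume, r_max = 10L, r_min = 2L) {
  grid <- if (inherits(volume, "voxel_volume")) volume$grid else volume
  r_max <- check_count(r_max, "r_max")
  r_min <- check_count(r_min, "r_min")
  if (r_max < r_min) stop("r_max must be >= r_min")
  if (!any(grid)) stop("volume is empty: no object to cover")
  rs <- seq.int(r_max, r_min)
  out <- data.frame(r = rs,
                    N = vapply(rs, function(r) count_boxes(grid, r), integer(1)))
  class(out) <- c("boxcount_series", "data.frame")
  out
}

#' Fit the fractal dimension from a box-count series
#'
#' Regresses y = log2 N(r) on x = log2(1/r) by ordinary least squares over
#' every contiguous window of at least `min_window` points and keeps the
#' window with the highest squared correlation (R^2) — the linear portion
#' of the log-log plot. The FD estimate is that window's slope; the
#' intercept k completes the line y = FD*x + k.
#'
#' Ties on R^2 (within 1e-12) are broken toward the longer window, then
#' toward the window containing the larger boxes; a window whose y values
#' are constant gets R^2 = 0 so it is never preferred over an informative
#' window.
#'
#' @param series a `boxcount_series` (or data.frame with columns `r`, `N`).
#' @param min_window minimum number of points in an admissible window.
#' @return An object of class `fd_fit` with elements `fd`, `intercept`,
#'   `r_squared`, `window` (start/end indices into the series), `x`, `y`,
#'   `window_r_max`, `window_r_min`.
#' @export
fit_fd <- function(series, min_window = 4L) {
  if (!is.data.frame(series) || !all(c("r", "N") %in% names(series)))
    stop("series must have columns r and N")
  min_window <- check_count(min_window, "min_window")
  if (min_window < 2L) stop("min_window must be at least 2")
  n <- nrow(series)
  if (n < min_window)
    stop("series has ", n, " points but min_window is ", min_window)
  if (any(series$N < 1)) stop("box counts must be >= 1")
  x <- log2(1 / series$r)
  y <- log2(series$N)

  best <- NULL
  for (start in seq_len(n - min_window + 1L)) {
    for (end in seq.int(start + min_window - 1L, n)) {
      xs <- x[start:end]; ys <- y[start:end]
      sxx <- sum((xs - mean(xs))^2)
      syy <- sum((ys - mean(ys))^2)
      sxy <- sum((xs - mean(xs)) * (ys - mean(ys)))
      r2 <- if (syy <= 0) 0 else (sxy^2) / (sxx * syy)
      cand <- list(start = start, end = end, r2 = r2,
                   len = end - start + 1L)
      if (is.null(best) ||
          r2 > best$r2 + 1e-12 ||
          (abs(r2 - best$r2) <= 1e-12 &&
           (cand$len > best$len ||
            (cand$len == best$len && start < best$start)))) {
        best <- cand
      }
    }
  }
  if (best$r2 == 0 && all(y == y[1]))
    stop("all box counts equal: R^2 undefined in every window")

  xs <- x[best$start:best$end]; ys <- y[best$start:best$end]
  slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / sum((xs - mean(xs))^2)
  intercept <- mean(ys) - slope * mean(xs)
  structure(list(fd = slope, intercept = intercept, r_squared = best$r2,
                 window = c(start = best$start, end = best$end),
                 x = x, y = y,
                 window_r_max = series$r[best$start],
                 window_r_min = series$r[best$end]),
            class = "fd_fit")
}

#' @export
print.fd_fit <- function(x, ...) {
  cat(sprintf("<fd_fit> FD = %.4f (R^2 = %.4f, window r = %d..%d)\n",
              x$fd, x$r_squared, x$window_r_max, x$window_r_min))
  invisible(x)
}

#' Fractal dimension of one parcellation region
#'
#' Binarizes the voxels carrying `region_id`, crops them to their tight
#' bounding box (so counts are object-relative rather than
#' field-of-view-relative; set `crop = FALSE` to keep the full grid), and
#' runs [boxcount_series()] + [fit_fd()].
#'
#' @param parc a `parcellation`.
#' @param region_id integer label to extract.
#' @param r_max,r_min box-size schedule, see [boxcount_series()].
#' @param min_window see [fit_fd()].
#' @param crop crop to the region's bounding box before counting.
#' @return An `fd_fit`.
#' @export
region_fd <- function(parc, region_id, r_max = 10L, r_min = 2L,
                      min_window = 4L, crop = TRUE) {
  stopifnot(inherits(parc, "parcellation"))
  mask <- parc$labels == region_id
  if (!any(mask))
    stop("region ", region_id, " is empty or unknown in this parcellation")
  if (crop) {
    rng <- apply(which(mask, arr.ind = TRUE), 2, range)
    mask <- mask[rng[1, 1]:rng[2, 1], rng[1, 2]:rng[2, 2],
                 rng[1, 3]:rng[2, 3], drop = FALSE]
  }
  fit_fd(boxcount_series(mask, r_max = r_max, r_min = r_min),
         min_window = min_window)
}

#' Per-region FD table for a parcellation
#'
#' Convenience wrapper running [region_fd()] over every region present in
#' the region table.
#'
#' @inheritParams region_fd
#' @param region_table a region table.
#' @return A data.frame with columns `region_id`, `abbreviation`, `label`,
#'   `fd`, `r_squared`, `window_r_max`, `window_r_min`.
#' @export
parcellation_fd_table <- function(parc, region_table = parc$region_table, ...) {
  fits <- lapply(region_table$id, function(j) region_fd(parc, j, ...))
  data.frame(region_id = region_table$id,
             abbreviation = region_table$abbreviation,
             label = region_table$label,
             fd = vapply(fits, `[[`, numeric(1), "fd"),
             r_squared = vapply(fits, `[[`, numeric(1), "r_squared"),
             window_r_max = vapply(fits, `[[`, numeric(1), "window_r_max"),
             window_r_min = vapply(fits, `[[`, numeric(1), "window_r_min"))
}
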