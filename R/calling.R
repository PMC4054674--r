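# Nucleosome calling from smoothed tiling signal.
#
# The caller follows the classic single-nucleosome detection scheme for
# MNase ChIP-chip: resample irregular probes onto a uniform grid, smooth
# with a Savitzky-Golay filter (which preserves peak areas, extremum
# positions and widths), take numerical first and second derivatives,
# read nucleosome centers off the downward zero crossings of the first
# derivative and peak borders off the flanking zero crossings of the second
# derivative, then refine center/height by a least-squares parabola fit
# over each peak's support.

#' Caller parameters
#'
#' @param grid_step bp between grid points after resampling (default 10).
#' @param sg_window Savitzky-Golay window, odd number of grid points
#'   (default 15, i.e. 150 bp at the default step — about one nucleosome
#'   footprint).
#' @param sg_order Savitzky-Golay polynomial order (default 3).
#' @param min_height minimum fitted peak height above the track median;
#'   `NULL` (default) uses 0.5 x the robust signal SD
#'   (`mad * 1.4826`-scaled) of the resampled track.
#' @param min_width,max_width bp bounds on the fitted width (defaults 80
#'   and 300: sub-nucleosomal and poly-nucleosomal peaks are discarded).
#' @param merge_distance bp below which calls from different channels are
#'   considered the same nucleosome (default 74, half a footprint).
#' @return a validated list of class `caller_params`.
#' @export
caller_params <- function(grid_step = 10, sg_window = 15, sg_order = 3,
                          min_height = NULL, min_width = 80,
                          max_width = 300, merge_distance = 74) {
  if (grid_step < 1) stop("grid_step must be >= 1")
  if (sg_window %% 2 != 1 || sg_window <= sg_order)
    stop("sg_window must be odd and greater than sg_order")
  if (min_width >= max_width) stop("min_width must be < max_width")
  structure(list(grid_step = grid_step, sg_window = sg_window,
                 sg_order = sg_order, min_height = min_height,
                 min_width = min_width, max_width = max_width,
                 merge_distance = merge_distance),
            class = "caller_params")
}

#' Resample a probe track onto a uniform grid
#'
#' Linear interpolation onto a regular grid of `grid_step` covering the
#' probe span; no extrapolation beyond the first/last probe.
#'
#' @param positions sorted probe positions (bp) of one chromosome.
#' @param values signal at those positions.
#' @param grid_step bp between grid points.
#' @return list with `pos` (grid positions) and `value`.
#' @export
resample_to_grid <- function(positions, values, grid_step) {
  if (length(positions) < 2)
    stop("resampling requires at least two probes")
  grid <- seq(positions[1], positions[length(positions)], by = grid_step)
  list(pos = grid,
       value = stats::approx(positions, values, xout = grid,
                             method = "linear", ties = "ordered")$y)
}

#' Savitzky-Golay smoothing with first and second derivatives
#'
#' Local least-squares polynomial fit per grid point. Derivatives are
#' returned in per-bp units (scaled by `grid_step`).
#'
#' @param signal uniform-grid signal values.
#' @param sg_window odd window length in grid points.
#' @param sg_order polynomial order.
#' @param grid_step bp between grid points.
#' @return list with `smoothed`, `d1`, `d2` (same length as `signal`).
#' @export
smooth_and_differentiate <- function(signal, sg_window, sg_order,
                                     grid_step = 1) {
  if (length(signal) < sg_window)
    stop("signal shorter than the smoothing window")
  list(smoothed = as.numeric(
         signal::sgolayfilt(signal, p = sg_order, n = sg_window, m = 0)),
       d1 = as.numeric(signal::sgolayfilt(signal, p = sg_order,
                                          n = sg_window, m = 1,
                                          ts = grid_step)),
       d2 = as.numeric(signal::sgolayfilt(signal, p = sg_order,
                                          n = sg_window, m = 2,
                                          ts = grid_step)))
}

#' Detect candidate peaks from derivative zero crossings
#'
#' A candidate is placed at each downward (+ to -) zero crossing of the
#' first derivative, with the center refined by linear interpolation of the
#' first derivative between the flanking grid points (an exactly-zero
#' plateau gives its midpoint). The support is bounded by the nearest
#' second-derivative zero crossings left and right of the center; a
#' candidate without both bounds is dropped.
#'
#' @param pos grid positions (bp).
#' @param d1,d2 first/second derivative from [smooth_and_differentiate()].
#' @return data.table with `center`, `support_left`, `support_right` and
#'   grid index columns `i_left`, `i_right` delimiting the support.
#' @export
detect_peaks <- function(pos, d1, d2) {
  n <- length(pos)
  empty <- data.table(center = numeric(0), support_left = numeric(0),
                      support_right = numeric(0), i_left = integer(0),
                      i_right = integer(0))
  # derivative magnitudes below round-off (relative to the signal's own
  # derivative scale) are treated as exact zeros, so flat stretches do not
  # produce spurious crossings
  tol <- 1e-10 * max(abs(d1))
  s <- sign(d1)
  s[abs(d1) <= tol] <- 0
  nz <- which(s != 0)
  if (length(nz) < 2) return(empty)
  # consecutive nonzero points bracketing a + to - transition; any
  # exactly-zero plateau between them contributes its midpoint
  i <- nz[-length(nz)]
  j <- nz[-1]
  dn <- s[i] > 0 & s[j] < 0
  i <- i[dn]; j <- j[dn]
  if (!length(i)) return(empty)
  adj <- j == i + 1
  centers <- numeric(length(i))
  centers[adj] <- pos[i[adj]] + (pos[j[adj]] - pos[i[adj]]) *
    d1[i[adj]] / (d1[i[adj]] - d1[j[adj]])
  centers[!adj] <- (pos[i[!adj] + 1] + pos[j[!adj] - 1]) / 2
  # d2 zero crossings, with sub-grid linear interpolation
  cross <- which(d2[-n] * d2[-1] <= 0 & (d2[-n] != 0 | d2[-1] != 0))
  if (!length(cross)) return(empty)
  zero_at <- pos[cross] + (pos[cross + 1] - pos[cross]) *
    d2[cross] / (d2[cross] - d2[cross + 1])
  zero_at <- sort(unique(zero_at))
  k <- findInterval(centers, zero_at)
  k[k >= 1 & zero_at[pmax(k, 1)] >= centers] <-
    k[k >= 1 & zero_at[pmax(k, 1)] >= centers] - 1L
  ok <- k >= 1 & k < length(zero_at)
  if (!any(ok)) return(empty)
  sl <- zero_at[k[ok]]
  sr <- zero_at[k[ok] + 1]
  data.table(center = centers[ok], support_left = sl, support_right = sr,
             i_left = findInterval(sl, pos) + 1L,
             i_right = findInterval(sr, pos))
}

#' Least-squares parabola fit over a peak support
#'
#' Fits `y = a (x - c)^2 + h` by ordinary least squares on the quadratic
#' basis; non-concave fits (`a >= 0`) are rejected (returns `NULL`).
#'
#' @param x grid positions over the support (>= 3 points).
#' @param y smoothed signal at `x`.
#' @return list with `center`, `height`, `a` (curvature) and `residual`
#'   (RMS of the fit), or `NULL` when the fit is not concave.
#' @export
fit_parabola <- function(x, y) {
  if (length(x) < 3) return(NULL)
  xm <- x - mean(x)                       # center basis for conditioning
  X <- cbind(1, xm, xm^2)
  beta <- tryCatch(solve(crossprod(X), crossprod(X, y)),
                   error = function(e) NULL)
  if (is.null(beta)) return(NULL)
  a <- beta[3]
  if (a >= 0) return(NULL)
  c0 <- -beta[2] / (2 * a)
  h <- beta[1] - beta[2]^2 / (4 * a)
  res <- sqrt(mean((X %*% beta - y)^2))
  list(center = c0 + mean(x), height = as.numeric(h), a = as.numeric(a),
       residual = res)
}

#' Call positioned nucleosomes on one track
#'
#' Pipeline: resample to a uniform grid, Savitzky-Golay smooth and
#' differentiate, detect derivative zero-crossing candidates, refine each by
#' a parabola fit over its support, and filter by fitted height (above the
#' track median) and width bounds. The call width is the distance between
#' the second-derivative zero crossings bounding the peak (the peak
#' borders); the parabola supplies center and height.
#'
#' @param track a [probe_track()] (any number of chromosomes).
#' @param params a [caller_params()].
#' @param channel label recorded per call (`"variant"` or `"histone"`).
#' @return data.table of calls sorted by chromosome and center, with
#'   columns `chrom`, `center`, `width`, `height`, `support_left`,
#'   `support_right`, `residual`, `channel`.
#' @export
call_nucleosomes <- function(track, params = caller_params(),
                             channel = "histone") {
  stopifnot(inherits(params, "caller_params"))
  one_chrom <- function(sub) {
    g <- resample_to_grid(sub$pos, sub$value, params$grid_step)
    sm <- smooth_and_differentiate(g$value, params$sg_window,
                                   params$sg_order, params$grid_step)
    cand <- detect_peaks(g$pos, sm$d1, sm$d2)
    if (nrow(cand) == 0) return(NULL)
    baseline <- median(g$value)
    min_h <- if (is.null(params$min_height))
      0.5 * mad(g$value) else params$min_height
    fits <- lapply(seq_len(nrow(cand)), function(i) {
      idx <- cand$i_left[i]:cand$i_right[i]
      if (length(idx) < 3) return(NULL)
      f <- fit_parabola(g$pos[idx], sm$smoothed[idx])
      if (is.null(f)) return(NULL)
      data.table(center = f$center,
                 width = cand$support_right[i] - cand$support_left[i],
                 height = f$height,
                 support_left = cand$support_left[i],
                 support_right = cand$support_right[i],
                 residual = f$residual)
    })
    calls <- rbindlist(fits)
    if (nrow(calls) == 0) return(NULL)
    calls <- calls[height - baseline > min_h &
                     width >= params$min_width & width <= params$max_width]
    calls
  }
  parts <- lapply(split(as.data.table(track), by = "chrom", sorted = TRUE),
                  one_chrom)
  keep <- !vapply(parts, is.null, TRUE)
  if (!any(keep))
    return(data.table(chrom = character(0), center = numeric(0),
                      width = numeric(0), height = numeric(0),
                      support_left = numeric(0), support_right = numeric(0),
                      residual = numeric(0), channel = character(0)))
  calls <- rbindlist(lapply(which(keep), function(i)
    cbind(chrom = names(parts)[i], parts[[i]])))
  calls[, channel := channel]
  setorder(calls, chrom, center)
  calls[]
}

#' Merge variant- and histone-channel call lists
#'
#' Union of the two lists: a variant-channel call whose center lies within
#' `merge_distance` of a histone-channel call on the same chromosome is
#' merged into it — the histone-channel geometry is kept and the provenance
#' recorded as `"both"`. Output is sorted with no cross-channel pair of
#' centers closer than `merge_distance`.
#'
#' @param calls_variant,calls_histone call tables from [call_nucleosomes()].
#' @param merge_distance bp (default 74).
#' @return merged call table with a `channel` column in
#'   `{"variant", "histone", "both"}`.
#' @export
merge_calls <- function(calls_variant, calls_histone, merge_distance = 74) {
  if (nrow(calls_histone) == 0) {
    out <- copy(calls_variant)
  } else if (nrow(calls_variant) == 0) {
    out <- copy(calls_histone)
  } else {
    hist_by <- split(calls_histone, by = "chrom")
    matched_h <- vector("list", length(hist_by))
    names(matched_h) <- names(hist_by)
    keep_v <- rep(TRUE, nrow(calls_variant))
    for (i in seq_len(nrow(calls_variant))) {
      cc <- calls_variant$chrom[i]
      h <- hist_by[[cc]]
      if (is.null(h)) next
      d <- abs(h$center - calls_variant$center[i])
      j <- which.min(d)
      if (d[j] <= merge_distance) {
        keep_v[i] <- FALSE
        matched_h[[cc]] <- c(matched_h[[cc]], j)
      }
    }
    hist_out <- rbindlist(lapply(names(hist_by), function(cc) {
      h <- copy(hist_by[[cc]])
      if (length(matched_h[[cc]]))
        h[unique(matched_h[[cc]]), channel := "both"]
      h
    }))
    out <- rbind(hist_out, calls_variant[keep_v])
  }
  setorder(out, chrom, center)
  out[, id := sprintf("nuc%06d", seq_len(.N))]
  out[]
}
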