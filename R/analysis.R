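#' Sample a cell field along a line segment
#'
#' Samples a cell-centered field at `n` evenly spaced points along a segment,
#' by multilinear interpolation between cell centers (default, reproduces
#' linear fields exactly) or nearest-cell lookup. This mirrors how simulated
#' fields are interpolated onto a thermometry imaging line for comparison.
#'
#' @param field per-cell values.
#' @param mesh a `thermo_mesh`.
#' @param start,end segment endpoints (m), length = mesh dimension; must lie
#'   inside the domain.
#' @param n number of samples, at least 2.
#' @param method `"multilinear"` or `"nearest"`.
#' @return a `thermo_profile` tibble with columns `position_mm` (distance
#'   along the segment, mm) and `value`; the endpoints and interpolation
#'   method are attached as attributes.
#' @export
line_profile <- function(field, mesh, start, end, n = 50,
                         method = c("multilinear", "nearest")) {
  method <- match.arg(method)
  if (n < 2) abort("need at least 2 samples", class = "thermo_input_error")
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != mesh$dim || length(end) != mesh$dim) {
    abort("segment endpoints must match the mesh dimension",
          class = "thermo_input_error")
  }
  for (pt in list(start, end)) {
    if (any(pt < -1e-12) || any(pt > mesh$extents + 1e-12)) {
      abort("line segment exits the domain", class = "thermo_input_error")
    }
  }
  tt <- seq(0, 1, length.out = n)
  pts <- outer(tt, end - start) + matrix(start, n, mesh$dim, byrow = TRUE)
  vals <- interp_cells(field, mesh, pts, method)
  dist_mm <- tt * sqrt(sum((end - start)^2)) * 1000
  out <- tibble(position_mm = dist_mm, value = vals)
  attr(out, "start") <- start
  attr(out, "end") <- end
  attr(out, "method") <- method
  class(out) <- c("thermo_profile", class(out))
  out
}

# Multilinear/nearest interpolation of cell-centered data at physical points.
# Clamped at the boundary (constant extrapolation over the half-cell rim).
interp_cells <- function(field, mesh, pts, method) {
  d <- mesh$dim
  h <- mesh$h
  nc <- mesh$cells
  stride <- cumprod(c(1L, nc))[seq_len(d)]
  npt <- nrow(pts)
  if (method == "nearest") {
    idx <- sapply(seq_len(d), function(k) {
      pmin(nc[k], pmax(1, ceiling(pts[, k] / h[k])))
    })
    idx <- matrix(idx, npt, d)
    lin <- 1 + as.vector((idx - 1) %*% stride)
    return(field[lin])
  }
  # multilinear: coordinate in cell-center units maps center of cell i to i-1;
  # clamped to the center range so the boundary half-cell extrapolates constant
  vals <- numeric(npt)
  fc <- sapply(seq_len(d), function(k) {
    pmin(nc[k] - 1, pmax(0, pts[, k] / h[k] - 0.5))
  })
  fc <- matrix(fc, npt, d)
  lo <- floor(fc)
  lo <- sapply(seq_len(d), function(k) pmin(max(nc[k] - 2, 0), lo[, k]))
  lo <- matrix(lo, npt, d)
  w <- fc - lo
  for (corner in seq_len(2^d) - 1L) {
    bits <- as.integer(intToBits(corner))[seq_len(d)]
    idx <- sweep(lo, 2, bits, `+`)
    idx <- sapply(seq_len(d), function(k) pmin(nc[k] - 1, idx[, k]))
    idx <- matrix(idx, npt, d)
    lin <- 1 + as.vector(idx %*% stride)
    wt <- rep(1, npt)
    for (k in seq_len(d)) {
      wt <- wt * if (bits[k] == 1L) w[, k] else (1 - w[, k])
    }
    vals <- vals + wt * field[lin]
  }
  vals
}

#' Compare a simulated and a measured line profile
#'
#' Pointwise validation statistics between two profiles on the same sample
#' positions: mean and maximum absolute temperature difference and the
#' Pearson correlation with its two-sided p-value.
#'
#' @param sim,meas `thermo_profile` objects (or data frames with
#'   `position_mm` and `value`) on identical positions.
#' @return a `profile_comparison` object with fields `mean_abs_diff`,
#'   `max_abs_diff`, `pearson_r`, `p_value`, `n`; supports [tidy()] and
#'   [glance()].
#' @export
compare_profiles <- function(sim, meas) {
  if (nrow(sim) != nrow(meas) ||
      max(abs(sim$position_mm - meas$position_mm)) > 1e-9) {
    abort("profiles must share identical sample positions",
          class = "thermo_input_error")
  }
  if (sd(sim$value) == 0 || sd(meas$value) == 0) {
    abort("correlation undefined: a profile has zero variance",
          class = "thermo_zero_variance")
  }
  d <- sim$value - meas$value
  ct <- cor.test(sim$value, meas$value, method = "pearson")
  structure(list(mean_abs_diff = mean(abs(d)),
                 max_abs_diff = max(abs(d)),
                 pearson_r = unname(ct$estimate),
                 p_value = ct$p.value,
                 n = nrow(sim)),
            class = "profile_comparison")
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("<profile_comparison> n = %d: mean |du| = %.2f C, max |du| = %.2f C, r = %.3f (p = %.3g)\n",
              x$n, x$mean_abs_diff, x$max_abs_diff, x$pearson_r, x$p_value))
  invisible(x)
}

#' Synthesize noisy thermometry frames from a simulated trajectory
#'
#' Emulates frame-by-frame temperature imaging of a simulation: checkpoints
#' are resampled at the frame interval and i.i.d. zero-mean Gaussian noise of
#' standard deviation `sigma_ref / snr` is added, as image noise with
#' Gaussian statistics scales inversely with the signal-to-noise ratio of the
#' magnitude images. `sigma_ref` is a calibration constant; the default gives
#' a 1 deg C noise floor at the default SNR of 10.
#'
#' @param sim a [run_simulation()] result.
#' @param snr signal-to-noise ratio, > 0.
#' @param frame_dt frame interval (s).
#' @param seed RNG seed for reproducible noise.
#' @param sigma_ref noise calibration constant (deg C at SNR 1).
#' @return list of frames, each `list(time, u)` with `u` the noisy field.
#' @export
synthesize_thermometry <- function(sim, snr = 10, frame_dt = 22.3,
                                   seed = 1, sigma_ref = 10) {
  if (snr <= 0) abort("snr must be positive", class = "thermo_input_error")
  sigma <- sigma_ref / snr
  times <- vapply(sim$checkpoints, `[[`, numeric(1), "time")
  frame_times <- seq(0, max(times), by = frame_dt)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(frame_times, function(tf) {
    k <- which.min(abs(times - tf))
    u <- sim$checkpoints[[k]]$u
    list(time = times[k], u = u + rnorm(length(u), 0, sigma))
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Probe time series at fixed points
#'
#' Extracts, per checkpoint, the field value at the cell nearest each probe
#' point -- the simulated analogue of per-voxel time-temperature curves.
#'
#' @param sim a [run_simulation()] result.
#' @param points a matrix of probe coordinates (rows = probes, cols = mesh
#'   dimension), inside the domain.
#' @param field which checkpoint field to probe.
#' @return a tibble with columns `time`, `probe` (row index), the probe
#'   coordinates, and `u` (or the chosen field's value).
#' @export
probe_timeseries <- function(sim, points, field = c("u", "s_bolus", "p_blood")) {
  field <- match.arg(field)
  mesh <- sim$config$mesh
  points <- matrix(as.numeric(points), ncol = mesh$dim)
  if (any(points < -1e-12) ||
      any(sweep(points, 2, mesh$extents) > 1e-12)) {
    abort("probe point outside the domain", class = "thermo_input_error")
  }
  stride <- cumprod(c(1L, mesh$cells))[seq_len(mesh$dim)]
  idx <- sapply(seq_len(mesh$dim), function(k) {
    pmin(mesh$cells[k], pmax(1, ceiling(points[, k] / mesh$h[k])))
  })
  idx <- matrix(idx, nrow(points), mesh$dim)
  lin <- 1 + as.vector((idx - 1) %*% stride)

  rows <- lapply(sim$checkpoints, function(cp) {
    data.frame(time = cp$time,
               probe = seq_len(nrow(points)),
               value = cp[[field]][lin])
  })
  out <- do.call(rbind, rows)
  coords <- as.data.frame(points[out$probe, , drop = FALSE])
  names(coords) <- paste0("x", seq_len(mesh$dim))
  res <- cbind(out[, c("time", "probe")], coords)
  res[[field]] <- out$value
  as_tibble(res)
}
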