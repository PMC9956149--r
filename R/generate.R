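# Synthetic fluorescence-field generator.
#
# Fields are rendered as soft-edged disks (radial cosine falloff over the
# outer 2 px) on a Gaussian camera background. Transfected cells carry a
# diffuse intensity drawn around `cell_mean_intensity` (lognormal multiplier
# with mean 1); untransfected cells carry no fluorescence and are invisible
# in the fluorescence channel (they exist only in the ground-truth sidecar).
# Aggregate foci are hard-edged disks whose pixel intensity is the parent
# cell's diffuse intensity times `aggregate_intensity_multiplier`, always
# placed fully inside the parent cell body.

# Truncated radius draws: mean +/- 2.5 sd, floored at 3 px.
draw_radii <- function(n, radius) {
  r <- stats::rnorm(n, radius[1], radius[2])
  pmax(3, pmin(pmax(r, radius[1] - 2.5 * radius[2]),
               radius[1] + 2.5 * radius[2]))
}

# Random sequential placement of non-overlapping disks (gap >= 3 px between
# outer radii). Errors out after a bounded number of rejections.
place_cells <- function(config, radii, gap = 3, max_tries_per_cell = 400L) {
  n <- config$n_cells
  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  rows <- numeric(n); cols <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- max_tries_per_cell * max(n, 1L)
  while (placed < n) {
    if (tries >= max_tries)
      stop(sprintf(
        "placement failure: could only place %d of %d non-overlapping cells in a %dx%d frame",
        placed, n, nr, nc), call. = FALSE)
    tries <- tries + 1L
    R <- radii[placed + 1L]
    if (nr - 2 * (R + 2) < 1 || nc - 2 * (R + 2) < 1)
      stop("frame too small for the configured cell radius", call. = FALSE)
    y <- stats::runif(1, R + 2, nr - R - 1)
    x <- stats::runif(1, R + 2, nc - R - 1)
    if (placed > 0L) {
      i <- seq_len(placed)
      if (any((rows[i] - y)^2 + (cols[i] - x)^2 <
              (radii[i] + R + gap)^2)) next
    }
    placed <- placed + 1L
    rows[placed] <- y; cols[placed] <- x
  }
  data.frame(row = rows, col = cols)
}

# Radial soft-disk profile (1 inside R-2, cosine falloff to 0 at R).
disk_profile <- function(d, R) {
  f <- numeric(length(d))
  f[d <= R - 2] <- 1
  edge <- d > R - 2 & d < R
  f[edge] <- 0.5 * (1 + cos(pi * (d[edge] - (R - 2)) / 2))
  f
}

# Place k non-overlapping foci centers inside radius R - 2 - r_agg of the
# cell center; falls back to overlapping placement after bounded retries.
place_foci <- function(k, cy, cx, R, r_agg) {
  if (k == 0L) return(data.frame(row = numeric(0), col = numeric(0)))
  rmax <- max(R - 2 - r_agg, 0.5)
  ys <- numeric(k); xs <- numeric(k)
  for (i in seq_len(k)) {
    ok <- FALSE
    for (try in seq_len(100L)) {
      a <- stats::runif(1, 0, 2 * pi)
      rr <- rmax * sqrt(stats::runif(1))
      y <- cy + rr * sin(a); x <- cx + rr * cos(a)
      if (i == 1L ||
          all((ys[seq_len(i - 1L)] - y)^2 + (xs[seq_len(i - 1L)] - x)^2 >=
              (2 * r_agg + 1)^2)) {
        ok <- TRUE; break
      }
    }
    ys[i] <- y; xs[i] <- x
  }
  data.frame(row = ys, col = xs)
}

# Render cells + foci onto a background canvas. `cells` must have columns
# row, col, radius, intensity (0 = invisible); `foci` columns cell, row, col.
render_field <- function(config, cells, foci) {
  nr <- config$frame_shape[1]; nc <- config$frame_shape[2]
  px <- matrix(stats::rnorm(nr * nc, config$background_level,
                            config$background_noise_sd), nr, nc)
  r_agg <- config$aggregate_radius_px
  mult <- config$aggregate_intensity_multiplier
  for (i in seq_len(nrow(cells))) {
    I <- cells$intensity[i]
    if (I <= 0) next
    R <- cells$radius[i]
    cy <- cells$row[i]; cx <- cells$col[i]
    rr <- max(1L, floor(cy - R)):min(nr, ceiling(cy + R))
    cc <- max(1L, floor(cx - R)):min(nc, ceiling(cx + R))
    d <- sqrt(outer((rr - cy)^2, (cc - cx)^2, "+"))
    contrib <- I * disk_profile(d, R)
    if (nrow(foci) > 0L) {
      fi <- foci[foci$cell == i, , drop = FALSE]
      for (j in seq_len(nrow(fi))) {
        df <- sqrt(outer((rr - fi$row[j])^2, (cc - fi$col[j])^2, "+"))
        contrib[df <= r_agg] <- I * mult
      }
    }
    px[rr, cc] <- px[rr, cc] + contrib
  }
  pmax(px, 0)
}

# Evaluate the foci intensity lambda at a time point.
lambda_at <- function(lambda, time_h) {
  if (is.function(lambda)) {
    if (is.na(time_h))
      stop("`time_h` is required when the foci rate is a function of time",
           call. = FALSE)
    lambda(time_h)
  } else lambda
}

#' Generate one synthetic fluorescence frame with ground truth
#'
#' Draws a field of non-overlapping soft-edged cells, marks each as
#' transfected with probability `transfected_fraction`, gives transfected
#' cells a diffuse intensity around `cell_mean_intensity`, and scatters
#' `Poisson(lambda)` aggregate foci (bright hard-edged disks at
#' `aggregate_intensity_multiplier` times the cell's diffuse intensity)
#' fully inside each transfected cell. The returned frame carries a
#' `ground_truth` attribute with per-cell positions, radii, intensities,
#' transfection flags and true foci counts, plus the foci table.
#'
#' @param config An [generator_config()] object.
#' @param time_h Hours post-transfection (needed when the foci rate is a
#'   function of time).
#' @param condition,replicate,channel Frame metadata.
#' @param seed RNG seed (default `config$seed`). Identical config and seed
#'   give bit-identical frames.
#'
#' @return An [frame()] object with a `ground_truth` attribute
#'   (`list(cells = <data.frame>, foci = <data.frame>)`).
#' @export
generate_frame <- function(config, time_h = NA_real_, condition = "none",
                           replicate = 1L, channel = "RFP",
                           seed = config$seed) {
  stopifnot(inherits(config, "fq_config"))
  with_seed(seed, {
    n <- config$n_cells
    if (n == 0L) {
      px <- pmax(matrix(stats::rnorm(prod(config$frame_shape),
                                     config$background_level,
                                     config$background_noise_sd),
                        config$frame_shape[1], config$frame_shape[2]), 0)
      fr <- frame(px, time_h, condition, replicate, channel)
      attr(fr, "ground_truth") <- list(
        cells = data.frame(cell = integer(0), row = numeric(0),
                           col = numeric(0), radius = numeric(0),
                           transfected = logical(0), intensity = numeric(0),
                           n_foci = integer(0)),
        foci = data.frame(cell = integer(0), row = numeric(0),
                          col = numeric(0)))
      return(fr)
    }
    radii <- draw_radii(n, config$cell_radius_px)
    transfected <- stats::runif(n) < config$transfected_fraction
    sdl <- config$cell_intensity_sdlog
    intensity <- config$cell_mean_intensity *
      stats::rlnorm(n, -sdl^2 / 2, sdl) * transfected
    centers <- place_cells(config, radii)
    lam <- lambda_at(config$aggregates_per_cell_lambda, time_h)
    n_foci <- ifelse(transfected, stats::rpois(n, lam), 0L)
    foci <- do.call(rbind, lapply(seq_len(n), function(i) {
      f <- place_foci(n_foci[i], centers$row[i], centers$col[i], radii[i],
                      config$aggregate_radius_px)
      if (nrow(f) > 0L) cbind(cell = i, f) else NULL
    }))
    if (is.null(foci))
      foci <- data.frame(cell = integer(0), row = numeric(0),
                         col = numeric(0))
    cells <- data.frame(cell = seq_len(n), row = centers$row,
                        col = centers$col, radius = radii,
                        transfected = transfected, intensity = intensity,
                        n_foci = as.integer(n_foci))
    px <- render_field(config, cells, foci)
    fr <- frame(px, time_h, condition, replicate, channel)
    attr(fr, "ground_truth") <- list(cells = cells, foci = foci)
    fr
  })
}

#' Generate a synthetic time lapse with persistent cells and rupture events
#'
#' Cells are placed once and persist across frames. At each frame the number
#' of foci in each surviving transfected cell is drawn around the trajectory
#' value `lambda(t)`. Between consecutive frames each surviving transfected
#' cell ruptures with probability `rupture_rate`; a ruptured cell and its
#' foci disappear from all subsequent frames (the released fluorescence is
#' modelled as disappearance). Rupture times are logged in the ground truth.
#'
#' Randomness is split into fixed streams so that the ground truth does not
#' depend on whether frames are rendered. The stream seeds are the first
#' `3 + length(times)` integers returned by `sample.int(2^31 - 2)` under
#' `set.seed(seed)`: stream 1 draws the cell population, stream 2 the
#' rupture uniforms (one per cell and frame gap, cell index varying
#' fastest), stream 3 the per-frame foci counts (cell index fastest), and
#' streams 4, 5, ... the per-frame rendering noise and foci placement.
#'
#' @param config An [generator_config()] object.
#' @param times Strictly increasing vector of acquisition times (hours).
#' @param trajectory Optional foci-rate trajectory `lambda(t)`; overrides
#'   `config$aggregates_per_cell_lambda`.
#' @param rupture_rate Optional override of `config$rupture_rate`.
#' @param condition,replicate Metadata applied to every frame.
#' @param seed RNG seed (default `config$seed`).
#' @param render Render pixel frames (`TRUE`) or return ground truth only
#'   (`FALSE`, much faster; used for count-level simulation studies).
#'
#' @return List with `frames` (list of [frame()] objects, or `NULL` when
#'   `render = FALSE`), `times`, and `ground_truth`: `cells` (the initial
#'   population), `ruptures` (`cell`, `frame`, `time_h` of first absence),
#'   and `series` (per frame: `time_h`, `n_alive`, `n_foci`, and the true
#'   `aggregates_per_cell`).
#' @export
generate_timelapse <- function(config, times, trajectory = NULL,
                               rupture_rate = NULL, condition = "none",
                               replicate = 1L, seed = config$seed,
                               render = TRUE) {
  stopifnot(inherits(config, "fq_config"))
  if (length(times) == 0L) stop("`times` must be non-empty", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  lambda <- if (!is.null(trajectory)) trajectory
            else config$aggregates_per_cell_lambda
  rrate <- if (!is.null(rupture_rate)) rupture_rate else config$rupture_rate
  stopifnot_scalar_prob(rrate, "rupture_rate")
  n <- config$n_cells
  nt <- length(times)
  stream <- with_seed(seed, sample.int(2147483646L, 3L + nt))

  # Stream 1: static cell population.
  pop <- with_seed(stream[1L], {
    radii <- draw_radii(n, config$cell_radius_px)
    transfected <- stats::runif(n) < config$transfected_fraction
    sdl <- config$cell_intensity_sdlog
    intensity <- config$cell_mean_intensity *
      stats::rlnorm(n, -sdl^2 / 2, sdl) * transfected
    centers <- place_cells(config, radii)
    data.frame(cell = seq_len(n), row = centers$row, col = centers$col,
               radius = radii, transfected = transfected,
               intensity = intensity)
  })

  # Stream 2: rupture uniforms, one per (cell, frame gap).
  U <- with_seed(stream[2L],
                 matrix(stats::runif(n * max(nt - 1L, 0L)), nrow = n))
  rupture_gap <- rep(NA_integer_, n)  # gap after which the cell is gone
  if (nt > 1L && rrate > 0 && n > 0L) {
    for (i in seq_len(n)) {
      if (!pop$transfected[i]) next
      hit <- which(U[i, ] < rrate)
      if (length(hit) > 0L) rupture_gap[i] <- hit[1L]
    }
  }
  # alive[i, j]: cell i present in frame j.
  alive <- matrix(TRUE, nrow = max(n, 1L), ncol = nt)
  if (n > 0L) {
    for (i in seq_len(n))
      if (!is.na(rupture_gap[i])) alive[i, -seq_len(rupture_gap[i])] <- FALSE
  }

  # Stream 3: per-frame foci counts (drawn for all cells; used when alive).
  K <- with_seed(stream[3L], {
    k <- matrix(0L, nrow = max(n, 1L), ncol = nt)
    for (j in seq_len(nt))
      if (n > 0L)
        k[, j] <- stats::rpois(n, lambda_at(lambda, times[j]))
    k
  })

  live_tr <- function(j) n > 0L & pop$transfected & alive[seq_len(max(n, 1L)), j]
  series <- data.frame(
    frame = seq_len(nt),
    time_h = times,
    n_alive = vapply(seq_len(nt), function(j) sum(live_tr(j)), integer(1)),
    n_foci = vapply(seq_len(nt), function(j) sum(K[live_tr(j), j]),
                    integer(1)))
  series$aggregates_per_cell <-
    ifelse(series$n_alive > 0, series$n_foci / series$n_alive, NA_real_)

  rupt <- which(!is.na(rupture_gap))
  ruptures <- data.frame(cell = rupt,
                         frame = rupture_gap[rupt] + 1L,
                         time_h = times[rupture_gap[rupt] + 1L])

  frames <- NULL
  if (render) {
    frames <- vector("list", nt)
    for (j in seq_len(nt)) {
      frames[[j]] <- with_seed(stream[3L + j], {
        cells_j <- pop
        cells_j$intensity[!alive[seq_len(max(n, 1L)), j]] <- 0
        present <- which(live_tr(j) & K[, j] > 0L)
        foci <- do.call(rbind, lapply(present, function(i) {
          f <- place_foci(K[i, j], pop$row[i], pop$col[i], pop$radius[i],
                          config$aggregate_radius_px)
          cbind(cell = i, f)
        }))
        if (is.null(foci))
          foci <- data.frame(cell = integer(0), row = numeric(0),
                             col = numeric(0))
        px <- render_field(config, cells_j, foci)
        fr <- frame(px, times[j], condition, replicate)
        attr(fr, "ground_truth") <- list(
          cells = cells_j[alive[seq_len(max(n, 1L)), j], , drop = FALSE],
          n_foci = series$n_foci[j])
        fr
      })
    }
  }
  list(frames = frames, times = times,
       ground_truth = list(cells = pop, ruptures = ruptures,
                           series = series))
}
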