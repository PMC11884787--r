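## Synthetic two-hemisphere retinotopic cortex and movie-like recordings.
## The generator provides the ground truth (maps, lines, loadings) that the
## homotopy, ICA and SRM analyses are validated against.

# area layout, dorsal to ventral rows; heights are deliberately unequal so a
# half-grid roll cannot map area boundaries onto area boundaries
AREA_ORDER <- c("V3A-B", "V3d", "V2d", "V1d", "V1v", "V2v", "V3v", "hV4")
AREA_STREAM <- c("dorsal", "dorsal", "dorsal", "dorsal",
                 "ventral", "ventral", "ventral", "ventral")
AREA_LEVEL <- c(4L, 3L, 2L, 1L, 1L, 2L, 3L, 4L)
AREA_HEIGHTS <- c(5L, 4L, 4L, 3L, 3L, 4L, 4L, 5L)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort. Defaults describe the study
#' conditions emulated throughout: 15 participants, a 32 x 32 unit grid per
#' hemisphere, two movies of 150 timepoints at TR = 2 s, 10 shared latent
#' features, retinotopic maps carrying half the spatial loading variance,
#' signal-to-noise ratio 1, a mild motion confound, and a 2-TR (4 s)
#' hemodynamic shift.
#'
#' @param n_participants cohort size.
#' @param grid_height,grid_width units per hemisphere grid; `grid_height`
#'   must admit the 8-area layout (>= 26).
#' @param n_timepoints timepoints per movie.
#' @param n_movies movies per participant.
#' @param tr repetition time, seconds.
#' @param k_latent number of shared latent stimulus features.
#' @param map_coupling fraction of spatial loading variance carried by the
#'   ground-truth maps, in `[0, 1]`.
#' @param snr ratio of shared-signal to noise standard deviation (> 0).
#' @param motion_amplitude motion confound amplitude relative to signal sd.
#' @param hemodynamic_shift_trs integer hemodynamic delay in TRs.
#' @param structure `"full"` for the retinotopically organized cohort;
#'   `"smooth_noise"` for a null cohort whose spatial loadings are mirrored
#'   smooth random fields with no area or map alignment (spatially smooth,
#'   bilaterally symmetric, anatomically unstructured).
#' @param seed master seed; all stage and participant seeds are derived from
#'   it via [child_seed()].
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 15L, grid_height = 32L,
                       grid_width = 32L, n_timepoints = 150L, n_movies = 2L,
                       tr = 2, k_latent = 10L, map_coupling = 0.5, snr = 1,
                       motion_amplitude = 0.3, hemodynamic_shift_trs = 2L,
                       structure = c("full", "smooth_noise"), seed = 42L) {
  structure <- match.arg(structure)
  cfg <- list(n_participants = as.integer(n_participants),
              grid_height = as.integer(grid_height),
              grid_width = as.integer(grid_width),
              n_timepoints = as.integer(n_timepoints),
              n_movies = as.integer(n_movies), tr = as.numeric(tr),
              k_latent = as.integer(k_latent),
              map_coupling = as.numeric(map_coupling),
              snr = as.numeric(snr),
              motion_amplitude = as.numeric(motion_amplitude),
              hemodynamic_shift_trs = as.integer(hemodynamic_shift_trs),
              structure = structure, seed = as.integer(seed))
  if (any(unlist(cfg[c("n_participants", "grid_height", "grid_width",
                       "n_timepoints", "n_movies", "k_latent")]) < 1L))
    stop_contract("all counts must be >= 1")
  if (cfg$map_coupling < 0 || cfg$map_coupling > 1)
    stop_contract("map_coupling must be in [0, 1]")
  if (cfg$snr <= 0) stop_contract("snr must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

area_row_heights <- function(grid_height) {
  extra <- grid_height - sum(AREA_HEIGHTS)
  if (extra < 0) stop_contract("grid_height too small for the 8-area layout (need >= 32)")
  h <- AREA_HEIGHTS
  # distribute surplus rows to the outermost areas, keeping heights unequal
  i <- 1L
  while (extra > 0L) {
    slot <- c(1L, 8L, 2L, 7L, 3L, 6L, 4L, 5L)[(i - 1L) %% 8L + 1L]
    h[slot] <- h[slot] + 1L
    extra <- extra - 1L
    i <- i + 1L
  }
  h
}

#' Build a labeled two-hemisphere cortical sheet
#'
#' Lays out the 8 retinotopic areas (V1v/d, V2v/d, V3v/d, hV4, V3A-B) as
#' contiguous row bands on a rectangular grid per hemisphere, mirrored across
#' hemispheres. Eccentricity runs 0 (foveal) to 1 (peripheral) along grid
#' columns; area identity changes along rows, dorsal areas at the top. Polar
#' angle is assigned so that each area occupies one quarter-cycle band,
#' placing the horizontal/vertical meridian representation at area
#' boundaries. Fully deterministic given the config.
#'
#' @param config a [sim_config()].
#' @return A `cortical_sheet` data frame with one row per unit: `unit`,
#'   `hemi`, `row`, `col`, `area`, `stream`, `level`, `ecc`, `polar`.
#' @export
build_cortical_sheet <- function(config = sim_config()) {
  H <- config$grid_height; W <- config$grid_width
  if (H < 16L || W < 16L) stop_contract("grid must be at least 16 x 16")
  heights <- area_row_heights(H)
  area_of_row <- rep(seq_along(AREA_ORDER), heights)
  one_hemi <- function(hemi) {
    row <- rep(seq_len(H), each = W)
    col <- rep(seq_len(W), times = H)
    ai <- area_of_row[row]
    # fractional position within the area band, in (0, 1)
    row0 <- cumsum(c(0L, heights))[ai]
    f <- (row - row0 - 0.5) / heights[ai]
    data.frame(hemi = hemi, row = row, col = col,
               area = AREA_ORDER[ai], stream = AREA_STREAM[ai],
               level = AREA_LEVEL[ai],
               ecc = (col - 1) / (W - 1),
               polar = (pi / 2) * (ai - 1) + 0.9 * (pi / 4) * (f - 0.5),
               stringsAsFactors = FALSE)
  }
  sheet <- rbind(one_hemi("left"), one_hemi("right"))
  sheet$unit <- seq_len(nrow(sheet))
  sheet <- sheet[, c("unit", "hemi", "row", "col", "area", "stream",
                     "level", "ecc", "polar")]
  attr(sheet, "grid_height") <- H
  attr(sheet, "grid_width") <- W
  attr(sheet, "area_heights") <- heights
  class(sheet) <- c("cortical_sheet", "data.frame")
  sheet
}

#' Index of the homotopic partner of each unit
#'
#' The two hemispheres are laid out identically, so the partner of unit `u`
#' in one hemisphere is the unit at the same grid position in the other.
#' @param sheet a `cortical_sheet`.
#' @return Integer vector of partner unit indices.
#' @export
homotopic_partner <- function(sheet) {
  n <- nrow(sheet) / 2L
  c(seq_len(n) + n, seq_len(n))
}

# smooth a H x W matrix with a small separable box kernel, replicate padding,
# optionally restricted to row bands (areas) so boundaries stay sharp
smooth_grid <- function(mat, width = 3L, bands = NULL) {
  sm1 <- function(v) {
    half <- width %/% 2L
    n <- length(v)
    vp <- c(rep(v[1], half), v, rep(v[n], half))
    as.numeric(stats::filter(vp, rep(1 / width, width), sides = 2))[half + seq_len(n)]
  }
  smooth_block <- function(m) {
    m <- apply(m, 2, sm1)       # along rows within band
    t(apply(m, 1, sm1))         # along eccentricity
  }
  if (is.null(bands)) return(smooth_block(mat))
  out <- mat
  for (b in unique(bands)) {
    rows <- which(bands == b)
    blk <- mat[rows, , drop = FALSE]
    if (length(rows) == 1L) out[rows, ] <- sm1(blk[1, ])
    else out[rows, ] <- smooth_block(blk)
  }
  out
}

sheet_matrix <- function(sheet, values, hemi) {
  H <- attr(sheet, "grid_height"); W <- attr(sheet, "grid_width")
  sel <- sheet$hemi == hemi
  m <- matrix(NA_real_, H, W)
  m[cbind(sheet$row[sel], sheet$col[sel])] <- values[sel]
  m
}

matrix_to_sheet <- function(sheet, mat_left, mat_right) {
  v <- numeric(nrow(sheet))
  sel <- sheet$hemi == "left"
  v[sel] <- mat_left[cbind(sheet$row[sel], sheet$col[sel])]
  v[!sel] <- mat_right[cbind(sheet$row[!sel], sheet$col[!sel])]
  v
}

#' Generate ground-truth retinotopic maps on a sheet
#'
#' The spatial-frequency map is a strictly decreasing function of
#' eccentricity (`cos(pi * ecc)`): high spatial frequency preference at the
#' fovea, low at the periphery. The meridian map is `cos(2 * polar)`, which
#' by the sheet's polar-angle layout alternates sign at every area boundary.
#' Both maps are lightly smoothed within area bands, which preserves the
#' monotone-gradient and sign-alternation invariants and the exact mirror
#' symmetry between hemispheres.
#'
#' @param sheet a `cortical_sheet`.
#' @return A `ground_truth_maps` list with numeric per-unit vectors
#'   `spatial_frequency` and `meridian`.
#' @export
generate_ground_truth_maps <- function(sheet) {
  sf_raw <- cos(pi * sheet$ecc)
  mer_raw <- cos(2 * sheet$polar)
  heights <- attr(sheet, "area_heights")
  bands <- rep(seq_along(heights), heights)
  smooth_map <- function(v) {
    l <- smooth_grid(sheet_matrix(sheet, v, "left"), bands = bands)
    r <- smooth_grid(sheet_matrix(sheet, v, "right"), bands = bands)
    matrix_to_sheet(sheet, l, r)
  }
  maps <- list(spatial_frequency = smooth_map(sf_raw),
               meridian = smooth_map(mer_raw))
  class(maps) <- "ground_truth_maps"
  maps
}

#' Trace gradient lines on a cortical sheet
#'
#' Parallel lines run foveal to peripheral along every row of every area band
#' (>= 3 per area per hemisphere). Perpendicular lines run across area
#' boundaries at fixed eccentricity: per hemisphere, a dorsal span
#' (V1d -> V3A-B) and a ventral span (V1v -> hV4) at each of two
#' eccentricities, each crossing 3 boundaries. Deterministic.
#'
#' @param sheet a `cortical_sheet`.
#' @param orientation `"parallel"` or `"perpendicular"`.
#' @return A list of `gradient_line` lists: `units` (ordered unit indices),
#'   `orientation`, `hemi`, `area` (parallel) or `areas` (perpendicular).
#' @export
trace_gradient_lines <- function(sheet, orientation = c("parallel", "perpendicular")) {
  orientation <- match.arg(orientation)
  W <- attr(sheet, "grid_width")
  lines <- list()
  for (hemi in c("left", "right")) {
    hs <- sheet[sheet$hemi == hemi, ]
    if (orientation == "parallel") {
      for (area in AREA_ORDER) {
        rows <- sort(unique(hs$row[hs$area == area]))
        for (r in rows) {
          seg <- hs[hs$row == r, ]
          seg <- seg[order(seg$col), ]
          lines[[length(lines) + 1L]] <- structure(
            list(units = seg$unit, orientation = "parallel",
                 hemi = hemi, area = area), class = "gradient_line")
        }
      }
    } else {
      spans <- list(dorsal = c("V1d", "V2d", "V3d", "V3A-B"),
                    ventral = c("V1v", "V2v", "V3v", "hV4"))
      for (cc in c(round(W / 3), round(2 * W / 3))) {
        for (sp in names(spans)) {
          seg <- hs[hs$col == cc & hs$area %in% spans[[sp]], ]
          # order from V1 outward along the hierarchy
          seg <- if (sp == "dorsal") seg[order(-seg$row), ] else seg[order(seg$row), ]
          lines[[length(lines) + 1L]] <- structure(
            list(units = seg$unit, orientation = "perpendicular",
                 hemi = hemi, areas = unique(seg$area),
                 area_of_pos = seg$area), class = "gradient_line")
        }
      }
    }
  }
  lines
}

# smooth standardized Gaussian random field; mirrored = identical values on
# the two hemisphere grids (used for the motion pattern), otherwise the
# hemispheres are drawn independently (participant-specific idiosyncrasy)
smooth_field <- function(sheet, smooth_width = 5L, mirrored = FALSE) {
  H <- attr(sheet, "grid_height"); W <- attr(sheet, "grid_width")
  one <- function() {
    f <- smooth_grid(matrix(stats::rnorm(H * W), H, W), width = smooth_width)
    (f - mean(f)) / stats::sd(f)
  }
  l <- one()
  matrix_to_sheet(sheet, l, if (mirrored) l else one())
}

# shared latent stimulus drive: smooth AR(2) low-passed draws, then
# balanced-parity construction. Each latent is an equal mix of one vector
# from an orthonormalized set of time-even components and one from an
# orthonormalized set of time-odd components (parity about the movie
# midpoint), so the time-reversed latent subspace is exactly orthogonal to
# the latent subspace: a reversed recording shares no stimulus-locked
# structure with the model, the property the flipped baseline tests. Long
# broadband recordings have this property approximately; the construction
# enforces it exactly at desk scale.
make_shared_latents <- function(k, t_len, shift = 0L, lowpass = 0.15) {
  draw <- function() {
    # the hemodynamic delay drops the first `shift` stimulus samples
    # (circular-free shift with cropping), alongside the AR burn-in
    x <- as.numeric(stats::filter(stats::rnorm(t_len + 40L + shift),
                                  c(1.2, -0.36),
                                  method = "recursive"))[-seq_len(40L + shift)]
    fx <- stats::fft(x)
    keep <- max(2L * k, ceiling(lowpass * t_len))
    idx <- seq_along(fx) - 1L
    fx[idx > keep & idx < t_len - keep] <- 0
    x <- Re(stats::fft(fx, inverse = TRUE)) / t_len
    x - mean(x)
  }
  raw <- t(vapply(seq_len(k), function(j) draw(), numeric(t_len)))
  evens <- (raw + raw[, rev(seq_len(t_len))]) / 2
  odds <- (raw - raw[, rev(seq_len(t_len))]) / 2
  qe <- qr.Q(qr(t(evens)))[, seq_len(k), drop = FALSE]
  qo <- qr.Q(qr(t(odds)))[, seq_len(k), drop = FALSE]
  s <- t(qe + qo) / sqrt(2)
  s / apply(s, 1, stats::sd)
}

# per-area latent signatures with an exact target Gram matrix: homotopic
# pairs share a signature exactly (mirror construction); within stream,
# similarity decays with hierarchy distance; same-level cross-stream pairs
# sit between adjacent and far-distal. With k >= 8 the Gram structure is
# realized exactly (signatures = chol(G)' Q with orthonormal-row Q), so the
# expected area-mean correlation ordering is built in, not sampled.
area_signature_gram <- function() {
  within <- c(1, 0.85, 0.70, 0.60) # hierarchy distance 0..3
  n <- length(AREA_ORDER)
  g <- matrix(0, n, n, dimnames = list(AREA_ORDER, AREA_ORDER))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d <- abs(AREA_LEVEL[i] - AREA_LEVEL[j]) + 1L
    g[i, j] <- if (AREA_STREAM[i] == AREA_STREAM[j]) within[d]
    else if (d == 1L) 0.62 else 0.75 * within[d]
  }
  g
}

make_area_signatures <- function(k) {
  g <- area_signature_gram()
  n <- nrow(g)
  if (k < n) { # low-k fallback: nearest realizable Gram in k dimensions
    eg <- eigen(g, symmetric = TRUE)
    u <- eg$vectors[, seq_len(k), drop = FALSE] %*%
      diag(sqrt(pmax(eg$values[seq_len(k)], 0)), k)
    q <- qr.Q(qr(matrix(stats::rnorm(k * k), k)))
    sig <- u %*% q
  } else {
    q <- t(qr.Q(qr(matrix(stats::rnorm(k * n), k, n)))) # n x k orthonormal rows
    sig <- t(chol(g)) %*% q
  }
  dimnames(sig) <- list(AREA_ORDER, NULL)
  sig
}

#' Simulate movie-like recordings for a cohort
#'
#' Every participant watching a movie shares one smooth low-rank latent time
#' course. Per-participant spatial loadings mix (i) area signatures shared
#' across hemispheres — homotopic areas load identically, adjacent areas
#' within a stream load similarly, (ii) the two ground-truth retinotopic maps
#' on two dedicated latent features, scaled by `map_coupling`, and (iii)
#' seeded participant-specific smooth patterns. Unit noise is added at the
#' configured SNR, a motion confound (spiky time course times a global
#' spatial pattern) at `motion_amplitude`, the signal is delayed by the
#' hemodynamic shift, and every unit is z-scored within movie.
#'
#' @param sheet a `cortical_sheet`.
#' @param maps `ground_truth_maps` for the cohort.
#' @param config a [sim_config()].
#' @return List of `participant_recording`s: `data` (units x time, z-scored
#'   per movie), `movie_bounds`, `motion`, `tr`, `seed`, `loading`
#'   (the generating units x k loading matrix, kept for oracle tests),
#'   `participant`.
#' @export
simulate_movie_responses <- function(sheet, maps, config = sim_config()) {
  if (config$snr <= 0) stop_contract("snr must be > 0")
  n_units <- nrow(sheet)
  k <- config$k_latent
  t_movie <- config$n_timepoints
  shift <- config$hemodynamic_shift_trs
  master <- config$seed

  sig <- with_seed(child_seed(master, 1L), make_area_signatures(k))
  latents <- lapply(seq_len(config$n_movies), function(m)
    with_seed(child_seed(master, 100L + m),
              make_shared_latents(k, t_movie, shift = shift)))

  norm_sd <- function(v) if (stats::sd(v) > 0) v / stats::sd(v) else v
  # one global scale for the signature block so its Gram structure survives
  base_patterns <- sig[sheet$area, , drop = FALSE]
  base_patterns <- base_patterns / mean(apply(base_patterns, 2, stats::sd))
  dimnames(base_patterns) <- NULL
  map_patterns <- matrix(0, n_units, k)
  if (k >= 1L) map_patterns[, 1] <- norm_sd(maps$spatial_frequency)
  if (k >= 2L) map_patterns[, 2] <- norm_sd(maps$meridian)

  if (identical(config$structure, "smooth_noise")) {
    w_map <- 0; w_area <- 0; w_ind <- 1
  } else {
    w_map <- sqrt(config$map_coupling)
    w_area <- sqrt(0.7 * (1 - config$map_coupling))
    w_ind <- sqrt(0.3 * (1 - config$map_coupling))
  }

  lapply(seq_len(config$n_participants), function(i) {
    pseed <- child_seed(master, 1000L + i)
    with_seed(pseed, {
      indiv <- vapply(seq_len(k), function(j)
        smooth_field(sheet,
                     mirrored = identical(config$structure, "smooth_noise")),
        numeric(n_units))
      loading <- w_area * base_patterns + w_map * map_patterns + w_ind * indiv

      blocks <- vector("list", config$n_movies)
      motion_all <- numeric(0)
      bounds <- vector("list", config$n_movies)
      t0 <- 0L
      for (m in seq_len(config$n_movies)) {
        signal <- loading %*% latents[[m]]
        sd_sig <- stats::sd(as.numeric(signal))
        # single-unit noise dominates the shared signal, as in fMRI voxels;
        # snr is calibrated at the area-mean level: averaging ~130 units
        # recovers a factor sqrt(130) ~ 11, so area-level signal-to-noise
        # is ~2.3 * snr while per-unit signal-to-noise is snr / 5
        noise <- matrix(stats::rnorm(n_units * t_movie,
                                     sd = 5 * sd_sig / config$snr),
                        n_units, t_movie)
        # motion transients are fast and spiky, unlike the low-passed
        # stimulus drive, so the regressor is nearly orthogonal to it
        mot <- as.numeric(stats::filter(stats::rnorm(t_movie), 0.2,
                                        method = "recursive"))
        spikes <- stats::rbinom(t_movie, 1, 0.08) * stats::rexp(t_movie, 1 / 3)
        mot <- norm_sd(mot + spikes)
        # near-global artifact pattern: positive everywhere, mean 1, mild
        # spatial variation, so the confound inflates correlations without
        # dominating any single unit's variance
        mp <- abs(smooth_field(sheet, mirrored = TRUE)) + 4
        mot_pattern <- mp / mean(mp)
        x <- signal + noise +
          config$motion_amplitude * sd_sig * outer(mot_pattern, mot)
        blocks[[m]] <- zscore_rows(x)
        motion_all <- c(motion_all, mot)
        bounds[[m]] <- c(start = t0 + 1L, end = t0 + t_movie)
        t0 <- t0 + t_movie
      }
      structure(list(data = do.call(cbind, blocks), movie_bounds = bounds,
                     motion = motion_all, tr = config$tr, seed = pseed,
                     loading = loading, participant = i),
                class = "participant_recording")
    })
  })
}

#' Displace ground-truth maps by a smooth spatial warp
#'
#' Emulates between-participant anatomical misalignment for the
#' anatomical-average baseline: unit values are resampled through a seeded
#' smooth displacement field whose RMS magnitude is `jitter_scale` grid
#' units. `jitter_scale = 0` is the identity.
#'
#' @param maps `ground_truth_maps`.
#' @param sheet the `cortical_sheet` the maps live on.
#' @param jitter_scale RMS displacement in grid units (>= 0).
#' @param seed integer seed.
#' @return Jittered `ground_truth_maps`.
#' @export
jitter_maps <- function(maps, sheet, jitter_scale, seed = 1L) {
  if (jitter_scale < 0) stop_contract("jitter_scale must be >= 0")
  if (jitter_scale == 0) return(maps)
  H <- attr(sheet, "grid_height"); W <- attr(sheet, "grid_width")
  warp_field <- function() {
    f <- smooth_grid(matrix(stats::rnorm(H * W), H, W), width = 7L)
    f / sqrt(mean(f^2)) * jitter_scale
  }
  bilinear <- function(m, rr, cc) {
    rr <- pmin(pmax(rr, 1), nrow(m)); cc <- pmin(pmax(cc, 1), ncol(m))
    r0 <- floor(rr); c0 <- floor(cc)
    r1 <- pmin(r0 + 1, nrow(m)); c1 <- pmin(c0 + 1, ncol(m))
    fr <- rr - r0; fc <- cc - c0
    m[cbind(r0, c0)] * (1 - fr) * (1 - fc) + m[cbind(r1, c0)] * fr * (1 - fc) +
      m[cbind(r0, c1)] * (1 - fr) * fc + m[cbind(r1, c1)] * fr * fc
  }
  with_seed(seed, {
    dxl <- warp_field(); dyl <- warp_field()
    dxr <- warp_field(); dyr <- warp_field()
    warp_one <- function(v) {
      grid <- expand.grid(row = seq_len(H), col = seq_len(W))
      l <- sheet_matrix(sheet, v, "left"); r <- sheet_matrix(sheet, v, "right")
      lw <- matrix(bilinear(l, grid$row + dyl[cbind(grid$row, grid$col)],
                            grid$col + dxl[cbind(grid$row, grid$col)]), H, W)
      rw <- matrix(bilinear(r, grid$row + dyr[cbind(grid$row, grid$col)],
                            grid$col + dxr[cbind(grid$row, grid$col)]), H, W)
      matrix_to_sheet(sheet, lw, rw)
    }
    out <- list(spatial_frequency = warp_one(maps$spatial_frequency),
                meridian = warp_one(maps$meridian))
    class(out) <- "ground_truth_maps"
    out
  })
}
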