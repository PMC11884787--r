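## Spatial ICA map discovery and validation: FastICA decomposition (units are
## samples, timepoints are mixtures), gradient-profile scoring against ground
## truth, percentile ranking among all components, a programmatic surrogate
## for the human candidate selection, and the rolled-component null.

sym_decorrelate <- function(w) {
  e <- eigen(w %*% t(w), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), nrow(w)) %*%
    t(e$vectors) %*% w
}

#' Spatial independent component analysis of a recording
#'
#' PCA-whitens the timepoint dimension to `n_components` and runs fixed-point
#' ICA (logcosh contrast, symmetric decorrelation) treating cortical units as
#' samples, so the recovered sources are spatial maps with associated time
#' courses. `n_components = "auto"` keeps the smallest rank retaining 90% of
#' variance, bounded to `[20, 170]`. Deterministic given `seed`; if the fixed
#' point has not converged after `max_iter` sweeps the best iterate is
#' returned with `converged = FALSE`.
#'
#' @param recording a `participant_recording` (or any list with a units x
#'   time `data` matrix).
#' @param n_components integer, or `"auto"`.
#' @param seed integer seed for the unmixing initialization.
#' @param max_iter,tol fixed-point iteration cap and convergence tolerance.
#' @return A `component_set`: `maps` (units x n_components, sign-arbitrary),
#'   `timecourses` (n_components x T), `explained_variance` (decreasing),
#'   `converged`, `seed`.
#' @export
spatial_ica <- function(recording, n_components = "auto", seed = 1L,
                        max_iter = 500L, tol = 1e-6) {
  x <- recording$data
  v <- nrow(x); t_len <- ncol(x)
  d <- t(x)                       # T x V, rows are timepoint "mixtures"
  d <- d - rowMeans(d)
  cov_t <- (d %*% t(d)) / v
  eg <- eigen(cov_t, symmetric = TRUE)
  if (identical(n_components, "auto")) {
    cum <- cumsum(pmax(eg$values, 0)) / sum(pmax(eg$values, 0))
    q <- which(cum >= 0.9)[1]
    q <- max(20L, min(170L, q, t_len - 1L, v - 1L))
  } else q <- as.integer(n_components)
  if (q >= t_len || q >= v)
    stop_contract("n_components must be below both T and the unit count")
  whit <- diag(1 / sqrt(eg$values[seq_len(q)]), q) %*% t(eg$vectors[, seq_len(q)])
  z <- whit %*% d                 # q x V, rows uncorrelated, unit variance

  w <- with_seed(seed, matrix(stats::rnorm(q * q), q, q))
  w <- sym_decorrelate(w)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    w_new <- (g %*% t(z)) / v - diag(gp, q) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(1 - abs(diag(w_new %*% t(w)))))
    w <- w_new
    if (delta < tol) { converged <- TRUE; break }
  }
  s <- w %*% z                    # q x V spatial sources, unit variance
  a_mix <- d %*% t(s) / v         # T x q mixing (time courses)
  ev <- colMeans(a_mix^2)
  ord <- order(ev, decreasing = TRUE)
  structure(list(maps = t(s)[, ord, drop = FALSE],
                 timecourses = t(a_mix)[ord, , drop = FALSE],
                 explained_variance = ev[ord],
                 converged = converged, seed = as.integer(seed)),
            class = "component_set")
}

#' Average a map's intensity along a set of gradient lines
#'
#' Reads the per-unit map values along each line in order and averages
#' position-wise across lines. All lines in the set must have equal length.
#'
#' @param map_values numeric per-unit vector.
#' @param lines list of `gradient_line`s.
#' @return Numeric profile (one value per line position) with an
#'   `orientation` attribute.
#' @export
sample_gradient_profile <- function(map_values, lines) {
  if (length(lines) == 0L) stop_contract("need at least one line")
  lens <- vapply(lines, function(l) length(l$units), integer(1))
  if (length(unique(lens)) != 1L)
    stop_contract("lines in a profile set must have equal length")
  idx <- vapply(lines, function(l) l$units, integer(lens[1]))
  if (any(idx < 1L) || any(idx > length(map_values)))
    stop_contract("line indexes out of range")
  prof <- rowMeans(matrix(map_values[idx], nrow = lens[1]))
  attr(prof, "orientation") <- lines[[1]]$orientation
  prof
}

#' Gradient correlation of a component map with a ground-truth map
#'
#' Correlates the two maps' gradient-line profiles. With `absolute = TRUE`
#' the absolute correlation is returned, appropriate for ICA components
#' whose sign is arbitrary; SRM predictions are scored signed.
#'
#' @param component_map,truth_map per-unit numeric vectors.
#' @param lines the gradient lines to profile along.
#' @param absolute take the absolute value (default `TRUE`).
#' @return Correlation value.
#' @export
score_component <- function(component_map, truth_map, lines, absolute = TRUE) {
  pc <- sample_gradient_profile(component_map, lines)
  pt <- sample_gradient_profile(truth_map, lines)
  r <- pearson_corr(pc, pt)
  if (absolute) abs(r) else r
}

#' Percentile rank of selected components among all components
#'
#' Ranks components by score (rank 1 = best, ties share the mean rank) and
#' converts to a percentile, `100 * (N - rank) / (N - 1)`, so the best
#' possible component scores 100, the worst 0, and chance averages 50.
#' Multiple selections are averaged.
#'
#' @param all_scores numeric scores for every component.
#' @param selected indices of the selected component(s).
#' @return Mean percentile of the selection, or `NA` if empty.
#' @export
rank_component_percentile <- function(all_scores, selected) {
  n <- length(all_scores)
  if (n < 2L) stop_contract("need at least 2 components to rank")
  if (length(selected) == 0L) return(NA_real_)
  if (any(selected < 1L | selected > n)) stop_contract("selected out of range")
  rk <- rank(-all_scores, ties.method = "average")
  mean(100 * (n - rk[selected]) / (n - 1))
}

#' Default thresholds for programmatic candidate selection
#' @return Named list of thresholds used by [auto_select_candidates()].
#' @export
default_select_thresholds <- function() {
  list(occipital_min = 0.5,   # energy fraction inside labeled visual cortex
       symmetry_min = 0.5,    # left/right mirror correlation
       monotonicity_min = 0.85, # Spearman |rho| of parallel profile vs ecc
       alternation_min = 0.8,  # fraction of boundaries with a sign change
       strength_min = 0.2,     # profile amplitude relative to map spread
       gradualness_min = 0.68) # fraction of profile steps in one direction
}

# criteria are computed on a lightly smoothed copy of the map: visual
# inspection judges symmetry and gradients at pattern scale, not at
# single-unit noise scale
smooth_map_for_inspection <- function(map_values, sheet, width = 5L) {
  l <- smooth_grid(sheet_matrix(sheet, map_values, "left"), width = width)
  r <- smooth_grid(sheet_matrix(sheet, map_values, "right"), width = width)
  matrix_to_sheet(sheet, l, r)
}

component_criteria <- function(map_values, sheet, par_lines, perp_lines) {
  map_values <- smooth_map_for_inspection(map_values, sheet)
  partner <- homotopic_partner(sheet)
  left <- which(sheet$hemi == "left")
  occ <- 1 # the whole synthetic sheet is labeled visual cortex
  sym <- tryCatch(pearson_corr(map_values[left], map_values[partner[left]]),
                  error = function(e) 0)
  map_sd <- stats::sd(map_values)
  prof <- sample_gradient_profile(map_values, par_lines)
  mono <- tryCatch(abs(stats::cor(prof, seq_along(prof), method = "spearman")),
                   error = function(e) 0)
  if (!is.finite(mono)) mono <- 0
  # rank statistics are scale-free, so a near-flat drifting profile would
  # count as a gradient; require the profile to carry real amplitude
  mono_strength <- stats::sd(prof) / map_sd
  # a retinotopic gradient is continuous: successive profile steps share one
  # sign, unlike an ordered staircase of discrete plateaus
  dsign <- sign(diff(as.numeric(prof)))
  gradualness <- if (length(dsign)) max(mean(dsign > 0), mean(dsign < 0)) else 0
  # average profiles across lines sharing an area sequence (the two
  # eccentricities and hemispheres of each span) before counting the
  # fraction of area boundaries with a sign change
  spans <- split(perp_lines,
                 vapply(perp_lines, function(l) paste(l$areas, collapse = ">"),
                        character(1)))
  alt_one <- function(lines_set) {
    prof <- sample_gradient_profile(map_values, lines_set)
    area_seq <- factor(lines_set[[1]]$area_of_pos,
                       levels = unique(lines_set[[1]]$area_of_pos))
    means <- tapply(as.numeric(prof), area_seq, mean)
    if (length(means) < 2L) return(c(0, 0))
    c(mean(diff(sign(means)) != 0), mean(abs(means)) / map_sd)
  }
  alts <- vapply(spans, alt_one, numeric(2))
  c(occipital = occ, symmetry = sym, monotonicity = mono,
    alternation = mean(alts[1, ]), mono_strength = mono_strength,
    alt_strength = mean(alts[2, ]), gradualness = gradualness)
}

#' Programmatic selection of retinotopic-looking components
#'
#' A deterministic surrogate for visual inspection: each component map is
#' scored on (i) energy fraction in labeled visual cortex, (ii) left/right
#' mirror-symmetry correlation, (iii) monotonicity of its foveal-peripheral
#' profile (Spearman |rho| along parallel lines), and (iv) the fraction of
#' area boundaries at which its perpendicular profile changes sign. A
#' spatial-frequency candidate passes (i) + (ii) + (iii); a meridian
#' candidate passes (i) + (ii) + (iv). Selection never consults the ground
#' truth.
#'
#' @param components a `component_set` (or a units x n matrix of maps).
#' @param sheet the `cortical_sheet`.
#' @param thresholds see [default_select_thresholds()].
#' @return List: `sf` and `meridian` selected index vectors, and `scores`
#'   (one row per component with the four criterion values).
#' @export
auto_select_candidates <- function(components, sheet,
                                   thresholds = default_select_thresholds()) {
  maps <- if (is.matrix(components)) components else components$maps
  par_lines <- trace_gradient_lines(sheet, "parallel")
  perp_lines <- trace_gradient_lines(sheet, "perpendicular")
  sc <- t(vapply(seq_len(ncol(maps)), function(j)
    component_criteria(maps[, j], sheet, par_lines, perp_lines), numeric(7)))
  colnames(sc) <- c("occipital", "symmetry", "monotonicity", "alternation",
                    "mono_strength", "alt_strength", "gradualness")
  smin <- thresholds$strength_min %||% 0
  gmin <- thresholds$gradualness_min %||% 0
  base_ok <- sc[, "occipital"] >= thresholds$occipital_min &
    sc[, "symmetry"] >= thresholds$symmetry_min
  sf_sel <- which(base_ok & sc[, "monotonicity"] >= thresholds$monotonicity_min &
                    sc[, "mono_strength"] >= smin &
                    sc[, "gradualness"] >= gmin)
  mer_sel <- which(base_ok & sc[, "alternation"] >= thresholds$alternation_min &
                     sc[, "alt_strength"] >= smin)
  list(sf = sf_sel, meridian = mer_sel, scores = as.data.frame(sc))
}

#' Roll a component map across the cortical sheet
#'
#' Produces a smoothness-preserving value permutation that misaligns the map
#' with the anatomy, the null for selection specificity.
#' `"hemisphere_swap"` transplants each hemisphere's values onto the other
#' hemisphere's grid at a transposed anchor — the grid axes are exchanged in
#' the transplant, so the eccentricity axis lands on the area axis and vice
#' versa (an exact isometry of the square grid, hence an involution that
#' preserves smoothness perfectly). `"circular_shift"` rolls values by half
#' the grid extent along both axes within each hemisphere (a near-isometry
#' with wrap seams).
#'
#' @param map_values per-unit numeric vector.
#' @param sheet the `cortical_sheet`.
#' @param mode `"hemisphere_swap"` or `"circular_shift"`.
#' @return Rolled per-unit vector (a permutation of the input values).
#' @export
make_rolled_component <- function(map_values, sheet,
                                  mode = c("hemisphere_swap", "circular_shift")) {
  mode <- match.arg(mode)
  H <- attr(sheet, "grid_height"); W <- attr(sheet, "grid_width")
  n <- nrow(sheet) / 2L
  pos_index <- function(hemi_offset, row, col)
    hemi_offset + (row - 1L) * W + col
  if (mode == "hemisphere_swap") {
    if (H != W)
      stop_contract("hemisphere_swap requires a square grid (transposed anchor)")
    src <- pos_index(ifelse(sheet$hemi == "left", n, 0L),
                     sheet$col, sheet$row)
  } else {
    row2 <- ((sheet$row - 1L + H %/% 2L) %% H) + 1L
    col2 <- ((sheet$col - 1L + W %/% 2L) %% W) + 1L
    src <- pos_index(ifelse(sheet$hemi == "left", 0L, n), row2, col2)
  }
  map_values[src]
}

#' Rolled-component null experiment
#'
#' For each participant, decomposes the recording with spatial ICA, rolls
#' every component map, intermixes originals and rolled copies under hashed
#' identities, runs the blind programmatic selection on the mix, and
#' cross-references the selections. Reports the fraction of selected
#' components that were original and an exact two-tailed binomial test
#' against chance (0.5).
#'
#' @param recordings list of `participant_recording`s.
#' @param sheet the `cortical_sheet`.
#' @param n_components components per participant (integer or `"auto"`).
#' @param thresholds selection thresholds.
#' @param mode rolling mode, see [make_rolled_component()].
#' @param seed integer seed (ICA init and identity shuffling).
#' @return List: `n_selected`, `n_original`, `fraction_original`, `binomial`
#'   (a `binomial_test_result`, or `NULL` if nothing was selected), and
#'   `per_participant` detail.
#' @export
rolled_null_experiment <- function(recordings, sheet, n_components = 20L,
                                   thresholds = default_select_thresholds(),
                                   mode = "hemisphere_swap", seed = 1L) {
  if (length(recordings) < 1L) stop_contract("need at least one participant")
  detail <- vector("list", length(recordings))
  n_orig_sel <- 0L; n_sel <- 0L
  for (i in seq_along(recordings)) {
    comp <- spatial_ica(recordings[[i]], n_components = n_components,
                        seed = child_seed(seed, 10L + i))
    rolled <- apply(comp$maps, 2, make_rolled_component, sheet = sheet,
                    mode = mode)
    pool <- cbind(comp$maps, rolled)
    is_original <- c(rep(TRUE, ncol(comp$maps)), rep(FALSE, ncol(rolled)))
    shuffle <- with_seed(child_seed(seed, 100L + i),
                         sample.int(ncol(pool)))
    sel <- auto_select_candidates(pool[, shuffle, drop = FALSE], sheet,
                                  thresholds)
    picked <- union(sel$sf, sel$meridian)
    orig_picked <- sum(is_original[shuffle][picked])
    n_sel <- n_sel + length(picked)
    n_orig_sel <- n_orig_sel + orig_picked
    detail[[i]] <- list(participant = i, n_selected = length(picked),
                        n_original = orig_picked)
  }
  binom <- if (n_sel > 0L) binomial_two_tailed(n_orig_sel, n_sel, 0.5) else NULL
  list(n_selected = n_sel, n_original = n_orig_sel,
       fraction_original = if (n_sel > 0L) n_orig_sel / n_sel else NA_real_,
       binomial = binom, per_participant = detail)
}
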