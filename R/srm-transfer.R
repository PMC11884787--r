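## Shared response modeling: deterministic SRM (orthogonal Procrustes /
## averaging alternation), frozen-model projection of held-out participants,
## inverse-mapping map prediction, flipped-time and anatomical-average
## baselines, and the leave-one-out transfer experiment.

procrustes_basis <- function(x, s) {
  sv <- svd(x %*% t(s))
  sv$u %*% t(sv$v)
}

srm_objective <- function(xs, ws, s) {
  sum(vapply(seq_along(xs), function(i)
    sum((xs[[i]] - ws[[i]] %*% s)^2), numeric(1)))
}

#' Fit a shared response model
#'
#' Minimizes `sum_i ||X_i - W_i S||^2` over per-participant orthonormal
#' bases `W_i` (units x k) and a shared time course `S` (k x T) by
#' alternating an orthogonal Procrustes update of each basis with averaging
#' of the back-projected data. Bases are initialized from the QR
#' decomposition of seeded Gaussian matrices; the objective is recorded per
#' iteration and never increases.
#'
#' @param recordings list of `participant_recording`s (or lists with a
#'   units x time `data` matrix), equal T.
#' @param k number of shared features (default 10).
#' @param max_iter,tol iteration cap and relative objective change
#'   tolerance.
#' @param seed integer seed for initialization.
#' @return A `shared_response_model`: `k`, `shared` (k x T), `bases` (list
#'   of units x k), `objective` (per-iteration trace), `seed`.
#' @export
fit_srm <- function(recordings, k = 10L, max_iter = 50L, tol = 1e-9,
                    seed = 1L) {
  xs <- lapply(recordings, function(r) if (is.list(r)) r$data else r)
  if (length(xs) < 1L) stop_contract("need at least one participant")
  t_len <- ncol(xs[[1]])
  for (x in xs) {
    if (ncol(x) != t_len) stop_contract("all participants must share T")
    if (ncol(x) < k) stop_contract("T must be >= k")
    if (nrow(x) < k) stop_contract("unit count must be >= k")
  }
  ws <- lapply(seq_along(xs), function(i) with_seed(child_seed(seed, i), {
    qr.Q(qr(matrix(stats::rnorm(nrow(xs[[i]]) * k), ncol = k)))
  }))
  s <- Reduce(`+`, lapply(seq_along(xs), function(i)
    t(ws[[i]]) %*% xs[[i]])) / length(xs)
  trace <- srm_objective(xs, ws, s)
  for (it in seq_len(max_iter)) {
    ws <- lapply(seq_along(xs), function(i) procrustes_basis(xs[[i]], s))
    s <- Reduce(`+`, lapply(seq_along(xs), function(i)
      t(ws[[i]]) %*% xs[[i]])) / length(xs)
    obj <- srm_objective(xs, ws, s)
    trace <- c(trace, obj)
    prev <- trace[length(trace) - 1L]
    if (prev - obj < tol * max(prev, 1e-300)) break
  }
  structure(list(k = as.integer(k), shared = s, bases = ws,
                 objective = trace, seed = as.integer(seed)),
            class = "shared_response_model")
}

#' @export
print.shared_response_model <- function(x, ...) {
  cat(sprintf("shared response model: k = %d, %d training participants, T = %d, final objective %.4g (%d iterations)\n",
              x$k, length(x$bases), ncol(x$shared),
              x$objective[length(x$objective)], length(x$objective) - 1L))
  invisible(x)
}

#' Transform a per-unit map into the shared space
#'
#' `W' m`: projects a participant's spatial map through their orthonormal
#' basis into the k-dimensional shared space. The group shared map is the
#' element-wise mean of the training participants' shared vectors.
#'
#' @param map_values per-unit numeric vector.
#' @param basis units x k orthonormal basis.
#' @return Length-k shared-space vector.
#' @export
transform_map_to_shared <- function(map_values, basis) {
  if (length(map_values) != nrow(basis)) stop_contract("dimension mismatch")
  as.numeric(t(basis) %*% map_values)
}

#' Fit a held-out participant against a frozen shared response
#'
#' A single orthogonal Procrustes solve of the held-out participant's data
#' against the already-learned shared time course `S`; `S` is not updated.
#'
#' @param model a `shared_response_model`.
#' @param recording held-out `participant_recording` (or units x time
#'   matrix) with T matching the model.
#' @return Units x k orthonormal basis for the test participant.
#' @export
fit_new_participant <- function(model, recording) {
  x <- if (is.list(recording)) recording$data else recording
  if (ncol(x) != ncol(model$shared)) stop_contract("T mismatch with frozen model")
  procrustes_basis(x, model$shared)
}

#' Predict a held-out participant's map from the shared space
#'
#' `W_test v`: carries the group shared map vector back into the test
#' participant's unit space through the inverse of their mapping (the
#' transpose, exact because the basis is orthonormal).
#'
#' @param shared_vector length-k group shared map vector.
#' @param test_basis units x k orthonormal basis of the test participant.
#' @return Per-unit predicted map.
#' @export
predict_map <- function(shared_vector, test_basis) {
  if (length(shared_vector) != ncol(test_basis)) stop_contract("dimension mismatch")
  as.numeric(test_basis %*% shared_vector)
}

#' Reverse a recording in time
#'
#' Flips each movie segment so the first timepoint becomes the last; the
#' null for functional alignment, since no valid stimulus-locked mapping can
#' be learned from time-reversed data. All other fields are untouched.
#'
#' @param recording a `participant_recording`.
#' @return The recording with each movie's timepoints reversed.
#' @export
flipped_baseline <- function(recording) {
  out <- recording
  for (b in recording$movie_bounds) {
    idx <- b[["start"]]:b[["end"]]
    out$data[, idx] <- recording$data[, rev(idx)]
  }
  out
}

#' Anatomical-average baseline map
#'
#' Element-wise mean of the other participants' ground-truth maps on the
#' common grid, emulating template-space anatomical alignment (optionally
#' degraded with [jitter_maps()] to emulate misalignment).
#'
#' @param other_maps list of `ground_truth_maps`.
#' @param field `"spatial_frequency"` or `"meridian"`.
#' @return Per-unit baseline map.
#' @export
anatomical_average_baseline <- function(other_maps, field = "spatial_frequency") {
  if (length(other_maps) < 1L) stop_contract("need at least one other participant")
  Reduce(`+`, lapply(other_maps, `[[`, field)) / length(other_maps)
}

recording_movie_block <- function(recording, movie) {
  b <- recording$movie_bounds[[movie]]
  recording$data[, b[["start"]]:b[["end"]], drop = FALSE]
}

#' Leave-one-out SRM map-transfer experiment
#'
#' For each held-out participant and each movie: fit an SRM on everyone
#' else, transform the training participants' ground-truth maps into the
#' shared space and average them, project the held-out participant against
#' the frozen shared time course, predict their maps through the inverse
#' mapping, and score the prediction by signed gradient correlation with the
#' participant's own ground truth (spatial frequency along parallel lines,
#' meridian along perpendicular lines). The same pipeline is repeated on
#' time-flipped data (null) and compared with the anatomical-average
#' baseline. Per-participant values are averaged across movies before the
#' bootstrap comparisons.
#'
#' @param recordings list of `participant_recording`s.
#' @param sheet the common `cortical_sheet`.
#' @param maps one `ground_truth_maps` shared by the cohort, or a list of
#'   per-participant maps.
#' @param k shared features (default 10).
#' @param fields map fields to transfer.
#' @param jitter_scale RMS misalignment applied to the maps entering the
#'   anatomical average (0 = perfectly aligned template space).
#' @param n_boot,seed bootstrap settings.
#' @return List: `results` (per participant x movie x field data frame of
#'   real / flipped / anatomical correlations), `per_participant` (movie
#'   averages), and `tests` (`real_vs_flipped`, `anatomical_vs_real`
#'   bootstrap results per field).
#' @export
leave_one_out_experiment <- function(recordings, sheet, maps, k = 10L,
                                     fields = c("spatial_frequency", "meridian"),
                                     jitter_scale = 0, n_boot = 2000L,
                                     seed = 1L) {
  n <- length(recordings)
  if (n < 3L) stop_contract("need at least 3 participants")
  per_part_maps <- if (inherits(maps, "ground_truth_maps"))
    replicate(n, maps, simplify = FALSE) else maps
  stopifnot(length(per_part_maps) == n)
  lines <- list(spatial_frequency = trace_gradient_lines(sheet, "parallel"),
                meridian = trace_gradient_lines(sheet, "perpendicular"))
  fields <- match.arg(fields, c("spatial_frequency", "meridian"),
                      several.ok = TRUE)
  n_movies <- length(recordings[[1]]$movie_bounds)

  rows <- list()
  for (test in seq_len(n)) {
    train <- setdiff(seq_len(n), test)
    for (m in seq_len(n_movies)) {
      model <- fit_srm(lapply(recordings[train], recording_movie_block,
                              movie = m),
                       k = k, seed = child_seed(seed, test * 100L + m))
      w_test <- fit_new_participant(model,
                                    recording_movie_block(recordings[[test]], m))
      w_flip <- fit_new_participant(model,
                                    recording_movie_block(
                                      flipped_baseline(recordings[[test]]), m))
      anat_maps <- lapply(seq_along(train), function(j) {
        mm <- per_part_maps[[train[j]]]
        if (jitter_scale > 0)
          mm <- jitter_maps(mm, sheet, jitter_scale,
                            seed = child_seed(seed, 7000L + train[j]))
        mm
      })
      for (f in fields) {
        shared_vec <- rowMeans(vapply(seq_along(train), function(j)
          transform_map_to_shared(per_part_maps[[train[j]]][[f]],
                                  model$bases[[j]]),
          numeric(k)))
        truth <- per_part_maps[[test]][[f]]
        score <- function(pred) tryCatch(
          score_component(pred, truth, lines[[f]], absolute = FALSE),
          error = function(e) NA_real_)
        rows[[length(rows) + 1L]] <- data.frame(
          participant = test, movie = m, field = f,
          real = score(predict_map(shared_vec, w_test)),
          flipped = score(predict_map(shared_vec, w_flip)),
          anatomical = score(anatomical_average_baseline(anat_maps, f)))
      }
    }
  }
  results <- do.call(rbind, rows)
  per_part <- stats::aggregate(cbind(real, flipped, anatomical) ~ participant + field,
                               data = results, FUN = mean)
  tests <- list()
  for (f in fields) {
    pp <- per_part[per_part$field == f, ]
    tests[[f]] <- list(
      real_vs_flipped = bootstrap_mean_difference(
        fisher_z(pp$real) - fisher_z(pp$flipped),
        n_boot = n_boot, seed = child_seed(seed, 1L)),
      anatomical_vs_real = bootstrap_mean_difference(
        fisher_z(pp$anatomical) - fisher_z(pp$real),
        n_boot = n_boot, seed = child_seed(seed, 2L)))
  }
  list(results = results, per_participant = per_part, tests = tests)
}

#' Choose the number of shared features by cross-validation
#'
#' Participant-wise cross-validation with held-out time halves: for each k
#' and each held-out participant, an SRM is fit on the other participants'
#' first time half, the held-out participant's basis is learned on that same
#' half against the frozen shared response, a second-half shared response is
#' formed from the training participants, and the held-out second half is
#' scored by the correlation between predicted and observed data. With no
#' grid supplied the established default k = 10 is returned.
#'
#' @param recordings list of `participant_recording`s.
#' @param k_grid integer vector of candidate k, or `NULL` for the default.
#' @param seed integer seed.
#' @return List: `k` (chosen), `scores` (named mean reconstruction
#'   correlation per k, `NULL` when defaulted).
#' @export
select_k_crossval <- function(recordings, k_grid = NULL, seed = 1L) {
  if (is.null(k_grid)) return(list(k = 10L, scores = NULL))
  if (length(k_grid) == 0L) stop_contract("k grid must be nonempty")
  n <- length(recordings)
  if (n < 3L) stop_contract("need at least 3 participants")
  t_len <- ncol(recordings[[1]]$data)
  half <- seq_len(t_len %/% 2L)
  rest <- setdiff(seq_len(t_len), half)
  xs1 <- lapply(recordings, function(r) r$data[, half, drop = FALSE])
  xs2 <- lapply(recordings, function(r) r$data[, rest, drop = FALSE])
  scores <- vapply(k_grid, function(k) {
    mean(vapply(seq_len(n), function(test) {
      train <- setdiff(seq_len(n), test)
      model <- fit_srm(xs1[train], k = k, seed = child_seed(seed, k * 100L + test))
      w_test <- fit_new_participant(model, xs1[[test]])
      s2 <- Reduce(`+`, lapply(seq_along(train), function(j)
        t(model$bases[[j]]) %*% xs2[[train[j]]])) / length(train)
      pred <- w_test %*% s2
      stats::cor(as.numeric(pred), as.numeric(xs2[[test]]))
    }, numeric(1)))
  }, numeric(1))
  names(scores) <- k_grid
  list(k = k_grid[which.max(scores)], scores = scores)
}
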