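## Cross-hemisphere homotopy analysis: area mean time courses, left x right
## correlation matrices (optionally motion-controlled), Fisher-Z cell-group
## contrasts, bootstrap inference, and MDS of the group matrix.

#' Average movie activity within each visual area
#'
#' Unweighted mean time course across the member units of every area, per
#' hemisphere, over the concatenated movies. Areas with no units are dropped
#' with a warning (missing areas are simply ignored downstream).
#'
#' @param recording a `participant_recording`.
#' @param sheet the `cortical_sheet` the recording was generated on.
#' @param areas optional subset of area labels to keep.
#' @return An `area_timecourses` list: `left` and `right` matrices
#'   (areas x time, rownames = area labels), plus `stream` and `level`
#'   metadata vectors named by area.
#' @export
extract_area_timecourses <- function(recording, sheet, areas = NULL) {
  if (nrow(recording$data) != nrow(sheet))
    stop_contract("recording units do not align with sheet units")
  keep <- if (is.null(areas)) AREA_ORDER else intersect(AREA_ORDER, areas)
  one_hemi <- function(hemi) {
    out <- list()
    for (a in keep) {
      idx <- which(sheet$hemi == hemi & sheet$area == a)
      if (length(idx) == 0L) {
        warning(sprintf("area %s has no units in %s hemisphere; excluded", a, hemi))
        next
      }
      out[[a]] <- colMeans(recording$data[idx, , drop = FALSE])
    }
    do.call(rbind, out)
  }
  left <- one_hemi("left"); right <- one_hemi("right")
  meta_idx <- match(rownames(left), AREA_ORDER)
  structure(list(left = left, right = right,
                 stream = stats::setNames(AREA_STREAM[meta_idx], rownames(left)),
                 level = stats::setNames(AREA_LEVEL[meta_idx], rownames(left))),
            class = "area_timecourses")
}

#' Cross-hemisphere area correlation matrix
#'
#' Pearson correlation of every left-hemisphere area time course against
#' every right-hemisphere one. The matrix is not diagonally symmetric in
#' general (left V1v x right V2v differs from left V2v x right V1v). When
#' motion confounds are supplied, each cell is a partial correlation with
#' motion regressed out of both time courses.
#'
#' @param tcs an `area_timecourses` set.
#' @param confounds optional numeric vector/matrix of confound time courses
#'   (e.g. the motion regressor).
#' @return A `cross_hemisphere_matrix`: left-areas x right-areas correlation
#'   matrix with `stream`/`level` metadata attributes.
#' @export
cross_hemisphere_matrix <- function(tcs, confounds = NULL) {
  if (is.null(tcs$left) || is.null(tcs$right) ||
      nrow(tcs$left) == 0L || nrow(tcs$right) == 0L)
    stop_contract("both hemispheres must have at least one area")
  la <- rownames(tcs$left); ra <- rownames(tcs$right)
  m <- matrix(NA_real_, length(la), length(ra), dimnames = list(la, ra))
  for (i in seq_along(la)) for (j in seq_along(ra)) {
    m[i, j] <- if (is.null(confounds))
      pearson_corr(tcs$left[i, ], tcs$right[j, ])
    else partial_corr(tcs$left[i, ], tcs$right[j, ], confounds)
  }
  attr(m, "stream") <- tcs$stream
  attr(m, "level") <- tcs$level
  class(m) <- c("cross_hemisphere_matrix", class(m))
  m
}

#' Homotopy cell-group contrasts of a cross-hemisphere matrix
#'
#' Groups the matrix cells by the relation between the left and right area:
#' same area / same stream (homotopic, e.g. LV1v x RV1v); same hierarchy
#' level but opposite stream (e.g. LV1v x RV1d); adjacent within stream
#' (hierarchy distance 1, e.g. LV1v x RV2v); distal within stream (distance
#' >= 2). Both asymmetric cells of each heterotopic pair enter their group.
#' Cell values are Fisher Z transformed before averaging; group means are
#' reported both in Fisher-Z units (`z_*`, used for differences and tests)
#' and back-transformed to correlations (`r_*`, for display).
#'
#' @param matrix a `cross_hemisphere_matrix`.
#' @return A `homotopy_contrasts` list of group means and the differences
#'   `d_same_cross`, `d_same_adjacent`, `d_adjacent_distal` (Fisher-Z units).
#'   Groups with no cells are `NA`.
#' @export
homotopy_contrasts <- function(matrix) {
  stream <- attr(matrix, "stream"); level <- attr(matrix, "level")
  if (is.null(stream) || is.null(level)) stop_contract("area metadata missing")
  la <- rownames(matrix); ra <- colnames(matrix)
  groups <- list(same_same = c(), same_cross = c(), adjacent = c(), distal = c())
  for (a in la) for (b in ra) {
    dist_lv <- abs(level[a] - level[b])
    same_stream <- stream[a] == stream[b]
    grp <- if (dist_lv == 0 && same_stream) "same_same"
    else if (dist_lv == 0) "same_cross"
    else if (same_stream && dist_lv == 1) "adjacent"
    else if (same_stream) "distal"
    else NA_character_
    if (!is.na(grp)) groups[[grp]] <- c(groups[[grp]], matrix[a, b])
  }
  zmean <- function(v) if (length(v)) mean(fisher_z(v)) else NA_real_
  z <- vapply(groups, zmean, numeric(1))
  out <- list(z_same_area_same_stream = z[["same_same"]],
              z_same_area_cross_stream = z[["same_cross"]],
              z_adjacent_same_stream = z[["adjacent"]],
              z_distal_same_stream = z[["distal"]],
              r_same_area_same_stream = inverse_fisher_z(z[["same_same"]]),
              r_same_area_cross_stream = inverse_fisher_z(z[["same_cross"]]),
              r_adjacent_same_stream = inverse_fisher_z(z[["adjacent"]]),
              r_distal_same_stream = inverse_fisher_z(z[["distal"]]),
              d_same_cross = z[["same_same"]] - z[["same_cross"]],
              d_same_adjacent = z[["same_same"]] - z[["adjacent"]],
              d_adjacent_distal = z[["adjacent"]] - z[["distal"]])
  class(out) <- "homotopy_contrasts"
  out
}

#' Group-level bootstrap test of a homotopy contrast
#'
#' Collects one contrast value per participant and tests its mean against
#' zero by resampling participants with replacement.
#'
#' @param contrasts list of per-participant `homotopy_contrasts`.
#' @param which contrast name: `"d_same_cross"`, `"d_same_adjacent"` or
#'   `"d_adjacent_distal"`.
#' @param n_boot pseudosample count.
#' @param seed integer seed.
#' @return A `bootstrap_result` (see [bootstrap_mean_difference()]).
#' @export
group_contrast_test <- function(contrasts, which = "d_same_cross",
                                n_boot = 10000L, seed = 1L) {
  if (length(contrasts) < 2L) stop_contract("need at least 2 participants")
  d <- vapply(contrasts, function(cc) cc[[which]], numeric(1))
  d <- d[!is.na(d)]
  bootstrap_mean_difference(d, n_boot = n_boot, seed = seed)
}

silhouette_score <- function(dist_mat, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)),
                             dmatrix = as.matrix(dist_mat))
  mean(sil[, "sil_width"])
}

#' MDS embedding of the group-average cross-hemisphere matrix
#'
#' Averages the participants' matrices element-wise, treats each area's row
#' of correlations as its feature vector, computes pairwise Euclidean
#' distances between areas, and embeds them in 2-D by metric MDS. Also
#' reports the mean silhouette of the dorsal/ventral stream labels in the
#' feature-distance space as a stream-separation score.
#'
#' @param matrices list of `cross_hemisphere_matrix` with a common area
#'   scheme.
#' @param n_dims embedding dimensionality (default 2).
#' @param seed integer seed for the MDS restarts.
#' @return An `mds_embedding` with extra fields `silhouette` (stream
#'   separation) and `labels`.
#' @export
mds_of_group_matrix <- function(matrices, n_dims = 2L, seed = 1L) {
  ref <- dimnames(matrices[[1]])
  for (m in matrices)
    if (!identical(dimnames(m), ref)) stop_contract("inconsistent area schemes")
  avg <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  d <- as.matrix(stats::dist(avg))
  emb <- mds_embed(d, n_dims = n_dims, seed = seed)
  emb$silhouette <- silhouette_score(d, attr(matrices[[1]], "stream")[rownames(avg)])
  emb$labels <- rownames(avg)
  rownames(emb$coordinates) <- rownames(avg)
  emb
}

#' Run the full homotopy analysis on a cohort
#'
#' Convenience wrapper: area time courses, cross-hemisphere matrices
#' (optionally motion-controlled), per-participant contrasts, and bootstrap
#' tests of the three contrast differences.
#'
#' @param recordings list of `participant_recording`s.
#' @param sheet the common `cortical_sheet`.
#' @param control_motion regress the motion regressor out of every cell.
#' @param n_boot,seed bootstrap settings.
#' @return List with `matrices`, `contrasts`, `tests` (named
#'   `bootstrap_result`s), and `group_matrix` (element-wise mean).
#' @export
run_homotopy <- function(recordings, sheet, control_motion = FALSE,
                         n_boot = 10000L, seed = 1L) {
  matrices <- lapply(recordings, function(rec) {
    tcs <- extract_area_timecourses(rec, sheet)
    cross_hemisphere_matrix(tcs, confounds = if (control_motion) rec$motion)
  })
  contrasts <- lapply(matrices, homotopy_contrasts)
  tests <- lapply(stats::setNames(nm = c("d_same_cross", "d_same_adjacent",
                                         "d_adjacent_distal")),
                  function(w) group_contrast_test(contrasts, w,
                                                  n_boot = n_boot,
                                                  seed = child_seed(seed, match(w, c("d_same_cross", "d_same_adjacent", "d_adjacent_distal")))))
  group <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  list(matrices = matrices, contrasts = contrasts, tests = tests,
       group_matrix = group)
}
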