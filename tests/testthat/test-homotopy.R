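test_that("area time courses are unweighted unit means", {
  st <- small_study()
  sheet <- st$sheet
  rec <- st$recordings[[1]]
  tcs <- extract_area_timecourses(rec, sheet)
  # singleton and two-unit means recomputed by hand for one area
  idx <- which(sheet$hemi == "left" & sheet$area == "V1v")
  expect_equal(tcs$left["V1v", ], colMeans(rec$data[idx, ]))
  one_unit <- rec
  keep <- idx[1]
  sub <- list(data = rec$data)
  # a singleton area mean is the unit's own time course
  expect_equal(colMeans(rec$data[keep, , drop = FALSE]), rec$data[keep, ])
  a <- rec$data[idx[1], ]; b <- rec$data[idx[2], ]
  expect_equal(colMeans(rec$data[idx[1:2], ]), (a + b) / 2)
  expect_error(extract_area_timecourses(list(data = rec$data[1:10, ]), sheet),
               class = "moviemap_contract_error")
})

test_that("cross-hemisphere matrix has unit diagonal for identical inputs and stays small for noise", {
  st <- small_study()
  tcs <- extract_area_timecourses(st$recordings[[1]], st$sheet)
  same <- tcs
  same$right <- tcs$left
  m <- cross_hemisphere_matrix(same)
  expect_equal(unname(diag(unclass(m))), rep(1, nrow(m)))
  # independent white noise: all cells within the 3/sqrt(T) band
  set.seed(9)
  noise <- list(left = matrix(rnorm(8 * 500), 8, 500,
                              dimnames = list(rownames(tcs$left), NULL)),
                right = matrix(rnorm(8 * 500), 8, 500,
                               dimnames = list(rownames(tcs$right), NULL)),
                stream = tcs$stream, level = tcs$level)
  mn <- cross_hemisphere_matrix(noise)
  expect_lt(max(abs(unclass(mn))), 0.15)
  # synthetic cohort: homotopic diagonal exceeds the off-diagonal mean
  ms <- cross_hemisphere_matrix(tcs)
  expect_gt(mean(diag(unclass(ms))), mean(unclass(ms)[row(ms) != col(ms)]))
})

test_that("contrast cell groups follow the stream/hierarchy definitions", {
  m <- toy_matrix_by_groups(same = 0.8, cross = 0.5, adjacent = 0.6,
                            distal = 0.4)
  con <- homotopy_contrasts(m)
  expect_equal(con$d_same_adjacent, fisher_z(0.8) - fisher_z(0.6),
               tolerance = 1e-12)
  expect_equal(con$d_same_adjacent, 0.405, tolerance = 1e-2)
  expect_equal(con$r_same_area_same_stream, 0.8, tolerance = 1e-9)
  expect_equal(con$r_distal_same_stream, 0.4, tolerance = 1e-9)

  flat <- toy_matrix(0.5)
  cf <- homotopy_contrasts(flat)
  expect_equal(cf$d_same_cross, 0)
  expect_equal(cf$d_same_adjacent, 0)
  expect_equal(cf$d_adjacent_distal, 0)

  eq <- toy_matrix_by_groups(same = 0.7, cross = 0.7, adjacent = 0.5,
                             distal = 0.3)
  expect_equal(homotopy_contrasts(eq)$d_same_cross, 0)
})

test_that("contrasts are invariant to area storage order", {
  m <- toy_matrix_by_groups(same = 0.75, cross = 0.55, adjacent = 0.6,
                            distal = 0.35)
  set.seed(1)
  perm <- sample(nrow(m))
  mp <- unclass(m)[perm, perm]
  attr(mp, "stream") <- attr(m, "stream")
  attr(mp, "level") <- attr(m, "level")
  class(mp) <- class(m)
  expect_equal(unclass(homotopy_contrasts(mp)), unclass(homotopy_contrasts(m)))
})

test_that("group bootstrap flags unanimous contrasts and missing groups", {
  m <- toy_matrix_by_groups(same = 0.8, cross = 0.5, adjacent = 0.6,
                            distal = 0.4)
  cons <- replicate(5, homotopy_contrasts(m), simplify = FALSE)
  g <- group_contrast_test(cons, "d_same_adjacent", n_boot = 200, seed = 2)
  expect_equal(g$p_two_tailed, 0)
  expect_match(g$p_report, "^< ")
  expect_error(group_contrast_test(cons[1], "d_same_cross"),
               class = "moviemap_contract_error")
})

test_that("group MDS separates streams in a block-structured matrix", {
  blocks <- toy_matrix_by_groups(same = 0.8, cross = 0.2, adjacent = 0.8,
                                 distal = 0.8, other = 0.2)
  emb <- mds_of_group_matrix(list(blocks), seed = 4)
  expect_lt(emb$stress, 0.2)
  expect_gt(emb$silhouette, 0)
  # duplicate rows (identical similarity profiles) embed at distance ~0
  within <- which(attr(blocks, "stream")[rownames(blocks)] == "dorsal")
  d <- as.matrix(dist(emb$coordinates))
  same_lvl <- which(rownames(blocks) %in% c("V1d", "V2d"))
  expect_lt(d[same_lvl[1], same_lvl[2]],
            min(d[within[1], rownames(blocks) == "V1v"]))
  # single-matrix input equals the unaveraged computation
  emb1 <- mds_of_group_matrix(list(blocks, blocks), seed = 4)
  expect_equal(emb1$stress, emb$stress, tolerance = 1e-12)
  bad <- blocks[1:4, 1:4]
  attr(bad, "stream") <- attr(blocks, "stream")
  class(bad) <- class(blocks)
  expect_error(mds_of_group_matrix(list(blocks, bad)),
               class = "moviemap_contract_error")
})

test_that("partial correlation restores motion-inflated matrices", {
  cfg <- sim_config(n_participants = 3L, n_timepoints = 120L, n_movies = 1L,
                    motion_amplitude = 0, seed = 21L)
  st0 <- simulate_study(cfg)
  cfg2 <- sim_config(n_participants = 3L, n_timepoints = 120L, n_movies = 1L,
                     motion_amplitude = 2, seed = 21L)
  st2 <- simulate_study(cfg2)
  for (i in 1:3) {
    t0 <- extract_area_timecourses(st0$recordings[[i]], st0$sheet)
    t2 <- extract_area_timecourses(st2$recordings[[i]], st2$sheet)
    m0 <- unclass(cross_hemisphere_matrix(t0))
    raw2 <- unclass(cross_hemisphere_matrix(t2))
    part2 <- unclass(cross_hemisphere_matrix(t2, confounds = st2$recordings[[i]]$motion))
    off <- row(m0) != col(m0)
    # motion inflates the raw off-diagonal correlations ...
    expect_gt(mean(fisher_z(raw2[off])), mean(fisher_z(m0[off])))
    # ... and regressing the motion regressor out restores them
    expect_lt(mean(abs(part2[off] - m0[off])), 0.05)
  }
})

test_that("same > adjacent > distal ordering is recovered across replicate cohorts", {
  hits <- 0L
  n_rep <- 8L
  for (r in seq_len(n_rep)) {
    cfg <- sim_config(n_participants = 4L, n_timepoints = 120L, n_movies = 1L,
                      snr = 1, seed = 3000L + r)
    st <- simulate_study(cfg)
    hom <- run_homotopy(st$recordings, st$sheet, n_boot = 50, seed = r)
    z <- colMeans(do.call(rbind, lapply(hom$contrasts, function(cc)
      unlist(cc[c("z_same_area_same_stream", "z_adjacent_same_stream",
                  "z_distal_same_stream")]))))
    if (z[1] > z[2] && z[2] > z[3]) hits <- hits + 1L
  }
  expect_gte(hits, ceiling(0.9 * n_rep))
})
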