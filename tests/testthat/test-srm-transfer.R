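# construct a noiseless SRM cohort: orthonormal bases times one shared
# time course, optionally with maps lying exactly in the shared span
make_srm_cohort <- function(n = 4, v = 200, t_len = 80, k = 5, seed = 1) {
  set.seed(seed)
  ws <- lapply(seq_len(n), function(i) qr.Q(qr(matrix(rnorm(v * k), v, k))))
  s <- matrix(rnorm(k * t_len), k, t_len)
  vbar <- rnorm(k)
  list(ws = ws, s = s, vbar = vbar,
       recs = lapply(ws, function(w) list(data = w %*% s)))
}

principal_angles <- function(a, b) {
  sv <- svd(crossprod(qr.Q(qr(a)), qr.Q(qr(b))))$d
  acos(pmin(1, sv))
}

test_that("SRM solver recovers noiseless constructions exactly", {
  ch <- make_srm_cohort()
  m <- fit_srm(ch$recs, k = 5, max_iter = 100, seed = 3)
  total <- sum(vapply(ch$recs, function(r) sum(r$data^2), numeric(1)))
  expect_lt(sqrt(m$objective[length(m$objective)] / total), 1e-6)
  for (i in seq_along(ch$ws))
    expect_lt(max(principal_angles(m$bases[[i]], ch$ws[[i]])), 1e-4)
})

test_that("SRM objective never increases and bases stay orthonormal", {
  st <- small_study()
  recs <- lapply(st$recordings, function(r)
    list(data = r$data[, 1:60]))
  m <- fit_srm(recs, k = 8, seed = 4)
  expect_true(all(diff(m$objective) <= 1e-6 * m$objective[1]))
  for (w in m$bases)
    expect_lt(max(abs(crossprod(w) - diag(m$k))), 1e-8)
  expect_error(fit_srm(recs, k = 70), class = "moviemap_contract_error")
})

test_that("single-participant k=1 SRM spans the top singular direction", {
  set.seed(6)
  x <- matrix(rnorm(120 * 50), 120, 50)
  m <- fit_srm(list(list(data = x)), k = 1, max_iter = 5000, tol = 1e-15,
               seed = 2)
  sv <- svd(x)
  rank1_err <- sum((x - sv$d[1] * outer(sv$u[, 1], sv$v[, 1]))^2)
  expect_equal(m$objective[length(m$objective)], rank1_err, tolerance = 1e-8)
  expect_lt(max(principal_angles(m$bases[[1]], sv$u[, 1, drop = FALSE])), 1e-4)
})

test_that("shared-space transform is the exact adjoint of the basis", {
  set.seed(7)
  w <- qr.Q(qr(matrix(rnorm(100 * 4), 100, 4)))
  v <- c(2, -1, 0.5, 3)
  expect_equal(transform_map_to_shared(w %*% v, w), v)
  # orthogonal-complement input is annihilated
  perp <- rnorm(100)
  perp <- perp - w %*% crossprod(w, perp)
  expect_equal(transform_map_to_shared(perp, w), rep(0, 4), tolerance = 1e-10)
  expect_equal(transform_map_to_shared(w[, 1] + w[, 3], w), c(1, 0, 1, 0))
  expect_error(transform_map_to_shared(rnorm(5), w),
               class = "moviemap_contract_error")
})

test_that("frozen-model projection fits only the new participant", {
  ch <- make_srm_cohort(n = 3)
  m <- fit_srm(ch$recs, k = 5, max_iter = 100, seed = 3)
  s_before <- m$shared
  set.seed(9)
  w_star <- qr.Q(qr(matrix(rnorm(200 * 5), 200, 5)))
  x_test <- w_star %*% m$shared
  w_test <- fit_new_participant(m, list(data = x_test))
  expect_identical(m$shared, s_before)
  expect_lt(max(abs(crossprod(w_test) - diag(5))), 1e-8)
  expect_lt(sqrt(sum((x_test - w_test %*% m$shared)^2) / sum(x_test^2)), 1e-6)
  # pure-noise data carries no shared structure into the prediction
  x_noise <- matrix(rnorm(200 * 80), 200, 80)
  w_noise <- fit_new_participant(m, list(data = x_noise))
  pred <- predict_map(ch$vbar, w_noise)
  truth <- predict_map(ch$vbar, w_star)
  expect_lt(abs(cor(pred, truth)), 0.35)
  expect_error(fit_new_participant(m, list(data = x_test[, 1:10])),
               class = "moviemap_contract_error")
})

test_that("map prediction closes the loop through the shared space", {
  ch <- make_srm_cohort()
  m <- fit_srm(ch$recs, k = 5, max_iter = 100, seed = 3)
  w_test <- fit_new_participant(m, ch$recs[[1]])
  expect_equal(predict_map(rep(0, 5), w_test), rep(0, nrow(ch$ws[[1]])))
  truth_map <- as.numeric(w_test %*% ch$vbar)
  expect_gt(cor(predict_map(ch$vbar, w_test), truth_map), 1 - 1e-9)
  expect_error(predict_map(1:3, w_test), class = "moviemap_contract_error")
})

test_that("flipped baseline reverses each movie and is an involution", {
  st <- small_study()
  rec <- st$recordings[[1]]
  fl <- flipped_baseline(rec)
  b <- rec$movie_bounds[[1]]
  expect_equal(fl$data[, b[["start"]]], rec$data[, b[["end"]]])
  expect_equal(flipped_baseline(fl)$data, rec$data)
  # palindromic time course is unchanged
  pal <- list(data = matrix(c(1, 2, 3, 2, 1), 1), movie_bounds = list(c(start = 1, end = 5)))
  expect_equal(flipped_baseline(pal)$data, pal$data)
})

test_that("anatomical-average baseline degrades monotonically with jitter", {
  sheet <- default_sheet()
  maps <- default_maps()
  expect_equal(anatomical_average_baseline(list(maps, maps, maps)),
               maps$spatial_frequency)
  expect_equal(anatomical_average_baseline(list(maps), "meridian"),
               maps$meridian)
  par_lines <- trace_gradient_lines(sheet, "parallel")
  cors <- vapply(c(0, 1, 2, 4), function(js) {
    jm <- lapply(1:3, function(i)
      jitter_maps(maps, sheet, js, seed = 100 + i))
    score_component(anatomical_average_baseline(jm),
                    maps$spatial_frequency, par_lines, absolute = FALSE)
  }, numeric(1))
  expect_true(all(diff(cors) < 0))
})

test_that("leave-one-out transfer beats the flipped null on a planted cohort", {
  cfg <- sim_config(n_participants = 5L, n_timepoints = 120L, n_movies = 1L,
                    map_coupling = 0.5, snr = 2, seed = 11L)
  st <- simulate_study(cfg)
  loo <- leave_one_out_experiment(st$recordings, st$sheet, st$maps, k = 10,
                                  n_boot = 500, seed = 4)
  sf <- loo$per_participant[loo$per_participant$field == "spatial_frequency", ]
  expect_gt(mean(sf$real), mean(sf$flipped))
  expect_lt(loo$tests$spatial_frequency$real_vs_flipped$p_two_tailed, 0.05)
  # degenerate identity cohort: the anatomical average is exact
  expect_equal(mean(sf$anatomical), 1.0, tolerance = 1e-9)
  expect_gte(mean(sf$anatomical), mean(sf$real))
})

test_that("cross-validated k selection honors the default and recovers truth", {
  st <- small_study()
  expect_equal(select_k_crossval(st$recordings)$k, 10L)
  # generative recovery: data built with k = 5
  ch <- make_srm_cohort(n = 4, v = 150, t_len = 80, k = 5, seed = 3)
  recs <- lapply(ch$recs, function(r)
    list(data = r$data + matrix(rnorm(length(r$data), sd = 0.05),
                                nrow(r$data))))
  res <- select_k_crossval(recs, k_grid = c(2, 5, 10), seed = 6)
  expect_gt(res$scores[["5"]], res$scores[["2"]])
  expect_gte(res$scores[["5"]], 0.95 * max(res$scores))
  # noiseless data at the true rank reconstructs perfectly
  resn <- select_k_crossval(ch$recs, k_grid = 5, seed = 6)
  expect_equal(unname(resn$scores[["5"]]), 1.0, tolerance = 1e-6)
  expect_error(select_k_crossval(st$recordings, k_grid = integer(0)),
               class = "moviemap_contract_error")
})
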