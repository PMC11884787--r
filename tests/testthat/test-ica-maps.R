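test_that("spatial ICA recovers planted spatial sources", {
  # rank-1: one spatial pattern times one time course plus tiny noise
  set.seed(2)
  v <- 300; tt <- 60
  pattern <- rnorm(v)^3 # non-Gaussian spatial source
  course <- sin(seq_len(tt) / 3)
  x <- outer(pattern, course) + matrix(rnorm(v * tt, sd = 1e-4), v, tt)
  comp <- spatial_ica(list(data = x), n_components = 2, seed = 1)
  best <- max(abs(cor(comp$maps, pattern)))
  expect_gt(best, 0.99)

  # two non-Gaussian sources under random temporal mixing
  s1 <- rnorm(v)^3; s2 <- rexp(v) - 1
  a <- matrix(rnorm(2 * tt), tt, 2)
  x2 <- cbind(s1, s2) %*% t(a) + matrix(rnorm(v * tt, sd = 1e-3), v, tt)
  c2 <- spatial_ica(list(data = x2), n_components = 2, seed = 1)
  rec <- abs(cor(c2$maps, cbind(s1, s2)))
  expect_gt(max(rec[, 1]), 0.95)
  expect_gt(max(rec[, 2]), 0.95)

  # determinism
  c3 <- spatial_ica(list(data = x2), n_components = 2, seed = 1)
  expect_identical(c2$maps, c3$maps)
  expect_error(spatial_ica(list(data = x2), n_components = 100),
               class = "moviemap_contract_error")
})

test_that("component maps are spatially decorrelated after whitening", {
  st <- planted_recording()
  comp <- spatial_ica(st$recordings[[1]], n_components = 15, seed = 2)
  cc <- cor(comp$maps)
  expect_lt(max(abs(cc[row(cc) != col(cc)])), 1e-6)
  expect_true(all(diff(comp$explained_variance) <= 1e-12))
})

test_that("gradient profiles average position-wise along lines", {
  sheet <- default_sheet()
  maps <- default_maps()
  par_lines <- trace_gradient_lines(sheet, "parallel")
  const <- rep(2.5, nrow(sheet))
  expect_equal(unique(as.numeric(sample_gradient_profile(const, par_lines))), 2.5)
  prof <- sample_gradient_profile(sheet$ecc, par_lines)
  expect_true(all(diff(as.numeric(prof)) > 0))
  # two hand lines with opposing values average to a flat profile
  l1 <- structure(list(units = 1:3, orientation = "parallel"), class = "gradient_line")
  l2 <- structure(list(units = 4:6, orientation = "parallel"), class = "gradient_line")
  vals <- c(1, 2, 3, 3, 2, 1)
  expect_equal(as.numeric(sample_gradient_profile(vals, list(l1, l2))), c(2, 2, 2))
  bad <- structure(list(units = c(1L, 999999L, 3L), orientation = "parallel"),
                   class = "gradient_line")
  expect_error(sample_gradient_profile(c(1, 2, 3), list(bad)),
               class = "moviemap_contract_error")
})

test_that("component scoring respects the sign-invariance flag", {
  sheet <- default_sheet()
  maps <- default_maps()
  par_lines <- trace_gradient_lines(sheet, "parallel")
  truth <- maps$spatial_frequency
  expect_equal(score_component(truth, truth, par_lines), 1.0)
  expect_equal(score_component(-truth, truth, par_lines, absolute = TRUE), 1.0)
  expect_equal(score_component(-truth, truth, par_lines, absolute = FALSE), -1.0)
})

test_that("percentile ranking maps best to 100, worst to 0, chance to 50", {
  scores <- seq(0.1, 0.9, length.out = 31)
  expect_equal(rank_component_percentile(scores, which.max(scores)), 100)
  expect_equal(rank_component_percentile(scores, which.min(scores)), 0)
  # ranks {1st, 3rd} of 5: percentiles (100, 50), averaged to 75
  s5 <- c(5, 4, 3, 2, 1)
  expect_equal(rank_component_percentile(s5, c(1, 3)), 75)
  expect_equal(mean(vapply(seq_along(s5), function(i)
    rank_component_percentile(s5, i), numeric(1))), 50)
  expect_true(is.na(rank_component_percentile(s5, integer(0))))
  expect_error(rank_component_percentile(s5, 9), class = "moviemap_contract_error")
})

test_that("auto-selection finds planted maps and rejects noise and asymmetry", {
  st <- planted_recording()
  sheet <- st$sheet
  # planted: the ground-truth SF map plus small noise among smooth noise maps
  set.seed(5)
  noise_cols <- sapply(1:30, function(i) moviemap:::smooth_field(sheet))
  planted <- st$maps$spatial_frequency + rnorm(nrow(sheet), sd = 0.1)
  pool <- cbind(planted, noise_cols)
  sel <- auto_select_candidates(pool, sheet)
  expect_true(1 %in% sel$sf)

  # pure smooth-noise components: false-selection rate below 10%
  set.seed(6)
  noise_only <- sapply(1:50, function(i) moviemap:::smooth_field(sheet))
  seln <- auto_select_candidates(noise_only, sheet)
  expect_lt(length(union(seln$sf, seln$meridian)) / 50, 0.10)

  # hemisphere-asymmetric gradient fails the symmetry criterion
  asym <- st$maps$spatial_frequency
  asym[sheet$hemi == "right"] <- 0
  sela <- auto_select_candidates(cbind(asym), sheet)
  expect_length(union(sela$sf, sela$meridian), 0)
})

test_that("rolled components permute values, are involutive and stay smooth", {
  sheet <- default_sheet()
  maps <- default_maps()
  v <- maps$spatial_frequency + 0.3 * maps$meridian
  rolled <- make_rolled_component(v, sheet, "hemisphere_swap")
  expect_equal(sort(rolled), sort(v))
  expect_equal(make_rolled_component(rolled, sheet, "hemisphere_swap"), v)
  r2 <- make_rolled_component(v, sheet, "circular_shift")
  expect_equal(sort(r2), sort(v))

  # lag-1 spatial autocorrelation is approximately preserved on smooth input
  set.seed(8)
  smooth <- moviemap:::smooth_field(sheet)
  lag1 <- function(vals) {
    m <- moviemap:::sheet_matrix(sheet, vals, "left")
    cor(as.numeric(m[, -ncol(m)]), as.numeric(m[, -1]))
  }
  a0 <- lag1(smooth)
  a1 <- lag1(make_rolled_component(smooth, sheet, "hemisphere_swap"))
  expect_lt(abs(a1 - a0) / abs(a0), 0.15)
})

test_that("rolled-null experiment favors original components on planted cohorts", {
  sel <- 0L; orig <- 0L
  last <- NULL
  for (s in 1:4) {
    st <- simulate_study(sim_config(n_participants = 1L, map_coupling = 0.5,
                                    snr = 1, seed = 400L + s))
    last <- rolled_null_experiment(st$recordings, st$sheet,
                                   n_components = 20, seed = s)
    sel <- sel + last$n_selected; orig <- orig + last$n_original
  }
  expect_gte(sel, 3)
  expect_gt(orig / sel, 0.5)
  if (!is.null(last$binomial)) {
    expect_equal(last$binomial$trials, last$n_selected)
    expect_equal(last$binomial$successes, last$n_original)
  }
})
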