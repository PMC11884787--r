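# Shared fixtures, built once per test run. Everything is generated in code
# from fixed seeds; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# small default-structure cohort for structural and homotopy tests
small_study <- function() fixture("small_study", function()
  simulate_study(sim_config(n_participants = 4L, n_timepoints = 100L,
                            n_movies = 2L, seed = 7L)))

# one-participant planted cohort for ICA map-recovery tests
planted_recording <- function() fixture("planted_recording", function() {
  cfg <- sim_config(n_participants = 1L, n_timepoints = 150L, n_movies = 2L,
                    map_coupling = 0.5, snr = 1, seed = 11L)
  simulate_study(cfg)
})

default_sheet <- function() fixture("default_sheet", function()
  build_cortical_sheet(sim_config()))

default_maps <- function() fixture("default_maps", function()
  generate_ground_truth_maps(default_sheet()))

# hand-built cross-hemisphere matrix with the full 8-area metadata
toy_matrix <- function(values) {
  sheet <- default_sheet()
  areas <- unique(sheet$area)
  idx <- match(areas, areas)
  stream <- stats::setNames(sheet$stream[match(areas, sheet$area)], areas)
  level <- stats::setNames(sheet$level[match(areas, sheet$area)], areas)
  m <- matrix(values, length(areas), length(areas),
              dimnames = list(areas, areas))
  attr(m, "stream") <- stream
  attr(m, "level") <- level
  class(m) <- c("cross_hemisphere_matrix", class(m))
  m
}

# fill a toy matrix cell-group-wise: diag (same area, same stream), same
# level cross-stream, adjacent within stream, distal within stream,
# cross-stream non-matching levels
toy_matrix_by_groups <- function(same, cross, adjacent, distal, other = 0.1) {
  m <- toy_matrix(other)
  stream <- attr(m, "stream"); level <- attr(m, "level")
  for (a in rownames(m)) for (b in colnames(m)) {
    d <- abs(level[a] - level[b]); ss <- stream[a] == stream[b]
    m[a, b] <- if (d == 0 && ss) same else if (d == 0) cross
    else if (ss && d == 1) adjacent else if (ss) distal else other
  }
  m
}
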