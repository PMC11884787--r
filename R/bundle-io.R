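## Study-bundle container I/O and pipeline orchestration. A bundle is a
## directory of TSV tables plus a JSON sidecar carrying the configuration,
## every seed, the package version and a content checksum, so a bundle can
## be re-generated bit-exactly from its own provenance block.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# content checksum over the data-bearing files of a bundle, so that a
# re-read can detect any edit to tables or sidecar-relevant content
bundle_checksum <- function(path) {
  files <- sort(list.files(path, pattern = "^(recording_|motion_|maps)", full.names = TRUE))
  digest::digest(lapply(files, digest::digest, file = TRUE, algo = "sha256"),
                 algo = "sha256")
}

# digest of the provenance-bearing sidecar fields, canonicalized through
# JSON so it is invariant to how the sidecar was deserialized
provenance_digest <- function(side) {
  fields <- side[c("package_version", "config", "participant_seeds",
                   "movie_bounds", "checksum")]
  digest::digest(as.character(jsonlite::toJSON(fields, auto_unbox = TRUE,
                                               digits = NA)), algo = "sha256")
}

#' Write a study bundle to disk
#'
#' Writes the cortical sheet, ground-truth maps, gradient lines, recordings
#' and motion regressors as TSV tables, with a JSON sidecar holding the
#' simulation config, all seeds, movie boundaries, the package version and a
#' content checksum.
#'
#' @param bundle list with `sheet`, `maps`, `recordings`, and `config`
#'   (a [sim_config()]), e.g. from [simulate_study()].
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  sheet <- bundle$sheet
  write_tsv(as.data.frame(unclass(sheet))[names(sheet)], file.path(path, "units.tsv"))
  write_tsv(data.frame(unit = sheet$unit,
                       spatial_frequency = bundle$maps$spatial_frequency,
                       meridian = bundle$maps$meridian),
            file.path(path, "maps.tsv"))
  for (ori in c("parallel", "perpendicular")) {
    ll <- trace_gradient_lines(sheet, ori)
    df <- do.call(rbind, lapply(seq_along(ll), function(i)
      data.frame(line = i, position = seq_along(ll[[i]]$units),
                 unit = ll[[i]]$units, hemi = ll[[i]]$hemi)))
    write_tsv(df, file.path(path, paste0("lines_", ori, ".tsv")))
  }
  for (i in seq_along(bundle$recordings)) {
    rec <- bundle$recordings[[i]]
    utils::write.table(rec$data, file.path(path, sprintf("recording_%02d.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    write_tsv(data.frame(timepoint = seq_along(rec$motion), motion = rec$motion),
              file.path(path, sprintf("motion_%02d.tsv", i)))
  }
  sidecar <- list(
    package_version = as.character(utils::packageVersion("moviemap")),
    config = unclass(bundle$config),
    participant_seeds = vapply(bundle$recordings, `[[`, integer(1), "seed"),
    movie_bounds = lapply(bundle$recordings[[1]]$movie_bounds, as.list),
    checksum = bundle_checksum(path))
  sidecar$provenance_digest <- provenance_digest(sidecar)
  jsonlite::write_json(sidecar, file.path(path, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a study bundle from disk
#'
#' Reconstructs the sheet, maps and recordings written by [write_bundle()]
#' and re-verifies the content checksum against the sidecar; a mismatch
#' (e.g. an edited sidecar) raises a provenance-mismatch warning.
#'
#' @param path bundle directory.
#' @return A bundle list (`sheet`, `maps`, `recordings`, `config`,
#'   `provenance`).
#' @export
read_bundle <- function(path) {
  side_path <- file.path(path, "sidecar.json")
  if (!file.exists(side_path)) stop("not a study bundle: missing sidecar.json")
  side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
  config <- do.call(sim_config, side$config[names(formals(sim_config))])
  sheet <- build_cortical_sheet(config)
  units <- read_tsv(file.path(path, "units.tsv"))
  if (!identical(units$area, sheet$area))
    stop("bundle incompatible with this package version: area layout differs")
  maps_df <- read_tsv(file.path(path, "maps.tsv"))
  maps <- structure(list(spatial_frequency = maps_df$spatial_frequency,
                         meridian = maps_df$meridian),
                    class = "ground_truth_maps")
  bounds <- if (is.data.frame(side$movie_bounds))
    lapply(seq_len(nrow(side$movie_bounds)), function(i)
      c(start = side$movie_bounds$start[i], end = side$movie_bounds$end[i]))
  else lapply(side$movie_bounds, function(b)
    c(start = unlist(b)[["start"]], end = unlist(b)[["end"]]))
  rec_files <- sort(list.files(path, pattern = "^recording_", full.names = TRUE))
  recordings <- lapply(seq_along(rec_files), function(i) {
    dat <- as.matrix(utils::read.table(rec_files[i], sep = "\t"))
    dimnames(dat) <- NULL
    mot <- read_tsv(file.path(path, sprintf("motion_%02d.tsv", i)))$motion
    structure(list(data = dat, movie_bounds = bounds, motion = mot,
                   tr = config$tr, seed = side$participant_seeds[i],
                   loading = NULL, participant = i),
              class = "participant_recording")
  })
  if (!identical(bundle_checksum(path), side$checksum))
    warning("provenance mismatch: bundle content does not match its sidecar checksum")
  if (!identical(provenance_digest(side), side$provenance_digest))
    warning("provenance mismatch: sidecar fields were edited after writing")
  list(sheet = sheet, maps = maps, recordings = recordings, config = config,
       provenance = side)
}

#' Generate a complete synthetic study
#'
#' Sheet, ground-truth maps and cohort recordings from one config.
#' @param config a [sim_config()].
#' @return Bundle list (`sheet`, `maps`, `recordings`, `config`).
#' @export
simulate_study <- function(config = sim_config()) {
  sheet <- build_cortical_sheet(config)
  maps <- generate_ground_truth_maps(sheet)
  recordings <- simulate_movie_responses(sheet, maps, config)
  list(sheet = sheet, maps = maps, recordings = recordings, config = config)
}

#' Export a per-unit map as a NIfTI volume
#'
#' Writes the two hemisphere grids as the two slices of a H x W x 2 volume,
#' for viewing in standard neuroimaging tools.
#' @param sheet a `cortical_sheet`.
#' @param map_values per-unit numeric vector.
#' @param path output `.nii`/`.nii.gz` path.
#' @return `path`, invisibly.
#' @export
export_map_nifti <- function(sheet, map_values, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("the RNifti package is required for NIfTI export")
  H <- attr(sheet, "grid_height"); W <- attr(sheet, "grid_width")
  arr <- array(0, dim = c(H, W, 2))
  arr[, , 1] <- sheet_matrix(sheet, map_values, "left")
  arr[, , 2] <- sheet_matrix(sheet, map_values, "right")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

validate_pipeline_config <- function(cfg) {
  known <- c("stages", "sim", "homotopy", "ica", "srm", "out")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop(sprintf("config error at '%s': unknown field", bad[1]))
  stages <- cfg$stages %||% c("simulate", "homotopy")
  allowed <- c("simulate", "homotopy", "ica", "srm")
  if (!all(stages %in% allowed))
    stop(sprintf("config error at 'stages': must be a subset of %s",
                 paste(allowed, collapse = ", ")))
  sim <- do.call(sim_config, as.list(cfg$sim %||% list()))
  if ("srm" %in% stages) {
    k <- cfg$srm$k %||% 10L
    if (k > sim$n_timepoints)
      stop("config error at 'srm.k': k exceeds timepoints per movie")
    if (sim$n_participants < 3L)
      stop("config error at 'srm': need at least 3 participants")
  }
  list(stages = stages, sim = sim,
       homotopy = cfg$homotopy %||% list(), ica = cfg$ica %||% list(),
       srm = cfg$srm %||% list(), out = cfg$out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline from a configuration
#'
#' Executes the requested stages — `simulate` (always implied), `homotopy`,
#' `ica`, `srm` — and assembles a JSON-serializable report carrying every
#' statistic and every seed. The configuration is schema-checked before any
#' computation; errors name the offending field.
#'
#' @param config a list, or a path to a YAML or JSON configuration file with
#'   fields `stages`, `sim` (arguments of [sim_config()]), `homotopy`
#'   (`n_boot`, `control_motion`), `ica` (`n_components`, `thresholds`),
#'   `srm` (`k`, `n_boot`, `jitter_scale`), `out` (optional report path).
#' @param out optional path for the JSON report (overrides `config$out`).
#' @return The report list, invisibly when written to file.
#' @export
run_pipeline <- function(config = list(), out = NULL) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  cfg <- validate_pipeline_config(config)
  out <- out %||% cfg$out
  seed <- cfg$sim$seed
  study <- simulate_study(cfg$sim)
  report <- list(config = unclass(cfg$sim), stages = cfg$stages,
                 seeds = list(master = seed,
                              participants = vapply(study$recordings, `[[`,
                                                    integer(1), "seed")))
  if ("homotopy" %in% cfg$stages) {
    hb <- cfg$homotopy$n_boot %||% 10000L
    hom <- run_homotopy(study$recordings, study$sheet,
                        control_motion = isTRUE(cfg$homotopy$control_motion),
                        n_boot = hb, seed = child_seed(seed, 21L))
    mean_con <- function(f) mean(vapply(hom$contrasts, `[[`, numeric(1), f),
                                 na.rm = TRUE)
    report$homotopy <- list(
      r_same_area_same_stream = mean_con("r_same_area_same_stream"),
      r_same_area_cross_stream = mean_con("r_same_area_cross_stream"),
      r_adjacent_same_stream = mean_con("r_adjacent_same_stream"),
      r_distal_same_stream = mean_con("r_distal_same_stream"),
      tests = lapply(hom$tests, unclass))
    emb <- mds_of_group_matrix(hom$matrices, seed = child_seed(seed, 22L))
    report$homotopy$mds <- list(stress = emb$stress,
                                silhouette = emb$silhouette)
  }
  if ("ica" %in% cfg$stages) {
    nc <- cfg$ica$n_components %||% 20L
    lines_par <- trace_gradient_lines(study$sheet, "parallel")
    evals <- lapply(seq_along(study$recordings), function(i) {
      comp <- spatial_ica(study$recordings[[i]], n_components = nc,
                          seed = child_seed(seed, 300L + i))
      scores <- vapply(seq_len(ncol(comp$maps)), function(j)
        score_component(comp$maps[, j], study$maps$spatial_frequency,
                        lines_par, absolute = TRUE), numeric(1))
      sel <- auto_select_candidates(comp, study$sheet)
      list(best_sf_corr = max(scores),
           percentile = rank_component_percentile(scores, sel$sf))
    })
    report$ica <- list(
      mean_best_sf_corr = mean(vapply(evals, `[[`, numeric(1), "best_sf_corr")),
      mean_sf_percentile = mean(vapply(evals, `[[`, numeric(1), "percentile"),
                                na.rm = TRUE))
  }
  if ("srm" %in% cfg$stages) {
    loo <- leave_one_out_experiment(
      study$recordings, study$sheet, study$maps,
      k = cfg$srm$k %||% 10L,
      jitter_scale = cfg$srm$jitter_scale %||% 0,
      n_boot = cfg$srm$n_boot %||% 2000L, seed = child_seed(seed, 400L))
    pp <- loo$per_participant
    sf <- pp[pp$field == "spatial_frequency", ]
    report$srm <- list(mean_real = mean(sf$real),
                       mean_flipped = mean(sf$flipped),
                       mean_anatomical = mean(sf$anatomical),
                       tests = lapply(loo$tests$spatial_frequency, unclass))
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}
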