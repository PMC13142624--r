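# End-to-end pipeline: per-tubule parallel tracking with a file-based
# human-in-the-loop queue. Tubules are independent (no shared mutable
# state), so a k-worker run equals the serial run track for track.

#' Read / write seed files (JSON lines)
#'
#' One record per tubule: `{"id": ..., "seed1_zyx_um": [z,y,x],
#' "seed2_zyx_um": [z,y,x], "stop_points": [[z,y,x], ...]}`.
#'
#' @param path file path.
#' @return `readSeeds`: a list of seed records.
#' @export
readSeeds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

#' @rdname readSeeds
#' @param seeds list of seed records.
#' @export
writeSeeds <- function(seeds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in seeds)
    writeLines(jsonlite::toJSON(s, auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' Read corrections (JSON lines)
#'
#' One record per correction: `{"track_id": ..., "points_zyx_um":
#' [[z,y,x], ...], "resume": true}`.
#'
#' @param path file path (may not exist: empty list).
#' @return list of correction records.
#' @export
readCorrections <- function(path) {
  if (!file.exists(path)) return(list())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, function(l) jsonlite::fromJSON(l, simplifyVector = TRUE))
}

trackToJson <- function(track, path) {
  jsonlite::write_json(list(
    id = track@id, status = track@status,
    seeds = track@seeds, nodes = track@nodes,
    flags = track@flags,
    interventions = length(track@interventionLog)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the tracking pipeline over a seeds file
#'
#' Tracks every seeded tubule (one worker per tubule when `workers` > 1),
#' writes per-track centerline JSON plus a flag queue, and resumes flagged
#' tracks from a corrections file on re-runs. Finished tracks are not
#' recomputed on re-run, so the pipeline is idempotent once all flags are
#' resolved.
#'
#' @param volume a [VoxelGrid-class], or a path readable by [loadVolume()].
#' @param seeds a seeds list (see [readSeeds()]) or a seeds file path.
#' @param config a [TrackingConfig-class].
#' @param models segmentation model suite.
#' @param outDir output directory.
#' @param workers worker count (forked via the parallel package).
#' @param correctionsPath optional corrections JSONL file.
#' @return list(tracks = list of [Track-class], flags = data.frame); exit
#'   status is reflected in attribute "unresolvedFlags".
#' @export
runPipeline <- function(volume, seeds, config = trackingConfig(),
                        models = list(segmentationModel("wall")),
                        outDir, workers = 1, correctionsPath = NULL) {
  if (is.character(volume)) {
    if (!file.exists(file.path(volume, "meta.json")) && !dir.exists(volume))
      stop("volume path '", volume, "' does not exist")
    volume <- loadVolume(volume)
  }
  if (is.character(seeds)) {
    if (!file.exists(seeds)) stop("seeds file '", seeds, "' does not exist")
    seeds <- readSeeds(seeds)
  }
  dir.create(file.path(outDir, "tracks"), showWarnings = FALSE,
             recursive = TRUE)
  corrections <- if (is.null(correctionsPath)) list()
                 else readCorrections(correctionsPath)
  corrById <- setNames(corrections,
                       vapply(corrections, `[[`, "", "track_id"))
  finished <- c("complete", "terminated_boundary", "terminated_merge")
  runOne <- function(sd) {
    id <- as.character(sd$id)
    rdsPath <- file.path(outDir, "tracks", paste0(id, ".rds"))
    prev <- if (file.exists(rdsPath)) readRDS(rdsPath) else NULL
    # finished tracks are never recomputed; corrections only apply to
    # flagged ones
    if (!is.null(prev) && prev@status %in% finished) return(prev)
    stopPts <- if (!is.null(sd$stop_points) && length(sd$stop_points) > 0)
      matrix(unlist(sd$stop_points), ncol = 3, byrow = !is.matrix(sd$stop_points))
    else NULL
    if (!is.null(prev) && prev@status == "flagged" && id %in% names(corrById)) {
      cr <- corrById[[id]]
      pts <- matrix(unlist(cr$points_zyx_um), ncol = 3,
                    byrow = !is.matrix(cr$points_zyx_um))
      tr <- applyCorrection(prev, pts,
                            resume = isTRUE(cr$resume), volume = volume,
                            config = config, models = models,
                            stopPoints = stopPts)
    } else {
      # deterministic per-track seed derived from (global seed, track id)
      set.seed((config@rngSeed + sum(utf8ToInt(id))) %% .Machine$integer.max)
      tr <- trackTubule(volume,
                        rbind(as.numeric(sd$seed1_zyx_um),
                              as.numeric(sd$seed2_zyx_um)),
                        config, models, stopPoints = stopPts, id = id)
    }
    tr
  }
  tracks <- if (workers > 1) {
    parallel::mclapply(seeds, runOne, mc.cores = workers, mc.preschedule = FALSE)
  } else lapply(seeds, runOne)
  flags <- emptyFlags()
  for (tr in tracks) {
    rdsPath <- file.path(outDir, "tracks", paste0(tr@id, ".rds"))
    jsonPath <- file.path(outDir, "tracks", paste0(tr@id, ".json"))
    prevIdentical <- file.exists(rdsPath) && {
      prev <- readRDS(rdsPath)
      identical(prev@nodes, tr@nodes) && identical(prev@status, tr@status)
    }
    if (!prevIdentical) {
      saveRDS(tr, rdsPath)
      trackToJson(tr, jsonPath)
    }
    flags <- rbind(flags, tr@flags)
  }
  flagPath <- file.path(outDir, "flags.jsonl")
  con <- file(flagPath, "w")
  for (i in seq_len(nrow(flags)))
    writeLines(jsonlite::toJSON(as.list(flags[i, ]), auto_unbox = TRUE,
                                digits = NA), con)
  close(con)
  out <- list(tracks = tracks, flags = flags)
  attr(out, "unresolvedFlags") <- nrow(flags)
  out
}

#' Export a morphometric profile as CSV
#'
#' Columns: arc_length_um, diameter_um, curvature_per_um, torsion_per_um.
#'
#' @param profile data.frame from [morphometricProfiles()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProfileCsv <- function(profile, path) {
  out <- data.frame(arc_length_um = profile$s,
                    diameter_um = profile$diameter,
                    curvature_per_um = profile$curvature,
                    torsion_per_um = profile$torsion)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a YAML tracking configuration
#'
#' Recognised keys mirror [trackingConfig()] arguments.
#'
#' @param path YAML file.
#' @return A [TrackingConfig-class].
#' @export
readTrackingConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(trackingConfig))
  y <- y[intersect(names(y), known)]
  do.call(trackingConfig, y)
}
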