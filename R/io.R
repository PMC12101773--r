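# Serialization: one CSV per participant (a row per round) plus a JSON
# metadata sidecar carrying the generating model, parameters and seeds, so
# cohorts round-trip losslessly for downstream recovery scoring.

#' Write a participant dataset to disk
#'
#' @param dataset A `participant_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the CSV path.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, dataset$participant_id)
  write.csv(dataset$rounds, paste0(base, ".csv"), row.names = FALSE)
  meta <- list(
    participant_id = dataset$participant_id,
    experiment_id = dataset$experiment_id,
    config_seed = dataset$config$rng_seed,
    metadata = dataset$metadata
  )
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(paste0(base, ".csv"))
}

#' Read a participant dataset written by [write_dataset()]
#'
#' The task configuration is reconstructed deterministically from the
#' experiment id and the stored schedule seed.
#'
#' @param csv_path Path to the per-participant CSV.
#' @return A `participant_dataset`.
#' @export
read_dataset <- function(csv_path) {
  rounds <- read.csv(csv_path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", csv_path),
                              simplifyVector = TRUE)
  config <- make_experiment_config(meta$experiment_id,
                                   seed = meta$config_seed)
  rounds$probe_response[rounds$probe_response == ""] <- NA
  structure(
    list(participant_id = meta$participant_id,
         experiment_id = meta$experiment_id,
         rounds = rounds, config = config,
         metadata = meta$metadata),
    class = "participant_dataset"
  )
}

#' Write a game configuration to a human-readable file
#'
#' YAML with the experiment id, suit table, block table and probe interval;
#' [read_config()] restores an identical `game_config`.
#'
#' @param config A `game_config`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "game_config"))
  yaml::write_yaml(list(
    experiment_id = config$experiment_id,
    rng_seed = config$rng_seed,
    probe_interval = config$probe_interval,
    suits = config$suits,
    blocks = config$blocks
  ), path, column.major = FALSE, precision = 12L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  structure(
    list(experiment_id = x$experiment_id,
         suits = do.call(rbind, lapply(x$suits, as.data.frame)),
         blocks = do.call(rbind, lapply(x$blocks, as.data.frame)),
         probe_interval = as.integer(x$probe_interval),
         rng_seed = x$rng_seed),
    class = "game_config"
  )
}

#' Write a cohort with a manifest
#'
#' @param cohort List of `participant_dataset` objects.
#' @param dir Output directory.
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  paths <- vapply(cohort, write_dataset, character(1), dir = dir)
  manifest <- list(n_participants = length(cohort),
                   files = basename(paths))
  mp <- file.path(dir, "cohort_manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE)
  invisible(mp)
}
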