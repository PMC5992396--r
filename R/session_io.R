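#' Write a simulated session to a directory
#'
#' Lays out one session as plain-text files: `eeg.tsv` (one column per
#' channel, header = channel labels, one row per 500 Hz sample), `emg.tsv`,
#' `vehicular.tsv` (`LIGHT`, `BRAKE` at 50 Hz), `events.tsv` (the ground
#' truth event table) and `meta.json` (rates, ids, seed). The serialisation
#' is canonical: writing a session that was read back produces byte-identical
#' files.
#'
#' @param session a [simulate_session()] object.
#' @param directory output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_session <- function(session, directory) {
  stopifnot(inherits(session, "braking_session"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(directory,
                     c("eeg.tsv", "emg.tsv", "vehicular.tsv",
                       "events.tsv", "meta.json"))
  eeg <- as.data.frame(t(session$eeg))
  data.table::fwrite(eeg, paths[1], sep = "\t")
  data.table::fwrite(data.frame(EMG = session$emg), paths[2], sep = "\t")
  data.table::fwrite(data.frame(LIGHT = session$light,
                                BRAKE = sprintf("%.2f", session$brake)),
                     paths[3], sep = "\t")
  data.table::fwrite(session$truth, paths[4], sep = "\t")
  meta <- list(fs_bio = session$fs_bio, fs_veh = session$fs_veh,
               participant_id = session$participant_id,
               session_id = session$session_id,
               seed = session$seed,
               channels = rownames(session$eeg),
               block_intervals = session$block_intervals)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), paths[5])
  invisible(paths)
}

#' Read a session directory written by [write_session()]
#'
#' @param directory session directory.
#' @return a `braking_session` object. Vehicular channels are recovered
#'   exactly; bio-signals to the precision of the text representation.
#' @export
read_session <- function(directory) {
  need <- c("eeg.tsv", "emg.tsv", "vehicular.tsv", "events.tsv", "meta.json")
  for (f in need) {
    if (!file.exists(file.path(directory, f))) {
      stop("missing_session_file: '", f, "' not found in ", directory)
    }
  }
  meta <- jsonlite::fromJSON(file.path(directory, "meta.json"))
  eeg <- data.table::fread(file.path(directory, "eeg.tsv"), sep = "\t")
  emg <- data.table::fread(file.path(directory, "emg.tsv"), sep = "\t")
  veh <- data.table::fread(file.path(directory, "vehicular.tsv"), sep = "\t")
  truth <- as.data.frame(data.table::fread(file.path(directory, "events.tsv"),
                                           sep = "\t"))
  eeg <- t(as.matrix(eeg))
  rownames(eeg) <- meta$channels
  structure(list(eeg = eeg, emg = as.numeric(emg$EMG),
                 light = as.numeric(veh$LIGHT),
                 brake = as.numeric(veh$BRAKE),
                 fs_bio = meta$fs_bio, fs_veh = meta$fs_veh,
                 truth = truth,
                 block_intervals = as.data.frame(meta$block_intervals),
                 participant_id = meta$participant_id,
                 session_id = meta$session_id,
                 seed = meta$seed,
                 signal_model = NULL),
            class = "braking_session")
}
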