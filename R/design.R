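#' Build an experimental design for one synthetic participant
#'
#' The default design mirrors the study protocol: 4 driving sessions (two
#' "morning", two "afternoon") of 8 blocks each, every block holding 15
#' emergency-braking events of a single experimental combination. Morning
#' sessions draw their blocks from the no-fatigue combinations
#' (`C_o`, `C_s`, `C_w`, `C_s+w`), afternoon sessions from the fatigue
#' combinations (`C_f`, `C_s+f`, `C_w+f`, `C_s+w+f`); each eligible
#' combination fills exactly two blocks per session, and the block order is
#' pseudo-random per session. Under the defaults this yields
#' 4 x 8 x 15 = 480 events per participant, 60 per combination.
#'
#' Consecutive stimuli within a block are separated by the 3 s brake-light-on
#' interval plus a uniform draw from `iei_range` measured from light-off.
#'
#' @param seed integer seed; the same seed always returns the same schedule.
#' @param n_sessions number of sessions (first half morning, second half
#'   afternoon).
#' @param blocks_per_session blocks per session. When not a multiple of 4 the
#'   four eligible combinations are allocated as evenly as possible.
#' @param events_per_block braking events per block.
#' @param iei_range uniform range (seconds) of the inter-event interval,
#'   measured from brake-light-off to the next stimulus.
#' @param light_duration_s how long the guide vehicle's brake lights stay on.
#' @param block_gap_s quiet gap between consecutive blocks (seconds).
#' @param lead_in_s quiet lead-in before the first block (seconds).
#' @return an object of class `braking_design`: the parameters above plus
#'   `schedule`, a list with one character vector of combination codes per
#'   session.
#' @export
#' @examples
#' d <- make_design(seed = 1)
#' total_events(d)  # 480
make_design <- function(seed,
                        n_sessions = 4L,
                        blocks_per_session = 8L,
                        events_per_block = 15L,
                        iei_range = c(5, 20),
                        light_duration_s = 3,
                        block_gap_s = 10,
                        lead_in_s = 15) {
  stopifnot(length(seed) == 1L, is.numeric(seed), seed >= 0,
            n_sessions >= 1L, blocks_per_session >= 1L,
            events_per_block >= 1L,
            length(iei_range) == 2L, iei_range[1] > 0,
            iei_range[2] >= iei_range[1])
  n_sessions <- as.integer(n_sessions)
  blocks_per_session <- as.integer(blocks_per_session)
  events_per_block <- as.integer(events_per_block)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(seed, "design"))

  n_morning <- ceiling(n_sessions / 2)
  schedule <- vector("list", n_sessions)
  for (s in seq_len(n_sessions)) {
    eligible <- if (s <= n_morning) MORNING_CONDITIONS else AFTERNOON_CONDITIONS
    pool <- rep(eligible, length.out = max(blocks_per_session,
                                           length(eligible)))
    pool <- pool[seq_len(blocks_per_session)]
    if (blocks_per_session %% length(eligible) == 0L) {
      pool <- rep(eligible, blocks_per_session / length(eligible))
    }
    schedule[[s]] <- sample(pool)
  }

  structure(list(n_sessions = n_sessions,
                 blocks_per_session = blocks_per_session,
                 events_per_block = events_per_block,
                 iei_range = iei_range,
                 light_duration_s = light_duration_s,
                 block_gap_s = block_gap_s,
                 lead_in_s = lead_in_s,
                 seed = as.integer(seed),
                 schedule = schedule),
            class = "braking_design")
}

#' Total number of braking events a design prescribes
#' @param design a `braking_design`.
#' @return integer event count (sessions x blocks x events per block).
#' @export
total_events <- function(design) {
  stopifnot(inherits(design, "braking_design"))
  design$n_sessions * design$blocks_per_session * design$events_per_block
}

#' @export
print.braking_design <- function(x, ...) {
  cat("Experimental design:", x$n_sessions, "session(s) x",
      x$blocks_per_session, "block(s) x", x$events_per_block,
      "events =", total_events(x), "braking events\n")
  for (s in seq_along(x$schedule)) {
    cat(sprintf("  session %d: %s\n", s,
                paste(x$schedule[[s]], collapse = " ")))
  }
  invisible(x)
}

# Save/restore the global RNG state so seeded package functions do not
# disturb the caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) {
    assign(".Random.seed", old, envir = globalenv())
  }
}
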