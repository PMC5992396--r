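#' Extract the three 1.5 s epoch types from kept data segments
#'
#' For every kept segment (valid event) three EEG epochs of exactly 1.5 s
#' (375 samples at 250 Hz) are cut from the continuous recording:
#' \describe{
#'   \item{pre_response}{`[-1.5, 0]` s relative to the response -- the
#'     braking-intention class;}
#'   \item{post_stimulus}{`[0, 1.5]` s relative to the stimulus -- used by
#'     the behavioural analyses only;}
#'   \item{non_braking}{a quiet window more than `exclusion_s` (3 s) from
#'     every stimulus and response -- the normal-driving class.}
#' }
#' Non-braking epochs are placed deterministically: for each event the wider
#' of the quiet intervals before/after it is chosen (unless already used by
#' a neighbouring event) and the epoch is centred on its midpoint. Events
#' for which no admissible quiet window exists are skipped with a logged
#' reason, and [build_dataset()] later drops their pre-response partners to
#' keep the classes balanced.
#'
#' @param recording the filtered, referenced `braking_recording`.
#' @param segments kept segments from [reject_segments()].
#' @param exclusion_s minimum distance of a non-braking epoch from any
#'   stimulus or response, seconds.
#' @param length_s epoch length, seconds.
#' @return list of class `braking_epochs`: each element has `eeg`
#'   (7 x 375), `emg`, `kind`, `t_start` (seconds), and `event` (row in the
#'   event table). Attribute `skipped` logs unplaceable non-braking epochs.
#' @export
extract_epochs <- function(recording, segments, exclusion_s = 3,
                           length_s = 1.5) {
  stopifnot(inherits(recording, "braking_recording"),
            inherits(segments, "braking_segments"))
  events <- attr(segments, "events")
  fs <- recording$fs
  n_len <- round(length_s * fs)
  T <- ncol(recording$eeg)
  if (T < n_len) stop("recording_too_short: cannot fit a single epoch")

  cut_epoch <- function(start_s, kind, event) {
    s0 <- round(start_s * fs) + 1L
    if (s0 < 1L || s0 + n_len - 1L > T) return(NULL)
    keep <- s0:(s0 + n_len - 1L)
    list(eeg = recording$eeg[, keep, drop = FALSE],
         emg = recording$emg[keep],
         kind = kind, t_start = (s0 - 1) / fs, event = event)
  }

  # anchors every non-braking epoch must stay clear of: all stimuli plus
  # every detected response (invalid events still flashed their lights)
  anchors <- sort(c(events$stimulus_time_s,
                    events$response_time_s[!is.na(events$response_time_s)]))
  end_s <- (T - 1) / fs

  epochs <- list()
  skipped <- data.frame(event = integer(), reason = character())
  used_gaps <- integer(0)  # index of the anchor opening each used gap

  for (seg in segments) {
    i <- seg$event
    stim <- events$stimulus_time_s[i]
    resp <- events$response_time_s[i]
    pre <- cut_epoch(resp - length_s, "pre_response", i)
    post <- cut_epoch(stim, "post_stimulus", i)

    # candidate quiet gaps: between this event and its neighbours
    gap_window <- function(lo_anchor, hi_anchor) {
      lo <- lo_anchor + exclusion_s
      hi <- hi_anchor - exclusion_s - length_s
      c(lo, hi)
    }
    k <- findInterval(stim, anchors)  # anchors[k] <= stim
    after_lo <- resp
    after_hi <- if (k + 2 <= length(anchors)) anchors[k + 2] else end_s
    before_hi <- stim
    before_lo <- if (k - 1 >= 1) anchors[k - 1] else 0
    cand <- list(after = c(id = k + 1L, gap_window(after_lo, after_hi)),
                 before = c(id = k - 1L, gap_window(before_lo, before_hi)))
    widths <- vapply(cand, function(z) z[3] - z[2], numeric(1))
    nb <- NULL
    for (j in order(widths, decreasing = TRUE)) {
      z <- cand[[j]]
      if (z[3] < z[2] || z[1] %in% used_gaps) next
      mid <- (z[2] + z[3]) / 2
      nb <- cut_epoch(mid, "non_braking", i)
      if (!is.null(nb)) { used_gaps <- c(used_gaps, z[1]); break }
    }
    if (!is.null(pre)) epochs[[length(epochs) + 1L]] <- pre
    if (!is.null(post)) epochs[[length(epochs) + 1L]] <- post
    if (!is.null(nb)) {
      epochs[[length(epochs) + 1L]] <- nb
    } else {
      skipped <- rbind(skipped, data.frame(
        event = i, reason = "no admissible quiet window for non-braking epoch"))
    }
  }
  structure(epochs, class = "braking_epochs", skipped = skipped,
            events = events, fs = fs)
}

# Deterministic partition of n samples into k consecutive windows whose
# boundaries are floor(j * n / k + 0.5): for 375 samples and 10 windows the
# sizes alternate 38/37.
window_boundaries <- function(n, k) {
  floor(seq_len(k) * n / k + 0.5)
}

#' Convert one epoch into a 7 x 10 time-domain feature map
#'
#' Each channel's 1.5 s trace is divided into 10 consecutive non-overlapping
#' 150 ms intervals and the arithmetic mean of each interval is one feature.
#' Since 150 ms at 250 Hz is 37.5 samples, the deterministic partition
#' alternates 38- and 37-sample windows (boundaries at
#' `floor(j * 375 / 10 + 0.5)`). Pre-response epochs are labelled `+1`
#' (braking intention), non-braking epochs `-1` (normal driving);
#' post-stimulus epochs yield an unlabelled map (`NA`).
#'
#' @param epoch one element of [extract_epochs()].
#' @param n_intervals number of intervals (default 10).
#' @return list of class `braking_feature_map` with `X` (7 x 10 matrix),
#'   `x` (length-70 vector, channel-major row-wise flattening), `label`,
#'   `kind` and `event`.
#' @export
epoch_to_feature_map <- function(epoch, n_intervals = 10) {
  n <- ncol(epoch$eeg)
  if (is.null(n) || n != 375L) {
    stop("bad_epoch_length: expected 375 samples (1.5 s at 250 Hz), got ", n)
  }
  bounds <- window_boundaries(n, n_intervals)
  starts <- c(1L, head(bounds, -1) + 1L)
  X <- vapply(seq_len(n_intervals), function(j)
    rowMeans(epoch$eeg[, starts[j]:bounds[j], drop = FALSE]),
    numeric(nrow(epoch$eeg)))
  dimnames(X) <- list(rownames(epoch$eeg), NULL)
  label <- switch(epoch$kind,
                  pre_response = 1, non_braking = -1, NA_real_)
  structure(list(X = X, x = as.vector(t(X)), label = label,
                 kind = epoch$kind, event = epoch$event),
            class = "braking_feature_map")
}

#' Assemble a balanced labelled dataset from epochs
#'
#' Takes the pre-response (+1) and non-braking (-1) feature maps, keeps only
#' events that contributed both kinds (so the classes stay exactly
#' balanced), and stacks them in deterministic event order.
#'
#' @param epochs a [extract_epochs()] list, or a list of such lists (e.g.
#'   one per session); `participant` and `session` label the provenance.
#' @param participant participant id recorded per instance.
#' @param session session id(s), one per epochs list.
#' @return object of class `braking_dataset`: `x` (n x 70 matrix), `y`
#'   (+1/-1), and `meta` (participant, session, event, kind per row).
#' @export
build_dataset <- function(epochs, participant = "p01", session = 1L) {
  if (inherits(epochs, "braking_epochs")) epochs <- list(epochs)
  stopifnot(length(session) == length(epochs))
  xs <- list(); ys <- numeric(0)
  meta <- data.frame(participant = character(), session = integer(),
                     event = integer(), kind = character(),
                     stringsAsFactors = FALSE)
  for (li in seq_along(epochs)) {
    ep <- epochs[[li]]
    kinds <- vapply(ep, `[[`, "", "kind")
    evs <- vapply(ep, `[[`, 0L, "event")
    pre_ev <- evs[kinds == "pre_response"]
    nb_ev <- evs[kinds == "non_braking"]
    both <- intersect(pre_ev, nb_ev)
    for (i in seq_along(ep)) {
      if (!(ep[[i]]$kind %in% c("pre_response", "non_braking"))) next
      if (!(ep[[i]]$event %in% both)) next
      fm <- epoch_to_feature_map(ep[[i]])
      xs[[length(xs) + 1L]] <- fm$x
      ys <- c(ys, fm$label)
      meta <- rbind(meta, data.frame(participant = participant,
                                     session = session[li],
                                     event = ep[[i]]$event,
                                     kind = ep[[i]]$kind,
                                     stringsAsFactors = FALSE))
    }
  }
  if (!length(xs)) stop("empty_dataset: no usable labelled epochs")
  ord <- order(meta$session, meta$event, meta$kind)
  x <- do.call(rbind, xs)[ord, , drop = FALSE]
  colnames(x) <- paste0("f", seq_len(ncol(x)))
  structure(list(x = x, y = ys[ord], meta = meta[ord, , drop = FALSE]),
            class = "braking_dataset")
}

#' @export
print.braking_dataset <- function(x, ...) {
  cat(sprintf(paste0("Labelled dataset: %d instances x %d features ",
                     "(%d braking intention, %d normal driving)\n"),
              nrow(x$x), ncol(x$x), sum(x$y == 1), sum(x$y == -1)))
  invisible(x)
}

#' Merge several labelled datasets
#' @param ... `braking_dataset` objects (or a single list of them).
#' @return a `braking_dataset` with rows concatenated.
#' @export
merge_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && !inherits(ds[[1]], "braking_dataset")) ds <- ds[[1]]
  structure(list(x = do.call(rbind, lapply(ds, `[[`, "x")),
                 y = unlist(lapply(ds, `[[`, "y")),
                 meta = do.call(rbind, lapply(ds, `[[`, "meta"))),
            class = "braking_dataset")
}

#' Write a dataset to `features.tsv`
#'
#' One row per instance: participant, session, event, label, then `f1..f70`
#' in channel-major order (channel 1 intervals 1..10, channel 2 intervals
#' 1..10, ...).
#'
#' @param dataset a `braking_dataset`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_features <- function(dataset, path) {
  df <- cbind(dataset$meta[, c("participant", "session", "event")],
              label = dataset$y, as.data.frame(dataset$x))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a `features.tsv` written by [write_features()]
#' @param path file path.
#' @return a `braking_dataset`.
#' @export
read_features <- function(path) {
  df <- as.data.frame(data.table::fread(path, sep = "\t"))
  fcols <- grep("^f[0-9]+$", names(df))
  structure(list(x = as.matrix(df[, fcols]),
                 y = df$label,
                 meta = df[, c("participant", "session", "event")]),
            class = "braking_dataset")
}
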