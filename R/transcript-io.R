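# Transcript serialization: a flat CSV of recall events (one row per event,
# several groups per file) and a JSON variant that additionally embeds study
# orders. The CSV schema also admits `pass` and `stop` actions so empirical
# chatroom exports can be read; the simulator itself only emits `recall`.

.transcript_cols <- c("condition", "group_id", "group_size", "round", "turn",
                      "agent", "action", "item", "novel")

#' Write group transcripts to CSV
#'
#' @param transcripts A list of `group_transcript` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_transcripts_csv <- function(transcripts, path) {
  if (inherits(transcripts, "group_transcript")) transcripts <- list(transcripts)
  rows <- lapply(seq_along(transcripts), function(g) {
    t <- transcripts[[g]]
    stopifnot(inherits(t, "group_transcript"))
    ev <- t$events
    if (nrow(ev) == 0L) return(NULL)
    data.frame(condition = t$condition, group_id = g,
               group_size = t$group_size, round = ev$round, turn = ev$turn,
               agent = ev$agent, action = ev$action, item = ev$item,
               novel = ev$novel, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(.transcript_cols)),
                                  .transcript_cols))
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read group transcripts from CSV
#'
#' Reconstructs one `group_transcript` per `group_id`. Study orders and
#' context trajectories are not representable in the flat CSV; use the JSON
#' variant to round-trip those.
#'
#' @param path CSV path with columns `condition, group_id, group_size, round,
#'   turn, agent, action, item, novel`.
#' @param list_length List length L (items are indices `1:L`).
#' @return A list of `group_transcript` objects.
#' @export
read_transcripts_csv <- function(path, list_length) {
  if (!file.exists(path)) stop_arg("transcript file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.transcript_cols, names(df))
  if (length(missing) > 0L) {
    stop_arg("transcript CSV missing column(s): %s", paste(missing, collapse = ", "))
  }
  list_length <- check_count(list_length, "list_length")
  lapply(split(df, df$group_id), function(g) {
    ev <- data.frame(round = as.integer(g$round), turn = as.integer(g$turn),
                     agent = as.integer(g$agent), action = as.character(g$action),
                     item = as.integer(g$item), novel = as.logical(g$novel),
                     stringsAsFactors = FALSE)
    new_group_transcript(g$condition[[1L]], g$group_size[[1L]], list_length,
                         ev, study_orders = NULL, trajectories = NULL,
                         stop_round = NULL)
  })
}

#' Write / read a single transcript as JSON (with study orders)
#'
#' The JSON variant embeds the event table, per-agent study orders and,
#' optionally, the per-agent context trajectories, so it round-trips
#' everything the analyses need.
#'
#' @param transcript A `group_transcript`.
#' @param path JSON file path.
#' @param trajectories Whether to embed context trajectories (default TRUE).
#' @return `path` invisibly (writer); a `group_transcript` (reader).
#' @export
write_transcript_json <- function(transcript, path, trajectories = TRUE) {
  stopifnot(inherits(transcript, "group_transcript"))
  obj <- list(
    condition = transcript$condition,
    group_size = transcript$group_size,
    list_length = transcript$list_length,
    events = transcript$events,
    study_orders = transcript$study_orders,
    stop_round = transcript$stop_round
  )
  if (isTRUE(trajectories) && !is.null(transcript$trajectories)) {
    obj$trajectories <- transcript$trajectories
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transcript_json
#' @export
read_transcript_json <- function(path) {
  if (!file.exists(path)) stop_arg("transcript file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  ev <- as.data.frame(obj$events, stringsAsFactors = FALSE)
  if (nrow(ev) == 0L) ev <- empty_events()
  ev$round <- as.integer(ev$round); ev$turn <- as.integer(ev$turn)
  ev$agent <- as.integer(ev$agent); ev$item <- as.integer(ev$item)
  ev$novel <- as.logical(ev$novel); ev$action <- as.character(ev$action)
  orders <- if (!is.null(obj$study_orders)) {
    if (is.matrix(obj$study_orders)) {
      lapply(seq_len(nrow(obj$study_orders)), function(i) as.integer(obj$study_orders[i, ]))
    } else lapply(obj$study_orders, as.integer)
  }
  trajs <- if (!is.null(obj$trajectories)) {
    tr <- obj$trajectories
    if (is.array(tr) && length(dim(tr)) == 3L) {
      # jsonlite collapses a list of equal-shaped matrices into a 3-D array
      lapply(seq_len(dim(tr)[1L]), function(i) {
        m <- tr[i, , , drop = TRUE]; storage.mode(m) <- "double"; m
      })
    } else {
      lapply(tr, function(m) {
        m <- as.matrix(m); storage.mode(m) <- "double"; m
      })
    }
  }
  new_group_transcript(obj$condition, obj$group_size, obj$list_length, ev,
                       orders, trajs,
                       if (!is.null(obj$stop_round)) as.integer(obj$stop_round))
}
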