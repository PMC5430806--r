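#' Read a mote ping log
#'
#' Parses the `emitter,receiver,timestamp` CSV dialect (ISO-8601
#' timestamps). Ids are kept as character strings and never coerced to
#' numbers. Malformed rows -- unparseable timestamps, empty ids, or records
#' where the emitter equals the receiver (a mote cannot hear itself) -- are
#' rejected with a warning listing their row numbers.
#'
#' @param path path to the CSV file.
#' @return data frame `emitter, receiver, timestamp` (POSIXct, UTC).
#' @export
read_ping_log <- function(path) {
  if (!file.exists(path)) stop("ping log not found: ", path)
  raw <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  need <- c("emitter", "receiver", "timestamp")
  if (!all(need %in% names(raw))) {
    stop("ping log format error: missing column(s) ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  }
  if (nrow(raw) == 0) {
    warning("empty ping log: ", path)
    return(data.frame(emitter = character(0), receiver = character(0),
                      timestamp = .as_utc(character(0))))
  }
  ts <- .parse_iso(raw$timestamp)
  bad <- is.na(ts) | !nzchar(raw$emitter) | !nzchar(raw$receiver) |
    raw$emitter == raw$receiver
  if (any(bad)) {
    warning(sum(bad), " malformed ping row(s) rejected (rows ",
            paste(utils::head(which(bad), 20), collapse = ", "),
            if (sum(bad) > 20) ", ..." else "", ")")
  }
  out <- data.frame(emitter = raw$emitter[!bad], receiver = raw$receiver[!bad],
                    timestamp = ts[!bad], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' @rdname read_ping_log
#' @export
read_roster <- function(path) {
  r <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(id = "character"))
  r$id <- as.character(r$id)
  r
}

#' @rdname read_ping_log
#' @export
read_presence <- function(path) {
  p <- read.csv(path, colClasses = "character", stringsAsFactors = FALSE)
  need <- c("individual", "camp", "enter", "exit")
  if (!all(need %in% names(p))) {
    stop("presence format error: missing column(s) ",
         paste(setdiff(need, names(p)), collapse = ", "))
  }
  p$enter <- .parse_iso(p$enter)
  p$exit <- .parse_iso(p$exit)
  p
}

#' Apply timestamped mote swap corrections
#'
#' Field protocols record occasional mote swaps (`time,old_id,new_id`);
#' detections at or after the swap time carrying the old id are remapped to
#' the new id. Swaps are applied in time order.
#'
#' @param pings a ping-log data frame.
#' @param swaps data frame `time, old_id, new_id`; `time` may be character
#'   ISO-8601 or POSIXct.
#' @return the corrected ping log.
#' @export
apply_mote_swaps <- function(pings, swaps) {
  if (is.null(swaps) || nrow(swaps) == 0) return(pings)
  tm <- if (inherits(swaps$time, "POSIXct")) swaps$time else .parse_iso(swaps$time)
  for (k in order(tm)) {
    sel <- pings$timestamp >= tm[k]
    pings$emitter[sel & pings$emitter == swaps$old_id[k]] <- swaps$new_id[k]
    pings$receiver[sel & pings$receiver == swaps$old_id[k]] <- swaps$new_id[k]
  }
  pings
}

#' Restrict pings to the daytime observation window
#'
#' Keeps records whose slot start falls in `[window[1], window[2])` hours of
#' the day (default 05:00--20:00, the window used to avoid recording
#' co-sleeping overnight). The boundary is half-open: a 05:00 ping is kept,
#' a 20:00 ping is dropped. Record order is preserved.
#'
#' @param pings ping-log data frame.
#' @param window clock-hour pair.
#' @return filtered ping-log data frame.
#' @export
filter_daytime <- function(pings, window = c(5, 20)) {
  mod <- .minute_of_day(pings$timestamp)
  out <- pings[mod >= window[1] * 60 & mod < window[2] * 60, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse directed detections to dyad-slot events
#'
#' Reciprocal detections (A hears B and B hears A in the same slot) are one
#' interaction; by default a one-sided detection also counts, since radio
#' loss is asymmetric and reciprocity is not required. `mode = "reciprocal"`
#' keeps only slots detected in both directions.
#'
#' @param pings daytime-filtered ping-log data frame.
#' @param slot_minutes slot length in minutes.
#' @param mode `"one_sided"` (default) or `"reciprocal"`.
#' @return data frame `id_a, id_b, slot, slot_time` with `id_a < id_b` and
#'   at most one row per dyad per slot.
#' @export
collapse_to_dyad_slots <- function(pings, slot_minutes = 2,
                                   mode = c("one_sided", "reciprocal")) {
  mode <- match.arg(mode)
  if (nrow(pings) == 0) {
    return(data.frame(id_a = character(0), id_b = character(0),
                      slot = integer(0), slot_time = .as_utc(character(0))))
  }
  slot <- floor(as.numeric(pings$timestamp) / (60 * slot_minutes))
  a <- pmin(pings$emitter, pings$receiver)
  b <- pmax(pings$emitter, pings$receiver)
  key <- paste(a, b, slot, sep = "\r")
  if (mode == "one_sided") {
    keep <- !duplicated(key)
  } else {
    both <- tapply(pings$emitter, key, function(e) length(unique(e)) >= 2)
    keep <- !duplicated(key) & both[key]
  }
  out <- data.frame(
    id_a = a[keep], id_b = b[keep], slot = as.integer(slot[keep]),
    slot_time = as.POSIXct(slot[keep] * 60 * slot_minutes,
                           origin = "1970-01-01", tz = "UTC"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$slot, out$id_a, out$id_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Daytime co-presence hours for one dyad
#'
#' Total hours within the daytime window during which both individuals were
#' present in the same camp, by interval intersection. This is the exposure
#' denominator that adjusts raw contact counts for time present in camp.
#'
#' @param presence_i,presence_j presence data frames
#'   (`individual, camp, enter, exit`) for the two individuals.
#' @param window clock-hour pair.
#' @return nonnegative hours; 0 when the two were never in the same camp.
#' @export
dyad_overlap_hours <- function(presence_i, presence_j, window = c(5, 20)) {
  total <- 0
  for (ci in seq_len(nrow(presence_i))) {
    for (cj in seq_len(nrow(presence_j))) {
      if (presence_i$camp[ci] != presence_j$camp[cj]) next
      lo <- max(presence_i$enter[ci], presence_j$enter[cj])
      hi <- min(presence_i$exit[ci], presence_j$exit[cj])
      if (hi > lo) total <- total + .daytime_hours(lo, hi, window)
    }
  }
  total
}
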