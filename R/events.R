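# Unbinding/rebinding event detection from (r, z) collective-variable traces
# and front/back-door classification.

#' Detect unbinding and rebinding events in a CV trace
#'
#' Two-state machine over frames, starting in state IN (bound): in state IN
#' the first frame with `r >= r_unbind` emits an unbinding event and switches
#' to OUT; in state OUT the first frame with `r <= r_rebind` emits a
#' rebinding event and switches back to IN.  Because biased simulations expel
#' the ligand almost immediately, the first emitted unbinding event is
#' discarded by default and counting starts at the subsequent rebinding
#' event.  The door is front if z >= 0 at the event frame (z = 0 ties count
#' as front), back otherwise.
#'
#' @param trace a [new_cv_trace()] / [cv_trace()] object
#' @param r_unbind unbinding threshold, Angstrom (default 9)
#' @param r_rebind rebinding threshold, Angstrom (default 1); must be less
#'   than `r_unbind`.
#' @param skip_initial_unbind discard the first unbinding event and start
#'   counting at the next rebinding event (default TRUE).
#' @return data.frame of class `event_record`: `frame`, `time`, `kind`
#'   ("unbind"/"rebind"), `door` ("front"/"back"), `z_at_event`.
#' @export
detect_events <- function(trace, r_unbind = 9, r_rebind = 1,
                          skip_initial_unbind = TRUE) {
  stopifnot(r_rebind < r_unbind)
  r <- trace$r
  z <- trace$z
  times <- trace$times
  state <- "IN"
  frame <- integer(0)
  kind <- character(0)
  for (f in seq_along(r)) {
    if (state == "IN" && r[f] >= r_unbind) {
      frame <- c(frame, f)
      kind <- c(kind, "unbind")
      state <- "OUT"
    } else if (state == "OUT" && r[f] <= r_rebind) {
      frame <- c(frame, f)
      kind <- c(kind, "rebind")
      state <- "IN"
    }
  }
  if (skip_initial_unbind && length(kind) > 0L && kind[1] == "unbind") {
    frame <- frame[-1]
    kind <- kind[-1]
  }
  out <- data.frame(frame = frame, time = times[frame], kind = kind,
                    door = ifelse(z[frame] >= 0, "front", "back"),
                    z_at_event = z[frame], stringsAsFactors = FALSE)
  class(out) <- c("event_record", "data.frame")
  out
}

check_alternation <- function(events) {
  k <- events$kind
  if (length(k) < 2L) return(TRUE)
  all(k[-1] != k[-length(k)])
}

#' Tabulate unbinding/rebinding events across trajectories
#'
#' Sums event counts per label into the four door/kind cells.  Each
#' per-trajectory event list must strictly alternate between unbinding and
#' rebinding (guaranteed by [detect_events()]; externally supplied lists are
#' validated and rejected otherwise).
#'
#' @param event_lists list of event data.frames (from [detect_events()]),
#'   one per trajectory.
#' @param labels one label per trajectory (e.g. the ligand); trajectories
#'   sharing a label are pooled into one row.
#' @return data.frame of class `event_table`: `ligand`, `unbind_front`,
#'   `unbind_back`, `rebind_front`, `rebind_back`.
#' @export
tabulate_events <- function(event_lists, labels = NULL) {
  if (is.null(labels)) labels <- rep("all", length(event_lists))
  stopifnot(length(labels) == length(event_lists))
  for (i in seq_along(event_lists)) {
    if (!check_alternation(event_lists[[i]]))
      stop(sprintf(paste0("tabulate_events: trajectory %d violates the ",
                          "unbind/rebind alternation invariant"), i))
  }
  ulab <- unique(labels)
  if (length(ulab) == 0L) {
    out <- data.frame(ligand = character(), unbind_front = integer(),
                      unbind_back = integer(), rebind_front = integer(),
                      rebind_back = integer(), stringsAsFactors = FALSE)
    class(out) <- c("event_table", "data.frame")
    return(out)
  }
  rows <- lapply(ulab, function(lb) {
    ev <- do.call(rbind, event_lists[labels == lb])
    cnt <- function(k, d) {
      if (is.null(ev) || nrow(ev) == 0L) return(0L)
      sum(ev$kind == k & ev$door == d)
    }
    data.frame(ligand = lb,
               unbind_front = cnt("unbind", "front"),
               unbind_back = cnt("unbind", "back"),
               rebind_front = cnt("rebind", "front"),
               rebind_back = cnt("rebind", "back"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("event_table", "data.frame")
  out
}
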