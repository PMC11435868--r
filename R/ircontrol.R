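# NEC frame timing constants (microseconds)
NEC_LEADER_PULSE <- 9000
NEC_LEADER_SPACE <- 4500
NEC_BIT_PULSE <- 562.5
NEC_SPACE_0 <- 562.5
NEC_SPACE_1 <- 1687.5

IR_PROTOCOLS <- c("NEC", "SONY12", "SONY20", "RC5", "UNKNOWN_RAW")
IR_BIT_WIDTH <- c(NEC = 32L, SONY12 = 12L, SONY20 = 20L, RC5 = 14L)

#' One stored remote command
#'
#' A recorded IR command: either a known protocol with a bit payload of the
#' protocol's width (NEC 32 bits; Sony 12 or 20; RC5 14) or an unknown
#' protocol stored as raw alternating pulse/space tick durations in
#' microseconds. Some remotes resend the full code while a button is held,
#' others send a dedicated repeat symbol; that behaviour is recorded
#' per code.
#'
#' @param id Identifier string.
#' @param protocol One of `"NEC"`, `"SONY12"`, `"SONY20"`, `"RC5"`,
#'   `"UNKNOWN_RAW"`.
#' @param payload Non-negative integer-valued payload for known protocols
#'   (as a double; NEC payloads span the full 32-bit range).
#' @param ticks_us Raw tick durations for `UNKNOWN_RAW` (>= 2 values,
#'   alternating pulse/space, all > 0).
#' @param repeat_behaviour `"resend_code"` or `"dedicated_repeat_symbol"`.
#' @return An object of class `ir_code`.
#' @export
ir_code <- function(id, protocol, payload = NULL, ticks_us = NULL,
                    repeat_behaviour = c("resend_code",
                                         "dedicated_repeat_symbol")) {
  protocol <- match.arg(protocol, IR_PROTOCOLS)
  repeat_behaviour <- match.arg(repeat_behaviour)
  if (protocol == "UNKNOWN_RAW") {
    if (is.null(ticks_us) || length(ticks_us) < 2L || any(ticks_us <= 0)) {
      stop("raw codes need >= 2 positive tick durations", call. = FALSE)
    }
    payload <- NULL
  } else {
    width <- IR_BIT_WIDTH[[protocol]]
    if (is.null(payload) || payload < 0 || payload >= 2^width ||
        payload != floor(payload)) {
      stop(sprintf("%s payload must be an integer in [0, 2^%d)",
                   protocol, width), call. = FALSE)
    }
    ticks_us <- NULL
  }
  structure(list(id = id, protocol = protocol, payload = payload,
                 ticks_us = ticks_us, repeat_behaviour = repeat_behaviour),
            class = "ir_code")
}

payload_bits <- function(payload, width) {
  # MSB first; payload handled as double so 32-bit values are exact
  floor(payload / 2^((width - 1):0)) %% 2
}

bits_to_payload <- function(bits) {
  sum(bits * 2^((length(bits) - 1):0))
}

# hex <-> double; full 32-bit payloads exceed R's integer range
hex_to_double <- function(h) {
  h <- sub("^0[xX]", "", h)
  digits <- strtoi(strsplit(toupper(h), "")[[1]], base = 16L)
  Reduce(function(acc, d) acc * 16 + d, digits, accumulate = FALSE, 0)
}

double_to_hex <- function(x, width = 8L) {
  chars <- character(width)
  for (i in width:1) {
    chars[i] <- substr("0123456789ABCDEF", x %% 16 + 1, x %% 16 + 1)
    x <- x %/% 16
  }
  paste0("0x", paste(chars, collapse = ""))
}

#' Encode an NEC frame as pulse/space tick durations
#'
#' Standard NEC pulse-distance frame: 9000 us leader pulse, 4500 us leader
#' space, then 32 data bits MSB-first (562.5 us pulse followed by a 562.5 us
#' space for a 0 or a 1687.5 us space for a 1), closed by a trailing
#' 562.5 us pulse: 67 ticks in total.
#'
#' @param payload Integer-valued double in \[0, 2^32).
#' @return Numeric vector of 67 tick durations in microseconds.
#' @export
nec_encode <- function(payload) {
  if (length(payload) != 1L || !is.finite(payload) || payload < 0 ||
      payload >= 2^32 || payload != floor(payload)) {
    stop("payload must be an integer in [0, 2^32)", call. = FALSE)
  }
  bits <- payload_bits(payload, 32L)
  spaces <- ifelse(bits == 1, NEC_SPACE_1, NEC_SPACE_0)
  c(NEC_LEADER_PULSE, NEC_LEADER_SPACE,
    as.vector(rbind(rep(NEC_BIT_PULSE, 32L), spaces)),
    NEC_BIT_PULSE)
}

within_tol <- function(observed, nominal, tol) {
  abs(observed - nominal) <= tol * nominal
}

#' Decode NEC tick durations
#'
#' Matches the leader pair, then classifies each data bit by its space
#' duration, all within a relative timing tolerance. A frame that does not
#' match the NEC pattern returns `NULL` (decode failure, not an error) so
#' that the caller can fall through to raw recording.
#'
#' @param ticks Numeric vector of tick durations in microseconds.
#' @param tolerance Relative timing tolerance in (0, 0.5) (default 0.25).
#' @return The decoded payload (double), or `NULL` when the frame is not
#'   NEC within tolerance.
#' @export
nec_decode <- function(ticks, tolerance = 0.25) {
  if (tolerance <= 0 || tolerance >= 0.5) {
    stop("'tolerance' must be in (0, 0.5)", call. = FALSE)
  }
  if (length(ticks) != 67L || any(!is.finite(ticks)) || any(ticks <= 0)) {
    return(NULL)
  }
  if (!within_tol(ticks[1], NEC_LEADER_PULSE, tolerance) ||
      !within_tol(ticks[2], NEC_LEADER_SPACE, tolerance) ||
      !within_tol(ticks[67], NEC_BIT_PULSE, tolerance)) {
    return(NULL)
  }
  pulses <- ticks[seq(3L, 65L, by = 2L)]
  spaces <- ticks[seq(4L, 66L, by = 2L)]
  if (!all(within_tol(pulses, NEC_BIT_PULSE, tolerance))) return(NULL)
  is0 <- within_tol(spaces, NEC_SPACE_0, tolerance)
  is1 <- within_tol(spaces, NEC_SPACE_1, tolerance)
  if (!all(xor(is0, is1))) return(NULL)
  bits_to_payload(as.numeric(is1))
}

#' Classify a received tick sequence
#'
#' Attempts protocol decoding (NEC); sequences that match no known pattern
#' are kept verbatim as `UNKNOWN_RAW` codes, which can be stored and
#' replayed in raw form.
#'
#' @param ticks Tick durations in microseconds.
#' @param id Identifier for the resulting code.
#' @param tolerance Relative timing tolerance (default 0.25).
#' @return An [ir_code()]: protocol `"NEC"` with the decoded payload, or
#'   `"UNKNOWN_RAW"` carrying the ticks.
#' @export
ir_classify <- function(ticks, id = "code", tolerance = 0.25) {
  payload <- nec_decode(ticks, tolerance)
  if (!is.null(payload)) {
    ir_code(id, "NEC", payload = payload)
  } else {
    ir_code(id, "UNKNOWN_RAW", ticks_us = ticks)
  }
}

ticks_match <- function(a, b, tolerance) {
  length(a) == length(b) && all(abs(a - b) <= tolerance * pmax(a, b))
}

#' Verify repeated recordings of an unknown-protocol code
#'
#' Scrambled recordings (reflections, attenuation) are effectively random,
#' so agreement between independent recordings marks the true protocol
#' pattern. The modal group of tick-wise matching recordings is accepted
#' when it has at least two members; otherwise the set is rejected.
#'
#' @param recordings List of >= 2 raw tick sequences (microseconds).
#' @param tolerance Relative per-tick tolerance (default 0.25).
#' @param id Identifier for the accepted code.
#' @return An `UNKNOWN_RAW` [ir_code()] holding the element-wise mean of the
#'   agreeing recordings, or `NULL` when no two recordings agree.
#' @export
verify_unknown <- function(recordings, tolerance = 0.25, id = "code") {
  if (!is.list(recordings) || length(recordings) < 2L) {
    stop("need at least 2 recordings", call. = FALSE)
  }
  n <- length(recordings)
  agree <- diag(TRUE, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      agree[i, j] <- agree[j, i] <-
        ticks_match(recordings[[i]], recordings[[j]], tolerance)
    }
  }
  sizes <- rowSums(agree)
  best <- which.max(sizes)
  if (sizes[best] < 2L) return(NULL)
  members <- recordings[agree[best, ]]
  ticks <- Reduce(`+`, members) / length(members)
  ir_code(id, "UNKNOWN_RAW", ticks_us = ticks)
}

#' Gesture-to-IR-code map
#'
#' Many-to-many relation between gesture labels and stored code ids: one
#' gesture may drive several devices at once (synchronous teleoperation) and
#' several gestures may share a code for redundancy.
#'
#' @param mapping Named list: gesture label -> character vector of code ids.
#' @param store Named list of [ir_code()] objects (names = ids); every
#'   referenced id must exist.
#' @return An object of class `gesture_map`.
#' @export
gesture_map <- function(mapping, store) {
  stopifnot(is.list(mapping), is.list(store))
  referenced <- unique(unlist(mapping, use.names = FALSE))
  missing <- setdiff(referenced, names(store))
  if (length(missing)) {
    stop("mapping references unknown code id(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  structure(list(mapping = mapping, store = store), class = "gesture_map")
}

#' Virtual IR transmission bus
#'
#' Stand-in for the physical transmitter: an append-only log of
#' transmissions, optionally mirrored to a JSON-lines file.
#'
#' @param path Optional file path for a JSON-lines mirror of the log.
#' @return An object of class `ir_bus` (environment).
#' @export
ir_bus <- function(path = NULL) {
  e <- new.env(parent = emptyenv())
  e$log <- list()
  e$path <- path
  class(e) <- "ir_bus"
  e
}

bus_transmit <- function(bus, code, gesture, timestamp, note = "") {
  entry <- list(timestamp = timestamp, gesture = gesture, code_id = code$id,
                protocol = code$protocol,
                payload = if (!is.null(code$payload)) code$payload,
                note = note)
  bus$log[[length(bus$log) + 1L]] <- entry
  if (!is.null(bus$path)) {
    cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
        sep = "", file = bus$path, append = TRUE)
  }
  invisible(entry)
}

#' Transmissions recorded on a bus
#'
#' @param bus An [ir_bus()].
#' @return Data frame with one row per transmission (timestamp, gesture,
#'   code_id, protocol, note).
#' @export
bus_log <- function(bus) {
  stopifnot(inherits(bus, "ir_bus"))
  if (!length(bus$log)) {
    return(data.frame(timestamp = numeric(0), gesture = character(0),
                      code_id = character(0), protocol = character(0),
                      note = character(0)))
  }
  do.call(rbind, lapply(bus$log, function(e) {
    data.frame(timestamp = e$timestamp, gesture = e$gesture,
               code_id = e$code_id, protocol = e$protocol, note = e$note)
  }))
}

#' Actuate mapped IR codes for an emitted gesture
#'
#' Called on every debounced state change. Each code mapped to the gesture
#' is transmitted once; with a `repeat_rate` controller output the codes are
#' re-transmitted at the implied rate over the hold interval, and with an
#' `index_increment` output the code at the computed index (1-based offset
#' into the gesture's code list) is selected instead.
#'
#' @param map A [gesture_map()].
#' @param gesture The emitted gesture label.
#' @param bus An [ir_bus()].
#' @param timestamp Transmission time in seconds (default 0).
#' @param output Optional spatial controller output ([spatial_update()]).
#' @param hold_s Hold duration used to expand `repeat_rate` outputs into
#'   repeat transmissions (default 0: no repeats).
#' @return Invisibly, the number of transmissions written to the bus.
#'   Unmapped gestures transmit nothing and raise a warning.
#' @export
actuate <- function(map, gesture, bus, timestamp = 0, output = NULL,
                    hold_s = 0) {
  stopifnot(inherits(map, "gesture_map"), inherits(bus, "ir_bus"))
  ids <- map$mapping[[gesture]]
  if (is.null(ids) || !length(ids)) {
    warning("gesture '", gesture, "' is not mapped to any IR code")
    return(invisible(0L))
  }
  n_tx <- 0L
  if (!is.null(output) && !is.null(output$index)) {
    # index_increment: select the code at the computed offset
    idx <- output$index
    if (idx >= 1L && idx <= length(ids)) {
      bus_transmit(bus, map$store[[ids[idx]]], gesture, timestamp,
                   note = sprintf("index_increment:%d", idx))
      n_tx <- 1L
    }
    return(invisible(n_tx))
  }
  for (id in ids) {
    bus_transmit(bus, map$store[[id]], gesture, timestamp)
    n_tx <- n_tx + 1L
  }
  if (!is.null(output) && !is.null(output$rate) && output$rate > 0 &&
      hold_s > 0) {
    repeats <- floor(output$rate * hold_s)
    if (repeats > 0) {
      times <- timestamp + seq_len(repeats) / output$rate
      for (k in seq_len(repeats)) {
        for (id in ids) {
          bus_transmit(bus, map$store[[id]], gesture, times[k],
                       note = "repeat_rate")
          n_tx <- n_tx + 1L
        }
      }
    }
  }
  invisible(n_tx)
}

#' Write / read an IR code store as JSON
#'
#' @param store Named list of [ir_code()] objects.
#' @param path JSON file path.
#' @return `write_ir_store`: invisibly the path; `read_ir_store`: the store.
#' @export
write_ir_store <- function(store, path) {
  entries <- lapply(store, function(cd) {
    list(id = cd$id, protocol = cd$protocol,
         payload_hex = if (!is.null(cd$payload)) double_to_hex(cd$payload),
         ticks_us = cd$ticks_us, repeat_behaviour = cd$repeat_behaviour)
  })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ir_store
#' @export
read_ir_store <- function(path) {
  entries <- jsonlite::read_json(path)
  store <- lapply(entries, function(e) {
    ir_code(e$id, e$protocol,
            payload = if (!is.null(e$payload_hex)) {
              hex_to_double(e$payload_hex)
            },
            ticks_us = if (!is.null(e$ticks_us)) {
              as.numeric(unlist(e$ticks_us))
            },
            repeat_behaviour = e$repeat_behaviour)
  })
  stats::setNames(store, vapply(store, `[[`, character(1), "id"))
}

#' Write / read a gesture map as YAML
#'
#' @param map A [gesture_map()] (codes are serialised separately with
#'   [write_ir_store()]).
#' @param path YAML file path.
#' @param store Code store used to validate the mapping on read.
#' @return `write_gesture_map`: invisibly the path; `read_gesture_map`: the
#'   [gesture_map()].
#' @export
write_gesture_map <- function(map, path) {
  stopifnot(inherits(map, "gesture_map"))
  yaml::write_yaml(lapply(map$mapping, as.list), path)
  invisible(path)
}

#' @rdname write_gesture_map
#' @export
read_gesture_map <- function(path, store) {
  mapping <- lapply(yaml::read_yaml(path), function(v) {
    as.character(unlist(v))
  })
  gesture_map(mapping, store)
}
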