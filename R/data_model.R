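#' Construct a trap array
#'
#' A trap array holds the detector locations (projected planar coordinates in
#' meters) together with a detector-by-occasion binary operation matrix.
#' Paired cameras at one station are treated as a single detector.
#'
#' @param station_id character vector of unique station labels.
#' @param xy numeric matrix (J x 2) of projected coordinates in meters.
#' @param operation binary matrix (J x K); entry 1 means the station was
#'   active during that occasion.
#' @param occasion_dates optional vector of `Date`s, the start of each
#'   occasion.
#' @param survey_window optional length-2 `Date` vector (start, end).
#'
#' @return An object of class `trap_array` with elements `station_id`, `xy`,
#'   `operation`, `occasion_dates`, `survey_window`.
#' @export
trap_array <- function(station_id, xy, operation, occasion_dates = NULL,
                       survey_window = NULL) {
  station_id <- as.character(station_id)
  xy <- as.matrix(xy)
  storage.mode(xy) <- "double"
  operation <- as.matrix(operation)
  storage.mode(operation) <- "double"
  if (anyDuplicated(station_id))
    stop("duplicate station ids: ",
         paste(unique(station_id[duplicated(station_id)]), collapse = ", "))
  if (nrow(xy) != length(station_id) || ncol(xy) != 2L)
    stop("'xy' must be a matrix with one row per station and columns x, y")
  if (!all(is.finite(xy))) stop("trap coordinates must be finite")
  if (nrow(operation) != length(station_id))
    stop("'operation' must have one row per station")
  if (!all(operation %in% c(0, 1)))
    stop("'operation' entries must be 0 or 1")
  if (sum(operation) <= 0) stop("total effort must be positive")
  colnames(xy) <- c("x", "y")
  rownames(xy) <- station_id
  rownames(operation) <- station_id
  structure(list(station_id = station_id, xy = xy, operation = operation,
                 occasion_dates = occasion_dates,
                 survey_window = survey_window),
            class = "trap_array")
}

#' @export
print.trap_array <- function(x, ...) {
  cat("Trap array:", n_traps(x), "stations,", n_occasions(x), "occasions,",
      sum(x$operation), "trap-occasions of effort\n")
  invisible(x)
}

#' Number of detectors / occasions
#' @param traps a [trap_array()].
#' @return integer count.
#' @export
n_traps <- function(traps) length(traps$station_id)

#' @rdname n_traps
#' @export
n_occasions <- function(traps) ncol(traps$operation)

#' Total survey effort in trap-occasions
#' @param traps a [trap_array()].
#' @return the number of active station-occasions (trap-days for daily
#'   occasions).
#' @export
effort <- function(traps) sum(traps$operation)

#' Read a trap deployment table
#'
#' Reads a CSV with columns `station`, `x`, `y` and either deployment dates
#' (`setup_date`, `retrieval_date`, ISO-8601) or per-day activity columns
#' (0/1, one per survey day).  Occasions are consecutive bins of
#' `occasion_length` days starting at the survey window start; a station is
#' active in an occasion if it operated on at least one day of the bin.
#'
#' @param path CSV file path.
#' @param survey_window length-2 `Date` (or coercible) vector: first and last
#'   survey day, inclusive.
#' @param occasion_length occasion length in days (default 1, daily
#'   occasions).
#' @return A [trap_array()].
#' @export
read_traps <- function(path, survey_window, occasion_length = 1) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("station", "x", "y")
  if (!all(req %in% names(df)))
    stop("traps CSV must contain columns: ", paste(req, collapse = ", "))
  if (anyNA(df$x) || anyNA(df$y)) stop("missing trap coordinates")
  survey_window <- as.Date(survey_window)
  days <- seq(survey_window[1], survey_window[2], by = "day")
  n_days <- length(days)
  K <- ceiling(n_days / occasion_length)
  occ_of_day <- rep(seq_len(K), each = occasion_length)[seq_len(n_days)]

  J <- nrow(df)
  daily <- matrix(0, J, n_days)
  if (all(c("setup_date", "retrieval_date") %in% names(df))) {
    setup <- as.Date(df$setup_date)
    retr <- as.Date(df$retrieval_date)
    clipped <- FALSE
    for (i in seq_len(J)) {
      a <- max(setup[i], survey_window[1])
      b <- min(retr[i], survey_window[2])
      if (setup[i] < survey_window[1] || retr[i] > survey_window[2])
        clipped <- TRUE
      if (a > b) {
        warning("station ", df$station[i],
                " operated entirely outside the survey window; ",
                "its operation row is all zero")
        next
      }
      daily[i, days >= a & days <= b] <- 1
    }
    if (clipped)
      warning("operation dates outside the survey window were clipped")
  } else {
    extra <- setdiff(names(df), c(req, "setup_date", "retrieval_date"))
    if (length(extra) < 1)
      stop("traps CSV needs setup/retrieval dates or per-day activity columns")
    act <- as.matrix(df[, extra, drop = FALSE])
    storage.mode(act) <- "double"
    if (ncol(act) != n_days)
      stop("found ", ncol(act), " activity columns for a window of ",
           n_days, " days")
    daily <- act
  }
  operation <- matrix(0, J, K)
  for (k in seq_len(K))
    operation[, k] <- as.numeric(rowSums(
      daily[, occ_of_day == k, drop = FALSE]) > 0)
  occ_dates <- days[!duplicated(occ_of_day)]
  trap_array(df$station, cbind(df$x, df$y), operation,
             occasion_dates = occ_dates, survey_window = survey_window)
}

#' Write a trap array to CSV (per-day activity layout)
#'
#' The inverse of [read_traps()] for daily occasions: columns `station`,
#' `x`, `y`, then one 0/1 column per occasion.
#'
#' @param traps a [trap_array()].
#' @param path output CSV path.
#' @export
write_traps <- function(traps, path) {
  op <- traps$operation
  colnames(op) <- paste0("occ", seq_len(ncol(op)))
  df <- data.frame(station = traps$station_id,
                   x = traps$xy[, 1], y = traps$xy[, 2], op,
                   check.names = FALSE, row.names = NULL)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a camera-trap record table
#'
#' Expects columns `station`, `datetime` (ISO-8601), `individual`; an empty
#' string or NA in `individual` marks an unidentified detection.
#'
#' @param path CSV file path.
#' @return data.frame with columns `station`, `datetime` (POSIXct),
#'   `individual` (NA = unidentified).
#' @export
read_record_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("station", "datetime", "individual")
  if (!all(req %in% names(df)))
    stop("record CSV must contain columns: ", paste(req, collapse = ", "))
  dt <- as.POSIXct(df$datetime, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                  "%Y-%m-%d %H:%M", "%Y-%m-%d"))
  bad <- which(is.na(dt))
  if (length(bad))
    stop("unparseable datetime in row(s): ", paste(head(bad, 5), collapse = ", "))
  ind <- as.character(df$individual)
  ind[!is.na(ind) & (ind == "" | toupper(ind) == "NA" |
                       toupper(ind) == "UNIDENTIFIED")] <- NA
  data.frame(station = as.character(df$station), datetime = dt,
             individual = ind, stringsAsFactors = FALSE)
}

#' Construct capture data
#'
#' @param y_id integer array (n_individuals x J x K) of identified detection
#'   counts.
#' @param n_noid integer matrix (J x K) of unidentified detection counts.
#' @param individual_ids character labels for the rows of `y_id`.
#' @param traps optional [trap_array()] used to check that no counts fall on
#'   inactive station-occasions.
#' @return An object of class `capture_data`.
#' @export
capture_data <- function(y_id, n_noid, individual_ids, traps = NULL) {
  y_id <- as.array(y_id)
  if (length(dim(y_id)) != 3L)
    stop("'y_id' must be a 3-d array: individual x trap x occasion")
  n_noid <- as.matrix(n_noid)
  if (any(y_id < 0) || any(n_noid < 0) ||
      any(y_id != round(y_id)) || any(n_noid != round(n_noid)))
    stop("counts must be nonnegative integers")
  if (dim(y_id)[2] != nrow(n_noid) || dim(y_id)[3] != ncol(n_noid))
    stop("trap/occasion dimensions of 'y_id' and 'n_noid' disagree")
  if (dim(y_id)[1] != length(individual_ids))
    stop("'individual_ids' must label the first dimension of 'y_id'")
  if (dim(y_id)[1] > 0 && any(apply(y_id, 1, sum) == 0))
    stop("every identified individual must have at least one detection")
  if (!is.null(traps)) {
    inactive <- traps$operation == 0
    if (any(n_noid[inactive] > 0))
      stop("unidentified counts at inactive station-occasions")
    if (dim(y_id)[1] > 0) {
      id_jk <- apply(y_id, c(2, 3), sum)
      if (any(id_jk[inactive] > 0))
        stop("identified counts at inactive station-occasions")
    }
  }
  structure(list(y_id = y_id, n_noid = n_noid,
                 individual_ids = as.character(individual_ids)),
            class = "capture_data")
}

#' @export
print.capture_data <- function(x, ...) {
  cat("Capture data:", dim(x$y_id)[1], "identified individuals,",
      sum(x$y_id), "identified and", sum(x$n_noid),
      "unidentified detections at", dim(x$y_id)[2], "stations\n")
  invisible(x)
}

#' Build capture matrices from a record table
#'
#' Consecutive records of the same individual (or consecutive unidentified
#' records) at the same station separated by less than `dedup_window` minutes
#' collapse into a single detection event; the chain rule applies, so a burst
#' of photographs counts once.  Events are then binned into the occasions of
#' `traps`.
#'
#' @param records data.frame as returned by [read_record_table()].
#' @param traps a [trap_array()] (must carry `survey_window` and
#'   `occasion_dates`).
#' @param dedup_window minutes; events closer than this collapse (default 30).
#' @param on_inactive what to do with an event at an inactive
#'   station-occasion: `"drop"` (default, with a warning) or `"activate"`
#'   (flip the operation cell to 1).
#' @return A [capture_data()] object; when `on_inactive = "activate"` the
#'   amended trap array is attached as attribute `"traps"`.
#' @export
build_capture_data <- function(records, traps, dedup_window = 30,
                               on_inactive = c("drop", "activate")) {
  on_inactive <- match.arg(on_inactive)
  if (is.null(traps$survey_window) || is.null(traps$occasion_dates))
    stop("'traps' must carry a survey window and occasion dates")
  unknown <- setdiff(unique(records$station), traps$station_id)
  if (length(unknown))
    stop("records reference unknown station(s): ",
         paste(unknown, collapse = ", "))
  win <- as.POSIXct(paste(traps$survey_window, c("00:00:00", "23:59:59")),
                    tz = "UTC")
  if (any(records$datetime < win[1] | records$datetime > win[2]))
    stop("record timestamps outside the survey window")

  # deduplicate: group key = station x individual (NA = unidentified chain)
  key <- paste(records$station, ifelse(is.na(records$individual), "<noID>",
                                       records$individual))
  ord <- order(key, records$datetime)
  records <- records[ord, ]
  key <- key[ord]
  gap <- c(Inf, diff(as.numeric(records$datetime)) / 60)
  new_event <- key != c("", key[-length(key)]) | gap > dedup_window
  events <- records[new_event, , drop = FALSE]

  J <- n_traps(traps)
  K <- n_occasions(traps)
  occ_breaks <- as.POSIXct(paste(traps$occasion_dates, "00:00:00"), tz = "UTC")
  occ <- findInterval(events$datetime, occ_breaks)
  stn <- match(events$station, traps$station_id)

  operation <- traps$operation
  keep <- rep(TRUE, nrow(events))
  inact <- which(operation[cbind(stn, occ)] == 0)
  if (length(inact)) {
    if (on_inactive == "drop") {
      warning(length(inact),
              " detection event(s) at inactive station-occasions dropped")
      keep[inact] <- FALSE
    } else {
      operation[cbind(stn[inact], occ[inact])] <- 1
      warning(length(inact), " inactive station-occasion(s) activated")
    }
  }
  events <- events[keep, , drop = FALSE]
  occ <- occ[keep]; stn <- stn[keep]

  ids <- sort(unique(events$individual[!is.na(events$individual)]))
  y_id <- array(0L, c(length(ids), J, K))
  n_noid <- matrix(0L, J, K)
  for (e in seq_along(occ)) {
    if (is.na(events$individual[e])) {
      n_noid[stn[e], occ[e]] <- n_noid[stn[e], occ[e]] + 1L
    } else {
      i <- match(events$individual[e], ids)
      y_id[i, stn[e], occ[e]] <- y_id[i, stn[e], occ[e]] + 1L
    }
  }
  traps_out <- traps
  traps_out$operation <- operation
  out <- capture_data(y_id, n_noid, ids, traps = traps_out)
  if (on_inactive == "activate") attr(out, "traps") <- traps_out
  out
}

#' Write / read capture matrices as wide CSV
#'
#' `write_capture_data()` stores the identified array in long-by-individual
#' wide-by-occasion form (`individual`, `station`, `occ1..occK`), with the
#' unidentified matrix appended under the reserved individual label
#' `"<noID>"`.  `read_capture_data()` inverts it.
#'
#' @param captures a [capture_data()].
#' @param path CSV path.
#' @param traps optional [trap_array()] for validation on read.
#' @return `read_capture_data()` returns a [capture_data()].
#' @export
write_capture_data <- function(captures, path) {
  J <- dim(captures$y_id)[2]; K <- dim(captures$y_id)[3]
  rows <- list()
  for (i in seq_along(captures$individual_ids)) {
    m <- captures$y_id[i, , , drop = TRUE]
    m <- matrix(m, J, K)
    nz <- which(rowSums(m) > 0)
    for (j in nz)
      rows[[length(rows) + 1L]] <-
        data.frame(individual = captures$individual_ids[i], station = j,
                   t(m[j, ]))
  }
  nz <- which(rowSums(captures$n_noid) > 0)
  for (j in nz)
    rows[[length(rows) + 1L]] <-
      data.frame(individual = "<noID>", station = j,
                 t(captures$n_noid[j, ]))
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(individual = character(), station = integer())
  if (nrow(df)) names(df) <- c("individual", "station",
                               paste0("occ", seq_len(K)))
  attr(df, "dims") <- c(J = J, K = K)
  write.csv(cbind(df, J = J, K = K), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_capture_data
#' @export
read_capture_data <- function(path, traps = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  J <- df$J[1]; K <- df$K[1]
  occ_cols <- paste0("occ", seq_len(K))
  ids <- sort(unique(df$individual[df$individual != "<noID>"]))
  y_id <- array(0L, c(length(ids), J, K))
  n_noid <- matrix(0L, J, K)
  for (r in seq_len(nrow(df))) {
    cnts <- as.integer(df[r, occ_cols])
    if (df$individual[r] == "<noID>") {
      n_noid[df$station[r], ] <- n_noid[df$station[r], ] + cnts
    } else {
      i <- match(df$individual[r], ids)
      y_id[i, df$station[r], ] <- y_id[i, df$station[r], ] + cnts
    }
  }
  capture_data(y_id, n_noid, ids, traps = traps)
}

#' Build the state space
#'
#' By default the state space is the bounding box of the traps expanded by
#' `buffer_width` meters on every side.  An optional polygon mask (vertex
#' matrix, meters) replaces the rectangle; its area is computed by the
#' shoelace formula and every trap must fall inside it.
#'
#' @param traps a [trap_array()].
#' @param buffer_width buffer in meters (>= 0).
#' @param mask optional polygon vertex matrix (n x 2, meters).
#' @return An object of class `state_space` with `type` ("rect" or
#'   "polygon"), `bounds` (xmin, xmax, ymin, ymax), `vertices`,
#'   `buffer_width`, and `area_km2`.
#' @export
build_state_space <- function(traps, buffer_width, mask = NULL) {
  if (buffer_width < 0) stop("'buffer_width' must be >= 0")
  xy <- traps$xy
  if (is.null(mask)) {
    bounds <- c(min(xy[, 1]) - buffer_width, max(xy[, 1]) + buffer_width,
                min(xy[, 2]) - buffer_width, max(xy[, 2]) + buffer_width)
    area_m2 <- (bounds[2] - bounds[1]) * (bounds[4] - bounds[3])
    ss <- list(type = "rect", bounds = bounds, vertices = NULL,
               buffer_width = buffer_width, area_km2 = area_m2 / 1e6)
  } else {
    mask <- as.matrix(mask)
    if (ncol(mask) != 2L || nrow(mask) < 3L)
      stop("'mask' must be an n x 2 vertex matrix with n >= 3")
    inside <- points_in_polygon_cpp(xy[, 1], xy[, 2], mask)
    if (!all(inside))
      stop("mask excludes trap(s): ",
           paste(traps$station_id[!inside], collapse = ", "))
    n <- nrow(mask)
    i2 <- c(2:n, 1)
    area_m2 <- abs(sum(mask[, 1] * mask[i2, 2] - mask[i2, 1] * mask[, 2])) / 2
    bounds <- c(range(mask[, 1]), range(mask[, 2]))[c(1, 2, 3, 4)]
    bounds <- c(min(mask[, 1]), max(mask[, 1]), min(mask[, 2]), max(mask[, 2]))
    ss <- list(type = "polygon", bounds = bounds, vertices = mask,
               buffer_width = buffer_width, area_km2 = area_m2 / 1e6)
  }
  if (ss$area_km2 <= 0) stop("state-space area must be positive")
  structure(ss, class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space (", x$type, "): area ", round(x$area_km2, 2),
      " km2, buffer ", x$buffer_width, " m\n", sep = "")
  invisible(x)
}

#' Test whether points lie inside a state space
#' @param state_space a [build_state_space()] result.
#' @param x,y numeric coordinate vectors (meters).
#' @return logical vector.
#' @export
in_state_space <- function(state_space, x, y) {
  if (state_space$type == "rect") {
    b <- state_space$bounds
    x >= b[1] & x <= b[2] & y >= b[3] & y <= b[4]
  } else {
    points_in_polygon_cpp(x, y, state_space$vertices)
  }
}

#' Bundle traps, captures and state space into one analysis-ready object
#'
#' @param traps a [trap_array()].
#' @param captures a [capture_data()].
#' @param state_space a [build_state_space()] result.
#' @param survey_window optional length-2 `Date` vector.
#' @return An object of class `scr_dataset`.
#' @export
scr_dataset <- function(traps, captures, state_space, survey_window = NULL) {
  J <- n_traps(traps)
  if (dim(captures$y_id)[2] != J || nrow(captures$n_noid) != J)
    stop("captures and traps disagree on the number of detectors")
  if (dim(captures$y_id)[3] != n_occasions(traps))
    stop("captures and traps disagree on the number of occasions")
  if (!all(in_state_space(state_space, traps$xy[, 1], traps$xy[, 2])))
    stop("some traps lie outside the state space")
  structure(list(traps = traps, captures = captures,
                 state_space = state_space,
                 survey_window = if (is.null(survey_window))
                   traps$survey_window else survey_window),
            class = "scr_dataset")
}

#' @export
print.scr_dataset <- function(x, ...) {
  print(x$traps); print(x$captures); print(x$state_space)
  invisible(x)
}
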