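#' Record schemas for field data
#'
#' The pipeline consumes four tabular record types, each a plain CSV with a
#' header row (RFC 4180, UTF-8):
#'
#' * `registry` -- one row per individual per year: `individual_id`, `year`,
#'   `sex` (`F`/`M`), `age_class` (`adult`/`yearling`/`pup`), `colony`,
#'   `n_traps` (number of captures that year).
#' * `copresence` -- one row per sighting or trap event: `individual_id`,
#'   `date` (ISO 8601), `location`.
#' * `interactions` -- one row per directed social act: `timestamp`
#'   (ISO 8601 date or date-time), `initiator_id`, `recipient_id` (either may
#'   be the sentinel `UNKNOWN`), `itype` (`affiliative`/`agonistic`),
#'   `location`.
#' * `reproduction` -- one row per mother per year: `mother_id`, `year`,
#'   `offspring` (pups weaned, pedigree-assigned), and optionally `exposure`
#'   (time at risk; defaults to 1 when the column is absent).
#'
#' @name record-schemas
#' @keywords internal
NULL

.schemas <- list(
  registry     = c("individual_id", "year", "sex", "age_class", "colony", "n_traps"),
  copresence   = c("individual_id", "date", "location"),
  interactions = c("timestamp", "initiator_id", "recipient_id", "itype", "location"),
  reproduction = c("mother_id", "year", "offspring")
)

UNKNOWN_ID <- "UNKNOWN"

#' Read and validate a record CSV
#'
#' Reads one of the four record schemas (see [record-schemas]) from a CSV
#' file, coerces columns to their declared types, and drops rows that violate
#' a row-level invariant. Rejected rows are collected, with their line number
#' and a reason, in the `"problems"` attribute of the returned data frame; a
#' missing required column is a schema error and aborts instead.
#'
#' Row-level invariants enforced per schema: `registry` rows must have a
#' valid sex and age class, a non-negative integer trap count, and a unique
#' (id, year) pair; `interactions` rows must have a parseable timestamp, a
#' valid interaction type, and distinct initiator and recipient when both are
#' known; `copresence` rows need a parseable date; `reproduction` rows need a
#' non-negative offspring count and strictly positive exposure.
#'
#' @param path path to a CSV file with a header row.
#' @param schema one of `"registry"`, `"copresence"`, `"interactions"`,
#'   `"reproduction"`.
#' @return A data frame of validated records. Rejected rows are reported in
#'   `attr(x, "problems")`, a data frame with columns `line` (file line
#'   number, counting the header as line 1) and `reason`.
#' @seealso [write_records()], [filter_agonistic_study_set()]
#' @export
read_records <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  raw <- utils::read.csv(path, colClasses = "character", check.names = TRUE,
                         strip.white = TRUE)
  required <- .schemas[[schema]]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("schema error: missing required column(s) for '", schema, "': ",
         paste(missing_cols, collapse = ", "))
  }
  validate_records(raw, schema)
}

# Coerce and validate raw character data for one schema; attach a "problems"
# attribute listing rejected rows (line = file line, header is line 1).
validate_records <- function(raw, schema) {
  n <- nrow(raw)
  reason <- character(n) # "" = keep
  note <- function(idx, why) {
    new <- idx & reason == ""
    reason[new] <<- why
  }

  out <- raw
  if (schema == "registry") {
    out$year <- suppressWarnings(as.integer(raw$year))
    out$n_traps <- suppressWarnings(as.integer(raw$n_traps))
    note(is.na(out$year), "unparseable year")
    note(!(raw$sex %in% c("F", "M")), "sex must be F or M")
    note(!(raw$age_class %in% c("adult", "yearling", "pup")),
         "age_class must be adult/yearling/pup")
    note(is.na(out$n_traps) | out$n_traps < 0, "n_traps must be a non-negative integer")
    note(duplicated(paste(raw$individual_id, raw$year)), "duplicate (individual_id, year)")
  } else if (schema == "copresence") {
    out$date <- as.Date(raw$date, format = "%Y-%m-%d")
    note(is.na(out$date), "unparseable date")
    note(raw$individual_id == "" | raw$individual_id == UNKNOWN_ID,
         "individual_id must be a known id")
  } else if (schema == "interactions") {
    ts <- as.POSIXct(rep(NA_real_, n), origin = "1970-01-01", tz = "UTC")
    for (fmt in c("%Y-%m-%d %H:%M:%S", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
      need <- is.na(ts)
      if (!any(need)) break
      ts[need] <- as.POSIXct(strptime(raw$timestamp[need], fmt, tz = "UTC"))
    }
    out$timestamp <- ts
    note(is.na(ts), "unparseable timestamp")
    note(!(raw$itype %in% c("affiliative", "agonistic")),
         "itype must be affiliative or agonistic")
    both_known <- raw$initiator_id != UNKNOWN_ID & raw$recipient_id != UNKNOWN_ID
    note(both_known & raw$initiator_id == raw$recipient_id,
         "initiator and recipient must differ")
  } else if (schema == "reproduction") {
    out$year <- suppressWarnings(as.integer(raw$year))
    out$offspring <- suppressWarnings(as.integer(raw$offspring))
    if (!"exposure" %in% names(out)) out$exposure <- "1"
    out$exposure <- suppressWarnings(as.numeric(out$exposure))
    note(is.na(out$year), "unparseable year")
    note(is.na(out$offspring) | out$offspring < 0, "offspring must be a non-negative integer")
    note(is.na(out$exposure) | out$exposure <= 0, "exposure must be positive")
  }

  keep <- reason == ""
  problems <- data.frame(line = which(!keep) + 1L, reason = reason[!keep],
                         stringsAsFactors = FALSE)
  res <- out[keep, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "problems") <- problems
  attr(res, "schema") <- schema
  res
}

#' Write records to CSV
#'
#' Inverse of [read_records()]: writes a validated record data frame back to
#' CSV so that reading it again reproduces the same collection.
#'
#' @param records a record data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records
  if ("date" %in% names(out)) out$date <- format(out$date, "%Y-%m-%d")
  if ("timestamp" %in% names(out)) {
    out$timestamp <- format(out$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Restrict interactions to the agonistic study set
#'
#' Applies the eligibility filters used before any network is built: only
#' agonistic interactions, between two known individuals, both of whom are
#' adult females in the focal year's registry with more than `min_traps`
#' captures (transients are excluded), and whose timestamp falls inside the
#' active season.
#'
#' @param interactions an interactions record data frame (see
#'   [read_records()]).
#' @param registry a registry record data frame covering `year`.
#' @param year focal study year (integer).
#' @param min_traps individuals must have been trapped strictly more than
#'   this many times in the focal year. Default 5, i.e. at least 6 captures.
#' @param season character vector of length 2, `"MM-DD"` bounds of the active
#'   season; records outside are dropped with a warning. Default Apr 15 to
#'   Sep 7.
#' @return The filtered interactions data frame. The filter is idempotent.
#' @export
filter_agonistic_study_set <- function(interactions, registry, year,
                                       min_traps = 5,
                                       season = c("04-15", "09-07")) {
  stopifnot(is.numeric(year), length(year) == 1L)
  x <- interactions
  in_year <- !is.na(x$timestamp) &
    as.integer(format(x$timestamp, "%Y")) == as.integer(year)
  x <- x[in_year, , drop = FALSE]

  lo <- as.POSIXct(paste0(year, "-", season[1], " 00:00:00"), tz = "UTC")
  hi <- as.POSIXct(paste0(year, "-", season[2], " 23:59:59"), tz = "UTC")
  in_season <- x$timestamp >= lo & x$timestamp <= hi
  if (any(!in_season)) {
    warning(sum(!in_season), " interaction(s) outside the ", season[1], " to ",
            season[2], " season dropped")
    x <- x[in_season, , drop = FALSE]
  }

  reg <- registry[registry$year == as.integer(year), , drop = FALSE]
  eligible <- reg$individual_id[reg$sex == "F" & reg$age_class == "adult" &
                                  reg$n_traps > min_traps]
  keep <- x$itype == "agonistic" &
    x$initiator_id != UNKNOWN_ID & x$recipient_id != UNKNOWN_ID &
    x$initiator_id %in% eligible & x$recipient_id %in% eligible
  res <- x[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}
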