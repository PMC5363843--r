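# Capture records, sampling schedules, and night x species abundance matrices.
#
# Conventions: the nocturnal window runs 720 minutes from nominal sunset
# (18:00) to nominal sunrise (06:00); capture times are minutes since 18:00,
# binned down to the start of their 30-min net-check interval. All interval
# arithmetic is half-open [a, b).

NIGHT_MINUTES <- 720L

#' Define a sampling schedule
#'
#' A schedule is the subset of the 12-h night during which nets are
#' (notionally) open, expressed as disjoint half-open minute intervals
#' `[a, b)` with `0 <= a < b <= 720` (minutes since 18:00).
#'
#' @param name Character label for the schedule.
#' @param windows A list of length-2 numeric vectors `c(a, b)`, or a
#'   two-column matrix with one row per window.
#' @return An object of class `nn_schedule` with elements `name` and
#'   `windows` (a two-column matrix, rows sorted by start).
#' @examples
#' schedule("6hB", list(c(0, 180), c(540, 720)))
#' @seealso [canonical_schedules()]
#' @export
schedule <- function(name, windows) {
  if (is.list(windows)) windows <- do.call(rbind, windows)
  windows <- matrix(as.numeric(windows), ncol = 2)
  windows <- windows[order(windows[, 1]), , drop = FALSE]
  if (any(windows[, 1] >= windows[, 2]))
    stop("schedule windows must satisfy a < b")
  if (any(windows < 0) || any(windows > NIGHT_MINUTES))
    stop("schedule windows must lie within [0, ", NIGHT_MINUTES, "]")
  if (nrow(windows) > 1 &&
      any(windows[-1, 1] < windows[-nrow(windows), 2]))
    stop("schedule windows must be pairwise disjoint")
  colnames(windows) <- c("start", "end")
  structure(list(name = name, windows = windows), class = "nn_schedule")
}

#' @export
print.nn_schedule <- function(x, ...) {
  w <- apply(x$windows, 1, function(r) sprintf("[%g, %g)", r[1], r[2]))
  cat("<schedule '", x$name, "': ", paste(w, collapse = " + "),
      " = ", schedule_minutes(x), " min>\n", sep = "")
  invisible(x)
}

#' Total minutes covered by a schedule
#' @param sched An `nn_schedule`.
#' @return Covered minutes (numeric scalar).
#' @export
schedule_minutes <- function(sched) {
  sum(sched$windows[, 2] - sched$windows[, 1])
}

#' Canonical sampling schedules
#'
#' The three strategies compared throughout: the full night (`12h` =
#' `[0,720)`), the first six hours (`6h` = `[0,360)`), and the alternative
#' split schedule covering the first three and last three hours
#' (`6hB` = `[0,180) + [540,720)`).
#'
#' @return Named list of `nn_schedule` objects (`12h`, `6h`, `6hB`).
#' @export
canonical_schedules <- function() {
  list(
    "12h" = schedule("12h", list(c(0, 720))),
    "6h"  = schedule("6h", list(c(0, 360))),
    "6hB" = schedule("6hB", list(c(0, 180), c(540, 720)))
  )
}

#' Test membership of times in a schedule
#' @param time_min Numeric vector of minutes since 18:00.
#' @param sched An `nn_schedule`.
#' @return Logical vector: is each time inside one of the windows
#'   (half-open test)?
#' @export
in_schedule <- function(time_min, sched) {
  inside <- rep(FALSE, length(time_min))
  for (i in seq_len(nrow(sched$windows))) {
    inside <- inside |
      (time_min >= sched$windows[i, 1] & time_min < sched$windows[i, 2])
  }
  inside
}

# Parse a time column: clock "HH:MM" strings or numeric minutes-since-sunset.
# Returns raw minutes since 18:00 (not yet binned); NA where unparseable.
.parse_times <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  clock <- grepl("^\\d{1,2}:\\d{2}$", x)
  out <- rep(NA_real_, length(x))
  if (any(clock)) {
    hh <- as.numeric(sub(":.*", "", x[clock]))
    mm <- as.numeric(sub(".*:", "", x[clock]))
    bad <- hh > 23 | mm > 59
    v <- (hh * 60 + mm - 18 * 60) %% 1440
    v[bad] <- NA_real_
    out[clock] <- v
  }
  numlike <- !clock & grepl("^-?\\d+(\\.\\d+)?$", x)
  out[numlike] <- as.numeric(x[numlike])
  out
}

#' Read capture records from CSV
#'
#' Expects one row per captured individual with columns `dataset`, `site`,
#' `night`, `species`, and a time column: either `time_min` (minutes since
#' 18:00) or `time` (clock `HH:MM`, mapped to minutes since 18:00, e.g.
#' `18:30` -> 30, `05:30` -> 690). Optional columns `family`, `guild`,
#' `count` (default 1) are carried through. Times are snapped down to the
#' start of their net-check interval; rows with times outside `[0, 720)`
#' (e.g. `06:00`, which maps to minute 720) are dropped with a warning.
#'
#' @param path Path to a UTF-8 comma-separated file with header.
#' @param check_interval Net-check interval in minutes (default 30).
#' @return A data frame of capture records (`dataset`, `site`, `night`,
#'   `species`, `family`, `guild`, `time_min`, `count`), with attribute
#'   `n_rejected` giving the number of out-of-window rows dropped.
#' @export
read_captures <- function(path, check_interval = 30) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  required <- c("dataset", "site", "night", "species")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("captures file is missing column(s): ",
         paste(missing, collapse = ", "))
  timecol <- intersect(c("time_min", "time"), names(df))[1]
  if (is.na(timecol)) stop("captures file is missing column(s): time")
  as_captures(
    data.frame(
      dataset = as.character(df$dataset),
      site    = as.character(df$site),
      night   = as.character(df$night),
      species = as.character(df$species),
      family  = if ("family" %in% names(df)) as.character(df$family)
                else NA_character_,
      guild   = if ("guild" %in% names(df)) as.character(df$guild)
                else NA_character_,
      time_raw = df[[timecol]],
      count   = if ("count" %in% names(df)) as.integer(df$count) else 1L,
      stringsAsFactors = FALSE
    ),
    check_interval = check_interval
  )
}

#' Validate and bin a capture-record data frame
#'
#' Normalises a raw record table to the package's capture-record contract:
#' parses the time column, rejects rows outside the `[0, 720)` night window,
#' and snaps times down to the start of their check interval.
#'
#' @param df Data frame with at least `dataset`, `site`, `night`, `species`
#'   and one of `time_min`/`time_raw`; optional `family`, `guild`, `count`.
#' @param check_interval Minutes per net-check interval.
#' @return Capture-record data frame with integer `time_min`
#'   (multiples of `check_interval`) and `count >= 1`.
#' @export
as_captures <- function(df, check_interval = 30) {
  tcol <- if ("time_raw" %in% names(df)) "time_raw" else "time_min"
  raw <- .parse_times(df[[tcol]])
  if (anyNA(raw))
    stop("unparseable capture time at row(s): ",
         paste(utils::head(which(is.na(raw)), 5), collapse = ", "))
  keep <- raw >= 0 & raw < NIGHT_MINUTES
  n_rej <- sum(!keep)
  if (n_rej > 0)
    warning(n_rej, " record(s) outside the [0,720) night window rejected")
  df <- df[keep, , drop = FALSE]
  df$time_min <- as.integer((raw[keep] %/% check_interval) * check_interval)
  df$time_raw <- NULL
  if (is.null(df$count)) df$count <- 1L
  if (any(df$count < 1)) stop("capture counts must be >= 1")
  if (is.null(df$family)) df$family <- NA_character_
  if (is.null(df$guild)) df$guild <- NA_character_
  rownames(df) <- NULL
  attr(df, "n_rejected") <- n_rej
  attr(df, "check_interval") <- check_interval
  df
}

#' Keep only captures of selected families
#'
#' Mist-net survey datasets are conventionally restricted to the families the
#' method samples reliably (for Neotropical understory netting,
#' Phyllostomidae and Vespertilionidae).
#'
#' @param records Capture-record data frame.
#' @param allowed Non-empty character vector of family labels to retain.
#' @return The retained records (order preserved), with attribute
#'   `fraction_retained`.
#' @export
filter_families <- function(records, allowed) {
  if (length(allowed) == 0) stop("'allowed' must be non-empty")
  keep <- records$family %in% allowed
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fraction_retained") <-
    if (nrow(records) == 0) NA_real_ else sum(keep) / nrow(records)
  out
}

#' Restrict captures to a sampling schedule
#'
#' Keeps records whose binned time falls inside one of the schedule windows
#' (half-open test). The set of night replicates is *not* reduced: nights
#' whose captures are all filtered out simply contribute all-zero rows to
#' downstream matrices, so poor schedule performance stays visible.
#'
#' @param records Capture-record data frame (binned times).
#' @param sched An `nn_schedule`.
#' @return The retained records.
#' @export
restrict_to_schedule <- function(records, sched) {
  out <- records[in_schedule(records$time_min, sched), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enumerate the night replicates present in a record set
#' @param records Capture-record data frame.
#' @return Data frame with unique `site`, `night` pairs, ordered.
#' @export
night_universe <- function(records) {
  nk <- unique(records[, c("site", "night")])
  nk <- nk[order(nk$site, nk$night), , drop = FALSE]
  rownames(nk) <- NULL
  nk
}

#' Build a night x species abundance matrix
#'
#' Rows are night replicates (keyed `"site:night"`), columns species, cells
#' summed capture counts. Passing the full-night species list and night
#' universe ensures schedule-restricted matrices share dimensions with the
#' full matrix (nights lost under a schedule become all-zero rows).
#'
#' @param records Capture-record data frame.
#' @param species Character vector of column labels; must be a superset of
#'   the species present in `records`. Default: species present.
#' @param nights Data frame with columns `site`, `night` declaring the row
#'   universe. Default: nights present in `records`.
#' @return Integer matrix with `"site:night"` rownames and species colnames;
#'   its grand total equals the total count of the records used.
#' @export
build_matrix <- function(records, species = NULL, nights = NULL) {
  if (is.null(species)) species <- sort(unique(records$species))
  if (is.null(nights)) nights <- night_universe(records)
  if (anyDuplicated(paste(nights$site, nights$night, sep = ":")))
    stop("duplicate (site, night) labels in the night universe")
  extra <- setdiff(unique(records$species), species)
  if (length(extra))
    stop("records contain species not in 'species': ",
         paste(extra, collapse = ", "))
  keys <- paste(nights$site, nights$night, sep = ":")
  mat <- matrix(0L, nrow = length(keys), ncol = length(species),
                dimnames = list(keys, species))
  if (nrow(records)) {
    rk <- paste(records$site, records$night, sep = ":")
    unknown <- setdiff(unique(rk), keys)
    if (length(unknown))
      stop("records reference nights not in the night universe: ",
           paste(unknown, collapse = ", "))
    tab <- tapply(records$count, list(rk, records$species), sum)
    mat[rownames(tab), colnames(tab)] <-
      ifelse(is.na(tab), 0L, as.integer(tab))
  }
  mat
}

#' Read a site coordinate table from CSV
#' @param path CSV with columns `site`, `lon`, `lat` and optionally
#'   `dataset`.
#' @return Data frame with unique `site` rows; coordinates validated to
#'   `[-180,180] x [-90,90]`.
#' @export
read_sites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing <- setdiff(c("site", "lon", "lat"), names(df))
  if (length(missing))
    stop("sites file is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$site)) stop("duplicate site ids in sites file")
  if (any(abs(df$lon) > 180) || any(abs(df$lat) > 90))
    stop("site coordinates out of range")
  df$site <- as.character(df$site)
  df
}

#' Write an abundance matrix as labeled CSV
#'
#' First column `site_night` holds the `"site:night"` row key.
#'
#' @param mat Abundance matrix from [build_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_csv <- function(mat, path) {
  df <- data.frame(site_night = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an abundance matrix written by [write_matrix_csv()]
#' @param path CSV path.
#' @return Integer abundance matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1]]
  mat
}

#' Convert an XLSX capture table to the package's CSV layout
#'
#' Thin converter for spreadsheet field data; requires the `readxl` package.
#'
#' @param path XLSX file.
#' @param out Output CSV path.
#' @param sheet Sheet index or name (default 1).
#' @return `out`, invisibly.
#' @export
convert_xlsx <- function(path, out, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("convert_xlsx() requires the 'readxl' package")
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  utils::write.csv(df, out, row.names = FALSE)
  invisible(out)
}
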