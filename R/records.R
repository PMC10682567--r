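# Photo-scored occurrence records: parsing, validation, filtering, summaries.

#' Species codes recognised by the pipeline
#'
#' The five North American *Lobelia* species covered by the analysis.
#' `siphilitica` and `spicata` are gynodioecious (separate female and
#' hermaphrodite plants); the other three are hermaphrodite-only.
#'
#' @format Character vectors of species codes.
#' @export
lobelia_species <- c("inflata", "cardinalis", "kalmii", "siphilitica", "spicata")

#' @rdname lobelia_species
#' @export
gynodioecious_species <- c("siphilitica", "spicata")

exsertion_levels <- c("present", "possible", "absent", "unscorable")
fruit_levels <- c("yes", "no", "unscorable")
sex_levels <- c("hermaphrodite", "female", "unknown")

record_columns <- c(
  "record_id", "source_observation_id", "species", "latitude", "longitude",
  "gps_accuracy", "observation_date", "exsertion_score", "n_visible_flowers",
  "n_exserted_flowers", "flowers_present", "fruit_present", "sex", "elevation"
)

# Columns that may be absent from an input file; filled with defaults.
optional_columns <- c("record_id", "source_observation_id", "gps_accuracy",
                      "flowers_present", "sex", "elevation")

new_diagnostic <- function(row, field, message) {
  tibble::tibble(row = as.integer(row), field = field, message = message)
}

empty_diagnostics <- function() {
  tibble::tibble(row = integer(), field = character(), message = character())
}

#' Parse a file of photo-scored occurrence records
#'
#' Reads a comma-separated file of plant datapoints (one row per scored
#' plant), validates every row against the record invariants, and returns
#' the valid records together with named diagnostics for every rejected
#' row. No row is dropped silently.
#'
#' Required columns (renameable through `col_map`): `species`, `latitude`,
#' `longitude`, `observation_date` (ISO-8601), `exsertion_score`
#' (`present`/`possible`/`absent`/`unscorable`), `n_visible_flowers`,
#' `n_exserted_flowers`, `fruit_present` (`yes`/`no`/`unscorable`).
#' Optional: `record_id`, `source_observation_id`, `gps_accuracy`, `sex`
#' (defaults to `hermaphrodite`), `flowers_present`, `elevation`.
#'
#' Validation enforces: species drawn from the closed code list
#' (unknown codes are rejected as probable typos); coordinates within
#' WGS84 bounds; parseable dates; non-negative integer flower counts with
#' `n_exserted_flowers <= n_visible_flowers`; score `present` if and only
#' if at least one exserted flower when both are recorded; and
#' `unscorable` implying zero clearly visible flowers.
#'
#' @param path Path to a comma-separated file with a header row.
#' @param col_map Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(latitude = "decimalLatitude")`.
#' @return A list with `records` (tibble of valid rows in canonical
#'   columns) and `diagnostics` (tibble with `row`, `field`, `message`).
#' @export
parse_records <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    stop("cannot read records file: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      if (col_map[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[canon]]] <- canon
      }
    }
  }
  required <- setdiff(record_columns, optional_columns)
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("records file lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(optional_columns, names(raw))) raw[[col]] <- NA_character_
  validate_records(coerce_records(raw))
}

suppress_num <- function(x) suppressWarnings(as.numeric(x))

coerce_records <- function(raw) {
  n <- nrow(raw)
  tibble::tibble(
    record_id = ifelse(is.na(raw$record_id), sprintf("r%06d", seq_len(n)), raw$record_id),
    source_observation_id = ifelse(is.na(raw$source_observation_id),
                                   raw$record_id, raw$source_observation_id),
    species = raw$species,
    latitude = suppress_num(raw$latitude),
    longitude = suppress_num(raw$longitude),
    gps_accuracy = suppress_num(raw$gps_accuracy),
    observation_date = suppressWarnings(as.Date(raw$observation_date, format = "%Y-%m-%d")),
    exsertion_score = raw$exsertion_score,
    n_visible_flowers = suppress_num(raw$n_visible_flowers),
    n_exserted_flowers = suppress_num(raw$n_exserted_flowers),
    flowers_present = ifelse(is.na(raw$flowers_present), TRUE,
                             tolower(raw$flowers_present) %in% c("true", "t", "yes", "1")),
    fruit_present = raw$fruit_present,
    sex = ifelse(is.na(raw$sex), "hermaphrodite", raw$sex),
    elevation = suppress_num(raw$elevation),
    .date_raw = raw$observation_date
  )
}

validate_records <- function(rec) {
  n <- nrow(rec)
  diagnostics <- empty_diagnostics()
  bad <- rep(FALSE, n)
  flag <- function(idx, field, message) {
    if (any(idx)) {
      diagnostics <<- rbind(diagnostics, new_diagnostic(which(idx), field, message))
      bad <<- bad | idx
    }
  }

  flag(!(rec$species %in% lobelia_species), "species",
       "unknown species code")
  flag(!is.na(rec$latitude) & abs(rec$latitude) > 90, "latitude",
       "coordinate out of range")
  flag(!is.na(rec$longitude) & abs(rec$longitude) > 180, "longitude",
       "coordinate out of range")
  flag(is.na(rec$observation_date) & !is.na(rec$.date_raw), "observation_date",
       "unparseable date (expected YYYY-MM-DD)")
  flag(is.na(rec$.date_raw), "observation_date", "missing date")
  flag(!(rec$exsertion_score %in% exsertion_levels), "exsertion_score",
       "unknown exsertion score")
  flag(!(rec$fruit_present %in% fruit_levels), "fruit_present",
       "unknown fruit score")
  flag(!(rec$sex %in% sex_levels), "sex", "unknown sex code")
  for (col in c("n_visible_flowers", "n_exserted_flowers")) {
    v <- rec[[col]]
    flag(!is.na(v) & (v < 0 | v != floor(v)), col,
         "count must be a non-negative integer")
  }
  flag(is.na(rec$n_visible_flowers), "n_visible_flowers", "missing flower count")
  ok_counts <- !bad & !is.na(rec$n_visible_flowers) & !is.na(rec$n_exserted_flowers)
  flag(ok_counts & rec$n_exserted_flowers > rec$n_visible_flowers,
       "n_exserted_flowers", "exserted count exceeds visible count")
  scored <- !bad & !is.na(rec$n_exserted_flowers) & rec$exsertion_score %in% c("present", "absent")
  flag(scored & rec$exsertion_score == "present" & rec$n_exserted_flowers < 1,
       "exsertion_score", "score 'present' requires at least one exserted flower")
  flag(scored & rec$exsertion_score == "absent" & rec$n_exserted_flowers >= 1,
       "exsertion_score", "score 'absent' contradicts a positive exserted count")
  flag(!bad & rec$exsertion_score == "unscorable" & rec$n_visible_flowers != 0,
       "exsertion_score", "score 'unscorable' requires zero clearly visible flowers")

  rec$.date_raw <- NULL
  rec$n_visible_flowers <- as.integer(rec$n_visible_flowers)
  rec$n_exserted_flowers <- as.integer(rec$n_exserted_flowers)
  list(records = rec[!bad, , drop = FALSE], diagnostics = diagnostics)
}

#' Write occurrence records to a comma-separated file
#'
#' Writes the canonical record columns so the output round-trips
#' losslessly through [parse_records()].
#'
#' @param records Tibble of occurrence records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  out <- records[, intersect(record_columns, names(records)), drop = FALSE]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

filter_rule_names <- c("missing_coordinates", "non_hermaphrodite", "score_possible",
                       "score_unscorable", "fruit_unscorable", "no_visible_flowers",
                       "missing_elevation", "score_absent", "missing_exserted_count")

#' Apply the inclusion filter cascade to occurrence records
#'
#' Reproduces the dataset-inclusion rules used before model fitting, in a
#' fixed deterministic order, charging each removed record to the first
#' rule it fails so the audit report is reproducible:
#' missing coordinates; non-hermaphrodite plants of the gynodioecious
#' species (females are expected a priori to exsert their styles);
#' exsertion score `possible` or `unscorable`; unscorable fruit; no
#' clearly visible flowers; missing elevation (only when
#' `require_elevation = TRUE`). For the count model
#' (`which_model = "count"`) records must additionally be scored
#' `present` (outcrossing-capable plants) with a recorded exserted-flower
#' count.
#'
#' @param records Tibble of validated occurrence records.
#' @param which_model `"binary"` (presence/absence dataset) or `"count"`
#'   (exserted-flower count dataset, present records only).
#' @param require_elevation Drop records lacking elevation (needed for the
#'   geographic models, where elevation is a covariate).
#' @return A list with `records` (retained rows) and `report`, a one-row
#'   tibble counting input rows, removals per rule, and retained rows.
#'   The arithmetic always closes: `n_input = n_retained + sum(removals)`.
#' @export
apply_filters <- function(records, which_model = c("binary", "count"),
                          require_elevation = FALSE) {
  which_model <- match.arg(which_model)
  n_input <- nrow(records)
  removed_by <- rep(NA_character_, n_input)
  charge <- function(idx, rule) {
    removed_by[is.na(removed_by) & idx] <<- rule
  }
  charge(is.na(records$latitude) | is.na(records$longitude), "missing_coordinates")
  charge(records$species %in% gynodioecious_species & records$sex != "hermaphrodite",
         "non_hermaphrodite")
  charge(records$exsertion_score == "possible", "score_possible")
  charge(records$exsertion_score == "unscorable", "score_unscorable")
  charge(records$fruit_present == "unscorable", "fruit_unscorable")
  charge(records$n_visible_flowers == 0, "no_visible_flowers")
  if (require_elevation) charge(is.na(records$elevation), "missing_elevation")
  if (which_model == "count") {
    charge(records$exsertion_score != "present", "score_absent")
    charge(is.na(records$n_exserted_flowers), "missing_exserted_count")
  }
  retained <- records[is.na(removed_by), , drop = FALSE]
  if (nrow(retained) == 0 && n_input > 0) {
    warning("filter cascade removed every record", call. = FALSE)
  }
  counts <- vapply(filter_rule_names,
                   function(r) sum(removed_by == r, na.rm = TRUE), integer(1))
  report <- tibble::as_tibble(c(list(n_input = n_input), as.list(counts),
                                list(n_retained = nrow(retained))))
  list(records = retained, report = report)
}

#' Split a multi-plant observation into per-plant records
#'
#' An observation whose photographs unambiguously show several individual
#' plants is split into one datapoint per plant at the same geographic
#' coordinates and source observation id, each with its own flower and
#' exserted-flower counts.
#'
#' @param record A single-row tibble (one occurrence record).
#' @param plant_partitions A data frame or tibble with columns
#'   `n_visible_flowers` and `n_exserted_flowers`, one row per plant.
#' @return Tibble with one record per plant; `record_id` gains a
#'   `_p<k>` suffix, coordinates and `source_observation_id` are shared.
#' @export
split_multiplant <- function(record, plant_partitions) {
  stopifnot(nrow(record) == 1)
  parts <- tibble::as_tibble(plant_partitions)
  if (!all(c("n_visible_flowers", "n_exserted_flowers") %in% names(parts))) {
    stop("plant_partitions needs n_visible_flowers and n_exserted_flowers columns",
         call. = FALSE)
  }
  if (any(parts$n_exserted_flowers > parts$n_visible_flowers, na.rm = TRUE)) {
    stop("partition violates n_exserted_flowers <= n_visible_flowers", call. = FALSE)
  }
  out <- record[rep(1L, nrow(parts)), , drop = FALSE]
  out$record_id <- paste0(record$record_id, "_p", seq_len(nrow(parts)))
  out$n_visible_flowers <- as.integer(parts$n_visible_flowers)
  out$n_exserted_flowers <- as.integer(parts$n_exserted_flowers)
  out$exsertion_score <- ifelse(
    is.na(out$n_exserted_flowers), out$exsertion_score,
    ifelse(out$n_exserted_flowers >= 1, "present",
           ifelse(out$n_visible_flowers == 0, "unscorable", "absent")))
  out
}

#' Per-species summary of exsertion scores
#'
#' Tabulates, per species, the raw counts of `present`, `possible`,
#' `absent` and `unscorable` datapoints; the fraction of scorable
#' datapoints showing exserted styles, `present / (present + absent)`
#' (the `possible` category is excluded); and the mean number of
#' exserted flowers among `present` datapoints.
#'
#' @param records Tibble of occurrence records (hermaphrodites only; the
#'   caller pre-filters if the species is gynodioecious).
#' @return Tibble with one row per species present in `records`.
#' @export
summarize_by_species <- function(records) {
  species <- sort(unique(records$species))
  rows <- lapply(species, function(sp) {
    r <- records[records$species == sp, , drop = FALSE]
    cnt <- function(lev) sum(r$exsertion_score == lev)
    present <- cnt("present"); absent <- cnt("absent")
    denom <- present + absent
    exs <- r$n_exserted_flowers[r$exsertion_score == "present"]
    exs <- exs[!is.na(exs)]
    tibble::tibble(
      species = sp,
      count_present = present,
      count_possible = cnt("possible"),
      count_absent = absent,
      count_unscorable = cnt("unscorable"),
      fraction_present = if (denom > 0) present / denom else NA_real_,
      mean_exserted_count = if (length(exs) > 0) mean(exs) else NA_real_
    )
  })
  do.call(rbind, rows)
}

#' Fraction of datapoints with all flowers obstructed
#'
#' Per species, the fraction of datapoints scored `unscorable` (all
#' flowers obstructed or not clearly visible) out of all datapoints.
#'
#' @param records Tibble of occurrence records.
#' @return Tibble with `species`, `n_unscorable`, `n_total`, `fraction`.
#' @export
obstructed_fraction <- function(records) {
  species <- sort(unique(records$species))
  rows <- lapply(species, function(sp) {
    r <- records[records$species == sp, , drop = FALSE]
    n <- nrow(r)
    u <- sum(r$exsertion_score == "unscorable")
    tibble::tibble(species = sp, n_unscorable = u, n_total = n,
                   fraction = if (n > 0) u / n else NA_real_)
  })
  do.call(rbind, rows)
}
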