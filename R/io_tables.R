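#' Read a cohort of cells from a canonical CSV file
#'
#' The canonical on-disk schema is plain CSV with one row per segmented
#' nucleus and columns `acinus_id`, `cell_id`, `x`, `y`, `z` (coordinates in
#' micrometres), `transduced` (one of `0/1/true/false/TRUE/FALSE`), and
#' optionally `diameter` (equivalent-sphere cell diameter, micrometres) and
#' `lineage_id`. Units are taken as micrometres throughout; no unit
#' auto-detection is attempted, because silent rescaling is the likeliest
#' corruption mode for centroid tables.
#'
#' @param path Path to a CSV file.
#' @param timepoint Which imaging timepoint the table describes, `"start"`
#'   or `"end"`. Stored in the `timepoint` column of the result.
#' @return A `cohort_table`: a tibble of cell records with a `provenance`
#'   attribute recording the source file, the column mapping used and an
#'   MD5 checksum.
#' @export
read_canonical_csv <- function(path, timepoint = c("start", "end")) {
  timepoint <- match.arg(timepoint)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  required <- c("acinus_id", "cell_id", "x", "y", "z", "transduced")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  out <- tibble::tibble(
    acinus_id = as.character(raw$acinus_id),
    cell_id = as.character(raw$cell_id),
    timepoint = timepoint,
    x = .parse_numeric_column(raw, "x"),
    y = .parse_numeric_column(raw, "y"),
    z = .parse_numeric_column(raw, "z"),
    transduced = .parse_logical_column(raw, "transduced")
  )
  if ("diameter" %in% names(raw)) {
    out$diameter <- .parse_numeric_column(raw, "diameter", allow_na = TRUE)
    if (any(out$diameter <= 0, na.rm = TRUE)) {
      stop("column 'diameter' must be > 0 for all cells", call. = FALSE)
    }
  }
  if ("lineage_id" %in% names(raw)) {
    out$lineage_id <- as.character(raw$lineage_id)
  }
  as_cohort_table(out,
    provenance = list(
      source = path,
      column_map = "canonical",
      checksum = unname(tools::md5sum(path))
    )
  )
}

.parse_numeric_column <- function(raw, col, allow_na = FALSE) {
  v <- suppressWarnings(as.numeric(raw[[col]]))
  bad <- which(is.na(v) & !is.na(raw[[col]]))
  if (length(bad) > 0) {
    stop(sprintf(
      "non-numeric value in column '%s' at row %d: '%s'",
      col, bad[1], raw[[col]][bad[1]]
    ), call. = FALSE)
  }
  if (!allow_na && anyNA(v)) {
    stop(sprintf(
      "missing value in column '%s' at row %d",
      col, which(is.na(v))[1]
    ), call. = FALSE)
  }
  if (any(!is.finite(v[!is.na(v)]))) {
    stop(sprintf("non-finite value in column '%s'", col), call. = FALSE)
  }
  v
}

.parse_logical_column <- function(raw, col) {
  v <- tolower(as.character(raw[[col]]))
  ok <- v %in% c("0", "1", "true", "false")
  if (any(!ok | is.na(v))) {
    bad <- which(!ok | is.na(v))[1]
    stop(sprintf(
      "column '%s' must be one of 0/1/true/false; row %d has '%s'",
      col, bad, raw[[col]][bad]
    ), call. = FALSE)
  }
  v %in% c("1", "true")
}

#' Construct and validate a cohort table
#'
#' Checks the cell-record invariants: finite coordinates, positive
#' diameters where present, and uniqueness of the
#' (`acinus_id`, `timepoint`, `cell_id`) key.
#'
#' @param x A data frame with at least the canonical cell columns.
#' @param provenance Optional list describing where the rows came from.
#' @return `x` as a tibble with class `cohort_table`.
#' @export
as_cohort_table <- function(x, provenance = NULL) {
  x <- tibble::as_tibble(x)
  required <- c("acinus_id", "cell_id", "timepoint", "x", "y", "z", "transduced")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  coords <- as.matrix(x[, c("x", "y", "z")])
  if (!all(is.finite(coords))) {
    stop("cohort coordinates must be finite", call. = FALSE)
  }
  if (!all(x$timepoint %in% c("start", "end"))) {
    stop("timepoint must be 'start' or 'end'", call. = FALSE)
  }
  if ("diameter" %in% names(x) && any(x$diameter <= 0, na.rm = TRUE)) {
    stop("cell diameters must be > 0", call. = FALSE)
  }
  key <- paste(x$acinus_id, x$timepoint, x$cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (acinus_id, timepoint, cell_id) key: ",
      key[which(duplicated(key))[1]],
      call. = FALSE
    )
  }
  end_only <- setdiff(
    x$acinus_id[x$timepoint == "end"],
    x$acinus_id[x$timepoint == "start"]
  )
  if ("start" %in% x$timepoint && length(end_only) > 0) {
    stop(
      "acini present at end but not at start: ",
      paste(end_only, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.null(provenance)) {
    attr(x, "provenance") <- provenance
  }
  class(x) <- c("cohort_table", class(x))
  x
}

#' Read per-acinus coordinate sheets from a supplementary-style workbook
#'
#' Ingests an XLSX workbook laid out with one sheet per acinus, as in the
#' deposited coordinate tables this analysis was designed for. Each sheet
#' name becomes the `acinus_id`. Because the column layout of such
#' workbooks is not standardised, the caller must supply `column_map`
#' naming which sheet columns hold the x/y/z coordinates (and, optionally,
#' the cell identifier and transduction label).
#'
#' Rows whose mapped coordinate cells are empty or non-numeric are skipped,
#' with a message giving the total skipped count. Sheets with no parseable
#' row are omitted with a warning.
#'
#' @param path Path to an `.xlsx` workbook.
#' @param column_map Named list with entries `x`, `y`, `z` (required) and
#'   optionally `cell_id` and `transduced`, giving the sheet column names.
#' @param timepoint `"start"` or `"end"`.
#' @return A [cohort_table][as_cohort_table]. When `column_map$transduced`
#'   is absent, all cells are read as untransduced; use
#'   [merge_transduced_labels()] to apply a label table.
#' @export
read_supplementary_xlsx <- function(path, column_map, timepoint = c("start", "end")) {
  timepoint <- match.arg(timepoint)
  if (!file.exists(path)) {
    stop("input file does not exist: ", path, call. = FALSE)
  }
  for (nm in c("x", "y", "z")) {
    if (is.null(column_map[[nm]])) {
      stop("column_map must name the '", nm, "' column", call. = FALSE)
    }
  }
  sheets <- readxl::excel_sheets(path)
  if (length(sheets) == 0) {
    stop("workbook has no sheets: ", path, call. = FALSE)
  }
  n_skipped <- 0L
  pieces <- list()
  for (sheet in sheets) {
    df <- suppressMessages(readxl::read_excel(path, sheet = sheet))
    mapped <- unlist(column_map[c("x", "y", "z")])
    missing <- setdiff(mapped, names(df))
    if (length(missing) > 0) {
      stop(sprintf(
        "sheet '%s' lacks mapped column(s): %s",
        sheet, paste(missing, collapse = ", ")
      ), call. = FALSE)
    }
    xyz <- vapply(
      c("x", "y", "z"),
      function(a) suppressWarnings(as.numeric(df[[column_map[[a]]]])),
      numeric(nrow(df))
    )
    if (nrow(df) == 1L) xyz <- matrix(xyz, nrow = 1L, dimnames = list(NULL, c("x", "y", "z")))
    keep <- rowSums(is.na(xyz) | !is.finite(xyz)) == 0
    n_skipped <- n_skipped + sum(!keep)
    if (!any(keep)) {
      warning("sheet '", sheet, "' has no parseable coordinate row; acinus omitted",
        call. = FALSE
      )
      next
    }
    cell_id <- if (!is.null(column_map$cell_id) && column_map$cell_id %in% names(df)) {
      as.character(df[[column_map$cell_id]])
    } else {
      sprintf("cell_%03d", seq_len(nrow(df)))
    }
    transduced <- if (!is.null(column_map$transduced) && column_map$transduced %in% names(df)) {
      .parse_logical_column(df, column_map$transduced)
    } else {
      rep(FALSE, nrow(df))
    }
    pieces[[sheet]] <- tibble::tibble(
      acinus_id = sheet,
      cell_id = cell_id[keep],
      timepoint = timepoint,
      x = unname(xyz[keep, 1]),
      y = unname(xyz[keep, 2]),
      z = unname(xyz[keep, 3]),
      transduced = transduced[keep]
    )
  }
  if (length(pieces) == 0) {
    stop("no acinus sheet with parseable rows in ", path, call. = FALSE)
  }
  if (n_skipped > 0) {
    message("read_supplementary_xlsx: skipped ", n_skipped, " row(s) without coordinates")
  }
  as_cohort_table(dplyr::bind_rows(pieces),
    provenance = list(
      source = path,
      column_map = column_map,
      checksum = unname(tools::md5sum(path)),
      n_rows_skipped = n_skipped
    )
  )
}

#' Mark transduced cells from a label table
#'
#' Applies a table of transduced-cell labels to a cohort, either by exact
#' (`acinus_id`, `cell_id`) key or by nearest-centroid matching within a
#' tolerance (for label tables that carry coordinates rather than ids).
#' After merging, `transduced` is `TRUE` exactly for the labelled cells.
#'
#' @param cohort A [cohort_table][as_cohort_table].
#' @param labels A data frame with `acinus_id` plus either `cell_id`
#'   (exact mode) or `x`, `y`, `z` (nearest mode).
#' @param mode `"exact"` or `"nearest"`.
#' @param tolerance Maximum centroid distance (micrometres) for a nearest
#'   match.
#' @return The cohort with `transduced` reset from the labels; the number
#'   of matched labels is stored in the `n_matched` attribute.
#' @export
merge_transduced_labels <- function(cohort, labels, mode = c("exact", "nearest"),
                                    tolerance = 1) {
  mode <- match.arg(mode)
  labels <- tibble::as_tibble(labels)
  cohort$transduced <- FALSE
  if (mode == "exact") {
    if (!all(c("acinus_id", "cell_id") %in% names(labels))) {
      stop("exact mode needs label columns acinus_id and cell_id", call. = FALSE)
    }
    ckey <- paste(cohort$acinus_id, cohort$cell_id, sep = "\r")
    lkey <- paste(labels$acinus_id, labels$cell_id, sep = "\r")
    unmatched <- setdiff(lkey, ckey)
    if (length(unmatched) > 0) {
      stop(
        "label(s) with no matching cell: ",
        paste(gsub("\r", "/", unmatched), collapse = ", "),
        call. = FALSE
      )
    }
    cohort$transduced <- ckey %in% lkey
    n_matched <- length(unique(lkey))
  } else {
    if (!all(c("acinus_id", "x", "y", "z") %in% names(labels))) {
      stop("nearest mode needs label columns acinus_id, x, y, z", call. = FALSE)
    }
    matched_rows <- integer(0)
    unmatched <- character(0)
    for (i in seq_len(nrow(labels))) {
      cand <- which(cohort$acinus_id == labels$acinus_id[i])
      if (length(cand) == 0) {
        unmatched <- c(unmatched, sprintf("label row %d (unknown acinus)", i))
        next
      }
      dd <- sqrt((cohort$x[cand] - labels$x[i])^2 +
        (cohort$y[cand] - labels$y[i])^2 +
        (cohort$z[cand] - labels$z[i])^2)
      j <- which.min(dd)
      if (dd[j] <= tolerance) {
        matched_rows <- c(matched_rows, cand[j])
      } else {
        unmatched <- c(unmatched, sprintf(
          "label row %d (nearest centroid %.3g um away)", i, dd[j]
        ))
      }
    }
    if (length(unmatched) > 0) {
      stop("unmatched label(s): ", paste(unmatched, collapse = "; "), call. = FALSE)
    }
    cohort$transduced[matched_rows] <- TRUE
    n_matched <- length(unique(matched_rows))
  }
  attr(cohort, "n_matched") <- n_matched
  cohort
}

#' Write pipeline tables and a run manifest
#'
#' Writes each table as canonical CSV (full numeric precision) into `path`
#' together with `manifest.json` recording the configuration, seed, package
#' version, input checksums and per-file MD5 checksums of the outputs.
#'
#' @param tables Named list of data frames.
#' @param path Output directory (created if needed).
#' @param config Optional configuration list echoed into the manifest.
#' @param seed Optional integer seed echoed into the manifest.
#' @param input_files Character vector of input paths to checksum.
#' @return The manifest, invisibly.
#' @export
write_results <- function(tables, path, config = NULL, seed = NULL,
                          input_files = character(0)) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (file.access(path, mode = 2) != 0) {
    stop("output directory is not writable: ", path, call. = FALSE)
  }
  files <- list()
  for (nm in names(tables)) {
    fp <- file.path(path, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(tables[[nm]]), fp, progress = FALSE)
    files[[nm]] <- list(
      file = basename(fp),
      rows = nrow(tables[[nm]]),
      checksum = unname(tools::md5sum(fp))
    )
  }
  manifest <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "oncoprox",
    version = as.character(utils::packageVersion("oncoprox")),
    seed = seed,
    config = config,
    inputs = lapply(
      input_files,
      function(f) list(file = f, checksum = unname(tools::md5sum(f)))
    ),
    outputs = files
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null", force = TRUE
  )
  invisible(manifest)
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "<cohort_table> %d cells, %d acini, %d transduced (timepoints: %s)\n",
    nrow(x), length(unique(x$acinus_id)), sum(x$transduced),
    paste(unique(x$timepoint), collapse = ", ")
  ))
  NextMethod()
}
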