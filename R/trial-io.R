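#' Construct a paired-intake trial
#'
#' A trial is an ordered collection of offerings. Each offering presents two
#' feed items to one subject on one occasion and records the mass consumed
#' from each bin (kg dry matter). Offered amounts per bin are optional but,
#' when present, bound the intakes.
#'
#' @param records A data frame with columns `subject`, `occasion`, `item_a`,
#'   `item_b`, `intake_a`, `intake_b` and optionally `offered_a`, `offered_b`.
#'   Intakes and offered amounts are kg DM.
#' @param metadata Free-form list of annotations carried with the trial.
#'
#' @return An object of class `"trial"`: a list with elements `records`
#'   (validated data frame, row order preserved), `items` (distinct feed
#'   labels in order of first appearance) and `metadata`.
#' @export
#' @examples
#' rec <- data.frame(subject = "h1", occasion = "d1",
#'                   item_a = "A0", item_b = "B0",
#'                   intake_a = 0.6, intake_b = 0.2)
#' trial(rec)
trial <- function(records, metadata = list()) {
  records <- as.data.frame(records)
  validate_trial_records(records)
  items <- unique(c(records$item_a, records$item_b))
  structure(
    list(records = records, items = items, metadata = metadata),
    class = "trial"
  )
}

required_trial_cols <- c("subject", "occasion", "item_a", "item_b",
                         "intake_a", "intake_b")

validate_trial_records <- function(records) {
  missing <- setdiff(required_trial_cols, names(records))
  if (length(missing) > 0L) {
    stop("trial records are missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("intake_a", "intake_b", "offered_a", "offered_b")) {
    if (col %in% names(records) && nrow(records) > 0L) {
      x <- records[[col]]
      if (!is.numeric(x) || anyNA(x)) {
        stop("column '", col, "' must be numeric with no missing values",
             call. = FALSE)
      }
    }
  }
  if (nrow(records) == 0L) return(invisible(records))

  bad <- which(records$intake_a < 0 | records$intake_b < 0)
  if (length(bad) > 0L) {
    stop("negative intake in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(records$item_a == records$item_b)
  if (length(bad) > 0L) {
    stop("item_a equals item_b in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (all(c("offered_a", "offered_b") %in% names(records))) {
    bad <- which(records$intake_a > records$offered_a + 1e-9 |
                   records$intake_b > records$offered_b + 1e-9)
    if (length(bad) > 0L) {
      stop("intake exceeds offered amount in row(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(records)
}

#' Default column mapping for trial CSV files
#'
#' Maps the canonical record fields to the column headers found in a source
#' file. Override entries to read files with arbitrary headers, e.g.
#' `trial_schema(item_a = "left_item", intake_a = "left_intake")`.
#'
#' @param subject,occasion,item_a,item_b,intake_a,intake_b,offered_a,offered_b
#'   Column names in the source file. `offered_a`/`offered_b` may be absent
#'   from the file.
#' @return Named character vector mapping canonical field -> file column.
#' @export
trial_schema <- function(subject = "subject", occasion = "occasion",
                         item_a = "item_a", item_b = "item_b",
                         intake_a = "intake_a", intake_b = "intake_b",
                         offered_a = "offered_a", offered_b = "offered_b") {
  c(subject = subject, occasion = occasion,
    item_a = item_a, item_b = item_b,
    intake_a = intake_a, intake_b = intake_b,
    offered_a = offered_a, offered_b = offered_b)
}

#' Read a paired-intake trial from CSV
#'
#' Reads a comma-separated UTF-8 file with a header row, maps columns through
#' `schema`, validates every row and returns a [trial()]. Item labels are
#' taken verbatim (no case folding); row order is preserved. Rows with zero
#' total intake are retained — their interpretation is decided at outcome
#' coding ([code_trial()]). Exactly duplicated rows raise a warning but are
#' retained.
#'
#' @param path Path to the CSV file.
#' @param schema Column mapping from [trial_schema()].
#' @return A [trial()].
#' @export
read_trial <- function(path, schema = trial_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  required <- schema[required_trial_cols]
  missing <- required[!required %in% names(raw)]
  if (length(missing) > 0L) {
    stop("input file is missing mapped column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  present <- schema[schema %in% names(raw)]
  records <- stats::setNames(raw[, present, drop = FALSE], names(present))
  for (col in intersect(c("intake_a", "intake_b", "offered_a", "offered_b"),
                        names(records))) {
    x <- suppressWarnings(as.numeric(records[[col]]))
    bad <- which(is.na(x) & !is.na(records[[col]]))
    if (length(bad) > 0L || anyNA(x)) {
      stop("column '", present[[col]], "' is not numeric in row(s): ",
           paste(if (length(bad)) bad else which(is.na(x)), collapse = ", "),
           call. = FALSE)
    }
    records[[col]] <- x
  }
  if (nrow(records) > 1L && anyDuplicated(records)) {
    warning("duplicated row(s) retained: ",
            paste(which(duplicated(records)), collapse = ", "),
            call. = FALSE)
  }
  trial(records, metadata = list(source = path))
}

#' Write a result table to CSV
#'
#' Writes any of the package's tabular results (or a plain data frame) as
#' CSV with a stable column order. Numeric columns are rounded to 6
#' significant digits, so a written table re-reads equal to the original at
#' that precision.
#'
#' @param x A data frame or a package result object with an
#'   `as.data.frame()` method ([fit_bt()] fits, pairwise test tables,
#'   multiverse summaries).
#' @param path Output file path.
#' @return Invisibly, the data frame that was written.
#' @export
write_table <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], signif, digits = 6L)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(df)
}

#' @export
print.trial <- function(x, ...) {
  cat("Paired-intake trial:", nrow(x$records), "offerings,",
      length(x$items), "items\n")
  if (length(x$items) > 0L) {
    cat("  items:", paste(x$items, collapse = ", "), "\n")
  }
  cat("  subjects:", length(unique(x$records$subject)), "\n")
  invisible(x)
}

#' @export
as.data.frame.trial <- function(x, ...) x$records
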