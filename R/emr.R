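#' EMR table dialect
#'
#' Describes the layout of a delimited EMR table. Two layouts are supported:
#' \describe{
#'   \item{wide}{one row per visit: \code{patient_id, date, dx1..dxK}; empty
#'     cells or the reserved token \code{"EPS"} mark absent diagnosis slots.}
#'   \item{long}{one row per diagnosis: \code{patient_id, date, dx}.}
#' }
#'
#' @param layout \code{"wide"} or \code{"long"}.
#' @param id_col,date_col column names for patient id and visit date.
#' @param dx_prefix wide layout: prefix of the diagnosis columns (dx1, dx2, ...).
#' @param dx_col long layout: the single diagnosis column.
#' @param date_format \code{strptime} format; default ISO-8601.
#' @param sep field separator.
#' @return a list of class \code{emr_dialect}.
#' @export
emr_dialect <- function(layout = c("wide", "long"),
                        id_col = "patient_id", date_col = "date",
                        dx_prefix = "dx", dx_col = "dx",
                        date_format = "%Y-%m-%d", sep = ",") {
  layout <- match.arg(layout)
  structure(list(layout = layout, id_col = id_col, date_col = date_col,
                 dx_prefix = dx_prefix, dx_col = dx_col,
                 date_format = date_format, sep = sep),
            class = "emr_dialect")
}

#' Load an EMR dialect from a YAML config
#'
#' @param path YAML file whose keys match the arguments of [emr_dialect()].
#' @return an \code{emr_dialect}.
#' @export
read_emr_dialect <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(emr_dialect, cfg[names(cfg) %in% names(formals(emr_dialect))])
}

#' Construct a patient record
#'
#' An ordered sequence of dated visits, each carrying one or more normalized
#' diagnosis codes.
#'
#' @param patient_id opaque identifier.
#' @param visits list of \code{list(date = Date, codes = character)} entries,
#'   dates non-decreasing, each codes vector non-empty.
#' @return an object of class \code{patient_record}.
#' @export
patient_record <- function(patient_id, visits) {
  stopifnot(length(visits) >= 1L)
  dates <- as.Date(vapply(visits, function(v) as.character(v$date), ""))
  if (is.unsorted(dates)) stop("visit dates must be non-decreasing", call. = FALSE)
  for (v in visits) {
    if (length(v$codes) < 1L) stop("each visit needs at least one code", call. = FALSE)
  }
  structure(list(patient_id = as.character(patient_id),
                 visits = lapply(seq_along(visits), function(i) {
                   list(date = as.Date(visits[[i]]$date),
                        codes = as.character(visits[[i]]$codes))
                 })),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("patient_record %s: %d visit(s), %d diagnoses\n",
              x$patient_id, length(x$visits),
              sum(lengths(lapply(x$visits, `[[`, "codes")))))
  invisible(x)
}

.is_eps <- function(x) {
  is.na(x) | trimws(x) == "" | toupper(trimws(x)) == "EPS"
}

#' Parse a delimited EMR table into patient records
#'
#' Reads a wide- or long-layout diagnosis table, drops empty/\code{EPS} slots,
#' normalizes codes, merges duplicate (patient, date) rows into a single visit
#' (with a message), and sorts visits chronologically.
#'
#' @param x path to a delimited file, or a \code{data.frame} already in memory.
#' @param dialect an [emr_dialect()].
#' @param keep codes exempt from truncation, passed to [normalize_icd9()].
#' @return list of [patient_record()] objects, ordered by patient id.
#' @export
read_emr <- function(x, dialect = emr_dialect(), keep = default_keep_codes()) {
  df <- if (is.data.frame(x)) x else
    utils::read.csv(x, sep = dialect$sep, colClasses = "character",
                    check.names = FALSE)
  if (nrow(df) == 0L) return(list())
  for (col in c(dialect$id_col, dialect$date_col)) {
    if (!col %in% names(df)) stop(sprintf("missing column '%s'", col), call. = FALSE)
  }
  dates <- as.Date(strptime(df[[dialect$date_col]], dialect$date_format))
  if (anyNA(dates)) {
    stop(sprintf("unparseable date at row(s): %s",
                 paste(utils::head(which(is.na(dates)), 5L), collapse = ", ")),
         call. = FALSE)
  }
  if (dialect$layout == "wide") {
    dx_cols <- grep(paste0("^", dialect$dx_prefix, "[0-9]+$"), names(df), value = TRUE)
    if (length(dx_cols) == 0L) stop("no diagnosis columns found", call. = FALSE)
    dx_cols <- dx_cols[order(as.integer(sub(dialect$dx_prefix, "", dx_cols)))]
    long <- do.call(rbind, lapply(seq_len(nrow(df)), function(i) {
      codes <- unlist(df[i, dx_cols], use.names = FALSE)
      codes <- codes[!.is_eps(codes)]
      if (length(codes) == 0L) return(NULL)
      data.frame(pid = df[[dialect$id_col]][i], date = dates[i],
                 dx = codes, row = i, stringsAsFactors = FALSE)
    }))
  } else {
    codes <- df[[dialect$dx_col]]
    ok <- !.is_eps(codes)
    long <- data.frame(pid = df[[dialect$id_col]][ok], date = dates[ok],
                       dx = codes[ok], row = which(ok), stringsAsFactors = FALSE)
  }
  if (is.null(long) || nrow(long) == 0L) return(list())
  long$dx <- normalize_icd9(long$dx, keep = keep)

  records <- lapply(split(long, long$pid), function(pd) {
    pd <- pd[order(pd$date, pd$row), , drop = FALSE]
    key <- as.character(pd$date)
    if (dialect$layout == "wide" && anyDuplicated(unique(pd[, c("date", "row")])$date)) {
      message(sprintf("patient %s: merged duplicate rows for the same visit date",
                      pd$pid[1L]))
    }
    visits <- lapply(split(seq_len(nrow(pd)), factor(key, levels = unique(key))),
                     function(ii) list(date = pd$date[ii[1L]], codes = pd$dx[ii]))
    patient_record(pd$pid[1L], unname(visits))
  })
  unname(records[order(names(records))])
}

#' Write patient records back to a delimited EMR table
#'
#' Inverse of [read_emr()]: wide layout pads short visits with empty cells,
#' long layout emits one row per diagnosis.
#'
#' @param records list of [patient_record()] objects.
#' @param path output file path.
#' @param dialect an [emr_dialect()].
#' @return \code{path}, invisibly.
#' @export
write_emr <- function(records, path, dialect = emr_dialect()) {
  rows <- list()
  if (dialect$layout == "wide") {
    k_max <- max(c(1L, unlist(lapply(records, function(r)
      lengths(lapply(r$visits, `[[`, "codes"))))))
    for (r in records) for (v in r$visits) {
      codes <- c(v$codes, rep("", k_max - length(v$codes)))
      rows[[length(rows) + 1L]] <- c(r$patient_id, format(v$date, "%Y-%m-%d"), codes)
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- c(dialect$id_col, dialect$date_col, paste0(dialect$dx_prefix, seq_len(k_max)))
  } else {
    for (r in records) for (v in r$visits) for (cd in v$codes) {
      rows[[length(rows) + 1L]] <- c(r$patient_id, format(v$date, "%Y-%m-%d"), cd)
    }
    df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
    names(df) <- c(dialect$id_col, dialect$date_col, dialect$dx_col)
  }
  utils::write.table(df, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write aligned sequences as JSON lines
#'
#' One JSON object per patient: \code{\{patient_id, D, VS, TIS\}} (plus any
#' extra fields such as denoiser scores supplied via \code{extra}).
#'
#' @param seqs named list of [aligned_sequences()] keyed by patient id.
#' @param path output file.
#' @param extra optional named list (parallel to \code{seqs}) of extra fields.
#' @return \code{path}, invisibly.
#' @export
write_sequences_jsonl <- function(seqs, path, extra = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (pid in names(seqs)) {
    obj <- list(patient_id = pid, D = seqs[[pid]]$D,
                VS = seqs[[pid]]$VS, TIS = seqs[[pid]]$TIS)
    if (!is.null(extra) && !is.null(extra[[pid]])) obj <- c(obj, extra[[pid]])
    writeLines(jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA), con)
  }
  invisible(path)
}
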