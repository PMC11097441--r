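#' Normalize an ICD-9 diagnosis code
#'
#' Truncates a raw ICD-9(-CM) token to the category-plus-one-decimal level
#' (\code{XXX.X}), the resolution at which codes are stable across coding-system
#' revisions. Codes with no decimal part (category-level codes such as
#' \code{"490"}) are returned unchanged. Codes listed in \code{keep} are never
#' truncated: curated code lists (the shipped influenza-like noise set, for
#' example) contain a few two-decimal codes such as \code{"466.11"} that must
#' survive normalization verbatim.
#'
#' @param raw character vector of ICD-9-like tokens (digits, optional single
#'   dot, optional leading \code{V}/\code{E}).
#' @param keep character vector of codes exempt from truncation. Defaults to
#'   the union of the shipped noise, trigger and target code lists.
#' @return character vector of normalized codes. Normalization is idempotent.
#' @examples
#' normalize_icd9("465.90")  # "465.9"
#' normalize_icd9("490")     # unchanged
#' normalize_icd9("466.11")  # kept verbatim: in the shipped noise list
#' @export
normalize_icd9 <- function(raw, keep = default_keep_codes()) {
  raw <- trimws(as.character(raw))
  bad <- !grepl("^[VEve]?[0-9]+(\\.[0-9]+)?$", raw) | raw == "" | is.na(raw)
  if (any(bad)) {
    stop(sprintf("malformed ICD-9 token(s): %s",
                 paste(utils::head(raw[bad], 5L), collapse = ", ")),
         call. = FALSE)
  }
  out <- raw
  trunc_it <- !(raw %in% keep)
  has_dec <- grepl("\\.", raw)
  idx <- trunc_it & has_dec
  out[idx] <- sub("^([VEve]?[0-9]+\\.[0-9]).*$", "\\1", raw[idx])
  out
}

#' @rdname normalize_icd9
#' @export
default_keep_codes <- function() {
  spec <- default_trigger_spec()
  unique(c(default_noise_codes(), spec$trigger, spec$targets))
}

#' Shipped influenza-like noise disease codes
#'
#' The default noise disease set: ICD-9 codes for influenza-like illnesses
#' (acute upper-respiratory infections, viral pneumonias, influenza, and
#' related symptom codes). These short-lived, seasonally driven diagnoses are
#' treated as noise to be filtered from sequences before prediction.
#'
#' @return character vector of ICD-9 codes.
#' @export
default_noise_codes <- function() {
  path <- system.file("extdata", "influenza_like_icd9.txt", package = "dxbert")
  readLines(path, warn = FALSE)
}

#' Construct a trigger/target specification
#'
#' A trigger disease is the index condition; its targets are the comorbid
#' diseases whose future occurrence is predicted. \code{k} is the number of
#' trigger occurrences required before the separator-insertion point.
#'
#' @param trigger single ICD-9 code.
#' @param targets character vector of ICD-9 codes, not containing the trigger.
#' @param k positive integer, trigger occurrence count.
#' @return an object of class \code{trigger_spec}.
#' @export
trigger_spec <- function(trigger, targets, k = 2L) {
  stopifnot(length(trigger) == 1L, k >= 1L, length(targets) >= 0L)
  if (trigger %in% targets) stop("trigger must not be one of its own targets", call. = FALSE)
  structure(list(trigger = as.character(trigger),
                 targets = as.character(targets),
                 k = as.integer(k)),
            class = "trigger_spec")
}

#' Default trigger/target specification
#'
#' Hypertension (401.9) as the trigger with its six most closely related
#' chronic diseases as targets: hypertensive heart disease (402.9), chronic
#' ischemic heart disease (414.9), diabetes mellitus (250.0), angina pectoris
#' (413.9), hyperlipidemia (272.4) and benign essential hypertension (401.1);
#' k = 2 trigger occurrences.
#'
#' @return a \code{trigger_spec}.
#' @export
default_trigger_spec <- function() {
  trigger_spec("401.9",
               c("402.9", "414.9", "250.0", "413.9", "272.4", "401.1"),
               k = 2L)
}

#' @export
print.trigger_spec <- function(x, ...) {
  cat(sprintf("trigger_spec: trigger %s (k=%d) -> targets {%s}\n",
              x$trigger, x$k, paste(x$targets, collapse = ", ")))
  invisible(x)
}
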