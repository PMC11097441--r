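#' Aligned diagnosis / visit / time-interval sequences
#'
#' The flattened representation of one patient record: \code{D} the
#' chronologically ordered diagnosis codes, \code{VS} the visit index repeated
#' for every code in that visit (starting at 1), and \code{TIS} the day gap to
#' the previous visit placed on the first code of each visit (0 elsewhere, and
#' 0 for the first visit).
#'
#' @param D character vector of codes.
#' @param VS integer vector of visit indices.
#' @param TIS integer vector of day gaps.
#' @return an object of class \code{aligned_sequences}.
#' @export
aligned_sequences <- function(D, VS, TIS) {
  n <- length(D)
  stopifnot(length(VS) == n, length(TIS) == n)
  structure(list(D = as.character(D), VS = as.integer(VS),
                 TIS = as.integer(TIS)),
            class = "aligned_sequences")
}

#' @export
print.aligned_sequences <- function(x, ...) {
  cat(sprintf("aligned_sequences (n=%d)\n  D:   %s\n  VS:  %s\n  TIS: %s\n",
              length(x$D), paste(x$D, collapse = " "),
              paste(x$VS, collapse = " "), paste(x$TIS, collapse = " ")))
  invisible(x)
}

#' Derive the aligned sequences of a patient record
#'
#' Flattens the record visit by visit. For a record with visits at dates
#' \eqn{dt_1 \le \dots \le dt_m}, position j of visit i contributes code
#' \eqn{d_{i,j}} to \code{D}, the value \eqn{i} to \code{VS}, and to
#' \code{TIS} the gap \eqn{dt_i - dt_{i-1}} in days if j = 1 (with
#' \eqn{dt_0 := dt_1}, so the first entry is always 0) and 0 otherwise.
#'
#' @param record a [patient_record()].
#' @return an [aligned_sequences()] of length equal to the record's total
#'   diagnosis count.
#' @export
derive_sequences <- function(record) {
  stopifnot(inherits(record, "patient_record"))
  codes <- lapply(record$visits, `[[`, "codes")
  m <- lengths(codes)
  dates <- vapply(record$visits, function(v) as.integer(v$date), 0L)
  gaps <- c(0L, diff(dates))
  TIS <- integer(sum(m))
  TIS[cumsum(c(1L, m[-length(m)]))] <- gaps
  aligned_sequences(unlist(codes, use.names = FALSE),
                    rep.int(seq_along(m), m), TIS)
}

#' Pad or truncate aligned sequences to a fixed length
#'
#' Truncation keeps the most recent \code{L} entries (the model predicts the
#' future, so recent history dominates). Padding appends \code{pad_value} to
#' \code{D} and 0 to \code{VS}/\code{TIS}.
#'
#' @param seqs an [aligned_sequences()].
#' @param L target length, at least 1.
#' @param pad_value pad sentinel for the code channel (default \code{"0"}).
#' @return an [aligned_sequences()] of length exactly \code{L}.
#' @export
pad_sequences <- function(seqs, L, pad_value = "0") {
  stopifnot(inherits(seqs, "aligned_sequences"), L >= 1L)
  n <- length(seqs$D)
  if (n > L) {
    idx <- (n - L + 1L):n
    return(aligned_sequences(seqs$D[idx], seqs$VS[idx], seqs$TIS[idx]))
  }
  if (n < L) {
    k <- L - n
    return(aligned_sequences(c(seqs$D, rep(pad_value, k)),
                             c(seqs$VS, rep(0L, k)),
                             c(seqs$TIS, rep(0L, k))))
  }
  seqs
}
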