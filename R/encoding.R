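# Vocabulary, input encoding, masked-code corruption, next-sentence labeling
# and pretraining-balance sampling for the compact BERT encoder.

#' Disease-code vocabulary
#'
#' Special tokens occupy the reserved low ids 1..4 (\code{[PAD]},
#' \code{[CLS]}, \code{[SEP]}, \code{[MASK]}); disease codes follow in sorted
#' order.
#'
#' @param codes character vector of disease codes.
#' @return object of class \code{dx_vocab}: \code{tokens} (id-ordered) and
#'   the reserved id constants.
#' @export
dx_vocabulary <- function(codes) {
  codes <- sort(unique(as.character(codes)))
  specials <- c("[PAD]", "[CLS]", "[SEP]", "[MASK]")
  if (any(codes %in% specials)) stop("codes clash with special tokens", call. = FALSE)
  structure(list(tokens = c(specials, codes),
                 pad_id = 1L, cls_id = 2L, sep_id = 3L, mask_id = 4L,
                 n_special = 4L),
            class = "dx_vocab")
}

#' @rdname dx_vocabulary
#' @param vocab a \code{dx_vocab}.
#' @param x codes (for \code{vocab_id}) or ids (for \code{vocab_token}).
#' @export
vocab_id <- function(vocab, x) {
  id <- match(x, vocab$tokens)
  if (anyNA(id)) stop(sprintf("code(s) not in vocabulary: %s",
                              paste(unique(x[is.na(id)]), collapse = ", ")),
                      call. = FALSE)
  id
}

#' @rdname dx_vocabulary
#' @export
vocab_token <- function(vocab, x) vocab$tokens[x]

#' @export
print.dx_vocab <- function(x, ...) {
  cat(sprintf("dx_vocab: %d tokens (%d codes + 4 special)\n",
              length(x$tokens), length(x$tokens) - 4L))
  invisible(x)
}

.time_bucket <- function(days) {
  # boundaries: 0 | 1-7 | 8-30 | 31-90 | 91-365 | >365
  findInterval(days, c(-Inf, 1, 8, 31, 91, 366))
}

#' Encode aligned sequences for the BERT module
#'
#' Produces the three aligned id channels the encoder consumes: token ids
#' (codes with \code{[CLS]} first and one \code{[SEP]} at \code{sep_after}),
#' segment ids (visit index, capped), and time ids (bucketized day gaps on
#' boundaries 0, 1\eqn{-}7, 8\eqn{-}30, 31\eqn{-}90, 91\eqn{-}365, >365),
#' plus the pad mask. Over-long inputs keep the most recent pre-separator
#' codes and the earliest post-separator codes.
#'
#' @param seqs an [aligned_sequences()] (unpadded).
#' @param vocab a [dx_vocabulary()].
#' @param L output length (default 75).
#' @param sep_after number of leading sequence positions preceding the
#'   \code{[SEP]} token; \code{length(seqs$D)} appends it at the end.
#' @param max_visit cap for the segment channel.
#' @return object of class \code{input_encoding}: \code{token_ids},
#'   \code{segment_ids}, \code{time_ids}, \code{side_ids} (1 up to and
#'   including \code{[SEP]}, 2 after it -- the sentence-A/B channel of the
#'   original BERT, which the next-sentence objective needs), and
#'   \code{pad_mask}, all length L.
#' @export
encode_input <- function(seqs, vocab, L = 75L, sep_after = length(seqs$D),
                         max_visit = 50L) {
  stopifnot(L >= 4L, sep_after >= 0L, sep_after <= length(seqs$D))
  tok <- vocab_id(vocab, seqs$D)
  seg <- pmin(pmax(seqs$VS, 1L), max_visit)
  tim <- .time_bucket(seqs$TIS)
  pre <- seq_len(sep_after)
  post <- if (sep_after < length(tok)) (sep_after + 1L):length(tok) else integer(0)
  # budget: L minus [CLS] and [SEP]; the post-separator part (which carries
  # the outcome window) has priority, the pre-separator history keeps its
  # most recent suffix in the remaining room
  n_keep <- L - 2L
  post <- post[seq_len(min(length(post), n_keep))]
  n_pre <- min(length(pre), n_keep - length(post))
  pre <- pre[seq.int(length.out = n_pre, to = length(pre))]  # most recent suffix
  seg_cls <- if (length(pre) > 0L) seg[pre[1L]] else 1L
  seg_sep <- if (length(pre) > 0L) seg[pre[length(pre)]] else 1L
  ids <- c(vocab$cls_id, tok[pre], vocab$sep_id, tok[post])
  segs <- c(seg_cls, seg[pre], seg_sep, seg[post])
  tims <- c(1L, tim[pre], 1L, tim[post])
  # separator-side channel (sentence A/B in the original BERT sense):
  # 1 up to and including [SEP], 2 after it
  side <- c(rep(1L, 2L + length(pre)), rep(2L, length(post)))
  n <- length(ids)
  pad <- L - n
  structure(list(token_ids = c(ids, rep(vocab$pad_id, pad)),
                 segment_ids = c(segs, rep(1L, pad)),
                 time_ids = c(tims, rep(1L, pad)),
                 side_ids = c(side, rep(1L, pad)),
                 pad_mask = c(rep(TRUE, n), rep(FALSE, pad))),
            class = "input_encoding")
}

#' Masking policy for the masked-code objective
#'
#' A position entering the objective is selected with probability
#' \code{p_select}; conditional on selection it is replaced by \code{[MASK]}
#' with probability 0.70, by a random non-special vocabulary code (never the
#' original) with probability 0.15, or kept with probability 0.15.
#'
#' @param p_select selection fraction (default 0.15).
#' @param p_mask,p_random,p_keep conditional replacement probabilities;
#'   must sum to 1.
#' @return a list of class \code{masking_policy}.
#' @export
masking_policy <- function(p_select = 0.15, p_mask = 0.70, p_random = 0.15,
                           p_keep = 0.15) {
  stopifnot(p_select >= 0, p_select < 1,
            abs(p_mask + p_random + p_keep - 1) < 1e-12)
  structure(list(p_select = p_select, p_mask = p_mask, p_random = p_random,
                 p_keep = p_keep), class = "masking_policy")
}

#' Apply masked-code corruption to an encoding
#'
#' Consumes the current RNG stream with a fixed contract, so a fixed seed
#' reproduces the exact corruption pattern: for each maskable position in
#' order, one uniform draw decides selection; for a selected position a
#' second uniform draw decides mask/random/keep, and a random replacement is
#' drawn by a single \code{sample.int} over the non-special vocabulary
#' excluding the original code.
#'
#' @param enc an [encode_input()] result.
#' @param vocab a [dx_vocabulary()].
#' @param policy a [masking_policy()].
#' @return list: \code{encoding} (corrupted), \code{targets} (named integer
#'   vector, original ids keyed by position), \code{action} (per-target
#'   \code{"mask"}/\code{"random"}/\code{"keep"}).
#' @export
apply_mlm_mask <- function(enc, vocab, policy = masking_policy()) {
  tok <- enc$token_ids
  maskable <- which(enc$pad_mask & tok > vocab$n_special)
  targets <- integer(0); action <- character(0)
  nv <- length(vocab$tokens)
  for (i in maskable) {
    if (stats::runif(1) >= policy$p_select) next
    orig <- tok[i]
    u <- stats::runif(1)
    if (u < policy$p_mask) {
      tok[i] <- vocab$mask_id
      act <- "mask"
    } else if (u < policy$p_mask + policy$p_random) {
      choices <- setdiff((vocab$n_special + 1L):nv, orig)
      tok[i] <- choices[sample.int(length(choices), 1L)]
      act <- "random"
    } else {
      act <- "keep"
    }
    targets <- c(targets, stats::setNames(orig, i))
    action <- c(action, act)
  }
  enc$token_ids <- tok
  list(encoding = enc, targets = targets, action = action)
}

#' Build a next-sentence example from a patient record
#'
#' Implements the separator-insertion and labeling rules: if the trigger
#' occurs at least k times, \code{[SEP]} is inserted after the visit holding
#' the k-th occurrence and the label is 1 iff any target code occurs in a
#' strictly later visit dated within the horizon of that visit (a target in
#' the separator visit itself does not count). A patient with trigger or
#' target diagnoses but fewer than k trigger occurrences gets \code{[SEP]}
#' at the end and label 0. A patient with neither trigger nor target codes
#' is excluded (returns \code{NULL}).
#'
#' @param record a [patient_record()].
#' @param spec a [trigger_spec()].
#' @param vocab a [dx_vocabulary()].
#' @param horizon_days prediction horizon T in days (default 365, one year).
#' @param L encoder length.
#' @param max_visit segment cap.
#' @param keep optional logical vector over the record's flattened sequence
#'   positions (a denoiser keep mask). The separator placement and the label
#'   are always determined on the raw record; only the encoded sequence is
#'   filtered.
#' @return an object of class \code{nsp_example} (\code{encoding},
#'   \code{label}, \code{sep_date}, \code{patient_id}, \code{horizon_days}),
#'   or \code{NULL} for an excluded patient.
#' @export
make_nsp_example <- function(record, spec, vocab, horizon_days = 365L,
                             L = 75L, max_visit = 50L, keep = NULL) {
  seqs <- derive_sequences(record)
  trig_pos <- which(seqs$D == spec$trigger)
  has_any <- length(trig_pos) > 0L || any(seqs$D %in% spec$targets)
  if (!has_any) return(NULL)
  dates <- as.Date(vapply(record$visits, function(v) as.character(v$date), ""))
  if (length(trig_pos) >= spec$k) {
    kth_visit <- seqs$VS[trig_pos[spec$k]]
    sep_after <- max(which(seqs$VS == kth_visit))   # end of the k-th trigger's visit
    sep_date <- dates[kth_visit]
    later <- which(seq_along(record$visits) > kth_visit &
                     dates <= sep_date + horizon_days)
    label <- as.integer(any(vapply(later, function(i)
      any(record$visits[[i]]$codes %in% spec$targets), FALSE)))
  } else {
    sep_after <- length(seqs$D)
    sep_date <- dates[length(dates)]
    label <- 0L
  }
  if (!is.null(keep)) {
    stopifnot(length(keep) == length(seqs$D))
    sep_after <- sum(keep[seq_len(sep_after)])
    seqs <- aligned_sequences(seqs$D[keep], seqs$VS[keep], seqs$TIS[keep])
    if (length(seqs$D) == 0L) return(NULL)
  }
  enc <- encode_input(seqs, vocab, L = L, sep_after = sep_after,
                      max_visit = max_visit)
  structure(list(encoding = enc, label = label, sep_date = sep_date,
                 patient_id = record$patient_id,
                 horizon_days = as.integer(horizon_days)),
            class = "nsp_example")
}

#' @export
print.nsp_example <- function(x, ...) {
  cat(sprintf("nsp_example %s: label %d, [SEP] visit date %s\n",
              x$patient_id, x$label, format(x$sep_date)))
  invisible(x)
}

#' Balance next-sentence examples for pretraining
#'
#' Stratified sampling without replacement to a fixed positive fraction
#' (default 20\% positive / 80\% negative, reflecting the rarity of
#' comorbidity onset). The largest total consistent with both class counts
#' is used; if a class is empty the best achievable composition is returned
#' with a warning.
#'
#' @param examples list of [make_nsp_example()] results.
#' @param positive_fraction requested positive share.
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return list of examples with positive fraction equal to the request up
#'   to integer rounding.
#' @export
balance_pretraining <- function(examples, positive_fraction = 0.20, seed = 1L) {
  labels <- vapply(examples, `[[`, 0L, "label")
  pos <- which(labels == 1L); neg <- which(labels == 0L)
  f <- positive_fraction
  if ((f > 0 && length(pos) == 0L) || (f < 1 && length(neg) == 0L)) {
    warning(sprintf("cannot reach positive fraction %.2f (pos=%d, neg=%d); returning best achievable",
                    f, length(pos), length(neg)))
    return(examples)
  }
  n_total <- if (f == 0) length(neg) else if (f == 1) length(pos) else
    min(floor(length(pos) / f), floor(length(neg) / (1 - f)))
  n_pos <- round(n_total * f); n_neg <- n_total - n_pos
  with_seed_(seed, {
    keep <- c(if (n_pos > 0L) pos[sample.int(length(pos), n_pos)],
              if (n_neg > 0L) neg[sample.int(length(neg), n_neg)])
    examples[sample(keep)]
  })
}
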