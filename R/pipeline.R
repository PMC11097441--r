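# End-to-end pipeline: cohort -> sequences -> comorbidity graph -> embedding
# -> denoiser -> encoder pretraining/fine-tuning -> prediction/metrics.
# `run_experiment()` is the in-R engine; the run_* functions wrap it with
# file IO for the command-line interface (inst/cli/dxbert.R).

#' Position labels for semi-supervised denoiser training
#'
#' Label 1 where the code is in the noise set, 0 where it is the trigger or
#' a target, \code{NA} (unlabeled) elsewhere.
#'
#' @param D character vector of codes.
#' @param noise_codes noise set.
#' @param spec a [trigger_spec()].
#' @return numeric vector of 1/0/\code{NA}.
#' @export
position_labels <- function(D, noise_codes, spec) {
  lab <- rep(NA_real_, length(D))
  lab[D %in% noise_codes] <- 1
  lab[D %in% c(spec$trigger, spec$targets)] <- 0
  lab
}

.embed_seq <- function(emb, D) t(emb$vectors[D, , drop = FALSE])

#' Fit and evaluate the full prediction pipeline on a cohort
#'
#' Builds the comorbidity graph and disease embeddings, trains the
#' double-attention denoiser on semi-supervised position labels, filters
#' each sequence at the threshold theta (skipped when
#' \code{denoise = FALSE}), constructs next-sentence examples, pretrains the
#' compact encoder on the balanced corpus, fine-tunes on the training split,
#' and evaluates on the held-out validation split.
#'
#' @param records named list of [patient_record()] objects.
#' @param spec a [trigger_spec()].
#' @param noise_codes noise set used for labels and graph exclusion.
#' @param denoise run the denoiser filter (\code{FALSE} feeds the raw
#'   sequences to the encoder).
#' @param theta keep threshold on the dense score.
#' @param alpha,beta denoiser mixing weights, or \code{"auto"} to estimate
#'   them from the training corpus via [estimate_mix_weights()].
#' @param L encoder sequence length.
#' @param d_emb,q embedding and denoiser hidden sizes.
#' @param denoiser_epochs,pretrain_epochs,finetune_epochs schedules.
#' @param bert_cfg a [bert_config()] (its \code{L} is overridden).
#' @param val_fraction held-out share of scoreable patients.
#' @param positive_fraction pretraining balance (see [balance_pretraining()]).
#' @param seed integer seed driving every stochastic step.
#' @return list: \code{metrics} (validation, [evaluate_predictions()]),
#'   \code{probs}, \code{labels}, \code{model}, \code{denoiser},
#'   \code{embedding}, \code{graph}, \code{n_excluded}.
#' @export
run_experiment <- function(records, spec = default_trigger_spec(),
                           noise_codes = default_noise_codes(),
                           denoise = TRUE, theta = 0.5,
                           alpha = "auto", beta = "auto",
                           L = 75L, d_emb = 32L, q = 16L,
                           denoiser_epochs = 8L, pretrain_epochs = 2L,
                           finetune_epochs = 25L,
                           bert_cfg = bert_config(hidden = 32L, d_ff = 64L),
                           val_fraction = 0.3, positive_fraction = 0.2,
                           seed = 1L) {
  all_codes <- unique(unlist(lapply(records, function(r)
    unlist(lapply(r$visits, `[[`, "codes")))))
  vocab <- dx_vocabulary(all_codes)
  seqs <- lapply(records, derive_sequences)

  triggers <- select_triggers(records, noise_codes = noise_codes, k = spec$k)
  if (!any(vapply(triggers, function(t) t$trigger == spec$trigger, FALSE))) {
    com <- find_comorbidities(records, spec$trigger, spec$k)
    if (length(com) > 0L) {
      triggers <- c(triggers, list(trigger_spec(spec$trigger, names(com), spec$k)))
    }
  }
  graph <- comorbidity_graph(records, triggers = triggers,
                             noise_codes = noise_codes)
  emb <- embed_graph(graph, d_emb = d_emb, vocab = all_codes,
                     seed = seed)

  if (identical(alpha, "auto") || identical(beta, "auto")) {
    mw <- estimate_mix_weights(records, noise_codes, spec$trigger)
    if (identical(alpha, "auto")) alpha <- mw$alpha
    if (identical(beta, "auto")) beta <- mw$beta
  }

  den <- NULL
  keeps <- stats::setNames(vector("list", length(records)), names(records))
  if (denoise) {
    X_list <- lapply(seqs, function(s) .embed_seq(emb, s$D))
    lab_list <- lapply(seqs, function(s) position_labels(s$D, noise_codes, spec))
    den <- train_denoiser(X_list, lab_list, q = q, alpha = alpha, beta = beta,
                          epochs = denoiser_epochs, seed = seed)
    for (pid in names(records)) {
      sc <- denoiser_scores(den$params, X_list[[pid]], alpha, beta)
      keeps[[pid]] <- sc > theta
    }
  }

  examples <- lapply(names(records), function(pid) {
    make_nsp_example(records[[pid]], spec, vocab, L = L,
                     keep = if (denoise) keeps[[pid]] else NULL)
  })
  names(examples) <- names(records)
  ok <- !vapply(examples, is.null, FALSE)
  n_excluded <- sum(!ok)
  examples <- examples[ok]
  if (length(examples) < 4L) stop("too few scoreable patients", call. = FALSE)

  with_seed_(seed + 17L, {
    n <- length(examples)
    val_idx <- sample.int(n, max(1L, round(val_fraction * n)))
  })
  train_ex <- examples[-val_idx]; val_ex <- examples[val_idx]

  cfg <- bert_cfg; cfg$L <- L
  model <- bert_init(cfg, vocab, seed = seed)
  pre_ex <- balance_pretraining(train_ex, positive_fraction, seed = seed)
  model <- pretrain_bert(model, pre_ex, epochs = pretrain_epochs, seed = seed)
  model <- finetune_bert(model, train_ex, epochs = finetune_epochs, seed = seed)

  probs <- predict_bert(model, val_ex)
  labels <- vapply(val_ex, `[[`, 0L, "label")
  list(metrics = evaluate_predictions(probs, labels),
       probs = probs, labels = labels, model = model, denoiser = den,
       embedding = emb, graph = graph, n_excluded = n_excluded,
       alpha = alpha, beta = beta, vocab = vocab)
}

#' Pipeline stage commands
#'
#' File-level wrappers used by the command-line interface: \code{run_simulate}
#' writes a synthetic cohort; \code{run_preprocess} parses an EMR table and
#' writes sequences, the comorbidity graph, embeddings and a run manifest;
#' \code{run_train_eval} runs [run_experiment()] and writes predictions and
#' a metrics JSON.
#'
#' @param out_dir output directory.
#' @param n_patients cohort size.
#' @param seed integer seed.
#' @param config a [cohort_config()] override.
#' @return the output directory, invisibly.
#' @export
run_simulate <- function(out_dir, n_patients = 1000L, seed = 1L,
                         config = NULL) {
  if (is.null(config)) config <- cohort_config(n_patients = as.integer(n_patients))
  cohort <- generate_cohort(config, seed = seed)
  write_cohort(cohort, out_dir)
}

#' @rdname run_simulate
#' @param emr_path input EMR table.
#' @param dialect an [emr_dialect()].
#' @param noise_codes noise set.
#' @param spec a [trigger_spec()].
#' @param d_emb embedding dimension.
#' @export
run_preprocess <- function(emr_path, out_dir, dialect = emr_dialect(),
                           noise_codes = default_noise_codes(),
                           spec = default_trigger_spec(), d_emb = 32L,
                           seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_emr(emr_path, dialect)
  names(records) <- vapply(records, `[[`, "", "patient_id")
  seqs <- lapply(records, derive_sequences)
  write_sequences_jsonl(seqs, file.path(out_dir, "sequences.jsonl"))
  triggers <- select_triggers(records, noise_codes = noise_codes, k = spec$k)
  manifest <- list(seed = seed, n_patients = length(records),
                   n_triggers = length(triggers))
  if (length(triggers) == 0L) {
    warning("no qualifying trigger diseases; graph stage skipped")
    manifest$graph <- "empty"
  } else {
    graph <- comorbidity_graph(records, triggers = triggers,
                               noise_codes = noise_codes)
    write_graph_tsv(graph, file.path(out_dir, "comorbidity"))
    all_codes <- unique(unlist(lapply(seqs, `[[`, "D")))
    emb <- embed_graph(graph, d_emb = d_emb, vocab = all_codes, seed = seed)
    write_embedding(emb, file.path(out_dir, "embedding"))
    manifest$n_vertices <- length(graph$vertices)
    manifest$n_edges <- nrow(graph$edges)
  }
  vocab <- dx_vocabulary(unique(unlist(lapply(seqs, `[[`, "D"))))
  excluded <- sum(vapply(records, function(r)
    is.null(make_nsp_example(r, spec, vocab)), FALSE))
  manifest$n_excluded <- excluded
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}

#' @rdname run_simulate
#' @param denoise logical; \code{FALSE} bypasses the denoiser.
#' @param ... passed to [run_experiment()].
#' @export
run_train_eval <- function(emr_path, out_dir, dialect = emr_dialect(),
                           spec = default_trigger_spec(), denoise = TRUE,
                           seed = 1L, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_emr(emr_path, dialect)
  names(records) <- vapply(records, `[[`, "", "patient_id")
  res <- run_experiment(records, spec = spec, denoise = denoise,
                        seed = seed, ...)
  utils::write.csv(data.frame(probability = res$probs, label = res$labels),
                   file.path(out_dir, "predictions.csv"), row.names = FALSE)
  jsonlite::write_json(c(res$metrics[c("auc", "accuracy", "precision",
                                       "recall", "f1")],
                         list(seed = seed, denoise = denoise,
                              n_excluded = res$n_excluded)),
                       file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(out_dir)
}
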