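# Synthetic EMR cohorts with the statistical structure the method assumes:
# short single-peak revisit intervals for noise (influenza-like) codes,
# multi-peak chronic revisit intervals for trigger/target codes, a planted
# trigger -> target causal rule, and per-position noise ground truth.

#' Synthetic cohort configuration
#'
#' Defaults emulate the claims-data structure the method was designed for:
#' a noise-position share of 0.205 (the marginal probability of
#' influenza-like diagnoses in the reference registry), log-normal noise
#' revisit intervals with mode near 10 days, a four-component Gaussian
#' mixture of chronic revisit intervals (four distinct peaks), and a
#' negative-binomial chronic event budget with mean 27.34 and standard
#' deviation 20.93 per patient.
#'
#' @param n_patients cohort size.
#' @param start_date first possible visit date.
#' @param noise_codes noise disease codes (default shipped influenza-like set).
#' @param spec a [trigger_spec()] (default hypertension and its six targets).
#' @param other_chronic background chronic codes outside the trigger/target
#'   sets (they co-occur with chronic streams, so they join the comorbidity
#'   graph rather than standing apart like noise codes).
#' @param noise_prevalence expected fraction of sequence positions carrying a
#'   noise code.
#' @param noise_meanlog,noise_sdlog log-normal parameters of noise revisit
#'   gaps (median \code{exp(noise_meanlog)} = 10 days).
#' @param chronic_peaks,chronic_sds,chronic_weights Gaussian-mixture revisit
#'   gaps for chronic codes, in days.
#' @param p_trigger probability a patient carries the trigger condition.
#' @param p_background_target probability a patient carries one target code
#'   as a pre-existing condition.
#' @param rule_strength probability that a patient satisfying the k-trigger
#'   rule develops a target disease within the horizon.
#' @param horizon_days prediction horizon T (days).
#' @param visits_mean,visits_sd negative-binomial chronic event budget.
#' @return a list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 1000L,
                          start_date = as.Date("2010-01-01"),
                          noise_codes = default_noise_codes(),
                          spec = default_trigger_spec(),
                          other_chronic = c("715.9", "724.2", "530.8",
                                            "533.9", "564.0", "585",
                                            "300.4", "311", "274.9",
                                            "493.9", "496", "719.4"),
                          noise_prevalence = 0.205,
                          noise_meanlog = log(10), noise_sdlog = 0.3,
                          chronic_peaks = c(30, 90, 180, 365),
                          chronic_sds = c(7, 15, 25, 40),
                          chronic_weights = c(0.35, 0.30, 0.20, 0.15),
                          p_trigger = 0.6, p_background_target = 0.15,
                          rule_strength = 0.5, horizon_days = 365L,
                          visits_mean = 27.34, visits_sd = 20.93) {
  stopifnot(noise_prevalence >= 0, noise_prevalence < 1,
            rule_strength >= 0, rule_strength <= 1,
            abs(sum(chronic_weights) - 1) < 1e-9)
  structure(as.list(environment()), class = "cohort_config")
}

.rgap_chronic <- function(n, cfg) {
  comp <- sample.int(length(cfg$chronic_peaks), n, replace = TRUE,
                     prob = cfg$chronic_weights)
  pmax(1, round(stats::rnorm(n, cfg$chronic_peaks[comp],
                             cfg$chronic_sds[comp])))
}

.rgap_noise <- function(n, cfg) {
  pmax(1, round(stats::rlnorm(n, cfg$noise_meanlog, cfg$noise_sdlog)))
}

# one condition stream: event dates for `n_ev` recurrences of one code
.stream <- function(code, n_ev, first_offset, gaps) {
  if (n_ev < 1L) return(NULL)
  offs <- first_offset + cumsum(c(0, gaps[seq_len(n_ev - 1L)]))
  data.frame(off = offs, code = code, stringsAsFactors = FALSE)
}

#' Generate a synthetic cohort with ground truth
#'
#' Each patient carries a set of chronic condition streams (trigger, targets,
#' background chronic codes) whose recurrences follow the multi-peak chronic
#' gap mixture, plus short noise episodes following the single-peak
#' log-normal gaps; events merge into dated visits. For patients whose
#' trigger occurs at least k times, target onset after the k-th trigger
#' visit is planted with probability \code{rule_strength} (and suppressed
#' within the horizon otherwise), so the cohort's next-sentence labels are
#' controlled by construction.
#'
#' @param config a [cohort_config()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return list with \code{records} (list of [patient_record()]),
#'   \code{truth} (per patient: \code{noise_flags} aligned to the derived
#'   disease sequence and \code{nsp_label}), \code{config}, \code{seed}.
#' @export
generate_cohort <- function(config = cohort_config(), seed = 1L) {
  cfg <- config
  if (cfg$n_patients == 0L) {
    return(list(records = list(), truth = list(), config = cfg, seed = seed))
  }
  with_seed_(seed, {
    nb_size <- if (cfg$visits_sd^2 > cfg$visits_mean)
      cfg$visits_mean^2 / (cfg$visits_sd^2 - cfg$visits_mean) else 100
    records <- vector("list", cfg$n_patients)
    truth <- vector("list", cfg$n_patients)
    for (i in seq_len(cfg$n_patients)) {
      pid <- sprintf("P%05d", i)
      budget <- max(3L, stats::rnbinom(1L, size = nb_size,
                                       mu = cfg$visits_mean))
      conds <- sample(cfg$other_chronic,
                      min(length(cfg$other_chronic), 1L + stats::rpois(1L, 1.5)))
      has_trigger <- stats::runif(1) < cfg$p_trigger
      if (has_trigger) conds <- c(cfg$spec$trigger, conds)
      if (stats::runif(1) < cfg$p_background_target) {
        conds <- c(conds, sample(cfg$spec$targets, 1L))
      }
      conds <- unique(conds)
      # split the chronic event budget across condition streams
      w <- stats::runif(length(conds), 0.5, 1.5)
      if (has_trigger) w[1L] <- w[1L] * 1.5   # the index condition recurs most
      n_ev <- pmax(1L, round(budget * w / sum(w)))
      ev <- do.call(rbind, lapply(seq_along(conds), function(j) {
        .stream(conds[j], n_ev[j],
                first_offset = sample.int(360L, 1L),
                gaps = .rgap_chronic(max(1L, n_ev[j]), cfg))
      }))
      # noise episodes sized so noise positions make up ~noise_prevalence
      n_noise <- stats::rpois(1L, cfg$noise_prevalence /
                                max(1e-9, 1 - cfg$noise_prevalence) * nrow(ev))
      if (n_noise > 0L) {
        remaining <- n_noise
        noise_ev <- list()
        while (remaining > 0L) {
          len <- min(remaining, sample(2:4, 1L))
          code <- sample(cfg$noise_codes, 1L)
          noise_ev[[length(noise_ev) + 1L]] <-
            .stream(code, len, first_offset = sample.int(900L, 1L),
                    gaps = .rgap_noise(len, cfg))
          remaining <- remaining - len
        }
        ev <- rbind(ev, do.call(rbind, noise_ev))
      }
      # enforce the planted trigger -> target rule
      ev <- ev[order(ev$off), , drop = FALSE]
      if (has_trigger) {
        tpos <- which(ev$code == cfg$spec$trigger)
        if (length(tpos) >= cfg$spec$k) {
          sep_off <- ev$off[tpos[cfg$spec$k]]
          in_window <- ev$code %in% cfg$spec$targets &
            ev$off > sep_off & ev$off <= sep_off + cfg$horizon_days
          if (stats::runif(1) < cfg$rule_strength) {
            if (!any(in_window)) {
              onset <- sep_off + sample(30:300, 1L)
              ev <- rbind(ev, data.frame(off = onset,
                                         code = sample(cfg$spec$targets, 1L)))
            }
          } else if (any(in_window)) {
            ev <- ev[!in_window, , drop = FALSE]
          }
        }
      }
      ev <- ev[order(ev$off), , drop = FALSE]
      dates <- cfg$start_date + ev$off
      visits <- lapply(split(seq_len(nrow(ev)),
                             factor(ev$off, levels = unique(ev$off))),
                       function(ii) list(date = dates[ii[1L]],
                                         codes = ev$code[ii]))
      rec <- patient_record(pid, unname(visits))
      records[[i]] <- rec
      D <- derive_sequences(rec)$D
      truth[[i]] <- list(patient_id = pid,
                         noise_flags = D %in% cfg$noise_codes,
                         nsp_label = NA_integer_)
    }
    names(records) <- vapply(records, `[[`, "", "patient_id")
    names(truth) <- names(records)
    vocab <- dx_vocabulary(unique(unlist(lapply(records, function(r)
      unlist(lapply(r$visits, `[[`, "codes"))))))
    for (i in seq_along(records)) {
      ex <- make_nsp_example(records[[i]], cfg$spec, vocab,
                             horizon_days = cfg$horizon_days)
      truth[[i]]$nsp_label <- if (is.null(ex)) NA_integer_ else ex$label
    }
    list(records = records, truth = truth, config = cfg, seed = seed)
  })
}

#' The worked four-visit example record
#'
#' A diabetic patient with four dated visits: 2013-11-11 (250.0), 2013-11-21
#' (726.0, 438.5, 847.0), 2013-12-05 (250.0), 2013-12-09 (414.0, 401.9,
#' 250.0). Its derived sequences are the package's canonical small fixture.
#'
#' @return a [patient_record()].
#' @export
worked_example <- function() {
  patient_record("A", list(
    list(date = as.Date("2013-11-11"), codes = "250.0"),
    list(date = as.Date("2013-11-21"), codes = c("726.0", "438.5", "847.0")),
    list(date = as.Date("2013-12-05"), codes = "250.0"),
    list(date = as.Date("2013-12-09"), codes = c("414.0", "401.9", "250.0"))))
}

#' The toy trigger/target map
#'
#' Three trigger diseases with their target sets: 250.0 -> {401.9, 272.4},
#' 401.9 -> {414.9, 437.0}, 272.4 -> {437.0}. Feeding this map to
#' [comorbidity_graph()] yields the five-vertex, five-edge toy graph.
#'
#' @return named list mapping trigger codes to target-code vectors.
#' @export
toy_graph_example <- function() {
  list("250.0" = c("401.9", "272.4"),
       "401.9" = c("414.9", "437.0"),
       "272.4" = "437.0")
}

#' Write a synthetic cohort to disk
#'
#' Emits the EMR table in the requested dialect plus a JSON-lines ground
#' truth sidecar (patient_id, noise_flags, nsp_label) and a JSON manifest
#' recording the seed.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param dialect an [emr_dialect()].
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir, dialect = emr_dialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (length(cohort$records) > 0L) {
    write_emr(cohort$records, file.path(dir, "emr.csv"), dialect)
  } else {
    writeLines(paste(dialect$id_col, dialect$date_col,
                     paste0(dialect$dx_prefix, 1L), sep = dialect$sep),
               file.path(dir, "emr.csv"))
  }
  con <- file(file.path(dir, "truth.jsonl"), "wt")
  for (tr in cohort$truth) {
    writeLines(jsonlite::toJSON(tr, auto_unbox = TRUE, na = "null"), con)
  }
  close(con)
  jsonlite::write_json(list(seed = cohort$seed,
                            n_patients = cohort$config$n_patients,
                            noise_prevalence = cohort$config$noise_prevalence),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
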