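#' Mine comorbidities of a trigger disease
#'
#' A disease u (distinct from the trigger) counts as a comorbidity for a
#' patient when some occurrence of u lies at a strictly later flattened
#' sequence position than the k-th occurrence of the trigger in that patient's
#' diagnosis sequence. Each patient contributes at most once per target
#' (prevalence, not incidence).
#'
#' @param records list of [patient_record()] objects.
#' @param trigger trigger disease code.
#' @param k required number of trigger occurrences (>= 1).
#' @return named integer vector: per-target patient-support counts, sorted by
#'   decreasing support then code.
#' @export
find_comorbidities <- function(records, trigger, k = 2L) {
  stopifnot(k >= 1L)
  support <- new.env(parent = emptyenv())
  for (r in records) {
    D <- derive_sequences(r)$D
    pos <- which(D == trigger)
    if (length(pos) < k) next
    kth <- pos[k]
    if (kth >= length(D)) next
    after <- unique(D[(kth + 1L):length(D)])
    after <- setdiff(after, trigger)
    for (u in after) {
      support[[u]] <- (if (is.null(support[[u]])) 0L else support[[u]]) + 1L
    }
  }
  out <- unlist(as.list(support))
  if (is.null(out)) return(stats::setNames(integer(0), character(0)))
  out[order(-out, names(out))]
}

#' Fraction of patients carrying a disease code
#'
#' @param records list of [patient_record()] objects.
#' @param code disease code.
#' @return fraction in [0, 1].
#' @export
patient_prevalence <- function(records, code) {
  if (length(records) == 0L) return(0)
  mean(vapply(records, function(r)
    any(vapply(r$visits, function(v) code %in% v$codes, FALSE)), FALSE))
}

#' Shannon entropy of a disease
#'
#' Default definition: the binary entropy of the disease's patient prevalence
#' p, \eqn{F = -p \log_2 p - (1-p)\log_2(1-p)}. The reference distribution is
#' pluggable via \code{entropy_fun}, which receives p and must return a
#' non-negative real.
#'
#' @param records list of [patient_record()] objects.
#' @param disease disease code; must be observed in \code{records}.
#' @param entropy_fun function of the prevalence p.
#' @return non-negative real.
#' @export
disease_entropy <- function(records, disease, entropy_fun = binary_entropy) {
  p <- patient_prevalence(records, disease)
  if (p == 0) stop(sprintf("disease %s not observed in records", disease), call. = FALSE)
  entropy_fun(p)
}

#' @rdname disease_entropy
#' @param p probability in [0, 1].
#' @export
binary_entropy <- function(p) {
  h <- function(q) ifelse(q <= 0 | q >= 1, 0, -q * log2(q))
  h(p) + h(1 - p)
}

#' Select trigger diseases from a cohort
#'
#' A disease qualifies as a trigger seed when it (a) appears more than twice
#' within at least one patient's record, (b) has a non-empty comorbidity set
#' at the given k, (c) is not a noise disease, and (d) occurs in at least
#' \code{min_prevalence} of patients.
#'
#' @param records list of [patient_record()] objects (non-empty).
#' @param noise_codes noise disease set to exclude (may be \code{NULL}).
#' @param min_prevalence minimum patient prevalence (default 1\%).
#' @param k occurrence count used for the comorbidity criterion.
#' @return list of [trigger_spec()] seeds, one per qualifying disease, each
#'   carrying its mined target set.
#' @export
select_triggers <- function(records, noise_codes = default_noise_codes(),
                            min_prevalence = 0.01, k = 2L) {
  stopifnot(length(records) > 0L)
  # diseases with > 2 occurrences in a single patient's record
  cand <- unique(unlist(lapply(records, function(r) {
    tab <- table(derive_sequences(r)$D)
    names(tab)[tab > 2L]
  })))
  cand <- setdiff(cand, noise_codes)
  cand <- cand[vapply(cand, function(d)
    patient_prevalence(records, d) >= min_prevalence, FALSE)]
  specs <- list()
  for (d in sort(cand)) {
    com <- find_comorbidities(records, d, k = k)
    if (length(com) == 0L) next
    specs[[d]] <- trigger_spec(d, names(com), k = k)
  }
  unname(specs)
}

.rank_list <- function(support) {
  # 1-based ranks, support descending, ties broken by code lexicographically
  ord <- order(-support, names(support))
  stats::setNames(seq_along(ord), names(support)[ord])
}

#' Edge weight of a comorbidity pair
#'
#' The mean, over the \eqn{N_{uv}} comorbidities k shared by u and v, of
#' \eqn{|R_{u,k} - R_{v,k}| F_k}, where \eqn{R_{i,j}} is the 1-based rank of
#' disease i in disease j's frequency-ordered comorbidity list and \eqn{F_k}
#' is the Shannon entropy of disease k. Returns \code{NA} when u and v share
#' no comorbidities (the caller substitutes the fallback weight).
#'
#' @param u,v disease codes.
#' @param rank_lists named list: for each disease with a comorbidity list, a
#'   named integer vector of ranks (as built by [comorbidity_graph()]).
#' @param entropies named numeric vector of per-disease entropies \eqn{F_k}.
#' @return non-negative real, or \code{NA_real_} if no common comorbidity.
#' @export
comorbidity_edge_weight <- function(u, v, rank_lists, entropies) {
  ru <- rank_lists[[u]]; rv <- rank_lists[[v]]
  common <- intersect(names(ru), names(rv))
  if (length(common) == 0L) return(NA_real_)
  fk <- entropies[common]
  fk[is.na(fk)] <- 1
  mean(abs(ru[common] - rv[common]) * fk)
}

#' Build the weighted comorbidity graph
#'
#' Vertices are the triggers and their mined targets (noise diseases
#' excluded); an undirected edge (u, v) exists whenever u is a target of v or
#' v is a target of u. Edge weights follow the rank-difference formula of
#' [comorbidity_edge_weight()]; pairs with no common comorbidity keep their
#' edge (adjacency is defined by the trigger/target relation alone) but
#' receive the maximum observed finite weight + 1 and are flagged, which
#' penalizes unrelated pairs in distance-sensitive downstream use.
#'
#' @param records list of [patient_record()] objects; may be \code{NULL} when
#'   \code{target_map} is supplied directly (entropies then default to 1).
#' @param triggers list of [trigger_spec()] (or a single one). Ignored when
#'   \code{target_map} is given.
#' @param noise_codes noise set excluded from the vertex set.
#' @param target_map optional named list mapping each trigger code to a
#'   character vector of its targets, bypassing mining (toy graphs, tests).
#' @param k occurrence count for mining when \code{target_map} is absent.
#' @param entropy_fun passed to [disease_entropy()].
#' @return an object of class \code{comorbidity_graph} with fields
#'   \code{vertices}, \code{edges} (data.frame u, v, weight, n_common,
#'   flagged), \code{rank_lists}, \code{entropies}, \code{target_map}.
#' @export
comorbidity_graph <- function(records = NULL, triggers = NULL,
                              noise_codes = NULL, target_map = NULL,
                              k = 2L, entropy_fun = binary_entropy) {
  if (is.null(target_map)) {
    if (inherits(triggers, "trigger_spec")) triggers <- list(triggers)
    stopifnot(length(triggers) > 0L)
    support_map <- list()
    for (ts in triggers) {
      sup <- find_comorbidities(records, ts$trigger, k = ts$k)
      sup <- sup[!(names(sup) %in% noise_codes)]
      support_map[[ts$trigger]] <- sup
    }
  } else {
    support_map <- lapply(target_map, function(tg) {
      tg <- setdiff(tg, noise_codes)
      stats::setNames(rep(1L, length(tg)), tg)  # uniform support: lexicographic ranks
    })
  }
  trig_codes <- setdiff(names(support_map), noise_codes)
  support_map <- support_map[trig_codes]
  vertices <- sort(unique(c(trig_codes, unlist(lapply(support_map, names)))))
  rank_lists <- lapply(support_map, .rank_list)

  entropies <- stats::setNames(rep(1, length(vertices)), vertices)
  if (!is.null(records)) {
    for (d in vertices) {
      p <- patient_prevalence(records, d)
      entropies[d] <- if (p > 0) entropy_fun(p) else NA_real_
    }
  }

  pairs <- unique(do.call(rbind, lapply(trig_codes, function(tg) {
    tgs <- names(support_map[[tg]])
    tgs <- setdiff(tgs, tg)
    if (length(tgs) == 0L) return(NULL)
    cbind(pmin(tg, tgs), pmax(tg, tgs))
  })))
  edges <- if (is.null(pairs) || nrow(pairs) == 0L) {
    data.frame(u = character(0), v = character(0), weight = numeric(0),
               n_common = integer(0), flagged = logical(0))
  } else {
    w <- numeric(nrow(pairs)); nc <- integer(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      ru <- rank_lists[[pairs[i, 1L]]]; rv <- rank_lists[[pairs[i, 2L]]]
      nc[i] <- length(intersect(names(ru), names(rv)))
      w[i] <- comorbidity_edge_weight(pairs[i, 1L], pairs[i, 2L],
                                      rank_lists, entropies)
    }
    flagged <- is.na(w)
    fallback <- if (any(!flagged)) max(w[!flagged]) + 1 else 1
    w[flagged] <- fallback
    data.frame(u = pairs[, 1L], v = pairs[, 2L], weight = w,
               n_common = nc, flagged = flagged, stringsAsFactors = FALSE)
  }
  structure(list(vertices = vertices, edges = edges, rank_lists = rank_lists,
                 entropies = entropies,
                 target_map = lapply(support_map, names)),
            class = "comorbidity_graph")
}

#' @export
print.comorbidity_graph <- function(x, ...) {
  cat(sprintf("comorbidity_graph: %d vertices, %d edges (%d weight-flagged)\n",
              length(x$vertices), nrow(x$edges), sum(x$edges$flagged)))
  invisible(x)
}

#' Convert a comorbidity graph to igraph
#'
#' @param g a \code{comorbidity_graph}.
#' @return an \code{igraph} undirected weighted graph.
#' @export
as_igraph <- function(g) {
  stopifnot(inherits(g, "comorbidity_graph"))
  ig <- igraph::graph_from_data_frame(g$edges[, c("u", "v")], directed = FALSE,
                                      vertices = data.frame(name = g$vertices))
  igraph::E(ig)$weight <- g$edges$weight
  ig
}

#' Export a comorbidity graph as TSV files
#'
#' Writes \code{<stem>_edges.tsv} (u, v, weight, n_common, flagged) and
#' \code{<stem>_vertices.tsv} (code, entropy, is_trigger).
#'
#' @param g a \code{comorbidity_graph}.
#' @param stem output path stem.
#' @return character vector of the two paths, invisibly.
#' @export
write_graph_tsv <- function(g, stem) {
  ep <- paste0(stem, "_edges.tsv"); vp <- paste0(stem, "_vertices.tsv")
  utils::write.table(g$edges, ep, sep = "\t", row.names = FALSE, quote = FALSE)
  vdf <- data.frame(code = g$vertices,
                    entropy = unname(g$entropies[g$vertices]),
                    is_trigger = g$vertices %in% names(g$rank_lists))
  utils::write.table(vdf, vp, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(c(ep, vp))
}
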