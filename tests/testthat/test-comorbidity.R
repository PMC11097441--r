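# Exhaustive position-scan oracle for Def-6 comorbidity mining: a target
# counts for a patient when any of its positions lies strictly after the
# k-th trigger position.
oracle_comorbidities <- function(records, trigger, k) {
  support <- list()
  for (r in records) {
    D <- derive_sequences(r)$D
    hits <- character(0)
    for (u in setdiff(unique(D), trigger)) {
      for (iu in which(D == u)) {
        tcount <- sum(D[seq_len(iu - 1L)] == trigger)
        if (tcount >= k) { hits <- c(hits, u); break }
      }
    }
    for (u in hits) support[[u]] <- (support[[u]] %||% 0L) + 1L
  }
  unlist(support) %||% stats::setNames(integer(0), character(0))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("hypertension is mined as a comorbidity of diabetes in the worked record", {
  cm <- find_comorbidities(list(worked_example()), "250.0", k = 2L)
  expect_true("401.9" %in% names(cm))
  # k beyond the trigger's count contributes nothing
  expect_length(find_comorbidities(list(worked_example()), "250.0", k = 5L), 0L)
})

test_that("comorbidity mining equals the exhaustive position-scan oracle", {
  set.seed(3)
  pool <- sprintf("%03d.0", 200:212)
  for (trial in 1:4) {
    recs <- lapply(1:50, function(i)
      random_record(sprintf("P%02d", i), n_visits = sample(2:10, 1L), pool = pool))
    trigger <- sample(pool, 1L)
    k <- sample(1:3, 1L)
    got <- find_comorbidities(recs, trigger, k)
    want <- oracle_comorbidities(recs, trigger, k)
    expect_mapequal(as.list(got), as.list(want))
  }
})

test_that("trigger selection applies all four rules", {
  # A occurs 3x in one patient and in every patient; N (noise) likewise;
  # B occurs 3x in one patient but has no comorbidities (always terminal);
  # C is frequent across patients but never >2 within one record.
  recs <- c(
    list(rec("p1", "2020-01-01 A", "2020-02-01 A", "2020-03-01 A", "2020-04-01 X"),
         rec("p2", "2020-01-01 N", "2020-02-01 N", "2020-03-01 N", "2020-04-01 B",
             "2020-05-01 B", "2020-06-01 B")),
    lapply(3:20, function(i)
      rec(sprintf("p%d", i), "2020-01-01 A C", "2020-02-01 N C", "2020-03-01 X")))
  specs <- select_triggers(recs, noise_codes = "N", min_prevalence = 0.01, k = 2L)
  expect_identical(vapply(specs, `[[`, "", "trigger"), "A")
  expect_true("X" %in% specs[[1L]]$targets)

  # only frequent code is noise -> empty
  recs_n <- lapply(1:20, function(i)
    rec(sprintf("q%d", i), "2020-01-01 N", "2020-02-01 N", "2020-03-01 N",
        "2020-04-01 N"))
  expect_length(select_triggers(recs_n, noise_codes = "N"), 0L)

  # degenerate thresholds reduce to rules (a) + (b)
  specs0 <- select_triggers(recs, noise_codes = character(0),
                            min_prevalence = 0, k = 2L)
  expect_setequal(vapply(specs0, `[[`, "", "trigger"), c("A", "N"))
})

test_that("binary prevalence entropy matches the closed form", {
  recs <- lapply(1:4, function(i)
    rec(sprintf("p%d", i), paste("2020-01-01", if (i <= 2) "A" else "B")))
  expect_equal(disease_entropy(recs, "A"), 1.0)      # p = 0.5
  recs_all <- lapply(recs, function(r) { r$visits[[1L]]$codes <- "A"; r })
  expect_equal(disease_entropy(recs_all, "A"), 0.0)  # p = 1
  expect_equal(disease_entropy(recs, "B", entropy_fun = binary_entropy),
               -0.5 * log2(0.5) * 2)                 # p = 0.5 again
  # p = 0.25 against an independently coded evaluation
  recs1 <- lapply(1:4, function(i)
    rec(sprintf("p%d", i), paste("2020-01-01", if (i == 1) "A" else "B")))
  p <- 0.25
  expect_equal(disease_entropy(recs1, "A"),
               -p * log2(p) - (1 - p) * log2(1 - p))
  expect_error(disease_entropy(recs, "ZZZ"), "not observed")
})

test_that("edge weight follows the rank-difference formula", {
  rl <- list(u = c(k1 = 1L, k2 = 2L, k3 = 3L),
             v = c(k1 = 1L, k2 = 2L, k3 = 3L))
  F1 <- c(k1 = 1, k2 = 0.5, k3 = 0.2)
  expect_equal(comorbidity_edge_weight("u", "v", rl, F1), 0)
  rl2 <- list(u = c(k = 1L), v = c(k = 3L))
  expect_equal(comorbidity_edge_weight("u", "v", rl2, c(k = 1)), 2.0)
  expect_true(is.na(comorbidity_edge_weight("u", "v",
                                            list(u = c(a = 1L), v = c(b = 1L)),
                                            c(a = 1, b = 1))))
  # brute-force summation oracle on a random 6-disease toy
  set.seed(5)
  for (trial in 1:20) {
    ks <- paste0("k", 1:6)
    ru <- stats::setNames(sample(1:6), sample(ks))
    rv <- stats::setNames(sample(1:6), sample(ks))
    common <- sample(ks, sample(1:6, 1L))
    ru <- ru[names(ru) %in% c(common, sample(ks, 2L))]
    Fk <- stats::setNames(stats::runif(6), ks)
    want <- {
      cc <- intersect(names(ru), names(rv))
      s <- 0
      for (k in cc) s <- s + abs(ru[[k]] - rv[[k]]) * Fk[[k]]
      s / length(cc)
    }
    expect_equal(comorbidity_edge_weight("u", "v", list(u = ru, v = rv), Fk),
                 want)
  }
})

test_that("the toy trigger/target map builds exactly its implied graph", {
  g <- comorbidity_graph(target_map = toy_graph_example())
  expect_setequal(g$vertices, c("250.0", "401.9", "272.4", "414.9", "437.0"))
  got <- sort(paste(g$edges$u, g$edges$v))
  want <- sort(c("250.0 401.9", "250.0 272.4", "401.9 414.9",
                 "401.9 437.0", "272.4 437.0"))
  expect_identical(got, want)
  # absent edge
  expect_false(any(g$edges$u == "250.0" & g$edges$v == "414.9") ||
                 any(g$edges$u == "414.9" & g$edges$v == "250.0"))
})

test_that("graph construction handles degenerate and random maps", {
  g0 <- comorbidity_graph(target_map = list("100.0" = character(0)))
  expect_identical(g0$vertices, "100.0")
  expect_identical(nrow(g0$edges), 0L)
  set.seed(8)
  codes <- sprintf("%03d.0", 300:309)
  for (trial in 1:5) {
    trig <- sample(codes, 4L)
    tm <- stats::setNames(
      lapply(trig, function(n) setdiff(sample(codes, sample(0:4, 1L)), n)),
      trig)
    g <- comorbidity_graph(target_map = tm)
    want <- unique(t(apply(do.call(rbind, lapply(names(tm), function(u)
      if (length(tm[[u]])) cbind(u, tm[[u]]))), 1L, sort)))
    got <- as.matrix(g$edges[, c("u", "v")])
    expect_identical(nrow(got), if (is.null(want)) 0L else nrow(want))
    if (!is.null(want) && nrow(want)) {
      expect_setequal(paste(got[, 1L], got[, 2L]), paste(want[, 1L], want[, 2L]))
    }
  }
})

test_that("graph invariants: symmetry, noise exclusion, non-negative weights", {
  set.seed(13)
  pool <- sprintf("%03d.0", 400:412)
  recs <- lapply(1:30, function(i)
    random_record(sprintf("P%02d", i), n_visits = sample(3:9, 1L), pool = pool))
  S <- pool[1:3]
  trig <- select_triggers(recs, noise_codes = S, min_prevalence = 0, k = 1L)
  if (length(trig) > 0L) {
    g <- comorbidity_graph(recs, triggers = trig, noise_codes = S)
    expect_length(intersect(g$vertices, S), 0L)
    expect_true(all(g$edges$weight >= 0))
    expect_true(all(g$edges$u <= g$edges$v))      # canonical unordered pairs
    expect_true(all(g$edges$n_common >= 0L))
    ig <- as_igraph(g)
    expect_equal(as.integer(igraph::vcount(ig)), length(g$vertices))
  }
})
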