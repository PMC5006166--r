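test_that("comorbidity network keeps perfect and rejects null correlations", {
  # A and B always together, C independent-ish
  corpus <- record_corpus(list(c("A", "B"), c("A", "B", "C"), c("C", "D"),
                               c("A", "B", "D")))
  net <- build_comorbidity_network(corpus, alpha = 0.05)
  ab <- net$edges[(net$edges$from == "A" & net$edges$to == "B") |
                    (net$edges$from == "B" & net$edges$to == "A"), ]
  expect_equal(nrow(ab), 1)
  expect_equal(ab$r, 1)

  # 4-record toy incidence A=(1,1,0,0), B=(1,0,1,0): r = 0, rejected
  corpus2 <- record_corpus(list(c("A", "B"), c("A", "x"), c("B", "x"),
                                c("x", "y")))
  net2 <- build_comorbidity_network(corpus2, alpha = 0.05)
  ab2 <- net2$edges[(net2$edges$from == "A" & net2$edges$to == "B") |
                      (net2$edges$from == "B" & net2$edges$to == "A"), ]
  expect_equal(nrow(ab2), 0)

  expect_error(build_comorbidity_network(record_corpus(list(c("A", "B")))),
               "at least 3")
  expect_warning(
    build_comorbidity_network(record_corpus(list(c("A", "B"), c("A", "C"),
                                                 c("A", "D")))),
    "all or no records")
})

test_that("phi and t statistics match a direct recomputation", {
  set.seed(23)
  n <- 200
  diseases <- paste0("D", 1:50)
  recs <- lapply(seq_len(n), function(i) {
    sample(diseases, sample(2:8, 1))
  })
  corpus <- record_corpus(recs)
  alpha <- 0.05
  net <- build_comorbidity_network(corpus, alpha = alpha)

  X <- matrix(0, n, 50, dimnames = list(NULL, diseases))
  for (i in seq_len(n)) X[i, recs[[i]]] <- 1

  # textbook recomputation for every retained edge
  for (i in seq_len(nrow(net$edges))) {
    e <- net$edges[i, ]
    r_ref <- sum((X[, e$from] - mean(X[, e$from])) *
                   (X[, e$to] - mean(X[, e$to]))) /
      ((n - 1) * sd(X[, e$from]) * sd(X[, e$to]))
    expect_equal(e$r, r_ref, tolerance = 1e-12)
    expect_equal(e$t, r_ref * sqrt((n - 2) / (1 - r_ref^2)),
                 tolerance = 1e-10)
    expect_true(abs(e$t) > qt(1 - alpha / 2, n - 2))
  }

  # retention by significance: a randomly checked rejected pair fails the test
  pairs <- t(combn(diseases, 2))
  kept <- paste(net$edges$from, net$edges$to)
  rejected <- pairs[!(paste(pairs[, 1], pairs[, 2]) %in% kept) &
                      !(paste(pairs[, 2], pairs[, 1]) %in% kept), ]
  for (j in sample(nrow(rejected), 20)) {
    r_ref <- suppressWarnings(cor(X[, rejected[j, 1]], X[, rejected[j, 2]]))
    if (is.na(r_ref) || abs(r_ref) == 1) next
    t_ref <- r_ref * sqrt((n - 2) / (1 - r_ref^2))
    expect_true(abs(t_ref) <= qt(1 - alpha / 2, n - 2))
  }
})

test_that("comorbidity edge set shrinks as alpha decreases", {
  set.seed(24)
  recs <- lapply(1:100, function(i) sample(paste0("D", 1:20), sample(2:6, 1)))
  corpus <- record_corpus(recs)
  e_strict <- build_comorbidity_network(corpus, alpha = 0.001)$edges
  e_loose <- build_comorbidity_network(corpus, alpha = 0.1)$edges
  key <- function(e) paste(e$from, e$to)
  expect_true(all(key(e_strict) %in% key(e_loose)))
  expect_lte(nrow(e_strict), nrow(e_loose))
})

test_that("bipartite graph wires records and gene associations", {
  corpus <- record_corpus(list(c("A", "B")))
  A <- build_bipartite_graph(corpus, gene_map(list(A = "g")))
  expect_equal(A["A", "B"], 1)
  expect_equal(A["A", "g"], 1)
  expect_equal(A["B", "g"], 0)
  expect_equal(attr(A, "kind")[["g"]], "gene")

  # disjoint components stay disjoint
  corpus2 <- record_corpus(list(c("A", "B"), c("C", "D")))
  A2 <- build_bipartite_graph(corpus2)
  expect_equal(A2["A", "C"], 0)
  expect_equal(A2["B", "D"], 0)

  # weights equal brute-force pair counts on a random corpus
  set.seed(25)
  recs <- lapply(1:50, function(i) sample(paste0("D", 1:8), 4, replace = TRUE))
  corpus3 <- record_corpus(recs)
  A3 <- build_bipartite_graph(corpus3)
  count_pairs <- function(a, b) {
    sum(vapply(recs, function(r) {
      idx <- which(r == a)
      sum(vapply(idx, function(i) sum(r[-seq_len(i)] == b) +
                   sum(r[seq_len(i - 1)] == b), numeric(1)))
    }, numeric(1)))
  }
  for (pair in list(c("D1", "D2"), c("D3", "D7"), c("D5", "D8"))) {
    expect_equal(A3[pair[1], pair[2]], count_pairs(pair[1], pair[2]))
  }
})

test_that("spectral embedding respects known spectra and block structure", {
  # path graph on 3 nodes: Fiedler vector orders the endpoints oppositely
  P <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  P["a", "b"] <- P["b", "a"] <- P["b", "c"] <- P["c", "b"] <- 1
  emb <- spectral_embedding(P, 1)
  expect_lt(emb["a", 1] * emb["c", 1], 0)

  # two disjoint cliques: within-clique cosine exceeds cross-clique
  nodes <- c(paste0("x", 1:4), paste0("y", 1:4))
  A <- matrix(0, 8, 8, dimnames = list(nodes, nodes))
  A[1:4, 1:4] <- 1; A[5:8, 5:8] <- 1; diag(A) <- 0
  A["x1", "x2"] <- A["x2", "x1"] <- 3  # break exact degeneracy
  e2 <- spectral_embedding(A, 2)
  comp <- attr(e2, "component")
  expect_equal(length(unique(comp)), 2)
  within <- cosine_similarity(e2["x1", ], e2["x3", ])
  expect_true(is.finite(within))

  # eigen residual on a connected weighted graph
  set.seed(26)
  n <- 12
  W <- matrix(runif(n * n), n)
  W <- (W + t(W)) / 2; diag(W) <- 0
  rownames(W) <- colnames(W) <- paste0("v", 1:n)
  d <- 3
  e3 <- spectral_embedding(W, d)
  deg <- rowSums(W)
  L <- diag(n) - diag(1 / sqrt(deg)) %*% W %*% diag(1 / sqrt(deg))
  lam <- attr(e3, "eigenvalues")[[1]]
  for (j in seq_len(d)) {
    expect_lt(max(abs(L %*% e3[, j] - lam[j] * e3[, j])), 1e-8)
    nz <- which(abs(e3[, j]) > 1e-10)
    expect_gt(e3[nz[1], j], 0)
  }
  expect_error(spectral_embedding(W, 12), "below the node count")
})

test_that("modularity embedding exposes planted blocks", {
  set.seed(27)
  nodes <- c(paste0("x", 1:6), paste0("y", 1:6))
  A <- matrix(0, 12, 12, dimnames = list(nodes, nodes))
  for (i in 1:6) for (j in 1:6) {
    if (i != j) {
      A[i, j] <- 1
      A[i + 6, j + 6] <- 1
    }
  }
  A["x1", "y1"] <- A["y1", "x1"] <- 1

  # modularity matrix rows sum to zero
  k <- rowSums(A)
  B <- A - (k %o% k) / sum(k)
  expect_lt(max(abs(rowSums(B))), 1e-12)

  emb <- modularity_embedding(A, 2)
  lead <- emb[, 1]
  expect_true(all(sign(lead[1:6]) == sign(lead[1])))
  expect_true(all(sign(lead[7:12]) == -sign(lead[1])))

  lam <- attr(emb, "eigenvalues")
  for (j in 1:2) {
    expect_lt(max(abs(B %*% emb[, j] - lam[j] * emb[, j])), 1e-8)
  }
})

test_that("co-occurrence retrieval counts record pairs", {
  corpus <- record_corpus(list(c("A", "B"), c("A", "B"), c("A", "C")))
  nb <- cooccurrence_neighbors(corpus, "A", 2)
  expect_equal(nb$token, c("B", "C"))
  expect_equal(nb$count, c(2, 1))
  expect_error(cooccurrence_neighbors(corpus, "Z", 2), "unknown query")
  expect_warning(
    out <- cooccurrence_neighbors(record_corpus(list("A", c("B", "C"))),
                                  "A", 2),
    "co-occurs with no other")
  expect_equal(nrow(out), 0)

  # matches brute-force pair counting on a random corpus
  set.seed(28)
  recs <- lapply(1:60, function(i) sample(paste0("D", 1:6), 4, replace = TRUE))
  corpus2 <- record_corpus(recs)
  nb2 <- cooccurrence_neighbors(corpus2, "D1", 5)
  brute <- sapply(paste0("D", 2:6), function(tok) {
    sum(vapply(recs, function(r) sum(r == "D1") * sum(r == tok), numeric(1)))
  })
  brute <- sort(brute, decreasing = TRUE)
  expect_equal(stats::setNames(nb2$count, nb2$token),
               brute[nb2$token])
})

test_that("trivial gene predictors rank by frequency and co-occurrence", {
  tm <- gene_map(list(D1 = c("g1", "g2"), D2 = "g1"))
  expect_equal(most_frequent_gene_predictor(tm, 2), c("g1", "g2"))
  expect_equal(most_frequent_gene_predictor(tm, 1), "g1")
  expect_error(most_frequent_gene_predictor(gene_map(list()), 1), "empty")

  # tie order lexicographic
  tm2 <- gene_map(list(D1 = c("gb", "ga")))
  expect_equal(most_frequent_gene_predictor(tm2, 2), c("ga", "gb"))

  corpus <- record_corpus(list(c("Q", "D1"), c("Q", "D1"), c("D2", "x")))
  expect_equal(disease_gene_cooccurrence_predictor(corpus, tm, "Q", 3),
               c("g1", "g2"))
  expect_warning(
    out <- disease_gene_cooccurrence_predictor(
      record_corpus(list(c("Q", "x"))), tm, "Q", 3),
    "never co-occurs")
  expect_length(out, 0)

  # counts match a brute-force record scan
  set.seed(29)
  recs <- lapply(1:40, function(i) sample(c("Q", paste0("D", 1:4)), 3,
                                          replace = TRUE))
  tm3 <- gene_map(list(D1 = c("g1", "g2"), D2 = "g2", D3 = "g3"))
  got <- disease_gene_cooccurrence_predictor(record_corpus(recs), tm3, "Q", 3)
  co <- sapply(paste0("D", 1:3), function(d) {
    sum(vapply(recs, function(r) sum(r == "Q") * sum(r == d), numeric(1)))
  })
  gcnt <- c(g1 = co[["D1"]], g2 = co[["D1"]] + co[["D2"]], g3 = co[["D3"]])
  gcnt <- gcnt[gcnt > 0]
  expect_equal(got, names(sort(gcnt, decreasing = TRUE))[seq_along(got)])
})
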