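test_that("subsampling keep probability follows min(1, sqrt(t/f))", {
  expect_equal(subsample_keep_probability(1e-3, 1e-3), 1)
  expect_equal(subsample_keep_probability(4e-3, 1e-3), 0.5)
  expect_error(subsample_keep_probability(0, 1e-3), "absent")

  # Monte-Carlo agreement of the Bernoulli discard rule with the formula
  set.seed(11)
  p <- subsample_keep_probability(f = 0.02, t = 1e-3)
  keep_rate <- mean(runif(1e5) < p)
  expect_lt(abs(keep_rate - p), 0.01)
})

test_that("noise distribution is count^power over diseases only", {
  corpus <- record_corpus(list(rep("A", 16), "B", c("A", "B")))
  v <- build_vocabulary(corpus, gene_map(list(A = "g1")), min_count = 1)
  p <- noise_distribution(v, power = 0.75)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[["g1"]], 0)
  # counts are A: 17, B: 2; check the 16:1 case exactly on counts (16, 1)
  v2 <- v
  v2$count[v2$index[c("A", "B")]] <- c(16, 1)
  p2 <- noise_distribution(v2, power = 0.75)
  expect_equal(unname(p2[c("A", "B")]), c(8 / 9, 1 / 9))

  v2$count[v2$index[c("A", "B")]] <- c(1, 1)
  p3 <- noise_distribution(v2, power = 0.75)
  expect_equal(unname(p3[c("A", "B")]), c(0.5, 0.5))
})

test_that("compiled noise sampler matches its distribution", {
  p <- c(0.5, 0.3, 0.15, 0.05)
  cdf <- cumsum(p)
  draws <- dgembed:::sample_noise_cpp(cdf, 1:4, 1e6, seed = 3)
  emp <- tabulate(draws, 4) / 1e6
  expect_lt(sum(abs(emp - p)), 0.01)
})

test_that("pair_update with lr = 0 is a no-op and raises the objective otherwise", {
  set.seed(5)
  mat <- matrix(rnorm(5 * 8, sd = 0.3), 5, 8,
                dimnames = list(paste0("t", 1:5), NULL))
  out <- matrix(rnorm(5 * 8, sd = 0.3), 5, 8,
                dimnames = list(paste0("t", 1:5), NULL))
  model <- make_model(mat, output = out)

  r0 <- pair_update(model, "t1", "t2", c("t3", "t4"), lr = 0)
  expect_identical(r0$model$input, model$input)
  expect_identical(r0$model$output, model$output)
  expect_true(is.finite(r0$objective))

  r1 <- pair_update(model, "t1", "t2", c("t3", "t4"), lr = 0.05)
  r2 <- pair_update(r1$model, "t1", "t2", c("t3", "t4"), lr = 0)
  expect_gt(r2$objective, r1$objective)

  expect_error(pair_update(model, "t1", "t2", c("t2", "t3"), lr = 0.1),
               "must differ")
  expect_error(pair_update(model, "nope", "t2", "t3", lr = 0.1), "unknown")
})

test_that("analytic gradients match central differences", {
  set.seed(99)
  for (i in 1:20) {
    D <- sample(2:10, 1)
    nneg <- sample(1:6, 1)
    cv <- rnorm(D); xv <- rnorm(D); nm <- matrix(rnorm(nneg * D), nneg)
    g <- dgembed:::sgns_pair_gradient_cpp(cv, xv, nm)
    gc_num <- num_grad(function(x) ref_sgns_objective(x, xv, nm), cv)
    gx_num <- num_grad(function(x) ref_sgns_objective(cv, x, nm), xv)
    expect_lt(max(abs(gc_num - g$center)) / max(abs(gc_num), 1e-8), 1e-5)
    expect_lt(max(abs(gx_num - g$context)) / max(abs(gx_num), 1e-8), 1e-5)
    expect_equal(g$objective, ref_sgns_objective(cv, xv, nm),
                 tolerance = 1e-10)
  }
})

test_that("exact softmax oracle gives -log W under zero vectors", {
  W <- 7
  mat <- matrix(0, W, 3, dimnames = list(paste0("d", 1:W), NULL))
  mat[] <- 1e-12  # nonzero so vocabulary stays usable, effectively uniform
  model <- make_model(mat, output = matrix(0, W, 3,
                                           dimnames = dimnames(mat)))
  corpus <- record_corpus(list(paste0("d", 1:4), paste0("d", c(5, 6))))
  ll <- exact_log_likelihood(model, corpus, b = 8)
  expect_equal(as.numeric(ll), -log(W), tolerance = 1e-9)
})

test_that("training raises the exact likelihood above the uniform baseline", {
  set.seed(21)
  pools <- list(paste0("A", 1:5), paste0("B", 1:5))
  corpus <- make_pool_corpus(pools, 400)
  cfg <- train_config(D = 12, b = 4, negatives = 5, epochs = 3,
                      min_count = 1, subsample_t = 0, seed = 2)
  m <- train_d2d(corpus, cfg)
  ll_trained <- exact_log_likelihood(m, corpus)
  expect_gt(as.numeric(ll_trained), -log(10))
})

test_that("joint objective is invariant to gene-list order", {
  set.seed(31)
  mat <- matrix(rnorm(6 * 4, sd = 0.2), 6, 4,
                dimnames = list(c("A", "B", "C", "g1", "g2", "g3"), NULL))
  out <- matrix(rnorm(6 * 4, sd = 0.2), 6, 4, dimnames = dimnames(mat))
  model <- make_model(mat, kind = c(rep("disease", 3), rep("gene", 3)),
                      output = out)
  corpus <- record_corpus(list(c("A", "B", "C"), c("B", "A")))
  gm1 <- structure(list(A = c("g1", "g2", "g3"), B = "g2"),
                   class = "gene_map")
  gm2 <- structure(list(A = c("g3", "g1", "g2"), B = "g2"),
                   class = "gene_map")
  ll1 <- exact_log_likelihood(model, corpus, gm1, b = 2)
  ll2 <- exact_log_likelihood(model, corpus, gm2, b = 2)
  expect_identical(as.numeric(ll1), as.numeric(ll2))
})

test_that("embeddings survive a text-format round trip", {
  set.seed(8)
  mat <- matrix(rnorm(5 * 3), 5, 3,
                dimnames = list(c("585.1", "585.2", "428.0", "340", "323.9"),
                                NULL))
  model <- make_model(mat)
  path <- tempfile(fileext = ".vec")
  save_embeddings(model, path)
  back <- load_embeddings(path)
  expect_equal(rownames(back$input), rownames(mat))
  expect_lt(max(abs(back$input - mat)), 1e-6)
  expect_equal(readLines(path)[1], "5 3")

  # header/row mismatch is a parse error with a line reference
  bad <- tempfile()
  writeLines(c("2 3", "a 1 2 3", "b 1 2 3", "c 1 2 3"), bad)
  expect_error(load_embeddings(bad), "header declares")
})
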