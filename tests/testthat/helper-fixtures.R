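# Shared fixtures built in code: tiny corpora, hand-made embedding models,
# and an R reference implementation of the negative-sampling objective used
# as the independent oracle for gradient checks.

# Corpus of records drawn from disjoint token pools (one pool per record).
make_pool_corpus <- function(pools, n_records, len = 5) {
  recs <- lapply(seq_len(n_records), function(i) {
    pool <- pools[[1 + (i - 1) %% length(pools)]]
    sample(pool, len, replace = TRUE)
  })
  record_corpus(recs)
}

# Assemble an embedding_model directly from a coordinate matrix.
make_model <- function(input, kind = NULL, output = NULL, b = 8L) {
  tokens <- rownames(input)
  stopifnot(!is.null(tokens))
  if (is.null(kind)) kind <- rep("disease", nrow(input))
  if (is.null(output)) output <- matrix(0, nrow(input), ncol(input),
                                        dimnames = dimnames(input))
  vocab <- structure(list(token = tokens, count = rep(1, nrow(input)),
                          kind = kind,
                          index = stats::setNames(seq_along(tokens), tokens)),
                     class = "dg_vocabulary")
  structure(list(input = input, output = output, vocab = vocab,
                 config = train_config(D = ncol(input), b = b, min_count = 1),
                 stats = NULL),
            class = "embedding_model")
}

# Reference negative-sampling objective
#   log sigma(ctx . c) + sum_k log sigma(-neg_k . c)
# written independently of the compiled code (plain R, log1p form).
ref_sgns_objective <- function(center, ctx, negs) {
  lsig <- function(x) ifelse(x >= 0, -log1p(exp(-x)), x - log1p(exp(x)))
  lsig(sum(center * ctx)) + sum(lsig(-(negs %*% center)))
}

# Central-difference gradient of f at x: five-point stencil, O(h^4)
# truncation error, so the oracle itself is accurate well below 1e-5.
num_grad <- function(f, x, h = 1e-3) {
  vapply(seq_along(x), function(j) {
    at <- function(d) {
      xx <- x; xx[j] <- xx[j] + d
      f(xx)
    }
    (at(-2 * h) - 8 * at(-h) + 8 * at(h) - at(2 * h)) / (12 * h)
  }, numeric(1))
}

# Brute-force cosine KNN used as the retrieval oracle.
brute_force_knn <- function(mat, query, K, pool) {
  pool <- setdiff(pool, query)
  sims <- vapply(pool, function(tok) {
    cosine_similarity(mat[query, ], mat[tok, ])
  }, numeric(1))
  ord <- order(-sims, pool)
  pool[ord[seq_len(min(K, length(pool)))]]
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
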