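#' Training configuration for the embedding models
#'
#' Defaults follow the experimental regime the models were designed for:
#' embedding dimension `D = 200` (the saturation point of precision@K over a
#' 50-1000 sweep), context half-window `b = 8` positions (chosen to sit near
#' the mean discharge-record length of 7.58 diagnoses), 25 negative samples
#' per update, and aggressive subsampling of very frequent tokens.
#'
#' @param D Embedding dimension.
#' @param b Context half-window: each center predicts up to `b` diseases
#'   before and `b` after it, truncated at record boundaries.
#' @param negatives Negative samples drawn per (center, context) update.
#' @param epochs Passes over the corpus.
#' @param lr_initial,lr_final Endpoints of the linear learning-rate decay,
#'   applied over the total number of scheduled context pairs.
#' @param subsample_t Frequency threshold `t` of the subsampling rule
#'   `keep = min(1, sqrt(t / f))`; `0` disables subsampling.
#' @param noise_power Exponent of the unigram noise distribution
#'   (`count^power`, the word2vec 3/4 convention).
#' @param min_count Vocabulary floor: disease tokens seen fewer times are
#'   dropped before training.
#' @param seed Integer seed governing initialization, subsampling, gene-bag
#'   shuffling and negative sampling; a fixed seed reproduces training
#'   bit-for-bit.
#' @return A `train_config` list.
#' @export
train_config <- function(D = 200L, b = 8L, negatives = 25L, epochs = 5L,
                         lr_initial = 0.025, lr_final = 1e-4,
                         subsample_t = 1e-3, noise_power = 0.75,
                         min_count = 5L, seed = 1L) {
  stopifnot(D >= 1, b >= 1, negatives >= 1, epochs >= 1,
            lr_initial > lr_final, lr_final > 0,
            subsample_t >= 0, min_count >= 1)
  structure(list(D = as.integer(D), b = as.integer(b),
                 negatives = as.integer(negatives),
                 epochs = as.integer(epochs),
                 lr_initial = lr_initial, lr_final = lr_final,
                 subsample_t = subsample_t, noise_power = noise_power,
                 min_count = as.integer(min_count),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Subsampling keep probability
#'
#' Very frequent tokens carry little gradient information per occurrence;
#' during training each center occurrence of a token with corpus frequency
#' `f` is kept with probability `min(1, sqrt(t / f))` and otherwise skipped.
#'
#' @param f Token frequency as a proportion of all disease tokens; must be
#'   in (0, 1].
#' @param t Subsampling threshold.
#' @return Keep probability in (0, 1].
#' @export
subsample_keep_probability <- function(f, t) {
  stopifnot(t > 0)
  if (any(f <= 0)) {
    stop("token frequency must be positive (token absent from corpus?)")
  }
  pmin(1, sqrt(t / f))
}

#' Noise distribution for negative sampling
#'
#' Negative targets are always diseases (genes never appear as softmax
#' outputs in either model), drawn with probability proportional to
#' `count^power`. Gene tokens receive probability zero.
#'
#' @param vocab A `dg_vocabulary`.
#' @param power Unigram exponent; default 0.75.
#' @return Named probability vector over all vocabulary tokens, summing to
#'   one, with zero mass on genes.
#' @export
noise_distribution <- function(vocab, power = 0.75) {
  is_d <- vocab$kind == "disease"
  if (!any(is_d)) {
    stop("vocabulary contains no disease tokens")
  }
  p <- numeric(length(vocab$token))
  w <- vocab$count[is_d]^power
  p[is_d] <- w / sum(w)
  stats::setNames(p, vocab$token)
}

# Shared setup for the compiled trainer: integer-coded records, per-row gene
# lists, keep probabilities and the noise CDF.
train_core <- function(corpus, gene_map, config) {
  vocab <- build_vocabulary(corpus, gene_map, config$min_count)
  W <- length(vocab$token)

  recs <- lapply(corpus, function(r) {
    idx <- vocab$index[r]
    as.integer(idx[!is.na(idx)])
  })
  recs <- recs[lengths(recs) > 0L]
  if (length(recs) == 0L) {
    stop("no record survives the vocabulary filter")
  }

  glists <- rep(list(integer(0)), W)
  if (!is.null(gene_map) && length(gene_map)) {
    hosts <- intersect(names(gene_map), vocab$token[vocab$kind == "disease"])
    for (d in hosts) {
      rows <- vocab$index[genes_of(gene_map, d)]
      if (anyNA(rows)) {
        stop("gene(s) of disease ", d, " are absent from the vocabulary")
      }
      glists[[vocab$index[[d]]]] <- as.integer(rows)
    }
  }

  total_d <- sum(vocab$count[vocab$kind == "disease"])
  freq <- vocab$count / total_d
  keep <- if (config$subsample_t > 0) {
    subsample_keep_probability(freq, config$subsample_t)
  } else {
    rep(1, W)
  }

  noise <- noise_distribution(vocab, config$noise_power)
  cand <- which(noise > 0)
  cdf <- cumsum(noise[cand])
  cdf[length(cdf)] <- 1

  fit <- sgns_train_cpp(recs, glists, keep, cdf, as.integer(cand),
                        W, config$D, config$b, config$negatives,
                        config$epochs, config$lr_initial, config$lr_final,
                        config$seed)
  input <- fit$input
  output <- fit$output
  rownames(input) <- rownames(output) <- vocab$token
  structure(list(input = input, output = output, vocab = vocab,
                 config = config,
                 stats = fit[c("pairs_trained", "pairs_scheduled",
                               "pairs_dropped")]),
            class = "embedding_model")
}

#' Train the disease-only skip-gram model
#'
#' Each record is a sentence; every center disease predicts the diseases up
#' to `b` positions before and after it, with the window truncated at record
#' boundaries. The full-softmax objective is optimized through its
#' negative-sampling surrogate by stochastic gradient ascent with a linearly
#' decaying learning rate.
#'
#' @param corpus A `record_corpus`.
#' @param config A [train_config()].
#' @return An `embedding_model` with paired input/output matrices; the
#'   query-time representation of a token is its input vector.
#' @export
train_d2d <- function(corpus, config = train_config()) {
  train_core(corpus, NULL, config)
}

#' Train the joint disease + gene model
#'
#' Extends [train_d2d()]: whenever the vector of a central disease is
#' updated to predict a context disease, the vectors of the genes associated
#' with that disease are updated against the same context as well, one
#' update per gene, each with its own negative samples. Gene bags are
#' re-shuffled at every center occurrence so any ordering bias in the source
#' association lists is removed; the objective itself is invariant to gene
#' order. With an empty gene map the update stream -- and hence the trained
#' model -- is identical to [train_d2d()] under the same seed.
#'
#' @param corpus A `record_corpus`.
#' @param gene_map A `gene_map` (may be empty).
#' @param config A [train_config()].
#' @return An `embedding_model` embedding diseases and genes in one space.
#' @export
train_dag2d <- function(corpus, gene_map, config = train_config()) {
  train_core(corpus, gene_map, config)
}

#' @export
print.embedding_model <- function(x, ...) {
  cat("embedding_model:", nrow(x$input), "tokens x", ncol(x$input),
      "dims (", sum(x$vocab$kind == "gene"), "genes )\n")
  invisible(x)
}

#' One negative-sampling gradient step on a single (center, context) pair
#'
#' Performs one gradient-ascent step on
#' `log sigma(v'_ctx . v) + sum_k log sigma(-v'_neg_k . v)`, updating the
#' context output vector, each negative's output vector and the center's
#' input vector. All gradients are evaluated at the pre-update point.
#'
#' @param model An `embedding_model`.
#' @param center Token whose input vector acts as the center.
#' @param context Positive target token (its output vector is used).
#' @param negatives Character vector of negative target tokens; none may
#'   equal `context`.
#' @param lr Learning rate.
#' @return List with the updated `model` and the pre-update `objective`.
#' @export
pair_update <- function(model, center, context, negatives, lr) {
  idx <- model$vocab$index
  rows <- idx[c(center, context, negatives)]
  if (anyNA(rows)) {
    stop("unknown token(s): ",
         paste(c(center, context, negatives)[is.na(rows)], collapse = ", "))
  }
  if (any(negatives == context)) {
    stop("negative samples must differ from the positive context token")
  }
  ci <- rows[[1]]; xi <- rows[[2]]; ni <- rows[-(1:2)]
  res <- sgns_pair_update_cpp(model$input[ci, ], model$output[xi, ],
                              model$output[ni, , drop = FALSE], lr)
  model$input[ci, ] <- res$center
  model$output[xi, ] <- res$context
  model$output[ni, ] <- res$negatives
  list(model = model, objective = res$objective)
}

#' Exact average log-likelihood under the full softmax
#'
#' Dense-softmax oracle for small instances: computes the exact average
#' log-likelihood of every in-window (center, context) pair -- and, when a
#' gene map is given, of every (gene-of-center, context) pair -- where the
#' conditional probability of a context disease is the softmax of output
#' scores over all disease tokens. Each conditional distribution is checked
#' to normalize to one within 1e-9.
#'
#' @param model An `embedding_model`.
#' @param corpus A `record_corpus`; every token must be in the vocabulary.
#' @param gene_map Optional `gene_map` adding the gene-center terms.
#' @param b Context half-window; defaults to the model's training value.
#' @param max_vocab Guard: refuse vocabularies larger than this.
#' @return The exact average log-likelihood (a scalar), with attribute
#'   `n_terms`.
#' @export
exact_log_likelihood <- function(model, corpus, gene_map = NULL,
                                 b = model$config$b, max_vocab = 5000L) {
  W <- length(model$vocab$token)
  if (W > max_vocab) {
    stop("oracle is for small instances (vocabulary ", W, " > ", max_vocab, ")")
  }
  idx <- model$vocab$index
  dis_rows <- which(model$vocab$kind == "disease")

  # logits[i, c] = v'_{disease i} . v_{token c}
  logits <- model$output[dis_rows, , drop = FALSE] %*% t(model$input)
  mx <- apply(logits, 2, max)
  z <- colSums(exp(sweep(logits, 2, mx)))
  if (any(abs(colSums(exp(sweep(logits, 2, mx + log(z)))) - 1) > 1e-9)) {
    stop("softmax normalization check failed")
  }
  logp <- sweep(logits, 2, mx + log(z))  # log P(context row | center col)
  ctx_pos <- match(seq_len(W), dis_rows)

  total <- 0
  n <- 0L
  for (rec in corpus) {
    rows <- idx[rec]
    if (anyNA(rows)) {
      stop("token(s) absent from vocabulary: ",
           paste(rec[is.na(rows)], collapse = ", "))
    }
    M <- length(rows)
    for (m in seq_len(M)) {
      lo <- max(1L, m - b); hi <- min(M, m + b)
      ctx <- rows[setdiff(lo:hi, m)]
      if (!length(ctx)) next
      centers <- rows[m]
      if (!is.null(gene_map)) {
        g <- genes_of(gene_map, rec[m])
        if (length(g)) {
          gr <- idx[g]
          if (anyNA(gr)) {
            stop("gene(s) absent from vocabulary: ",
                 paste(g[is.na(gr)], collapse = ", "))
          }
          centers <- c(centers, gr)
        }
      }
      for (cc in centers) {
        total <- total + sum(logp[ctx_pos[ctx], cc])
        n <- n + length(ctx)
      }
    }
  }
  if (n == 0L) {
    stop("corpus yields no context pairs")
  }
  structure(total / n, n_terms = n)
}

#' Save embeddings in word2vec text format
#'
#' Header line `"W D"`, then one line per token: the token followed by its
#' `D` input-vector coordinates. Token kinds, counts and the training
#' configuration go to a JSON sidecar manifest at `<path>.json`.
#'
#' @param model An `embedding_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_embeddings <- function(model, path) {
  W <- nrow(model$input); D <- ncol(model$input)
  lines <- character(W + 1L)
  lines[1] <- paste(W, D)
  body <- apply(model$input, 1, function(v) {
    paste(sprintf("%.9g", v), collapse = " ")
  })
  lines[-1] <- paste(model$vocab$token, body)
  writeLines(lines, path)
  jsonlite::write_json(
    list(kind = model$vocab$kind, count = model$vocab$count,
         config = unclass(model$config)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load embeddings written by [save_embeddings()]
#'
#' @param path Path to the text embedding file; the `<path>.json` sidecar is
#'   read when present (token kinds default to `"disease"` otherwise).
#' @return An `embedding_model` whose `output` matrix is `NULL` (only input
#'   vectors are serialized; retrieval uses input vectors).
#' @export
load_embeddings <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  if (length(hdr) != 2L || anyNA(suppressWarnings(as.integer(hdr)))) {
    stop("malformed header on line 1 of ", path)
  }
  W <- as.integer(hdr[1]); D <- as.integer(hdr[2])
  if (length(lines) - 1L != W) {
    stop("header declares ", W, " rows but file has ", length(lines) - 1L,
         " (line ", min(W, length(lines) - 1L) + 2L, ")")
  }
  toks <- character(W)
  mat <- matrix(NA_real_, W, D)
  for (i in seq_len(W)) {
    parts <- strsplit(trimws(lines[i + 1L]), "[[:space:]]+")[[1]]
    if (length(parts) != D + 1L) {
      stop("expected ", D + 1L, " fields on line ", i + 1L, ", got ",
           length(parts))
    }
    toks[i] <- parts[1]
    v <- suppressWarnings(as.numeric(parts[-1]))
    if (anyNA(v)) {
      stop("non-numeric coordinate on line ", i + 1L)
    }
    mat[i, ] <- v
  }
  rownames(mat) <- toks
  meta_path <- paste0(path, ".json")
  kind <- rep("disease", W)
  count <- rep(NA_real_, W)
  config <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$kind) && length(meta$kind) == W) kind <- meta$kind
    if (!is.null(meta$count) && length(meta$count) == W) count <- meta$count
    if (!is.null(meta$config)) {
      config <- structure(as.list(meta$config), class = "train_config")
    }
  }
  vocab <- structure(list(token = toks, count = count, kind = kind,
                          index = stats::setNames(seq_len(W), toks)),
                     class = "dg_vocabulary")
  structure(list(input = mat, output = NULL, vocab = vocab, config = config,
                 stats = NULL),
            class = "embedding_model")
}
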