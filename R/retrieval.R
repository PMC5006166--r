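#' Cosine similarity of two vectors
#'
#' @param u,v Numeric vectors of equal length with nonzero norm.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @export
cosine_similarity <- function(u, v) {
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("degenerate vector: zero norm")
  }
  sum(u * v) / (nu * nv)
}

# Row-normalize a matrix, dropping zero-norm rows with a warning that names
# the offending tokens.
normalize_rows <- function(mat) {
  nrm <- sqrt(rowSums(mat^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning("degenerate vector(s) dropped: ",
            paste(head(rownames(mat)[zero], 5), collapse = ", "))
    mat <- mat[!zero, , drop = FALSE]
    nrm <- nrm[!zero]
  }
  mat / nrm
}

# Rank candidate rows of a normalized matrix by cosine against one
# normalized query vector; ties broken by lexicographic token order.
rank_cosine <- function(cand_norm, qvec_norm, K) {
  sims <- as.vector(cand_norm %*% qvec_norm)
  ord <- order(-sims, rownames(cand_norm))
  take <- seq_len(min(K, length(ord)))
  data.frame(token = rownames(cand_norm)[ord[take]],
             similarity = sims[ord[take]], row.names = NULL)
}

#' Cosine K-nearest-neighbour query in the embedding space
#'
#' @param model An `embedding_model` (input vectors are used).
#' @param query Token present in the vocabulary.
#' @param K Number of neighbours.
#' @param kind Restrict candidates to `"disease"` or `"gene"` tokens;
#'   `"any"` uses the full vocabulary.
#' @param candidates Optional character vector further restricting the
#'   candidate pool.
#' @return Data frame with columns `token` and `similarity`, similarities
#'   non-increasing, the query itself excluded. If `K` exceeds the pool the
#'   full pool is returned with a warning.
#' @export
nearest_neighbors <- function(model, query, K,
                              kind = c("disease", "gene", "any"),
                              candidates = NULL) {
  kind <- match.arg(kind)
  stopifnot(K >= 1)
  if (!query %in% model$vocab$token) {
    stop("unknown query token: ", query)
  }
  pool <- model$vocab$token
  if (kind != "any") pool <- pool[model$vocab$kind == kind]
  if (!is.null(candidates)) pool <- intersect(pool, candidates)
  pool <- setdiff(pool, query)
  if (length(pool) == 0L) {
    stop("empty candidate pool for query ", query)
  }
  if (K > length(pool)) {
    warning("K = ", K, " exceeds candidate pool (", length(pool),
            "); returning the full pool")
  }
  q <- model$input[query, ]
  nq <- sqrt(sum(q^2))
  if (nq == 0) {
    stop("degenerate vector: query ", query, " has zero norm")
  }
  cand <- normalize_rows(model$input[pool, , drop = FALSE])
  rank_cosine(cand, q / nq, K)
}

# Neighbour lists for many queries at once over a fixed candidate pool
# (query excluded per row). Returns a named list of character vectors.
neighbor_lists <- function(mat, queries, pool, K) {
  cand <- normalize_rows(mat[pool, , drop = FALSE])
  qn <- normalize_rows(mat[queries, , drop = FALSE])
  sims <- qn %*% t(cand)
  out <- vector("list", nrow(qn))
  names(out) <- rownames(qn)
  toks <- rownames(cand)
  for (i in seq_len(nrow(qn))) {
    s <- sims[i, ]
    self <- which(toks == rownames(qn)[i])
    if (length(self)) s[self] <- -Inf
    ord <- order(-s, toks)
    ord <- ord[is.finite(s[ord])]
    out[[i]] <- toks[ord[seq_len(min(K, length(ord)))]]
  }
  out
}

#' Disease-phenotyping precision@K against shared-gene labels
#'
#' For every query disease the K nearest diseases are retrieved by cosine
#' similarity; a neighbour counts as positive when it shares at least one
#' associated gene with the query. By default both queries and candidates
#' are the diseases that have gene annotations and are present in the
#' model, so a neighbour's label is always defined; set `pool = "all"` to
#' rank against every disease in the vocabulary.
#'
#' @param model An `embedding_model`.
#' @param gene_map A `gene_map` providing the shared-gene labels.
#' @param K_list Values of K to report (default `c(1, 2, 5, 10)`).
#' @param pool `"annotated"` (default) or `"all"`.
#' @return Data frame with columns `K` and `precision`; attributes
#'   `n_queries` and `skipped`.
#' @export
precision_at_k_phenotype <- function(model, gene_map,
                                     K_list = c(1, 2, 5, 10),
                                     pool = c("annotated", "all")) {
  pool <- match.arg(pool)
  dis <- model$vocab$token[model$vocab$kind == "disease"]
  queries <- intersect(dis, names(gene_map))
  if (length(queries) == 0L) {
    stop("no disease is present in both the model and the gene map")
  }
  cand <- if (pool == "annotated") queries else dis
  Kmax <- max(K_list)
  nbrs <- neighbor_lists(model$input, queries, cand, Kmax)

  prec <- sapply(K_list, function(K) {
    mean(vapply(queries, function(q) {
      nb <- head(nbrs[[q]], K)
      if (!length(nb)) return(0)
      gq <- genes_of(gene_map, q)
      pos <- vapply(nb, function(n) {
        length(intersect(gq, genes_of(gene_map, n))) > 0
      }, logical(1))
      sum(pos) / K
    }, numeric(1)))
  })
  structure(data.frame(K = K_list, precision = prec),
            n_queries = length(queries), skipped = 0L)
}

#' Percentage of overlapping genes between neighbouring diseases
#'
#' For every query disease and each of its K nearest disease neighbours the
#' gene-set overlap is computed and averaged, first over the K neighbours
#' and then over queries. The default overlap is the Jaccard index
#' `|G_q intersect G_n| / |G_q union G_n|`; `normalizer = "query"` divides
#' by `|G_q|` instead.
#'
#' @inheritParams precision_at_k_phenotype
#' @param normalizer `"jaccard"` (default) or `"query"`.
#' @return Data frame with columns `K` and `overlap`.
#' @export
gene_overlap_at_k <- function(model, gene_map, K_list = c(1, 2, 5, 10),
                              pool = c("annotated", "all"),
                              normalizer = c("jaccard", "query")) {
  pool <- match.arg(pool)
  normalizer <- match.arg(normalizer)
  dis <- model$vocab$token[model$vocab$kind == "disease"]
  queries <- intersect(dis, names(gene_map))
  if (length(queries) == 0L) {
    stop("no disease is present in both the model and the gene map")
  }
  cand <- if (pool == "annotated") queries else dis
  Kmax <- max(K_list)
  nbrs <- neighbor_lists(model$input, queries, cand, Kmax)

  pair_overlap <- function(q, n) {
    gq <- genes_of(gene_map, q); gn <- genes_of(gene_map, n)
    inter <- length(intersect(gq, gn))
    if (normalizer == "jaccard") {
      u <- length(union(gq, gn))
      if (u == 0) 0 else inter / u
    } else {
      if (length(gq) == 0) 0 else inter / length(gq)
    }
  }
  ov <- sapply(K_list, function(K) {
    mean(vapply(queries, function(q) {
      nb <- head(nbrs[[q]], K)
      if (!length(nb)) return(0)
      mean(vapply(nb, pair_overlap, numeric(1), q = q))
    }, numeric(1)))
  })
  structure(data.frame(K = K_list, overlap = ov),
            n_queries = length(queries))
}

#' Gene-discovery precision@K on a held-out gene map
#'
#' Protocol for evaluating the joint disease + gene model: the model is
#' trained with the training split of the gene map only; for each held-out
#' disease the K most cosine-similar gene tokens are retrieved and
#' precision@K is the fraction of them found in that disease's held-out
#' gene set.
#'
#' @param model An `embedding_model` trained on the training split.
#' @param test_map The held-out `gene_map`.
#' @param K_list Values of K to report.
#' @return Data frame with columns `K` and `precision`; attributes
#'   `n_queries` and `skipped` (held-out diseases absent from the model,
#'   reported with a warning).
#' @export
precision_at_k_genes <- function(model, test_map, K_list = c(1, 2, 5, 10)) {
  genes <- model$vocab$token[model$vocab$kind == "gene"]
  if (length(genes) == 0L) {
    stop("model contains no gene vectors")
  }
  queries <- names(test_map)
  present <- queries %in% model$vocab$token
  if (any(!present)) {
    warning(sum(!present), " held-out disease(s) absent from the model, ",
            "skipped: ", paste(head(queries[!present], 5), collapse = ", "))
  }
  queries <- queries[present]
  if (length(queries) == 0L) {
    stop("no held-out disease is present in the model")
  }
  Kmax <- max(K_list)
  nbrs <- neighbor_lists(model$input, queries, genes, Kmax)
  prec <- sapply(K_list, function(K) {
    mean(vapply(queries, function(q) {
      nb <- head(nbrs[[q]], K)
      length(intersect(nb, genes_of(test_map, q))) / K
    }, numeric(1)))
  })
  structure(data.frame(K = K_list, precision = prec),
            n_queries = length(queries), skipped = sum(!present))
}
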