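#' Build a comorbidity network from discharge records
#'
#' Classic phenotypic-network construction: diseases are nodes, and two
#' diseases are linked when their co-occurrence across records is
#' statistically significant. Each disease becomes a binary incidence
#' vector over records; the edge weight is the Pearson correlation of the
#' two incidence vectors (the phi coefficient), and an edge is kept when
#' the two-sided t-test `t = r * sqrt((n - 2) / (1 - r^2))` with
#' `n =` number of records rejects independence at level `alpha`.
#' Perfectly correlated pairs (`r = +-1`, infinite t) are kept. Diseases
#' present in all or in no records have undefined correlations: the node is
#' retained but its edges are dropped with a warning.
#'
#' @param corpus A `record_corpus` with at least 3 records.
#' @param alpha Two-sided significance level for edge retention
#'   (default 0.05).
#' @return A `comorbidity_network`: list with `nodes`, an `edges` data
#'   frame (`from`, `to`, `r`, `t`), and `n` (record count).
#' @export
build_comorbidity_network <- function(corpus, alpha = 0.05) {
  n <- length(corpus)
  if (n < 3) {
    stop("need at least 3 records to test correlations")
  }
  nodes <- sort(unique(unlist(corpus, use.names = FALSE)))
  X <- matrix(0L, n, length(nodes), dimnames = list(NULL, nodes))
  for (i in seq_len(n)) X[i, unique(corpus[[i]])] <- 1L

  degen <- colSums(X) %in% c(0L, n)
  if (any(degen)) {
    warning("disease(s) present in all or no records; their edges are ",
            "dropped: ", paste(head(nodes[degen], 5), collapse = ", "))
  }
  R <- suppressWarnings(cor(X))
  Tm <- R * sqrt((n - 2) / pmax(1 - R^2, 0))
  tcrit <- qt(1 - alpha / 2, df = n - 2)

  ut <- which(upper.tri(R), arr.ind = TRUE)
  r <- R[ut]; tt <- Tm[ut]
  ok <- !is.na(r) & !degen[ut[, 1]] & !degen[ut[, 2]] &
    (abs(r) == 1 | abs(tt) > tcrit)
  edges <- data.frame(from = nodes[ut[ok, 1]], to = nodes[ut[ok, 2]],
                      r = r[ok], t = tt[ok], row.names = NULL)
  structure(list(nodes = nodes, edges = edges, n = n, alpha = alpha),
            class = "comorbidity_network")
}

#' @export
print.comorbidity_network <- function(x, ...) {
  cat("comorbidity_network:", length(x$nodes), "diseases,",
      nrow(x$edges), "significant edges (alpha =", x$alpha, ")\n")
  invisible(x)
}

#' Rank a disease's neighbours in the comorbidity network
#'
#' Neighbours are ranked by edge weight (the phi correlation), ties broken
#' lexicographically; rejected edges do not appear.
#'
#' @param network A `comorbidity_network`.
#' @param query Disease token.
#' @param K Number of neighbours.
#' @return Data frame with columns `token` and `weight`.
#' @export
network_neighbors <- function(network, query, K) {
  if (!query %in% network$nodes) {
    stop("unknown query token: ", query)
  }
  e <- network$edges
  hit <- e$from == query | e$to == query
  other <- ifelse(e$from[hit] == query, e$to[hit], e$from[hit])
  w <- e$r[hit]
  if (length(other) == 0L) {
    warning("query ", query, " has no retained edges")
    return(data.frame(token = character(0), weight = numeric(0)))
  }
  ord <- order(-w, other)
  take <- seq_len(min(K, length(ord)))
  data.frame(token = other[ord[take]], weight = w[ord[take]],
             row.names = NULL)
}

#' Build the disease (and gene) co-occurrence adjacency graph
#'
#' Disease-disease edges are weighted by their record co-occurrence count
#' (each co-occurring pair of token occurrences counts once). When a gene
#' map is given, disease-gene edges enter with unit weight and, optionally,
#' gene-gene edges are weighted by the number of shared host diseases.
#'
#' @param corpus A `record_corpus`.
#' @param gene_map Optional `gene_map` adding gene nodes.
#' @param gene_gene_edges Also connect genes sharing a host disease
#'   (default `TRUE`).
#' @return A symmetric weighted adjacency matrix with an attribute `kind`
#'   (named character vector, `"disease"` or `"gene"`).
#' @export
build_bipartite_graph <- function(corpus, gene_map = NULL,
                                  gene_gene_edges = TRUE) {
  dis <- sort(unique(unlist(corpus, use.names = FALSE)))
  genes <- if (is.null(gene_map)) character(0) else
    sort(unique(unlist(gene_map, use.names = FALSE)))
  nodes <- c(dis, genes)
  A <- matrix(0, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (rec in corpus) {
    M <- length(rec)
    if (M < 2) next
    for (i in seq_len(M - 1)) {
      for (j in seq(i + 1, M)) {
        a <- rec[i]; b <- rec[j]
        if (a == b) next
        A[a, b] <- A[a, b] + 1
        A[b, a] <- A[b, a] + 1
      }
    }
  }
  if (!is.null(gene_map)) {
    for (d in intersect(names(gene_map), dis)) {
      for (g in genes_of(gene_map, d)) {
        A[d, g] <- 1
        A[g, d] <- 1
      }
    }
    if (gene_gene_edges && length(genes) > 1) {
      for (d in intersect(names(gene_map), dis)) {
        gs <- genes_of(gene_map, d)
        if (length(gs) < 2) next
        for (i in seq_len(length(gs) - 1)) {
          for (j in seq(i + 1, length(gs))) {
            A[gs[i], gs[j]] <- A[gs[i], gs[j]] + 1
            A[gs[j], gs[i]] <- A[gs[j], gs[i]] + 1
          }
        }
      }
    }
  }
  attr(A, "kind") <- stats::setNames(
    rep(c("disease", "gene"), c(length(dis), length(genes))), nodes)
  A
}

# Deterministic sign convention: flip each eigenvector so its first
# coordinate exceeding the tolerance in absolute value is positive.
fix_signs <- function(V, tol = 1e-10) {
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > tol)
    if (length(nz) && V[nz[1], j] < 0) V[, j] <- -V[, j]
  }
  V
}

as_adjacency <- function(graph) {
  if (inherits(graph, "comorbidity_network")) {
    A <- matrix(0, length(graph$nodes), length(graph$nodes),
                dimnames = list(graph$nodes, graph$nodes))
    e <- graph$edges
    for (i in seq_len(nrow(e))) {
      A[e$from[i], e$to[i]] <- e$r[i]
      A[e$to[i], e$from[i]] <- e$r[i]
    }
    A
  } else {
    stopifnot(is.matrix(graph), nrow(graph) == ncol(graph))
    graph
  }
}

#' Laplacian spectral embedding of a graph
#'
#' Embeds nodes with the eigenvectors of the symmetric normalized Laplacian
#' `L = I - D^{-1/2} A D^{-1/2}` associated with its `d` smallest nonzero
#' eigenvalues (equivalently, the largest eigenvectors of `I - L`).
#' Connected components are embedded separately; rows carry a `component`
#' attribute and isolated nodes get the zero vector. Eigenvector signs are
#' fixed deterministically (first nonzero coordinate positive).
#'
#' @param graph Symmetric weighted adjacency matrix with row names, or a
#'   `comorbidity_network`.
#' @param d Embedding dimension; must be smaller than the node count.
#' @return Node-by-`d` matrix with attributes `component` and
#'   `eigenvalues` (per component).
#' @export
spectral_embedding <- function(graph, d) {
  A <- as_adjacency(graph)
  n <- nrow(A)
  if (d >= n) {
    stop("embedding dimension d = ", d, " must be below the node count ", n)
  }
  g <- igraph::graph_from_adjacency_matrix(abs(A) > 0, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  emb <- matrix(0, n, d, dimnames = list(rownames(A), NULL))
  evals <- list()
  for (cc in unique(comp)) {
    idx <- which(comp == cc)
    if (length(idx) < 2) next
    Ac <- A[idx, idx, drop = FALSE]
    deg <- rowSums(abs(Ac))
    isqrt <- 1 / sqrt(deg)
    L <- diag(length(idx)) - (isqrt %o% isqrt) * Ac
    eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
    nz <- which(rev(eig$values) > 1e-8)  # ascending order positions
    vals <- rev(eig$values)
    vecs <- eig$vectors[, rev(seq_along(eig$values)), drop = FALSE]
    take <- nz[seq_len(min(d, length(nz)))]
    V <- fix_signs(vecs[, take, drop = FALSE])
    emb[idx, seq_len(ncol(V))] <- V
    evals[[as.character(cc)]] <- vals[take]
  }
  attr(emb, "component") <- comp
  attr(emb, "eigenvalues") <- evals
  emb
}

#' Modularity-matrix embedding of a graph
#'
#' Embeds nodes with the top-`d` eigenvectors (by eigenvalue) of the
#' modularity matrix `B = A - k k' / (2m)`, whose leading eigenvectors
#' expose community structure. Signs are fixed deterministically.
#'
#' @inheritParams spectral_embedding
#' @return Node-by-`d` matrix with attribute `eigenvalues`.
#' @export
modularity_embedding <- function(graph, d) {
  A <- as_adjacency(graph)
  n <- nrow(A)
  if (d >= n) {
    stop("embedding dimension d = ", d, " must be below the node count ", n)
  }
  k <- rowSums(A)
  two_m <- sum(k)
  B <- if (two_m > 0) A - (k %o% k) / two_m else A
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  V <- fix_signs(eig$vectors[, seq_len(d), drop = FALSE])
  rownames(V) <- rownames(A)
  attr(V, "eigenvalues") <- eig$values[seq_len(d)]
  V
}

#' Rank diseases by raw co-occurrence with a query
#'
#' The simplest retrieval baseline: neighbours are the diseases most often
#' observed in the same records as the query, ties broken
#' lexicographically.
#'
#' @param corpus A `record_corpus`.
#' @param query Disease token present in the corpus.
#' @param K Number of neighbours.
#' @return Data frame with columns `token` and `count`; empty (with a
#'   warning) if the query never co-occurs with another disease.
#' @export
cooccurrence_neighbors <- function(corpus, query, K) {
  counts <- cooccurrence_counts(corpus, query)
  if (length(counts) == 0L) {
    warning("query ", query, " co-occurs with no other disease")
    return(data.frame(token = character(0), count = numeric(0)))
  }
  toks <- names(counts)
  ord <- order(-counts, toks)
  take <- seq_len(min(K, length(ord)))
  data.frame(token = toks[ord[take]], count = as.numeric(counts[ord[take]]),
             row.names = NULL)
}

# Per-occurrence co-occurrence counts of every other disease with `query`.
cooccurrence_counts <- function(corpus, query) {
  found <- FALSE
  acc <- new.env(parent = emptyenv())
  for (rec in corpus) {
    nq <- sum(rec == query)
    if (nq == 0) next
    found <- TRUE
    for (tok in rec[rec != query]) {
      acc[[tok]] <- (if (is.null(acc[[tok]])) 0 else acc[[tok]]) + nq
    }
  }
  if (!found) {
    stop("unknown query token: ", query)
  }
  toks <- ls(acc)
  stats::setNames(vapply(toks, function(t) acc[[t]], numeric(1)), toks)
}

#' Most-frequent-gene trivial predictor
#'
#' Ranks genes by the number of training diseases they are associated with
#' (ties lexicographic) and returns the same top-K list for every query.
#'
#' @param train_map Training `gene_map`.
#' @param K List length.
#' @return Character vector of gene tokens.
#' @export
most_frequent_gene_predictor <- function(train_map, K) {
  if (length(train_map) == 0L) {
    stop("empty gene map")
  }
  genes <- unlist(train_map, use.names = FALSE)
  cnt <- table(genes)
  toks <- names(cnt)
  ord <- order(-as.numeric(cnt), toks)
  toks[ord[seq_len(min(K, length(ord)))]]
}

#' Disease-gene co-occurrence trivial predictor
#'
#' For a query disease, ranks genes by how often they appear -- through
#' their training host diseases -- in records containing the query, counting
#' once per host-disease occurrence.
#'
#' @param corpus A `record_corpus`.
#' @param train_map Training `gene_map`.
#' @param query Disease token present in the corpus.
#' @param K List length.
#' @return Character vector of gene tokens; empty (with a warning) when the
#'   query never co-occurs with a gene-bearing disease.
#' @export
disease_gene_cooccurrence_predictor <- function(corpus, train_map, query, K) {
  co <- cooccurrence_counts(corpus, query)
  hosts <- intersect(names(co), names(train_map))
  if (length(hosts) == 0L) {
    warning("query ", query, " never co-occurs with a gene-bearing disease")
    return(character(0))
  }
  gcnt <- tapply(rep(co[hosts], lengths(unclass(train_map)[hosts])),
                 unlist(unclass(train_map)[hosts], use.names = FALSE), sum)
  toks <- names(gcnt)
  ord <- order(-as.numeric(gcnt), toks)
  toks[ord[seq_len(min(K, length(ord)))]]
}
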