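#' Specification of a synthetic discharge-record study
#'
#' The generator plants phenotype clusters: each record draws a cluster and
#' fills its diagnosis list mostly from that cluster's diseases, and
#' annotated diseases draw their genes from a per-cluster gene pool, so
#' same-cluster diseases share genes while cross-cluster pairs share none.
#' Defaults emulate the summary statistics of a large inpatient discharge
#' database: mean record length 7.58 diagnoses (records capped at 25
#' codes) and gene annotations covering 23.5% of diseases.
#'
#' @param n_clusters Number of planted phenotype clusters.
#' @param diseases_per_cluster Diseases per cluster.
#' @param gene_pool_per_cluster Size of each cluster's gene pool.
#' @param genes_per_disease Genes drawn (without replacement) per annotated
#'   disease; must not exceed the pool size.
#' @param n_records Number of discharge records.
#' @param record_length_mean Mean diagnosis count per record; lengths are
#'   `2 + Poisson(mean - 2)` capped at 25, so every record yields at least
#'   one context pair.
#' @param noise_rate Per-token probability of drawing the diagnosis from a
#'   different cluster (in `[0, 1)`).
#' @param annotation_fraction Share of each cluster's diseases given gene
#'   annotations (the first `round(fraction * diseases_per_cluster)`,
#'   at least one).
#' @param frequency_profile `"uniform"` disease usage within a cluster, or
#'   `"zipf"` (weight `1/rank`) to exercise subsampling and the unigram
#'   noise distribution.
#' @param seed Integer seed; the same spec reproduces identical output.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_clusters = 10L, diseases_per_cluster = 20L,
                           gene_pool_per_cluster = 30L,
                           genes_per_disease = 10L, n_records = 20000L,
                           record_length_mean = 7.58, noise_rate = 0.05,
                           annotation_fraction = 0.235,
                           frequency_profile = c("uniform", "zipf"),
                           seed = 1L) {
  frequency_profile <- match.arg(frequency_profile)
  stopifnot(n_clusters >= 1, diseases_per_cluster >= 1,
            gene_pool_per_cluster >= 1, genes_per_disease >= 1,
            n_records >= 1, record_length_mean >= 2,
            noise_rate >= 0, noise_rate < 1,
            annotation_fraction > 0, annotation_fraction <= 1)
  if (genes_per_disease > gene_pool_per_cluster) {
    stop("genes_per_disease exceeds the per-cluster gene pool")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 diseases_per_cluster = as.integer(diseases_per_cluster),
                 gene_pool_per_cluster = as.integer(gene_pool_per_cluster),
                 genes_per_disease = as.integer(genes_per_disease),
                 n_records = as.integer(n_records),
                 record_length_mean = record_length_mean,
                 noise_rate = noise_rate,
                 annotation_fraction = annotation_fraction,
                 frequency_profile = frequency_profile,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic corpus, gene map and ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `corpus` (a `record_corpus`), `gene_map`
#'   (a `gene_map`), and `truth` (named cluster labels `disease_cluster`
#'   and `gene_cluster`, plus `annotated` diseases).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  nc <- spec$n_clusters
  dpc <- spec$diseases_per_cluster
  dis <- outer(seq_len(nc), seq_len(dpc),
               function(c, i) sprintf("d%02d.%02d", c, i))
  dis_cluster <- stats::setNames(rep(seq_len(nc), dpc), as.vector(dis))
  gen <- outer(seq_len(nc), seq_len(spec$gene_pool_per_cluster),
               function(c, i) sprintf("g%02d_%03d", c, i))
  gene_cluster <- stats::setNames(rep(seq_len(nc), spec$gene_pool_per_cluster),
                                  as.vector(gen))

  wts <- if (spec$frequency_profile == "zipf") 1 / seq_len(dpc) else
    rep(1, dpc)
  wts <- wts / sum(wts)

  records <- vector("list", spec$n_records)
  clusters <- sample.int(nc, spec$n_records, replace = TRUE)
  lens <- pmin(2L + rpois(spec$n_records, spec$record_length_mean - 2), 25L)
  for (i in seq_len(spec$n_records)) {
    cl <- clusters[i]
    M <- lens[i]
    own <- sample(dis[cl, ], M, replace = TRUE, prob = wts)
    if (spec$noise_rate > 0 && nc > 1) {
      flip <- runif(M) < spec$noise_rate
      if (any(flip)) {
        other <- as.vector(dis[-cl, , drop = FALSE])
        own[flip] <- sample(other, sum(flip), replace = TRUE)
      }
    }
    records[[i]] <- own
  }

  n_ann <- max(1L, round(spec$annotation_fraction * dpc))
  assoc <- list()
  for (cl in seq_len(nc)) {
    for (i in seq_len(min(n_ann, dpc))) {
      assoc[[dis[cl, i]]] <- sample(gen[cl, ], spec$genes_per_disease)
    }
  }

  list(corpus = record_corpus(records),
       gene_map = gene_map(assoc),
       truth = list(disease_cluster = dis_cluster,
                    gene_cluster = gene_cluster,
                    annotated = names(assoc),
                    record_cluster = clusters,
                    spec = spec))
}

#' Cluster-label precision@K for retrieved neighbour lists
#'
#' Ground-truth analogue of the shared-gene phenotyping precision: a
#' retrieved neighbour is positive when it belongs to the query's planted
#' cluster. When the gene map is exactly cluster-determined (same cluster
#' if and only if a gene is shared) this equals
#' [precision_at_k_phenotype()] on the same neighbour lists.
#'
#' @param truth The `truth` element of [generate_synthetic()] output (or
#'   any named cluster-label vector passed as `truth$disease_cluster`).
#' @param neighbor_lists Named list: query token -> character vector of
#'   retrieved neighbour tokens (at least `max(K_list)` long where
#'   available).
#' @param K_list Values of K to report.
#' @return Data frame with columns `K` and `precision`.
#' @export
expected_cluster_precision <- function(truth, neighbor_lists,
                                       K_list = c(1, 2, 5, 10)) {
  labels <- truth$disease_cluster
  queries <- names(neighbor_lists)
  stopifnot(all(queries %in% names(labels)))
  prec <- sapply(K_list, function(K) {
    mean(vapply(queries, function(q) {
      nb <- head(neighbor_lists[[q]], K)
      if (!length(nb)) return(0)
      sum(labels[nb] == labels[[q]]) / K
    }, numeric(1)))
  })
  data.frame(K = K_list, precision = prec)
}
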