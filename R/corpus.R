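#' Read a discharge-record corpus
#'
#' One record per line, diagnosis tokens separated by whitespace, ordered as
#' diagnosed (first token is the primary reason for admission). Blank lines
#' are skipped with a message; token order within a line is preserved
#' exactly.
#'
#' @param path Path to a UTF-8 text file.
#' @return A `record_corpus`: a list of character vectors, one per record.
#' @export
load_records <- function(path) {
  if (!file.exists(path)) {
    stop("cannot read record file: ", path)
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  keep <- lengths(toks) > 0L & vapply(toks, function(x) any(nzchar(x)), logical(1))
  if (any(!keep)) {
    message(sum(!keep), " blank line(s) skipped in ", path)
  }
  record_corpus(toks[keep])
}

#' Construct a record corpus from a list of token vectors
#'
#' @param records List of character vectors; each must contain at least one
#'   non-empty, whitespace-free token.
#' @return A `record_corpus` object.
#' @export
record_corpus <- function(records) {
  records <- lapply(records, as.character)
  bad <- vapply(records, function(r) {
    length(r) == 0L || any(!nzchar(r)) || any(grepl("[[:space:]]", r))
  }, logical(1))
  if (any(bad)) {
    stop("record ", which(bad)[1], " contains empty or whitespace tokens")
  }
  structure(records, class = "record_corpus")
}

#' @export
print.record_corpus <- function(x, ...) {
  cat("record_corpus:", length(x), "records,",
      sum(lengths(x)), "diagnosis tokens\n")
  invisible(x)
}

#' Write a corpus back to disk
#'
#' Inverse of [load_records()] up to whitespace normalization: each record
#' becomes one line of space-separated tokens.
#'
#' @param corpus A `record_corpus`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(corpus, path) {
  writeLines(vapply(corpus, paste, character(1), collapse = " "), path)
  invisible(path)
}

#' Construct a disease-gene association map
#'
#' @param associations Named list: disease token -> character vector of gene
#'   tokens. Empty gene sets are dropped; duplicates within a set are
#'   removed.
#' @param pvalues Optional data.frame with columns `disease`, `gene`,
#'   `pvalue` recording the provenance of each retained pair.
#' @return A `gene_map` object. Looking up a disease that is absent yields
#'   `character(0)` (see [genes_of()]).
#' @export
gene_map <- function(associations, pvalues = NULL) {
  associations <- lapply(associations, function(g) sort(unique(as.character(g))))
  associations <- associations[lengths(associations) > 0L]
  if (length(associations) && is.null(names(associations))) {
    stop("associations must be a named list (disease -> genes)")
  }
  structure(associations, pvalues = pvalues, class = "gene_map")
}

#' @export
print.gene_map <- function(x, ...) {
  cat("gene_map:", length(x), "diseases,",
      length(unique(unlist(x, use.names = FALSE))), "distinct genes\n")
  invisible(x)
}

#' Look up the gene set of a disease
#'
#' @param map A `gene_map`.
#' @param disease Disease token.
#' @return Character vector of gene tokens; empty if the disease has no
#'   recorded associations.
#' @export
genes_of <- function(map, disease) {
  g <- map[[disease]]
  if (is.null(g)) character(0) else g
}

#' Load a disease-gene association table
#'
#' Reads a TSV with header columns `disease`, `gene`, `pvalue` (the shape of
#' a GWAS-catalog disease-gene mapping) and keeps rows whose association
#' p-value is below `p_threshold`. Duplicated (disease, gene) pairs keep the
#' smallest p-value.
#'
#' @param path Path to the TSV file.
#' @param p_threshold Retain associations with `pvalue < p_threshold`.
#'   Default `1e-5`, the conventional genome-wide suggestive threshold.
#' @return A `gene_map`.
#' @export
load_gene_map <- function(path, p_threshold = 1e-5) {
  stopifnot(is.numeric(p_threshold), p_threshold > 0, p_threshold <= 1)
  if (!file.exists(path)) {
    stop("cannot read gene map file: ", path)
  }
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    colClasses = "character", quote = "")
  for (col in c("disease", "gene", "pvalue")) {
    if (!col %in% names(tab)) {
      stop("gene map file is missing column '", col, "'")
    }
  }
  pv <- suppressWarnings(as.numeric(tab$pvalue))
  if (anyNA(pv) && nrow(tab)) {
    bad <- which(is.na(pv))[1]
    stop("non-numeric p-value on data line ", bad, " of ", path)
  }
  keep <- which(pv < p_threshold)
  tab <- tab[keep, , drop = FALSE]
  pv <- pv[keep]
  if (nrow(tab) == 0L) {
    return(gene_map(list(),
                    pvalues = data.frame(disease = character(0),
                                         gene = character(0),
                                         pvalue = numeric(0))))
  }
  ord <- order(tab$disease, tab$gene, pv)
  tab <- tab[ord, , drop = FALSE]
  pv <- pv[ord]
  dup <- duplicated(tab[c("disease", "gene")])
  tab <- tab[!dup, , drop = FALSE]
  pv <- pv[!dup]
  gene_map(split(tab$gene, tab$disease),
           pvalues = data.frame(disease = tab$disease, gene = tab$gene,
                                pvalue = pv, row.names = NULL))
}

#' Write a gene map as a 3-column TSV
#'
#' @param map A `gene_map`.
#' @param path Output path.
#' @param default_pvalue P-value written for pairs without recorded
#'   provenance.
#' @return `path`, invisibly.
#' @export
write_gene_map <- function(map, path, default_pvalue = 1e-8) {
  dis <- rep(names(map), lengths(map))
  gen <- unlist(unname(map))
  pv <- rep(default_pvalue, length(gen))
  prov <- attr(map, "pvalues")
  if (!is.null(prov) && nrow(prov)) {
    key <- paste(prov$disease, prov$gene, sep = "\r")
    hit <- match(paste(dis, gen, sep = "\r"), key)
    pv[!is.na(hit)] <- prov$pvalue[hit[!is.na(hit)]]
  }
  tab <- data.frame(disease = dis, gene = gen, pvalue = pv)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build the token vocabulary of a corpus
#'
#' Disease tokens are counted over the corpus and those below `min_count`
#' are dropped. When a gene map is supplied, every gene attached to a
#' retained disease enters the vocabulary with kind `"gene"`; a gene is
#' "seen" once per occurrence of each of its host diseases, so its count is
#' the summed corpus count of its retained hosts. Disease and gene token
#' namespaces must not collide.
#'
#' @param corpus A `record_corpus`.
#' @param gene_map Optional `gene_map`.
#' @param min_count Drop disease tokens occurring fewer than this many
#'   times. Default 5, the usual floor for embedding vocabularies.
#' @return A `dg_vocabulary`: parallel vectors `token`, `count`, `kind`
#'   plus a token -> row lookup.
#' @export
build_vocabulary <- function(corpus, gene_map = NULL, min_count = 5L) {
  stopifnot(min_count >= 1)
  if (length(corpus) == 0L) {
    stop("empty corpus")
  }
  tok <- unlist(corpus, use.names = FALSE)
  cnt <- table(tok)
  cnt <- cnt[cnt >= min_count]
  if (length(cnt) == 0L) {
    stop("no disease token reaches min_count = ", min_count)
  }
  d_tok <- names(cnt)
  d_cnt <- as.numeric(cnt)

  g_tok <- character(0)
  g_cnt <- numeric(0)
  if (!is.null(gene_map) && length(gene_map)) {
    hosts <- intersect(names(gene_map), d_tok)
    if (length(hosts)) {
      host_cnt <- d_cnt[match(hosts, d_tok)]
      genes <- unlist(gene_map[hosts], use.names = FALSE)
      per_host <- rep(host_cnt, lengths(gene_map[hosts]))
      agg <- tapply(per_host, genes, sum)
      g_tok <- names(agg)
      g_cnt <- as.numeric(agg)
      clash <- intersect(g_tok, d_tok)
      if (length(clash)) {
        stop("namespace collision: token(s) appear as both disease and gene: ",
             paste(head(clash, 5), collapse = ", "))
      }
    }
  }

  token <- c(d_tok, g_tok)
  vocab <- structure(list(
    token = token,
    count = c(d_cnt, g_cnt),
    kind = rep(c("disease", "gene"), c(length(d_tok), length(g_tok))),
    index = stats::setNames(seq_along(token), token)
  ), class = "dg_vocabulary")
  vocab
}

#' @export
print.dg_vocabulary <- function(x, ...) {
  cat("dg_vocabulary:", sum(x$kind == "disease"), "diseases,",
      sum(x$kind == "gene"), "genes\n")
  invisible(x)
}

#' Attach gene bags to a discharge record
#'
#' Each disease position of the record receives its (possibly empty) gene
#' set as an attached bag whose order is freshly shuffled; the disease
#' sequence itself is untouched -- genes never occupy sequence positions, so
#' context-window offsets are unaffected. Uses the current R random stream;
#' call `set.seed()` first for reproducibility.
#'
#' @param record Character vector of disease tokens.
#' @param gene_map A `gene_map`.
#' @return List with elements `diseases` (the unchanged record) and `genes`
#'   (a list of shuffled gene bags, one per position).
#' @export
attach_genes <- function(record, gene_map) {
  bags <- lapply(record, function(d) {
    g <- genes_of(gene_map, d)
    if (length(g) > 1L) g[sample.int(length(g))] else g
  })
  list(diseases = record, genes = bags)
}

#' Split a gene map for held-out gene discovery
#'
#' A uniform random `fraction` of the diseases that have gene associations
#' is selected; their entire gene sets move to the test map, leaving the
#' rest as training associations. Uses the current R random stream.
#'
#' @param gene_map A `gene_map`.
#' @param fraction Proportion of annotated diseases to hold out (default
#'   0.2, i.e. a 20% disease holdout).
#' @return List with `gene_map` elements `train` and `test`, plus the
#'   held-out disease tokens in `test_diseases`.
#' @export
holdout_gene_map <- function(gene_map, fraction = 0.2) {
  stopifnot(fraction > 0, fraction < 1)
  diseases <- names(gene_map)
  n_test <- round(fraction * length(diseases))
  if (n_test < 1) {
    stop("holdout too small: fraction ", fraction, " of ", length(diseases),
         " annotated diseases selects no test disease")
  }
  test_d <- sort(sample(diseases, n_test))
  prov <- attr(gene_map, "pvalues")
  split_prov <- function(keep) {
    if (is.null(prov)) NULL else prov[prov$disease %in% keep, , drop = FALSE]
  }
  train_d <- setdiff(diseases, test_d)
  list(
    train = gene_map(unclass(gene_map)[train_d], pvalues = split_prov(train_d)),
    test = gene_map(unclass(gene_map)[test_d], pvalues = split_prov(test_d)),
    test_diseases = test_d
  )
}
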