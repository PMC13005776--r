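#' Read a miRNA-target table
#'
#' Tab-separated file with columns `mirna`, `gene`, `source`, `evidence`
#' (e.g. exports from curated experimentally-validated target databases).
#' Gene symbols are upper-cased and duplicate (mirna, gene, source) rows are
#' collapsed.
#'
#' @param path file path.
#' @return data frame of unique target records.
#' @export
read_target_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("mirna", "gene", "source")
  miss <- setdiff(req, names(d))
  if (length(miss)) {
    abort_mirogtt(sprintf("target table missing column(s): %s",
                          paste(miss, collapse = ", ")), "mirogtt_schema")
  }
  d$gene <- toupper(d$gene)
  d[!duplicated(d[, req]), ]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated gene symbols.
#'
#' @param path file path.
#' @return named list of character vectors (genes, upper-cased).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort_mirogtt("GMT line needs name, description and >= 1 gene",
                    "mirogtt_schema")
    }
    unique(toupper(f[-(1:2)]))
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Common validated targets of a miRNA list within an expressed universe
#'
#' Takes, per miRNA, the union of its targets across source databases
#' (either database suffices for "validated"), intersects across all listed
#' miRNAs, and restricts to the expressed-gene universe (e.g. genes expressed
#' in human islets). Optionally flags the subset found in a supplied
#' disease-association gene list.
#'
#' @param targets target table (see [read_target_table()]); can combine rows
#'   from several databases.
#' @param mirnas character vector; every miRNA must target a gene for it to
#'   be retained.
#' @param universe character vector of expressed genes.
#' @param disease_genes optional character vector of disease-associated genes.
#' @return list: `common` (sorted gene vector), `disease` (subset of common
#'   found in `disease_genes`).
#' @export
common_targets <- function(targets, mirnas, universe, disease_genes = NULL) {
  if (length(universe) == 0) {
    abort_mirogtt("expressed universe is empty", "mirogtt_validation")
  }
  universe <- toupper(universe)
  sets <- lapply(mirnas, function(m) {
    g <- unique(toupper(targets$gene[targets$mirna == m]))
    if (length(g) == 0) {
      abort_mirogtt(sprintf("miRNA %s absent from all target tables", m),
                    "mirogtt_validation")
    }
    g
  })
  common <- Reduce(intersect, sets)
  common <- sort(intersect(common, universe))
  disease <- if (is.null(disease_genes)) character(0) else
    intersect(common, toupper(disease_genes))
  list(common = common, disease = disease)
}

#' Hypergeometric over-representation analysis
#'
#' For each pathway, tests whether the query gene set overlaps it more than
#' expected under random draws from the universe:
#' `p = P[X >= k]` with `X ~ Hypergeometric(N, K, n)` where N is the universe
#' size, K the pathway size within the universe, n the query size and k the
#' overlap. BH FDR across pathways; results sorted by p.
#'
#' @param query character vector of genes; must be contained in `universe`.
#' @param pathways named list of gene vectors (see [read_gmt()]); each is
#'   intersected with the universe first.
#' @param universe character vector of background genes.
#' @return data frame: `pathway`, `overlap_k`, `set_size_K`, `query_n`,
#'   `universe_N`, `p`, `q`, `genes` (semicolon-joined overlap), sorted by p.
#' @export
hypergeom_ora <- function(query, pathways, universe) {
  query <- unique(toupper(query)); universe <- unique(toupper(universe))
  if (length(query) == 0) {
    abort_mirogtt("query gene set is empty", "mirogtt_validation")
  }
  if (!all(query %in% universe)) {
    abort_mirogtt("query contains genes outside the universe",
                  "mirogtt_validation")
  }
  N <- length(universe); n <- length(query)
  rows <- lapply(names(pathways), function(nm) {
    set <- intersect(unique(toupper(pathways[[nm]])), universe)
    K <- length(set)
    hit <- intersect(query, set)
    k <- length(hit)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(pathway = nm, overlap_k = k, set_size_K = K, query_n = n,
               universe_N = N, p = p,
               genes = paste(sort(hit), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bh_fdr(res$p)
  res <- res[order(res$p), c("pathway", "overlap_k", "set_size_K", "query_n",
                             "universe_N", "p", "q", "genes")]
  rownames(res) <- NULL
  res
}
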