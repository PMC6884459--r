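#' Fisher's exact overrepresentation test for annotated terms
#'
#' One-sided ("greater") Fisher's exact test per term: the p-value is the
#' hypergeometric upper tail P(X >= k) where k study genes of n carry the
#' term, against K of N background genes.  Only terms annotating at least
#' one study gene are tested; q-values are BH-adjusted across tested terms
#' and results are sorted by (q, p).
#'
#' @param study_genes character vector of study gene ids; must be a subset
#'   of `background_genes`.
#' @param background_genes character vector: the background universe
#'   (typically all annotated genes).
#' @param annotation data frame with columns `gene_id`, `term_id` and
#'   optionally `term_name`; rows mapping genes to terms. Annotations of
#'   genes outside the background are ignored.
#' @return A data frame of class `enrichment_result`: `term_id`,
#'   `term_name`, `k_study`, `n_study`, `K_background`, `N_background`,
#'   `fold_enrichment`, `p_value`, `q_value`.
#' @examples
#' ann <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
#'                   term_id = c("T1", "T1", "T1", "T2"))
#' fisher_overrepresentation(c("g1", "g2"), paste0("g", 1:10), ann)
#' @export
fisher_overrepresentation <- function(study_genes, background_genes,
                                      annotation) {
  study_genes <- unique(as.character(study_genes))
  background_genes <- unique(as.character(background_genes))
  if (length(background_genes) == 0L)
    stop_devdelay("background must be non-empty", class = "devdelay_value_error")
  stray <- setdiff(study_genes, background_genes)
  if (length(stray))
    stop_devdelay("study gene '%s' is absent from the background", stray[1L],
                  class = "devdelay_value_error")
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "term_id") %in% names(annotation)))
  if (is.null(annotation$term_name)) annotation$term_name <- annotation$term_id

  ann <- unique(annotation[annotation$gene_id %in% background_genes,
                           c("gene_id", "term_id", "term_name")])
  empty <- data.frame(term_id = character(), term_name = character(),
                      k_study = integer(), n_study = integer(),
                      K_background = integer(), N_background = integer(),
                      fold_enrichment = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
  class(empty) <- c("enrichment_result", "data.frame")
  if (length(study_genes) == 0L || nrow(ann) == 0L) return(empty)

  N <- length(background_genes)
  n <- length(study_genes)
  k_tab <- table(factor(ann$term_id[ann$gene_id %in% study_genes]))
  if (length(k_tab) == 0L) return(empty)
  K_tab <- table(factor(ann$term_id, levels = names(k_tab)))
  term_names <- ann$term_name[match(names(k_tab), ann$term_id)]

  k <- as.integer(k_tab); K <- as.integer(K_tab)
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(
    term_id = names(k_tab), term_name = term_names,
    k_study = k, n_study = n, K_background = K, N_background = N,
    fold_enrichment = (k / n) / (K / N),
    p_value = pmin(p, 1), q_value = bh_adjust(pmin(p, 1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$q_value, out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment_result", "data.frame")
  out
}

# descendants of each node in the parent -> children edge list, by BFS;
# the edge graph is first checked acyclic (Kahn's algorithm)
term_descendants <- function(term_edges, terms) {
  stopifnot(is.data.frame(term_edges),
            all(c("parent_id", "child_id") %in% names(term_edges)))
  parent <- as.character(term_edges$parent_id)
  child <- as.character(term_edges$child_id)
  nodes <- unique(c(parent, child))
  indeg <- stats::setNames(tabulate(match(child, nodes), length(nodes)), nodes)
  kids <- split(child, factor(parent, levels = nodes))
  queue <- nodes[indeg == 0]
  removed <- 0L
  while (length(queue)) {
    v <- queue[[1L]]; queue <- queue[-1L]; removed <- removed + 1L
    for (w in kids[[v]]) {
      indeg[[w]] <- indeg[[w]] - 1L
      if (indeg[[w]] == 0L) queue <- c(queue, w)
    }
  }
  if (removed < length(nodes))
    stop_devdelay("cycle detected in the term hierarchy",
                  class = "devdelay_value_error")
  lapply(stats::setNames(terms, terms), function(t) {
    seen <- character(0)
    frontier <- kids[[t]] %||% character(0)
    while (length(frontier)) {
      new <- setdiff(frontier, seen)
      seen <- c(seen, new)
      frontier <- unique(unlist(kids[new], use.names = FALSE))
    }
    seen
  })
}

#' Keep only the most specific significant terms
#'
#' Reduces an enrichment result to the bottom of the term hierarchy:
#' significant terms (`q_value < alpha`) are retained only if no descendant
#' in the transitive closure of the parent->child edge table is itself
#' significant.  With no edge table supplied, all significant terms are
#' returned unchanged and the result carries a `no_hierarchy` warning
#' attribute.
#'
#' @param results an `enrichment_result` from
#'   [fisher_overrepresentation()].
#' @param term_edges data frame with columns `parent_id`, `child_id`
#'   (acyclic over the mentioned terms), or `NULL`.
#' @param alpha significance threshold on q-values (default 0.05).
#' @return The filtered `enrichment_result` (same columns, q-sorted).
#' @export
most_specific_terms <- function(results, term_edges = NULL, alpha = 0.05) {
  stopifnot(inherits(results, "data.frame"))
  sig <- results[results$q_value < alpha, , drop = FALSE]
  if (is.null(term_edges)) {
    attr(sig, "no_hierarchy") <- TRUE
    return(sig)
  }
  desc <- term_descendants(term_edges, sig$term_id)
  keep <- vapply(sig$term_id, function(t)
    !any(desc[[t]] %in% sig$term_id), TRUE)
  out <- sig[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
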