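# Over-representation analysis: hypergeometric upper-tail test of DE gene
# sets against GO-style (BP/CC/MF) and pathway collections, with BH
# correction within each namespace and top-N reporting.

#' Gene-set collection with a background universe
#'
#' @param terms named list; each element a list with `name`, `namespace`
#'   (one of BP, CC, MF, pathway) and `members` (gene ids).
#' @param background character vector, the gene universe.
#' @return a `gene_set_collection`. Members outside the background are
#'   dropped; empty terms are removed.
#' @export
gene_set_collection <- function(terms, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background")
  terms <- lapply(terms, function(t) {
    stopifnot(t$namespace %in% c("BP", "CC", "MF", "pathway"))
    t$members <- intersect(t$members, background)
    t
  })
  terms <- terms[vapply(terms, function(t) length(t$members) >= 1L, logical(1))]
  structure(list(terms = terms, background = background),
            class = "gene_set_collection")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing at
#' least `k` marked genes when drawing `n` from a universe of `N` containing
#' `K` marked. Computed via the stable distribution-function routine.
#'
#' @param k observed overlap.
#' @param K term size.
#' @param n draw (DE set) size.
#' @param N background size.
#' @return the upper-tail p-value.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || k > min(n, K) || K > N || n > N) {
    stop("inconsistent hypergeometric counts")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Over-representation analysis of a DE gene set
#'
#' One hypergeometric upper-tail test per term; BH q-values are computed
#' within each namespace (BP/CC/MF/pathway separately). DE genes outside the
#' background are dropped (count reported via the `n_dropped` attribute).
#'
#' @param de_genes character vector of DE gene ids.
#' @param collection a [gene_set_collection()].
#' @param min_term_size terms smaller than this are skipped (default 2).
#' @return data.frame sorted by q, then p, then term id: term, name,
#'   namespace, k, n, K, N, p, q, fold_enrichment.
#' @export
enrich <- function(de_genes, collection, min_term_size = 2L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  bg <- collection$background
  de <- unique(de_genes)
  dropped <- sum(!de %in% bg)
  de <- intersect(de, bg)
  N <- length(bg)
  n <- length(de)
  keep <- vapply(collection$terms, function(t) length(t$members) >= min_term_size,
                 logical(1))
  terms <- collection$terms[keep]
  rows <- lapply(names(terms), function(tid) {
    t <- terms[[tid]]
    K <- length(t$members)
    k <- length(intersect(de, t$members))
    data.frame(term = tid, name = t$name, namespace = t$namespace,
               k = k, n = n, K = K, N = N,
               p = hypergeom_upper_tail(k, K, n, N),
               fold_enrichment = if (n > 0) (k / n) / (K / N) else 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term = character(0), name = character(0),
                      namespace = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), p = numeric(0),
                      q = numeric(0), fold_enrichment = numeric(0),
                      stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- dropped
    return(out)
  }
  out$q <- NA_real_
  for (ns in unique(out$namespace)) {
    i <- out$namespace == ns
    out$q[i] <- adjust_bh(out$p[i])
  }
  out <- out[order(out$q, out$p, out$term), c("term", "name", "namespace",
                                              "k", "n", "K", "N", "p", "q",
                                              "fold_enrichment")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Top-N enriched terms per namespace
#'
#' @param results output of [enrich()].
#' @param n_top terms to keep per namespace (default 30, the usual reporting
#'   convention for GO bar charts).
#' @return filtered results data.frame.
#' @export
top_enriched <- function(results, n_top = 30L) {
  out <- do.call(rbind, lapply(split(results, results$namespace), head, n_top))
  out <- out[order(out$q, out$p, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
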