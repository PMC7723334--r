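# Thresholded Pearson co-expression networks between DE feature sets.
# Default gate follows the coding/non-coding network construction rule:
# |r| >= 0.99 and correlation p < 0.05; miRNA-mRNA edges are restricted to
# negative correlations. Edges are unordered pairs; self-pairs excluded.

#' Pearson correlation with a t-distribution p-value
#'
#' Two-sided p from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom; `|r| = 1` gives p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3, both non-constant.
#' @return list with `r` and `p`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  n <- length(x)
  if (n < 3L) stop("need >= 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0) stop("correlation undefined for a constant vector")
  r <- cor(x, y)
  p <- cor_p_from_r(r, n)
  list(r = r, p = p)
}

cor_p_from_r <- function(r, n) {
  r2 <- pmin(r^2, 1)
  p <- ifelse(r2 >= 1, 0,
              2 * pt(abs(r) * sqrt((n - 2) / (1 - r2)), n - 2, lower.tail = FALSE))
  pmin(p, 1)
}

#' Correlation gate for network edges
#'
#' @param min_abs_r minimum |Pearson r| (default 0.99).
#' @param alpha correlation p threshold (default 0.05).
#' @param required_sign `"any"`, `"positive"` or `"negative"`.
#' @return a `correlation_rule` list.
#' @export
correlation_rule <- function(min_abs_r = 0.99, alpha = 0.05,
                             required_sign = c("any", "positive", "negative")) {
  if (min_abs_r < 0 || min_abs_r > 1) stop("min_abs_r must lie in [0, 1]")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  structure(list(min_abs_r = min_abs_r, alpha = alpha,
                 required_sign = match.arg(required_sign)),
            class = "correlation_rule")
}

#' Build a thresholded co-expression network between two DE feature sets
#'
#' Correlations are computed over the shared samples of the two matrices
#' (optionally restricted to `samples`, e.g. the six samples of one
#' comparison). An edge is emitted for exactly the DE-feature pairs passing
#' `|r| >= min_abs_r`, `p < alpha`, and the sign requirement.
#'
#' @param mat_a,mat_b [expression_matrix()] objects sharing samples.
#' @param de_a,de_b character vectors of DE feature ids in each matrix.
#' @param rule a [correlation_rule()].
#' @param samples optional sample ids over which to correlate (default: all
#'   shared samples).
#' @return edge data.frame: node_a, species_a, node_b, species_b, r, p, sign.
#' @export
build_pair_network <- function(mat_a, mat_b, de_a, de_b,
                               rule = correlation_rule(), samples = NULL) {
  stopifnot(inherits(mat_a, "expr_matrix"), inherits(mat_b, "expr_matrix"))
  shared <- intersect(colnames(mat_a$values), colnames(mat_b$values))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  if (length(shared) < 3L) stop("need >= 3 shared samples")
  de_a <- intersect(de_a, rownames(mat_a$values))
  de_b <- intersect(de_b, rownames(mat_b$values))
  empty <- data.frame(node_a = character(0), species_a = character(0),
                      node_b = character(0), species_b = character(0),
                      r = numeric(0), p = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (!length(de_a) || !length(de_b)) return(empty)
  va <- mat_a$values[de_a, shared, drop = FALSE]
  vb <- mat_b$values[de_b, shared, drop = FALSE]
  keep_a <- apply(va, 1, sd) > 0
  keep_b <- apply(vb, 1, sd) > 0
  va <- va[keep_a, , drop = FALSE]; vb <- vb[keep_b, , drop = FALSE]
  if (!nrow(va) || !nrow(vb)) return(empty)
  rmat <- cor(t(va), t(vb))
  pmat <- cor_p_from_r(rmat, length(shared))
  hit <- abs(rmat) >= rule$min_abs_r & pmat < rule$alpha
  if (rule$required_sign == "positive") hit <- hit & rmat > 0
  if (rule$required_sign == "negative") hit <- hit & rmat < 0
  idx <- which(hit, arr.ind = TRUE)
  if (!nrow(idx)) return(empty)
  edges <- data.frame(
    node_a = rownames(rmat)[idx[, 1]], species_a = mat_a$species,
    node_b = colnames(rmat)[idx[, 2]], species_b = mat_b$species,
    r = rmat[idx], p = pmat[idx], sign = ifelse(rmat[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE
  )
  # unordered pairs: drop self-pairs and (b,a) duplicates of (a,b)
  same_univ <- mat_a$species == mat_b$species
  if (same_univ) {
    edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
    key <- ifelse(edges$node_a < edges$node_b,
                  paste(edges$node_a, edges$node_b),
                  paste(edges$node_b, edges$node_a))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  edges
}

#' Degree, edge and component summary of an edge list
#'
#' @param edges edge data.frame from [build_pair_network()].
#' @return list: `degrees` (named, decreasing, ties broken lexically),
#'   `n_edges`, `n_components`.
#' @export
summarize_network <- function(edges) {
  if (!nrow(edges)) {
    return(list(degrees = setNames(integer(0), character(0)),
                n_edges = 0L, n_components = 0L))
  }
  nodes <- c(edges$node_a, edges$node_b)
  deg <- table(nodes)
  deg <- setNames(as.integer(deg), names(deg))
  deg <- deg[order(-deg, names(deg))]
  g <- igraph::graph_from_data_frame(edges[, c("node_a", "node_b")],
                                     directed = FALSE)
  list(degrees = deg, n_edges = nrow(edges),
       n_components = as.integer(igraph::components(g)$no))
}
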