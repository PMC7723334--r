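# Normalisation, exploratory clustering/PCA, and differential-expression
# calling. Convention: fold changes are signed ratios (never inside (-1, 1)):
# log2fc of +1 is FC +2, log2fc of -1 is FC -2. DE gates combine a |FC|
# threshold with a species-dependent p mode (BH-adjusted for lncRNA/mRNA/
# miRNA, raw t-test p for circRNA), adjusted within each species x comparison
# family.

#' Quantile normalisation of an expression matrix
#'
#' Forces every sample (column) onto the identical value distribution, the
#' row-wise mean of the sorted columns; ties within a column receive the mean
#' of their would-be normalised values.
#'
#' @param mat an [expression_matrix()] with >= 2 samples.
#' @return the normalised `expr_matrix`.
#' @export
quantile_normalize <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (ncol(mat$values) < 2L) stop("quantile normalisation needs >= 2 samples")
  if (nrow(mat$values) == 0L) stop("empty matrix")
  if (nrow(mat$values) == 1L) {
    # forced by the definition: a single quantile, the row mean
    v <- matrix(mean(mat$values), 1L, ncol(mat$values))
  } else {
    v <- limma::normalizeQuantiles(mat$values, ties = TRUE)
  }
  dimnames(v) <- dimnames(mat$values)
  expression_matrix(v, mat$species, mat$condition_of)
}

#' Median-centre every feature (row)
#'
#' After centring, each row has median 0. Idempotent.
#'
#' @param mat an [expression_matrix()] or plain numeric matrix.
#' @return same type as the input.
#' @export
median_center_rows <- function(mat) {
  if (inherits(mat, "expr_matrix")) {
    v <- mat$values - apply(mat$values, 1, median)
    return(expression_matrix(v, mat$species, mat$condition_of))
  }
  mat - apply(mat, 1, median)
}

#' Agglomerative average-linkage (UPGMA) clustering
#'
#' @param mat an [expression_matrix()] or numeric matrix.
#' @param axis `"features"` (rows) or `"samples"` (columns).
#' @param distance `"euclidean"` or `"one_minus_pearson"`.
#' @return list with `merge`, `height`, `order`, `labels` (as in
#'   [stats::hclust()]) plus `newick`, the tree in Newick format with merge
#'   heights as branch lengths.
#' @export
hierarchical_cluster <- function(mat, axis = c("samples", "features"),
                                 distance = c("euclidean", "one_minus_pearson")) {
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  v <- if (inherits(mat, "expr_matrix")) mat$values else mat
  items <- if (axis == "samples") t(v) else v
  if (nrow(items) < 2L) stop("need >= 2 items to cluster")
  d <- if (distance == "euclidean") {
    dist(items)
  } else {
    as.dist(1 - cor(t(items)))
  }
  hc <- hclust(d, method = "average")
  phy <- ape::as.phylo(hc)
  list(merge = hc$merge, height = hc$height, order = hc$order,
       labels = hc$labels, hclust = hc,
       newick = ape::write.tree(phy))
}

#' Principal component analysis of samples
#'
#' Samples are the observations; features are column-centred before SVD.
#'
#' @param mat an [expression_matrix()] or numeric matrix (features x samples).
#' @param n_components number of components to keep.
#' @return list with `scores` (samples x components), `loadings`
#'   (orthonormal, features x components), `explained_variance_ratio`.
#' @export
pca_samples <- function(mat, n_components = 2L) {
  v <- if (inherits(mat, "expr_matrix")) mat$values else mat
  x <- t(v)  # samples x features
  if (n_components > min(dim(x))) {
    stop("n_components exceeds min(samples, features)")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  k <- seq_len(n_components)
  list(scores = pc$x[, k, drop = FALSE],
       loadings = pc$rotation[, k, drop = FALSE],
       explained_variance_ratio = evr[k])
}

#' Per-feature two-sample differential test between two conditions
#'
#' Unpaired two-sided Student's t-test; pooled variance by default, Welch
#' optional. `log2fc = mean(b) - mean(a)` on the log2 scale; `fold_change` is
#' the signed ratio `2^log2fc` for log2fc >= 0, else `-2^(-log2fc)`.
#' Degenerate rows (pooled variance 0) get p = 1 when the means agree and
#' p = 0 with `degenerate = TRUE` when they differ.
#'
#' @param mat an [expression_matrix()].
#' @param condition_a reference condition label.
#' @param condition_b alternative condition label.
#' @param var_equal pooled (TRUE, default) or Welch (FALSE) variance.
#' @return data.frame: feature_id, log2fc, fold_change, p_raw, degenerate.
#' @export
differential_test <- function(mat, condition_a, condition_b, var_equal = TRUE) {
  stopifnot(inherits(mat, "expr_matrix"))
  for (cn in c(condition_a, condition_b)) {
    if (!cn %in% mat$condition_of) stop("condition not present: ", cn)
  }
  a <- mat$values[, samples_of(mat, condition_a), drop = FALSE]
  b <- mat$values[, samples_of(mat, condition_b), drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1, var); vb <- apply(b, 1, var)
  log2fc <- mb - ma
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tstat <- log2fc / se
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se == 0 | !is.finite(tstat)
  p[degenerate & log2fc == 0] <- 1
  p[degenerate & log2fc != 0] <- 0
  data.frame(
    feature_id = rownames(mat$values),
    log2fc = unname(log2fc),
    fold_change = signed_fc(unname(log2fc)),
    p_raw = unname(p),
    degenerate = unname(degenerate & log2fc != 0),
    stringsAsFactors = FALSE
  )
}

# signed fold-change convention: never inside (-1, 1)
signed_fc <- function(log2fc) {
  ifelse(log2fc >= 0, 2^log2fc, -(2^(-log2fc)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
adjust_bh <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Holm step-down adjustment
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
adjust_holm <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Per-species differential-expression thresholds
#'
#' Defaults: |FC| >= 2 with BH-adjusted p < 0.05 for lncRNA and mRNA, |FC| >=
#' 2 with raw t-test p < 0.05 for circRNA, and |FC| >= 1.5 with q < 0.05 for
#' miRNA (the laxer ratio reflecting the smaller number of differential
#' miRNAs on such platforms).
#'
#' @param min_fc named per-species minimum |fold change|.
#' @param p_mode named per-species p gate, `"adjusted"` or `"raw"`.
#' @param alpha significance level.
#' @return a `threshold_policy` list.
#' @export
threshold_policy <- function(min_fc = c(lncRNA = 2, circRNA = 2, miRNA = 1.5, mRNA = 2),
                             p_mode = c(lncRNA = "adjusted", circRNA = "raw",
                                        miRNA = "adjusted", mRNA = "adjusted"),
                             alpha = 0.05) {
  if (any(min_fc < 1)) stop("|FC| thresholds must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stopifnot(all(p_mode %in% c("adjusted", "raw")))
  structure(list(min_fc = min_fc[RNA_SPECIES], p_mode = p_mode[RNA_SPECIES],
                 alpha = alpha), class = "threshold_policy")
}

#' Call differential expression for one species and comparison
#'
#' Adjusted p-values are computed within this species x comparison family.
#' `direction` is `up` iff `fold_change >= min_fc` and the policy-selected p
#' (adjusted or raw, by species) is below alpha; `down` symmetric; otherwise
#' `not_de`.
#'
#' @param stats output of [differential_test()] for one comparison.
#' @param policy a [threshold_policy()].
#' @param species species of the tested matrix.
#' @param comparison comparison label recorded in the calls.
#' @return data.frame of calls: feature_id, species, comparison, log2fc,
#'   fold_change, p_raw, p_adj, direction.
#' @export
call_de <- function(stats, policy = threshold_policy(), species,
                    comparison = "AvsCtrl") {
  species <- match.arg(species, RNA_SPECIES)
  p_adj <- adjust_bh(stats$p_raw)
  p_gate <- if (policy$p_mode[[species]] == "adjusted") p_adj else stats$p_raw
  thr <- policy$min_fc[[species]]
  direction <- rep("not_de", nrow(stats))
  direction[stats$fold_change >= thr & p_gate < policy$alpha] <- "up"
  direction[stats$fold_change <= -thr & p_gate < policy$alpha] <- "down"
  data.frame(
    feature_id = stats$feature_id, species = species, comparison = comparison,
    log2fc = stats$log2fc, fold_change = stats$fold_change,
    p_raw = stats$p_raw, p_adj = p_adj, direction = direction,
    stringsAsFactors = FALSE
  )
}

#' Direction-consistent intersection of two comparisons' DE calls
#'
#' A feature enters the merged group iff it is differential in both
#' comparisons with the same direction; conflicting directions are excluded.
#' Merged log2fc/p columns carry the first comparison's values for reference.
#'
#' @param calls_a,calls_b [call_de()] outputs for the same species.
#' @return merged call data.frame (`comparison = "merged"`).
#' @export
merge_comparisons <- function(calls_a, calls_b) {
  if (!identical(unique(calls_a$species), unique(calls_b$species))) {
    stop("species mismatch between call sets")
  }
  a <- calls_a[calls_a$direction != "not_de", ]
  b <- calls_b[calls_b$direction != "not_de", ]
  key_b <- setNames(b$direction, b$feature_id)
  keep <- a$feature_id %in% b$feature_id &
    a$direction == key_b[a$feature_id]
  out <- a[keep, , drop = FALSE]
  out$comparison <- rep("merged", nrow(out))
  rownames(out) <- NULL
  out
}

#' Run normalisation and DE calling for every species and comparison
#'
#' Convenience wrapper: tests the two resistant conditions against the
#' reference for each species, calls DE under the policy, and forms the
#' merged (direction-consistent intersection) group. Input matrices are
#' expected to carry platform-normalised log2 intensities; set
#' `normalize = TRUE` to quantile-normalise unnormalised input first (note
#' that re-normalising panels in which a large fraction of features truly
#' changes biases effect estimates, the usual caveat of quantile
#' normalisation).
#'
#' @param expression named list of four [expression_matrix()] objects.
#' @param conditions ordered condition labels (reference first).
#' @param policy a [threshold_policy()].
#' @param normalize quantile-normalise before testing (default FALSE).
#' @param var_equal pooled (TRUE) or Welch (FALSE) t-test.
#' @return list: `calls` (species -> comparison -> call data.frame) and
#'   `de_sets` (species -> comparison -> data.frame feature_id, direction of
#'   DE features only).
#' @export
run_de_analysis <- function(expression, conditions, policy = threshold_policy(),
                            normalize = FALSE, var_equal = TRUE) {
  ctrl <- conditions[1]
  comps <- list(AvsCtrl = conditions[2], BvsCtrl = conditions[3])
  calls <- lapply(RNA_SPECIES, function(sp) {
    mat <- expression[[sp]]
    if (normalize) mat <- quantile_normalize(mat)
    per_comp <- lapply(names(comps), function(cmp) {
      st <- differential_test(mat, ctrl, comps[[cmp]], var_equal = var_equal)
      call_de(st, policy, sp, cmp)
    })
    names(per_comp) <- names(comps)
    per_comp$merged <- merge_comparisons(per_comp$AvsCtrl, per_comp$BvsCtrl)
    per_comp
  })
  names(calls) <- RNA_SPECIES
  de_sets <- lapply(calls, function(per_comp) {
    lapply(per_comp, function(cl) {
      de <- cl[cl$direction != "not_de", c("feature_id", "direction")]
      rownames(de) <- NULL
      de
    })
  })
  list(calls = calls, de_sets = de_sets)
}
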