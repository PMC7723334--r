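#' Expression matrix for one RNA species
#'
#' Lightweight container holding a features x samples matrix of log2
#' intensities together with the species label and the sample-to-condition
#' map. All downstream stages (normalisation, differential testing,
#' correlation networks) operate on this container.
#'
#' @param values numeric matrix, features in rows (rownames = feature ids),
#'   samples in columns (colnames = sample ids). Log2 scale.
#' @param species one of `"lncRNA"`, `"circRNA"`, `"miRNA"`, `"mRNA"`.
#' @param condition_of named character vector mapping every sample id to a
#'   condition label.
#' @return an object of class `expr_matrix`.
#' @export
expression_matrix <- function(values, species, condition_of) {
  species <- match.arg(species, RNA_SPECIES)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values needs feature ids as rownames and sample ids as colnames")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate feature ids")
  if (anyDuplicated(colnames(values))) stop("duplicate sample ids")
  if (anyNA(values)) stop("missing values are not allowed")
  missing <- setdiff(colnames(values), names(condition_of))
  if (length(missing)) {
    stop("samples without a condition label: ", paste(missing, collapse = ", "))
  }
  condition_of <- condition_of[colnames(values)]
  reps <- table(condition_of)
  if (any(reps < 2L)) {
    stop("every condition needs >= 2 replicates; offending: ",
         paste(names(reps)[reps < 2L], collapse = ", "))
  }
  structure(
    list(values = values, species = species, condition_of = condition_of),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %s: %d features x %d samples (%s)\n",
    x$species, nrow(x$values), ncol(x$values),
    paste(sprintf("%s n=%d", names(table(x$condition_of)),
                  as.integer(table(x$condition_of))), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix to a set of samples
#'
#' @param mat an [expression_matrix()].
#' @param samples sample ids to keep (order preserved).
#' @return an `expr_matrix` restricted to `samples`.
#' @export
subset_samples <- function(mat, samples) {
  stopifnot(inherits(mat, "expr_matrix"))
  missing <- setdiff(samples, colnames(mat$values))
  if (length(missing)) stop("unknown samples: ", paste(missing, collapse = ", "))
  expression_matrix(mat$values[, samples, drop = FALSE], mat$species,
                    mat$condition_of[samples])
}

#' Samples belonging to a set of conditions
#'
#' @param mat an [expression_matrix()].
#' @param conditions condition labels.
#' @return character vector of sample ids, in matrix column order.
#' @export
samples_of <- function(mat, conditions) {
  stopifnot(inherits(mat, "expr_matrix"))
  colnames(mat$values)[mat$condition_of %in% conditions]
}

#' Write an expression matrix as TSV
#'
#' First column `feature_id`, remaining columns one per sample, values log2
#' intensities. The condition map is not stored in the TSV; it travels in the
#' dataset's sample sheet.
#'
#' @param mat an [expression_matrix()].
#' @param path output file.
#' @export
write_expression_tsv <- function(mat, path) {
  stopifnot(inherits(mat, "expr_matrix"))
  df <- data.frame(feature_id = rownames(mat$values), mat$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV written by [write_expression_tsv()]
#'
#' @param path TSV file.
#' @param species species label for the matrix.
#' @param condition_of named character vector, sample id -> condition.
#' @return an `expr_matrix`.
#' @export
read_expression_tsv <- function(path, species, condition_of) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "feature_id") stop("expected first column 'feature_id'")
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$feature_id
  expression_matrix(values, species, condition_of)
}
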