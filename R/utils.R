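#' @importFrom stats cor median na.omit p.adjust pf phyper prcomp pt rnorm
#'   runif sd setNames var hclust dist as.dendrogram
#' @importFrom utils read.delim write.table head
NULL

RNA_SPECIES <- c("lncRNA", "circRNA", "miRNA", "mRNA")

#' Reverse complement of a DNA/RNA character string
#'
#' U is accepted on input and normalised to T; output is always DNA alphabet.
#'
#' @param x single character string over A/C/G/T/U/N.
#' @return reverse complement as a character string (DNA alphabet).
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(rna_to_dna(x))))
}

# U -> T, uppercase; errors on anything outside A/C/G/T/U/N
rna_to_dna <- function(x) {
  x <- toupper(x)
  x <- chartr("U", "T", x)
  if (grepl("[^ACGTN]", x)) {
    stop("invalid sequence alphabet (expected A/C/G/T/U/N): ",
         substr(gsub("[ACGTN]", "", x), 1L, 10L))
  }
  x
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
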