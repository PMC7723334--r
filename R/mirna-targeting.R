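# Canonical-seed miRNA target-site scanner. This is the package's declared,
# transparent replacement for an alignment/energy-based target predictor:
# sites are classified by Watson-Crick complementarity to miRNA seed
# positions 2-8 (8mer > 7mer-m8 > 7mer-A1 > 6mer), with no thermodynamic
# scoring. The DNA alphabet is used internally (U normalised to T).
#
# Site semantics: every occurrence of the 6mer core (reverse complement of
# miRNA positions 2-7) anchors at most one site, reported at its highest
# class. If the position 5' of the core matches the complement of miRNA
# position 8 the site extends to 7mer-m8/8mer; an A opposite miRNA position 1
# (immediately 3' of the seed match) upgrades to 7mer-A1 or 8mer.

SITE_CLASSES <- c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)

#' Seed of a miRNA (positions 2-8, 5'->3')
#'
#' @param mirna_sequence miRNA sequence, length >= 8, alphabet ACGU/ACGT.
#' @return the 7-mer seed as a DNA string (U normalised to T).
#' @export
seed_of <- function(mirna_sequence) {
  s <- rna_to_dna(mirna_sequence)
  if (nchar(s) < 8L) stop("miRNA must be at least 8 nt")
  substr(s, 2L, 8L)
}

#' Find canonical seed-match sites of one miRNA in one target sequence
#'
#' Scans the target 5'->3' for reverse-complement matches to the seed:
#' 8mer (positions 2-8 matched, plus A opposite position 1), 7mer-m8
#' (positions 2-8), 7mer-A1 (positions 2-7 plus A), 6mer (positions 2-7).
#' A window matching several patterns is reported once, at its highest
#' class. Scores are the class weights 4/3/2/1.
#'
#' @param mirna_sequence miRNA sequence (>= 8 nt).
#' @param target_sequence target sequence (>= 6 nt).
#' @return data.frame: start (0-based), end (half-open), site_class, score.
#' @export
find_seed_sites <- function(mirna_sequence, target_sequence) {
  m <- rna_to_dna(mirna_sequence)
  target <- rna_to_dna(target_sequence)
  if (nchar(m) < 8L) stop("miRNA must be at least 8 nt")
  empty <- data.frame(start = integer(0), end = integer(0),
                      site_class = character(0), score = numeric(0),
                      stringsAsFactors = FALSE)
  if (nchar(target) < 6L) return(empty)
  core6 <- revcomp(substr(m, 2L, 7L))          # matches miRNA positions 2-7
  m8c <- revcomp(substr(m, 8L, 8L))            # complement of position 8
  hits <- Biostrings::matchPattern(core6, Biostrings::DNAString(target))
  if (!length(hits)) return(empty)
  starts1 <- Biostrings::start(hits)           # 1-based start of the 6mer core
  tlen <- nchar(target)
  rows <- lapply(starts1, function(j) {
    has_m8 <- j > 1L && substr(target, j - 1L, j - 1L) == m8c
    if (has_m8) {
      a_pos <- j + 6L
      has_a <- a_pos <= tlen && substr(target, a_pos, a_pos) == "A"
      cls <- if (has_a) "8mer" else "7mer-m8"
      start0 <- j - 2L
      end0 <- start0 + (if (has_a) 8L else 7L)
    } else {
      a_pos <- j + 6L
      has_a <- a_pos <= tlen && substr(target, a_pos, a_pos) == "A"
      cls <- if (has_a) "7mer-A1" else "6mer"
      start0 <- j - 1L
      end0 <- start0 + (if (has_a) 7L else 6L)
    }
    data.frame(start = start0, end = end0, site_class = cls,
               score = unname(SITE_CLASSES[cls]), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict miRNA targets across a set of transcripts
#'
#' Retains (miRNA, transcript) pairs with at least one site of class >=
#' `min_class`. Output ordering is deterministic (miRNA, then transcript id)
#' and independent of input ordering.
#'
#' @param mirna_seqs named character vector of miRNA sequences.
#' @param transcript_seqs named character vector of target sequences (mRNA
#'   3'UTRs, lncRNA or circRNA bodies).
#' @param min_class minimum site class (default `"7mer-A1"`).
#' @return data.frame: mirna_id, transcript_id, start, end, site_class,
#'   score — one row per retained site.
#' @export
predict_targets <- function(mirna_seqs, transcript_seqs,
                            min_class = c("7mer-A1", "6mer", "7mer-m8", "8mer")) {
  min_class <- match.arg(min_class)
  min_score <- SITE_CLASSES[[min_class]]
  if (is.null(names(mirna_seqs)) || is.null(names(transcript_seqs))) {
    stop("sequences must be named")
  }
  mids <- sort(names(mirna_seqs))
  tids <- sort(names(transcript_seqs))
  rows <- list()
  for (mid in mids) {
    for (tid in tids) {
      sites <- find_seed_sites(mirna_seqs[[mid]], transcript_seqs[[tid]])
      sites <- sites[sites$score >= min_score, , drop = FALSE]
      if (nrow(sites)) {
        rows[[length(rows) + 1L]] <- cbind(
          data.frame(mirna_id = mid, transcript_id = tid,
                     stringsAsFactors = FALSE),
          sites)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      site_class = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
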