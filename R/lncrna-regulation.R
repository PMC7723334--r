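# Cis target prediction by genomic proximity (10 kb window) with positional
# classification, trans prediction by lncRNA-vs-3'UTR local sequence
# similarity, and promoter-window transcription-factor motif scanning.
# Coordinates are 0-based half-open throughout; TSS is start for + features
# and end-1 for - features.

#' Classify the cis relation between a lncRNA and a protein-coding gene
#'
#' Precedence: intronic (lncRNA wholly inside a gene intron, either strand) >
#' sense (overlap, same strand) > antisense (overlap, opposite strand) >
#' divergent (no overlap, opposite strands, head-to-head, TSS-to-TSS gap <=
#' `divergent_gap`) > neighbor (no overlap, gap <= `window`); otherwise NULL.
#' "Divergent" covers what is elsewhere called bidirectional (head-to-head)
#' promoter arrangement.
#'
#' @param lnc,gene lists/rows with chrom, start, end (0-based half-open),
#'   strand.
#' @param introns data.frame of the gene's introns (columns start, end), or
#'   NULL.
#' @param window maximum gap in bp (default 10000).
#' @param divergent_gap maximum TSS-to-TSS distance for the divergent class.
#' @return list with `category` and `distance` (0 if overlapping), or NULL if
#'   no relation within the window.
#' @export
classify_cis_relation <- function(lnc, gene, introns = NULL, window = 10000,
                                  divergent_gap = 1000) {
  stopifnot(lnc$start < lnc$end, gene$start < gene$end)
  if (lnc$chrom != gene$chrom) return(NULL)
  tss <- function(f) if (f$strand == "+") f$start else f$end - 1L
  overlap <- lnc$start < gene$end && gene$start < lnc$end
  if (!is.null(introns) && nrow(introns)) {
    inside <- any(lnc$start >= introns$start & lnc$end <= introns$end)
    if (inside) return(list(category = "intronic", distance = 0L))
  }
  if (overlap) {
    cat <- if (lnc$strand == gene$strand) "sense" else "antisense"
    return(list(category = cat, distance = 0L))
  }
  gap <- if (lnc$end <= gene$start) gene$start - lnc$end else lnc$start - gene$end
  if (lnc$strand != gene$strand) {
    head_to_head <- if (lnc$end <= gene$start) {
      lnc$strand == "-" && gene$strand == "+"
    } else {
      lnc$strand == "+" && gene$strand == "-"
    }
    if (head_to_head && abs(tss(lnc) - tss(gene)) <= divergent_gap) {
      return(list(category = "divergent", distance = as.integer(gap)))
    }
  }
  if (gap <= window) return(list(category = "neighbor", distance = as.integer(gap)))
  NULL
}

#' Find cis lncRNA-gene pairs by proximity plus co-expression
#'
#' Candidate pairs are lncRNA-gene pairs on the same chromosome within the
#' window, classified by [classify_cis_relation()], then filtered by
#' positive Pearson r >= `min_r` and Holm-adjusted correlation p <
#' `holm_alpha` across the whole candidate-pair family. The permissive Holm
#' threshold of 0.5 is the convention this pipeline follows for cis/trans
#' correlation filtering; it is a default, not hard-coded.
#'
#' @param lnc_features,gene_features annotation data.frames (id, chrom,
#'   start, end, strand).
#' @param introns intron data.frame (gene_id, start, end).
#' @param lnc_expr,gene_expr [expression_matrix()] objects.
#' @param window proximity window, bp (default 10000).
#' @param min_r minimum Pearson r (positive; default 0.99).
#' @param holm_alpha Holm-adjusted p threshold (default 0.5).
#' @param samples optional sample ids over which to correlate.
#' @return data.frame: lncrna_id, gene_id, category, distance, r, p_holm.
#' @export
find_cis_pairs <- function(lnc_features, gene_features, introns,
                           lnc_expr, gene_expr, window = 10000,
                           min_r = 0.99, holm_alpha = 0.5, samples = NULL) {
  shared <- intersect(colnames(lnc_expr$values), colnames(gene_expr$values))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  rows <- list()
  for (i in seq_len(nrow(lnc_features))) {
    lnc <- as.list(lnc_features[i, ])
    if (!lnc$id %in% rownames(lnc_expr$values)) next
    near <- gene_features[gene_features$chrom == lnc$chrom &
                            gene_features$start < lnc$end + window &
                            gene_features$end > lnc$start - window, , drop = FALSE]
    for (j in seq_len(nrow(near))) {
      gene <- as.list(near[j, ])
      if (!gene$id %in% rownames(gene_expr$values)) next
      rel <- classify_cis_relation(
        lnc, gene, introns[introns$gene_id == gene$id, , drop = FALSE], window)
      if (is.null(rel)) next
      x <- lnc_expr$values[lnc$id, shared]
      y <- gene_expr$values[gene$id, shared]
      if (sd(x) == 0 || sd(y) == 0) next
      cp <- pearson_with_p(x, y)
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = lnc$id, gene_id = gene$id, category = rel$category,
        distance = rel$distance, r = cp$r, p = cp$p, stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(lncrna_id = character(0), gene_id = character(0),
                      category = character(0), distance = integer(0),
                      r = numeric(0), p_holm = numeric(0), stringsAsFactors = FALSE)
  if (!length(rows)) return(empty)
  cand <- do.call(rbind, rows)
  cand$p_holm <- adjust_holm(cand$p)
  keep <- cand$r >= min_r & cand$p_holm < holm_alpha
  out <- cand[keep, c("lncrna_id", "gene_id", "category", "distance", "r", "p_holm")]
  out <- out[order(out$lncrna_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Optimal local (Smith-Waterman) alignment of two sequences
#'
#' Linear gap penalty; default scores match +1, mismatch -1, gap -2.
#'
#' @param seq_a,seq_b DNA sequences (U normalised to T).
#' @param match,mismatch,gap alignment scores.
#' @return list: score, a_start/a_end and b_start/b_end (0-based half-open
#'   coordinates of the aligned regions; 0-width when no positive-scoring
#'   alignment exists), length (alignment columns), identity (matched
#'   columns / alignment columns; 0 for the empty alignment).
#' @export
local_align <- function(seq_a, seq_b, match = 1, mismatch = -1, gap = -2) {
  a <- rna_to_dna(seq_a); b <- rna_to_dna(seq_b)
  if (!nchar(a) || !nchar(b)) stop("sequences must be non-empty")
  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                      mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = sub_mat, gapOpening = 0, gapExtension = -gap)
  sc <- Biostrings::score(aln)
  if (sc <= 0) {
    return(list(score = 0, a_start = 0L, a_end = 0L, b_start = 0L, b_end = 0L,
                length = 0L, identity = 0, a_aligned = "", b_aligned = ""))
  }
  pr <- aln@pattern@range
  sr <- aln@subject@range
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  len <- nchar(pa)
  list(score = sc,
       a_start = Biostrings::start(pr) - 1L, a_end = Biostrings::end(pr),
       b_start = Biostrings::start(sr) - 1L, b_end = Biostrings::end(sr),
       length = len,
       identity = Biostrings::nmatch(aln) / len,
       a_aligned = pa, b_aligned = pb)
}

# Best-scoring contiguous column window of an alignment that satisfies the
# length and identity gates; the optimal local alignment can dilute an exact
# core with low-identity extensions, so hits are gated on this refined
# segment rather than on the full alignment.
best_identity_segment <- function(pa, pb, min_len, min_identity,
                                  match = 1, mismatch = -1, gap = -2) {
  a <- strsplit(pa, "")[[1]]
  b <- strsplit(pb, "")[[1]]
  n <- length(a)
  if (n < min_len) return(NULL)
  is_gap <- a == "-" | b == "-"
  is_match <- !is_gap & a == b
  col_score <- ifelse(is_gap, gap, ifelse(is_match, match, mismatch))
  cm <- cumsum(c(0, is_match))
  cs <- cumsum(c(0, col_score))
  best <- NULL
  for (i in seq_len(n - min_len + 1L)) {
    js <- (i + min_len - 1L):n
    len <- js - i + 1L
    idy <- (cm[js + 1L] - cm[i]) / len
    sc <- cs[js + 1L] - cs[i]
    ok <- idy >= min_identity
    if (!any(ok)) next
    k <- which(ok)[order(-sc[ok], -len[ok])[1]]
    cand <- list(start_col = i, end_col = js[k], score = sc[k],
                 length = len[k], identity = idy[k])
    if (is.null(best) || cand$score > best$score ||
        (cand$score == best$score && cand$length > best$length)) {
      best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  best$a_offset <- sum(a[seq_len(best$start_col - 1L)] != "-")
  best$b_offset <- sum(b[seq_len(best$start_col - 1L)] != "-")
  best
}

#' Trans lncRNA target prediction by sequence similarity to 3'UTRs
#'
#' Candidate pairs are restricted to co-expressed (edge-connected) lncRNA-
#' mRNA pairs; a hit requires, within the optimal local alignment of the
#' lncRNA full sequence against the mRNA 3'UTR, a contiguous segment of
#' length >= `min_len` with identity >= `min_identity` (same-strand
#' similarity, consistent with a miRNA-sequestration mechanism). The
#' best-scoring such segment is reported.
#'
#' @param lnc_seqs,utr_seqs named character vectors.
#' @param edges lncRNA-mRNA co-expression edges ([build_pair_network()]).
#' @param min_len minimum alignment length (default 20).
#' @param min_identity minimum identity fraction (default 0.9).
#' @return data.frame: lncrna_id, mrna_id, lnc_start, utr_start, length,
#'   identity, score.
#' @export
predict_trans_targets <- function(lnc_seqs, utr_seqs, edges,
                                  min_len = 20, min_identity = 0.9) {
  rows <- list()
  for (i in seq_len(nrow(edges))) {
    lid <- edges$node_a[i]; mid <- edges$node_b[i]
    if (!lid %in% names(lnc_seqs)) stop("missing lncRNA sequence: ", lid)
    if (!mid %in% names(utr_seqs)) stop("missing 3'UTR sequence: ", mid)
    aln <- local_align(lnc_seqs[[lid]], utr_seqs[[mid]])
    if (aln$length < min_len) next
    seg <- best_identity_segment(aln$a_aligned, aln$b_aligned,
                                 min_len, min_identity)
    if (!is.null(seg)) {
      rows[[length(rows) + 1L]] <- data.frame(
        lncrna_id = lid, mrna_id = mid,
        lnc_start = aln$a_start + seg$a_offset,
        utr_start = aln$b_start + seg$b_offset,
        length = seg$length, identity = seg$identity,
        score = seg$score, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(lncrna_id = character(0), mrna_id = character(0),
                      lnc_start = integer(0), utr_start = integer(0),
                      length = integer(0), identity = numeric(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# genomic interval [ws, we) of the promoter window, unclipped
promoter_interval <- function(start, end, strand, upstream = 2000, downstream = 500) {
  if (strand == "+") {
    tss <- start
    c(tss - upstream, tss + downstream)
  } else {
    tss <- end - 1L
    c(tss - downstream, tss + upstream)
  }
}

#' Extract the promoter window of a feature
#'
#' Strand-aware window from `upstream` bp upstream to `downstream` bp
#' downstream of the TSS, reported 5'->3' on the feature's strand (reverse
#' complemented for minus-strand features) and clipped at chromosome ends.
#'
#' @param feature list/row with chrom, start, end, strand.
#' @param chrom_seqs named character vector of chromosome sequences.
#' @param upstream,downstream window extent in bp (defaults 2000 and 500).
#' @return list: sequence, start, end (genomic, clipped), clipped flag.
#' @export
extract_promoter_window <- function(feature, chrom_seqs,
                                    upstream = 2000, downstream = 500) {
  if (!feature$chrom %in% names(chrom_seqs)) {
    stop("chromosome absent from sequence store: ", feature$chrom)
  }
  chrom <- chrom_seqs[[feature$chrom]]
  w <- promoter_interval(feature$start, feature$end, feature$strand,
                         upstream, downstream)
  ws <- max(0L, w[1]); we <- min(nchar(chrom), w[2])
  seq <- strand_sub(chrom, ws, we, feature$strand)
  list(sequence = seq, start = as.integer(ws), end = as.integer(we),
       clipped = ws != w[1] || we != w[2])
}

#' Position weight matrix
#'
#' Counts are smoothed with a +1 pseudocount and converted to per-position
#' base probabilities; each column of `probs` sums to 1.
#'
#' @param id motif identifier.
#' @param counts 4 x L numeric matrix, rows A/C/G/T.
#' @param background base frequencies (named A/C/G/T).
#' @return a `pwm` object.
#' @export
pwm <- function(id, counts, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(nrow(counts) == 4L)
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  if (ncol(counts) < 4L) stop("motif length must be >= 4")
  storage.mode(counts) <- "double"
  colnames(counts) <- NULL
  sm <- counts + 1
  probs <- sweep(sm, 2, colSums(sm), "/")
  structure(list(id = id, counts = counts, probs = probs,
                 background = background[c("A", "C", "G", "T")]),
            class = "pwm")
}

#' Scan a sequence with a PWM on both strands
#'
#' Per-position score is the summed log2 odds `log2(p_base / bg_base)`; hits
#' are positions where the score reaches `threshold` times the maximum
#' attainable score. Minus-strand hits are reported at their leftmost
#' position on the given (forward) sequence.
#'
#' @param window sequence to scan (length >= motif length).
#' @param p a [pwm()].
#' @param threshold fraction of the maximum attainable score (default 0.8).
#' @return data.frame: offset (0-based), strand, score.
#' @export
scan_pwm <- function(window, p, threshold = 0.8) {
  stopifnot(inherits(p, "pwm"))
  w <- rna_to_dna(window)
  L <- ncol(p$probs)
  if (nchar(w) < L) stop("window shorter than motif")
  lo <- log2(sweep(p$probs, 1, p$background, "/"))
  max_score <- sum(apply(lo, 2, max))
  cutoff <- threshold * max_score
  scan_one <- function(s) {
    chars <- strsplit(s, "")[[1]]
    # N scores as the background (log-odds 0)
    idx <- match(chars, c("A", "C", "G", "T"))
    n <- length(chars) - L + 1L
    sc <- numeric(n)
    for (k in seq_len(L)) {
      v <- lo[, k][idx[k:(k + n - 1L)]]
      v[is.na(v)] <- 0
      sc <- sc + v
    }
    sc
  }
  fwd <- scan_one(w)
  rev <- scan_one(revcomp(w))
  n <- nchar(w)
  fi <- which(fwd >= cutoff); ri <- which(rev >= cutoff)
  hits <- rbind(
    data.frame(offset = fi - 1L, strand = rep("+", length(fi)),
               score = fwd[fi], stringsAsFactors = FALSE),
    data.frame(offset = n - L - (ri - 1L), strand = rep("-", length(ri)),
               score = rev[ri], stringsAsFactors = FALSE)
  )
  hits <- hits[order(hits$offset, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Bipartite lncRNA-transcription factor network from promoter motif hits
#'
#' An edge (lncRNA, TF) is created iff the TF's PWM has at least one hit in
#' the lncRNA's promoter window; a TF's degree is its number of connected
#' lncRNAs.
#'
#' @param lnc_features annotation data.frame of lncRNAs.
#' @param pwms named list of [pwm()] objects.
#' @param chrom_seqs named character vector of chromosome sequences.
#' @param threshold [scan_pwm()] threshold.
#' @param upstream,downstream promoter window extent.
#' @return list: `edges` (lncrna_id, motif_id, n_hits, best_score) and
#'   `tf_degree` (named, decreasing, ties lexical).
#' @export
build_tf_network <- function(lnc_features, pwms, chrom_seqs, threshold = 0.8,
                             upstream = 2000, downstream = 500) {
  rows <- list()
  for (i in seq_len(nrow(lnc_features))) {
    f <- as.list(lnc_features[i, ])
    win <- extract_promoter_window(f, chrom_seqs, upstream, downstream)
    for (p in pwms) {
      if (nchar(win$sequence) < ncol(p$probs)) next
      hits <- scan_pwm(win$sequence, p, threshold)
      if (nrow(hits)) {
        rows[[length(rows) + 1L]] <- data.frame(
          lncrna_id = f$id, motif_id = p$id, n_hits = nrow(hits),
          best_score = max(hits$score), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    edges <- data.frame(lncrna_id = character(0), motif_id = character(0),
                        n_hits = integer(0), best_score = numeric(0),
                        stringsAsFactors = FALSE)
  } else {
    edges <- do.call(rbind, rows)
    edges <- edges[order(edges$lncrna_id, edges$motif_id), , drop = FALSE]
    rownames(edges) <- NULL
  }
  deg <- if (nrow(edges)) {
    d <- table(edges$motif_id)
    d <- setNames(as.integer(d), names(d))
    d[order(-d, names(d))]
  } else setNames(integer(0), character(0))
  list(edges = edges, tf_degree = deg)
}
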