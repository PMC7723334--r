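# Readers/writers for the dataset's on-disk formats. Annotation travels as
# GTF (1-based inclusive on disk, 0-based half-open internally), sequences as
# FASTA, gene sets as GMT, motifs as JASPAR-style count matrices, truth as
# JSON. Expression TSVs live in expression-matrix.R.

#' Write genomic annotation as GTF
#'
#' Internal coordinates are 0-based half-open; GTF records are 1-based
#' inclusive. Features are emitted as `transcript` lines; genes with introns
#' additionally get `exon` lines (the introns being the gaps between exons).
#'
#' @param features data.frame with columns id, chrom, start, end (0-based
#'   half-open integers), strand, biotype.
#' @param introns data.frame with columns gene_id, start, end (0-based
#'   half-open), or NULL.
#' @param path output GTF file.
#' @export
write_gtf <- function(features, introns = NULL, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L, end = features$end),
    strand = features$strand,
    type = "transcript",
    source = "cernet",
    gene_id = features$id,
    transcript_id = features$id,
    biotype = features$biotype
  )
  exon_gr <- NULL
  if (!is.null(introns) && nrow(introns)) {
    exons <- do.call(rbind, lapply(seq_len(nrow(introns)), function(i) {
      g <- features[features$id == introns$gene_id[i], ]
      data.frame(
        id = g$id, chrom = g$chrom, strand = g$strand, biotype = g$biotype,
        start = c(g$start, introns$end[i]),
        end = c(introns$start[i], g$end),
        stringsAsFactors = FALSE
      )
    }))
    exon_gr <- GenomicRanges::GRanges(
      seqnames = exons$chrom,
      ranges = IRanges::IRanges(start = exons$start + 1L, end = exons$end),
      strand = exons$strand,
      type = "exon",
      source = "cernet",
      gene_id = exons$id,
      transcript_id = exons$id,
      biotype = exons$biotype
    )
  }
  all_gr <- if (is.null(exon_gr)) gr else c(gr, exon_gr)
  rtracklayer::export(all_gr, path, format = "gtf")
  invisible(path)
}

#' Read a GTF into the internal 0-based annotation tables
#'
#' @param path GTF file.
#' @return list with `features` (id, chrom, start, end, strand, biotype;
#'   0-based half-open) and `introns` (gene_id, start, end), both data.frames.
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  tx <- gr[gr$type == "transcript"]
  features <- data.frame(
    id = tx$transcript_id,
    chrom = as.character(GenomicRanges::seqnames(tx)),
    start = GenomicRanges::start(tx) - 1L,
    end = GenomicRanges::end(tx),
    strand = as.character(GenomicRanges::strand(tx)),
    biotype = tx$biotype,
    stringsAsFactors = FALSE
  )
  ex <- gr[gr$type == "exon"]
  introns <- data.frame(gene_id = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  if (length(ex)) {
    by_gene <- split(ex, ex$transcript_id)
    rows <- lapply(names(by_gene), function(id) {
      e <- sort(by_gene[[id]])
      if (length(e) < 2L) return(NULL)
      data.frame(gene_id = id,
                 start = GenomicRanges::end(e)[-length(e)],
                 end = GenomicRanges::start(e)[-1L] - 1L,
                 stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) introns <- do.call(rbind, rows)
    introns <- introns[order(introns$gene_id, introns$start), , drop = FALSE]
    rownames(introns) <- NULL
  }
  list(features = features, introns = introns)
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output file.
#' @param as_rna if TRUE, write with U instead of T (miRNA convention).
#' @export
write_fasta <- function(seqs, path, as_rna = FALSE) {
  if (as_rna) {
    set <- Biostrings::RNAStringSet(chartr("T", "U", seqs))
  } else {
    set <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a FASTA into a named character vector (DNA alphabet, U normalised)
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- vapply(as.character(set), rna_to_dna, character(1))
  names(out) <- names(set)
  out
}

#' Write a gene-set collection as GMT
#'
#' One tab-delimited line per term: term id, description, member ids. The
#' description field carries `"<namespace>|<name>"` so the GO class
#' (BP/CC/MF) or pathway label survives the round trip.
#'
#' @param collection a [gene_set_collection()].
#' @param path output file.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection$terms), function(id) {
    t <- collection$terms[[id]]
    paste(c(id, paste0(t$namespace, "|", t$name), t$members), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT written by [write_gmt()]
#'
#' Descriptions of the form `"<namespace>|<name>"` are split back; plain
#' descriptions get namespace `"pathway"`.
#'
#' @param path GMT file.
#' @param background gene universe for the collection.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path, background) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  terms <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    desc <- parts[2]
    if (grepl("|", desc, fixed = TRUE)) {
      ns <- sub("\\|.*$", "", desc)
      nm <- sub("^[^|]*\\|", "", desc)
    } else {
      ns <- "pathway"
      nm <- desc
    }
    list(id = parts[1], name = nm, namespace = ns, members = parts[-(1:2)])
  })
  ids <- vapply(terms, `[[`, character(1), "id")
  terms <- lapply(terms, function(t) t[c("name", "namespace", "members")])
  names(terms) <- ids
  gene_set_collection(terms, background)
}

#' Write position weight matrices in JASPAR-like count format
#'
#' @param pwms list of [pwm()] objects.
#' @param path output file.
#' @export
write_pwm_file <- function(pwms, path) {
  lines <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$id, " ", p$id),
      vapply(c("A", "C", "G", "T"), function(b) {
        paste0(b, "  [ ", paste(sprintf("%4d", p$counts[b, ]), collapse = " "),
               " ]")
      }, character(1)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a JASPAR-like count matrix file
#'
#' Counts are converted to per-position base probabilities with a +1
#' pseudocount.
#'
#' @param path motif file.
#' @param background base frequencies (named A/C/G/T), default uniform.
#' @return named list of [pwm()] objects.
#' @export
read_pwm_file <- function(path, background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  headers <- grep("^>", lines)
  pwms <- lapply(seq_along(headers), function(i) {
    id <- sub("^>(\\S+).*$", "\\1", lines[headers[i]])
    block <- lines[(headers[i] + 1):(headers[i] + 4)]
    counts <- t(vapply(block, function(l) {
      nums <- gsub("^[ACGT]\\s*\\[|\\]\\s*$", "", l)
      as.numeric(strsplit(trimws(nums), "\\s+")[[1]])
    }, numeric(length(strsplit(trimws(gsub("^[ACGT]\\s*\\[|\\]\\s*$", "",
                                           block[1])), "\\s+")[[1]]))))
    rownames(counts) <- substr(block, 1, 1)
    counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
    pwm(id, counts, background)
  })
  names(pwms) <- vapply(pwms, `[[`, character(1), "id")
  pwms
}

#' Write the planted-truth object as JSON
#'
#' @param truth a `synthetic_truth` list (see [generate_dataset()]).
#' @param path output JSON file.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, dataframe = "columns",
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a truth JSON written by [write_truth_json()]
#'
#' @param path JSON file.
#' @return a `synthetic_truth` list.
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  canonical_truth(raw)
}
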