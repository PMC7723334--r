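# Sign-constrained ceRNA triplet assembly. A (sponge, miRNA, mRNA) triplet is
# licensed by: a positive sponge-mRNA co-expression edge; predicted seed
# sites of the miRNA in both the sponge and the mRNA 3'UTR; and negative
# miRNA-sponge and miRNA-mRNA correlation edges passing the same gate. The
# miRNA's own differential direction is recorded but not used as a gate.

#' Assemble ceRNA triplets from co-expression edges and target predictions
#'
#' @param sponge_mrna_edges edge data.frame (sponge vs mRNA) from
#'   [build_pair_network()]; only positive-sign edges are used.
#' @param mirna_sponge_edges negative-sign miRNA-sponge edge data.frame.
#' @param mirna_mrna_edges negative-sign miRNA-mRNA edge data.frame.
#' @param target_sites site table from [predict_targets()] covering both
#'   sponge and mRNA transcripts.
#' @return triplet data.frame, ordered by (sponge, miRNA, mRNA): sponge_id,
#'   sponge_species, mirna_id, mrna_id, sponge_mrna_r, mirna_sponge_r,
#'   mirna_mrna_r, n_sites_sponge, n_sites_mrna.
#' @export
assemble_triplets <- function(sponge_mrna_edges, mirna_sponge_edges,
                              mirna_mrna_edges, target_sites) {
  empty <- data.frame(sponge_id = character(0), sponge_species = character(0),
                      mirna_id = character(0), mrna_id = character(0),
                      sponge_mrna_r = numeric(0), mirna_sponge_r = numeric(0),
                      mirna_mrna_r = numeric(0), n_sites_sponge = integer(0),
                      n_sites_mrna = integer(0), stringsAsFactors = FALSE)
  sm <- sponge_mrna_edges[sponge_mrna_edges$sign == "positive", , drop = FALSE]
  ms <- mirna_sponge_edges[mirna_sponge_edges$sign == "negative", , drop = FALSE]
  mm <- mirna_mrna_edges[mirna_mrna_edges$sign == "negative", , drop = FALSE]
  if (!nrow(sm) || !nrow(ms) || !nrow(mm) || !nrow(target_sites)) return(empty)
  site_count <- function(mir, tx) {
    sum(target_sites$mirna_id == mir & target_sites$transcript_id == tx)
  }
  ms_key <- paste(ms$node_a, ms$node_b)
  mm_key <- paste(mm$node_a, mm$node_b)
  rows <- list()
  for (i in seq_len(nrow(sm))) {
    sponge <- sm$node_a[i]; mrna <- sm$node_b[i]
    mirs_sponge <- unique(target_sites$mirna_id[target_sites$transcript_id == sponge])
    mirs_mrna <- unique(target_sites$mirna_id[target_sites$transcript_id == mrna])
    shared <- intersect(mirs_sponge, mirs_mrna)
    for (mir in shared) {
      j <- match(paste(mir, sponge), ms_key)
      k <- match(paste(mir, mrna), mm_key)
      if (is.na(j) || is.na(k)) next
      rows[[length(rows) + 1L]] <- data.frame(
        sponge_id = sponge, sponge_species = sm$species_a[i],
        mirna_id = mir, mrna_id = mrna,
        sponge_mrna_r = sm$r[i], mirna_sponge_r = ms$r[j],
        mirna_mrna_r = mm$r[k],
        n_sites_sponge = site_count(mir, sponge),
        n_sites_mrna = site_count(mir, mrna),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$sponge_id, out$mirna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Degree summary of a triplet network
#'
#' Bipartite-projected degrees: a miRNA's degree is its number of distinct
#' sponge/mRNA partners; sponges and mRNAs count distinct partners likewise.
#' Rankings are deterministic (degree decreasing, ties lexical).
#'
#' @param triplets output of [assemble_triplets()].
#' @return list: `mirna_degree`, `node_degree` (named integer vectors).
#' @export
triplet_network_summary <- function(triplets) {
  if (!nrow(triplets)) {
    return(list(mirna_degree = setNames(integer(0), character(0)),
                node_degree = setNames(integer(0), character(0))))
  }
  mir_deg <- vapply(unique(triplets$mirna_id), function(m) {
    sub <- triplets[triplets$mirna_id == m, ]
    length(unique(c(sub$sponge_id, sub$mrna_id)))
  }, integer(1))
  others <- unique(c(triplets$sponge_id, triplets$mrna_id))
  node_deg <- vapply(others, function(x) {
    sub <- triplets[triplets$sponge_id == x | triplets$mrna_id == x, ]
    partners <- unique(c(sub$mirna_id,
                         sub$sponge_id[sub$mrna_id == x],
                         sub$mrna_id[sub$sponge_id == x]))
    length(setdiff(partners, x))
  }, integer(1))
  list(mirna_degree = mir_deg[order(-mir_deg, names(mir_deg))],
       node_degree = node_deg[order(-node_deg, names(node_deg))])
}

#' Export a triplet set or edge list for network viewers
#'
#' Formats: `tsv` (re-importable; [import_network()] reproduces the triplet
#' multiset), `sif` (one binary relation per line), `graphml` (via igraph,
#' schema-valid XML). SIF/GraphML decompose each triplet into its
#' sponge-mRNA, miRNA-sponge and miRNA-mRNA relations.
#'
#' @param x triplet data.frame from [assemble_triplets()] or an edge
#'   data.frame from [build_pair_network()].
#' @param path output file.
#' @param format `"tsv"`, `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(x, path, format = c("tsv", "sif", "graphml")) {
  format <- match.arg(format)
  is_triplet <- "mirna_id" %in% names(x)
  if (format == "tsv") {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    rel <- if (is_triplet) {
      rbind(
        data.frame(a = x$sponge_id, type = "sponges", b = x$mrna_id),
        data.frame(a = x$mirna_id, type = "targets", b = x$sponge_id),
        data.frame(a = x$mirna_id, type = "targets", b = x$mrna_id)
      )
    } else {
      data.frame(a = x$node_a, type = paste0("coexpr_", x$sign), b = x$node_b)
    }
    rel <- unique(rel)
    if (format == "sif") {
      writeLines(paste(rel$a, rel$type, rel$b, sep = "\t"), path)
    } else {
      g <- igraph::graph_from_data_frame(rel[, c("a", "b", "type")],
                                         directed = FALSE)
      igraph::write_graph(g, path, format = "graphml")
    }
  }
  invisible(path)
}

#' Re-import a TSV network written by [export_network()]
#'
#' @param path TSV file.
#' @return the triplet or edge data.frame.
#' @export
import_network <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
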