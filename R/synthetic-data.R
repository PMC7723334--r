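# Synthetic study generator. Emulates the structure of a three-cell-line
# (parental + two endocrine-resistant derivatives), three-replicate microarray
# study profiling four RNA species on a shared sample set, with planted ground
# truth for every downstream stage: differential features, near-perfectly
# correlated pairs, ceRNA triplets (sponge up, mRNA up, miRNA down, with seed
# sites planted in both sponge and 3'UTR), cis lncRNA-gene neighbours in each
# positional category, trans sequence similarity, and promoter motifs.

GENE_LEN <- 2000L       # mRNA gene span on the synthetic chromosome
GENE_EXON1 <- 500L      # exon 1 = [0, 500), intron = [500, 1500), exon 2 = rest
GENE_INTRON_END <- 1500L
LNC_LEN <- 400L
MIR_LEN <- 22L
CIRC_LEN <- 300L
UTR_LEN <- 300L
MOTIF_LEN <- 10L

#' Configuration for the synthetic study generator
#'
#' Defaults mirror the emulated design: three conditions (a parental line and
#' two resistant derivatives), three biological replicates each, four RNA
#' species on a shared sample set, condition effects of 2 log2 units against
#' replicate noise of 0.25 log2 units.
#'
#' @param n_features named integer vector of feature counts per species.
#' @param n_replicates replicates per condition (>= 2).
#' @param conditions ordered condition labels; the first is the reference,
#'   the second and third define the two comparisons.
#' @param de_fraction proportion of features planted as generic differential
#'   background, per species (recycled from a scalar). These are planted in
#'   addition to the structurally planted members (triplets, cis pairs,
#'   motif promoters, which are differential in both resistant conditions)
#'   and are split between shared and condition-specific responses
#'   (both/A-only/B-only at 2:1:1), so each resistant condition carries its
#'   own expression signature.
#' @param de_log2_effect planted condition effect, log2 units.
#' @param noise_sd replicate noise sd for ordinary features, log2 units.
#' @param latent_jitter_sd per-sample sd of the shared latent driver behind
#'   planted correlated pairs. Besides keeping within-pair r below 1, the
#'   jitter makes distinct planted units identifiable: members of different
#'   triplets share the same condition profile, and their cross-unit
#'   correlation is roughly `var_cond / (var_cond + jitter^2)`, which must
#'   sit clearly below the 0.99 edge gate while within-unit correlation
#'   stays above it.
#' @param pair_noise_sd private noise sd of latent-driven features; kept well
#'   below `latent_jitter_sd` so planted pairs reach Pearson r >= 0.99.
#' @param n_planted_triplets planted (sponge, miRNA, mRNA) ceRNA triplets;
#'   sponges alternate between lncRNA and circRNA.
#' @param n_planted_cis_pairs planted lncRNA-gene cis pairs, cycling through
#'   the five positional categories.
#' @param n_motifs number of transcription-factor motifs (PWMs) generated.
#' @param motif_sites number of lncRNA promoters each motif is planted in.
#' @param feature_spacing intergenic gap on the synthetic chromosome, bp.
#' @param seed master seed; fully determines the dataset.
#' @return a `sim_config` list.
#' @export
simulation_config <- function(n_features = c(lncRNA = 120L, circRNA = 100L,
                                             miRNA = 60L, mRNA = 200L),
                              n_replicates = 3L,
                              conditions = c("control", "resistantA", "resistantAB"),
                              de_fraction = 0.1,
                              de_log2_effect = 2.0,
                              noise_sd = 0.25,
                              latent_jitter_sd = 0.25,
                              pair_noise_sd = 0.04,
                              n_planted_triplets = 8L,
                              n_planted_cis_pairs = 10L,
                              n_motifs = 4L,
                              motif_sites = 3L,
                              feature_spacing = 12000L,
                              seed = 1L) {
  if (length(de_fraction) == 1L) {
    de_fraction <- setNames(rep(de_fraction, 4L), RNA_SPECIES)
  }
  cfg <- list(
    n_features = n_features[RNA_SPECIES], n_replicates = as.integer(n_replicates),
    conditions = conditions, de_fraction = de_fraction[RNA_SPECIES],
    de_log2_effect = de_log2_effect, noise_sd = noise_sd,
    latent_jitter_sd = latent_jitter_sd, pair_noise_sd = pair_noise_sd,
    n_planted_triplets = as.integer(n_planted_triplets),
    n_planted_cis_pairs = as.integer(n_planted_cis_pairs),
    n_motifs = as.integer(n_motifs), motif_sites = as.integer(motif_sites),
    feature_spacing = as.integer(feature_spacing), seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (anyNA(cfg$n_features) || any(cfg$n_features < 1L)) {
    stop("n_features must name all four species with positive counts")
  }
  if (cfg$n_replicates < 2L) stop("n_replicates must be >= 2")
  if (length(cfg$conditions) < 3L) stop("need at least 3 condition labels")
  if (any(cfg$de_fraction < 0) || any(cfg$de_fraction > 1) || anyNA(cfg$de_fraction)) {
    stop("de_fraction must lie in [0, 1]")
  }
  if (cfg$de_log2_effect <= 0 || cfg$noise_sd <= 0) {
    stop("de_log2_effect and noise_sd must be positive")
  }
  if (cfg$n_planted_triplets < 0L || cfg$n_planted_cis_pairs < 0L) {
    stop("planted structure counts must be >= 0")
  }
  n_lnc_special <- ceiling(cfg$n_planted_triplets / 2) + cfg$n_planted_cis_pairs +
    cfg$n_motifs * cfg$motif_sites
  if (n_lnc_special > cfg$n_features["lncRNA"]) {
    stop("not enough lncRNA features for the requested planted structure")
  }
  if (cfg$n_planted_triplets + cfg$n_planted_cis_pairs > cfg$n_features["mRNA"]) {
    stop("not enough mRNA features for the requested planted structure")
  }
  if (floor(cfg$n_planted_triplets / 2) > cfg$n_features["circRNA"]) {
    stop("not enough circRNA features for the requested planted triplets")
  }
  if (cfg$n_planted_triplets > cfg$n_features["miRNA"]) {
    stop("not enough miRNA features for the requested planted triplets")
  }
  invisible(cfg)
}

# Canonical empty/typed truth tables so JSON round trips compare equal.
canonical_truth <- function(x) {
  df <- function(d, cols) {
    if (is.null(d) || length(d) == 0L || (is.data.frame(d) && nrow(d) == 0L)) {
      d <- as.data.frame(setNames(rep(list(character(0)), length(cols)), names(cols)),
                         stringsAsFactors = FALSE)
      for (nm in names(cols)) if (cols[[nm]] == "integer") d[[nm]] <- integer(0)
      return(d)
    }
    d <- as.data.frame(d, stringsAsFactors = FALSE)
    for (nm in names(cols)) {
      d[[nm]] <- if (cols[[nm]] == "integer") as.integer(d[[nm]]) else as.character(d[[nm]])
    }
    rownames(d) <- NULL
    d[, names(cols), drop = FALSE]
  }
  de_cols <- c(feature_id = "character", direction = "character")
  planted_de <- lapply(c("AvsCtrl", "BvsCtrl", "merged"), function(cmp) {
    sp <- x$planted_de[[cmp]]
    out <- lapply(RNA_SPECIES, function(s) df(sp[[s]], de_cols))
    names(out) <- RNA_SPECIES
    out
  })
  names(planted_de) <- c("AvsCtrl", "BvsCtrl", "merged")
  structure(list(
    planted_de = planted_de,
    planted_pairs = df(x$planted_pairs, c(node_a = "character", species_a = "character",
                                          node_b = "character", species_b = "character",
                                          sign = "character")),
    planted_triplets = df(x$planted_triplets, c(sponge_id = "character",
                                                sponge_species = "character",
                                                mirna_id = "character",
                                                mrna_id = "character")),
    planted_cis = df(x$planted_cis, c(lncrna_id = "character", gene_id = "character",
                                      category = "character")),
    planted_motifs = df(x$planted_motifs, c(lncrna_id = "character",
                                            motif_id = "character",
                                            offset = "integer")),
    planted_trans = df(x$planted_trans, c(lncrna_id = "character", mrna_id = "character",
                                          length = "integer"))
  ), class = "synthetic_truth")
}

strand_sub <- function(genome, start0, end0, strand) {
  s <- substr(genome, start0 + 1L, end0)
  if (strand == "-") revcomp(s) else s
}

`strand_sub_write<-` <- function(genome, start0, strand, value) {
  if (strand == "-") value <- revcomp(value)
  substr(genome, start0 + 1L, start0 + nchar(value)) <- value
  genome
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Produces four expression matrices on a shared sample set, a single-
#' chromosome annotation with sequences, gene sets, motifs, and the
#' `synthetic_truth` object recording everything that was planted. Identical
#' `(config, seed)` yields identical output; the caller's RNG state is
#' restored on exit.
#'
#' Expression model: per-feature baseline `N(8, 1.5)` plus condition effect
#' (planted features only) plus Gaussian replicate noise, all on the log2
#' scale. Planted correlated pairs share a latent condition-driven profile
#' with small private noise so their sample Pearson r exceeds 0.99 without
#' being exactly 1. Values are rounded to 10 decimal places so the TSV
#' serialisation round-trips exactly.
#'
#' @param config a [simulation_config()].
#' @return list with elements `bundle` (expression, annotation, sequences,
#'   gene_sets, pwms, conditions, condition_of) and `truth`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }, add = TRUE)

  conds <- config$conditions[1:3]
  reps <- config$n_replicates
  sample_ids <- unlist(lapply(conds, function(cn) paste0(cn, "_r", seq_len(reps))))
  condition_of <- setNames(rep(conds, each = reps), sample_ids)
  n_samp <- length(sample_ids)
  in_cond <- function(which) as.numeric(condition_of %in% which)

  ids <- list(
    lncRNA = sprintf("lnc_%04d", seq_len(config$n_features["lncRNA"])),
    circRNA = sprintf("circ_%04d", seq_len(config$n_features["circRNA"])),
    miRNA = sprintf("mir_%04d", seq_len(config$n_features["miRNA"])),
    mRNA = sprintf("mrna_%04d", seq_len(config$n_features["mRNA"]))
  )

  ## ---- roles and planted DE (master seed) ----
  set.seed(config$seed)
  nt <- config$n_planted_triplets
  nc <- config$n_planted_cis_pairs
  n_lnc_sponge <- ceiling(nt / 2)
  sponge_species <- rep(c("lncRNA", "circRNA"), length.out = nt)
  lnc_sponges <- ids$lncRNA[seq_len(n_lnc_sponge)]
  circ_sponges <- ids$circRNA[seq_len(floor(nt / 2))]
  sponge_ids <- character(nt)
  sponge_ids[sponge_species == "lncRNA"] <- lnc_sponges
  sponge_ids[sponge_species == "circRNA"] <- circ_sponges
  triplet_mirs <- ids$miRNA[seq_len(nt)]
  triplet_mrnas <- ids$mRNA[seq_len(nt)]
  cis_lncs <- ids$lncRNA[n_lnc_sponge + seq_len(nc)]
  cis_genes <- ids$mRNA[nt + seq_len(nc)]
  cis_categories <- rep(c("sense", "antisense", "intronic", "divergent", "neighbor"),
                        length.out = nc)
  cis_dirs <- rep(c("up", "down"), length.out = nc)
  motif_lncs <- ids$lncRNA[n_lnc_sponge + nc +
                             seq_len(config$n_motifs * config$motif_sites)]

  # per-species planted DE table: feature_id, direction, group (both/Aonly/Bonly)
  de_tab <- list()
  for (sp in RNA_SPECIES) {
    special <- switch(sp,
      lncRNA = data.frame(feature_id = c(lnc_sponges, cis_lncs, motif_lncs),
                          direction = c(rep("up", length(lnc_sponges)), cis_dirs,
                                        rep(c("up", "down"),
                                            length.out = length(motif_lncs))),
                          stringsAsFactors = FALSE),
      circRNA = data.frame(feature_id = circ_sponges,
                           direction = rep("up", length(circ_sponges)),
                           stringsAsFactors = FALSE),
      miRNA = data.frame(feature_id = triplet_mirs,
                         direction = rep("down", length(triplet_mirs)),
                         stringsAsFactors = FALSE),
      mRNA = data.frame(feature_id = c(triplet_mrnas, cis_genes),
                        direction = c(rep("up", length(triplet_mrnas)), cis_dirs),
                        stringsAsFactors = FALSE)
    )
    if (nrow(special)) special$group <- "both"
    extra_n <- round(config$de_fraction[[sp]] * config$n_features[[sp]])
    pool <- setdiff(ids[[sp]], special$feature_id)
    extra <- data.frame(feature_id = character(0), direction = character(0),
                        group = character(0), stringsAsFactors = FALSE)
    if (extra_n > 0L && length(pool)) {
      picked <- sample(pool, min(extra_n, length(pool)))
      extra <- data.frame(
        feature_id = picked,
        direction = sample(c("up", "down"), length(picked), replace = TRUE),
        group = sample(c("both", "Aonly", "Bonly"), length(picked),
                       replace = TRUE, prob = c(0.5, 0.25, 0.25)),
        stringsAsFactors = FALSE
      )
    }
    de_tab[[sp]] <- rbind(special, extra)
  }

  ## ---- latent drivers for planted correlated structure ----
  set.seed(config$seed + 257L)
  eff <- config$de_log2_effect
  resistant <- conds[2:3]
  latent <- function() eff * in_cond(resistant) +
    rnorm(n_samp, 0, config$latent_jitter_sd)
  z_trip <- if (nt > 0) replicate(nt, latent(), simplify = FALSE) else list()
  z_cis <- if (nc > 0) replicate(nc, latent(), simplify = FALSE) else list()

  ## ---- expression per species (child seeds by fixed offsets) ----
  sp_offset <- c(lncRNA = 301L, circRNA = 302L, miRNA = 303L, mRNA = 304L)
  expr <- list()
  for (sp in RNA_SPECIES) {
    set.seed(config$seed + sp_offset[[sp]])
    n <- config$n_features[[sp]]
    base <- rnorm(n, 8, 1.5)
    vals <- matrix(rnorm(n * n_samp, 0, config$noise_sd), n, n_samp) + base
    rownames(vals) <- ids[[sp]]
    colnames(vals) <- sample_ids
    tab <- de_tab[[sp]]
    latent_ids <- c(sponge_ids, triplet_mirs, triplet_mrnas, cis_lncs, cis_genes)
    for (i in seq_len(nrow(tab))) {
      fid <- tab$feature_id[i]
      if (fid %in% latent_ids) next  # handled below with shared drivers
      affected <- switch(tab$group[i], both = resistant,
                         Aonly = conds[2], Bonly = conds[3])
      sgn <- if (tab$direction[i] == "up") 1 else -1
      vals[fid, ] <- vals[fid, ] + sgn * eff * in_cond(affected)
    }
    expr[[sp]] <- vals
  }
  # overwrite latent-driven rows (shared across species matrices)
  set.seed(config$seed + 401L)
  priv <- function() rnorm(n_samp, 0, config$pair_noise_sd)
  for (t in seq_len(nt)) {
    sp <- sponge_species[t]
    expr[[sp]][sponge_ids[t], ] <- rnorm(1, 8, 1.5) + z_trip[[t]] + priv()
    expr$mRNA[triplet_mrnas[t], ] <- rnorm(1, 8, 1.5) + z_trip[[t]] + priv()
    expr$miRNA[triplet_mirs[t], ] <- rnorm(1, 8, 1.5) - z_trip[[t]] + priv()
  }
  for (k in seq_len(nc)) {
    sgn <- if (cis_dirs[k] == "up") 1 else -1
    expr$lncRNA[cis_lncs[k], ] <- rnorm(1, 8, 1.5) + sgn * z_cis[[k]] + priv()
    expr$mRNA[cis_genes[k], ] <- rnorm(1, 8, 1.5) + sgn * z_cis[[k]] + priv()
  }
  expr <- lapply(expr, function(v) round(v, 10))

  ## ---- genomic placement ----
  set.seed(config$seed + 101L)
  spacing <- config$feature_spacing
  cursor <- 3000L
  place <- function(len) {
    s <- cursor
    cursor <<- cursor + as.integer(len) + spacing
    c(s, s + as.integer(len))
  }
  feat <- list()
  add_feat <- function(id, start, end, strand, biotype) {
    feat[[length(feat) + 1L]] <<- data.frame(
      id = id, chrom = "chrS", start = as.integer(start), end = as.integer(end),
      strand = strand, biotype = biotype, stringsAsFactors = FALSE)
  }
  gene_pos <- list()
  for (i in seq_along(ids$mRNA)) {
    p <- place(GENE_LEN)
    strand <- sample(c("+", "-"), 1)
    gene_pos[[ids$mRNA[i]]] <- list(start = p[1], end = p[2], strand = strand)
    add_feat(ids$mRNA[i], p[1], p[2], strand, "mRNA")
  }
  # circRNAs live inside host genes (round robin), sharing the host strand
  for (j in seq_along(ids$circRNA)) {
    host <- ids$mRNA[((j - 1L) %% length(ids$mRNA)) + 1L]
    hp <- gene_pos[[host]]
    off <- 100L + 50L * ((j - 1L) %/% length(ids$mRNA))
    add_feat(ids$circRNA[j], hp$start + off, hp$start + off + CIRC_LEN,
             hp$strand, "circRNA")
  }
  cis_of <- setNames(cis_genes, cis_lncs)
  cat_of <- setNames(cis_categories, cis_lncs)
  for (i in seq_along(ids$lncRNA)) {
    id <- ids$lncRNA[i]
    if (id %in% cis_lncs) {
      g <- gene_pos[[cis_of[[id]]]]
      gs <- g$strand
      anti <- if (gs == "+") "-" else "+"
      pos <- switch(cat_of[[id]],
        sense = c(g$start + 1700L, gs),
        antisense = c(g$start + 100L, anti),
        intronic = c(g$start + GENE_EXON1 + 200L, sample(c("+", "-"), 1)),
        divergent = if (gs == "+") c(g$start - 900L, "-") else c(g$end + 100L, "+"),
        neighbor = if (gs == "+") c(g$end + 5000L, gs) else c(g$start - 5400L, gs)
      )
      add_feat(id, as.integer(pos[1]), as.integer(pos[1]) + LNC_LEN, pos[2], "lncRNA")
    } else {
      p <- place(LNC_LEN)
      add_feat(id, p[1], p[2], sample(c("+", "-"), 1), "lncRNA")
    }
  }
  for (i in seq_along(ids$miRNA)) {
    p <- place(MIR_LEN)
    add_feat(ids$miRNA[i], p[1], p[2], sample(c("+", "-"), 1), "miRNA")
  }
  features <- do.call(rbind, feat)
  rownames(features) <- NULL
  introns <- data.frame(
    gene_id = ids$mRNA,
    start = vapply(ids$mRNA, function(g) gene_pos[[g]]$start + GENE_EXON1, integer(1)),
    end = vapply(ids$mRNA, function(g) gene_pos[[g]]$start + GENE_INTRON_END, integer(1)),
    stringsAsFactors = FALSE
  )
  introns <- introns[order(introns$gene_id, introns$start), , drop = FALSE]
  rownames(introns) <- NULL
  genome_len <- cursor + 3000L

  ## ---- sequences ----
  set.seed(config$seed + 211L)
  genome <- random_dna(genome_len)
  frow <- function(id) features[features$id == id, ]
  extract <- function(id) {
    f <- frow(id)
    strand_sub(genome, f$start, f$end, f$strand)
  }
  lnc_seq <- setNames(vapply(ids$lncRNA, extract, character(1)), ids$lncRNA)
  circ_seq <- setNames(vapply(ids$circRNA, extract, character(1)), ids$circRNA)
  mir_seq <- setNames(vapply(ids$miRNA, extract, character(1)), ids$miRNA)
  utr_seq <- setNames(vapply(ids$mRNA, function(id) {
    f <- frow(id)
    if (f$strand == "+") strand_sub(genome, f$end - UTR_LEN, f$end, "+")
    else strand_sub(genome, f$start, f$start + UTR_LEN, "-")
  }, character(1)), ids$mRNA)

  # plant 8mer seed sites (reverse complement of miRNA positions 2-8, plus A)
  planted_trans <- list()
  for (t in seq_len(nt)) {
    site <- paste0(revcomp(substr(mir_seq[[triplet_mirs[t]]], 2, 8)), "A")
    utr <- utr_seq[[triplet_mrnas[t]]]
    upos <- sample(100:(UTR_LEN - 10L), 1)
    substr(utr, upos, upos + 7L) <- site
    utr_seq[[triplet_mrnas[t]]] <- utr
    if (sponge_species[t] == "lncRNA") {
      s <- lnc_seq[[sponge_ids[t]]]
      spos <- sample(1:60, 1)
      substr(s, spos, spos + 7L) <- site
      # planted trans signal: exact 30-nt copy of the partner 3'UTR
      substr(s, 201, 230) <- substr(utr, 51, 80)
      lnc_seq[[sponge_ids[t]]] <- s
      planted_trans[[length(planted_trans) + 1L]] <- data.frame(
        lncrna_id = sponge_ids[t], mrna_id = triplet_mrnas[t], length = 30L,
        stringsAsFactors = FALSE)
    } else {
      s <- circ_seq[[sponge_ids[t]]]
      spos <- sample(1:(CIRC_LEN - 10L), 1)
      substr(s, spos, spos + 7L) <- site
      circ_seq[[sponge_ids[t]]] <- s
    }
  }

  ## ---- motifs ----
  pwms <- list()
  planted_motifs <- list()
  if (config$n_motifs > 0L) {
    for (m in seq_len(config$n_motifs)) {
      mid <- sprintf("TF_%02d", m)
      consensus <- random_dna(MOTIF_LEN)
      counts <- matrix(0, 4, MOTIF_LEN, dimnames = list(c("A", "C", "G", "T"), NULL))
      for (p in seq_len(MOTIF_LEN)) counts[substr(consensus, p, p), p] <- 20
      pwms[[mid]] <- pwm(mid, counts)
      targets <- motif_lncs[(m - 1L) * config$motif_sites + seq_len(config$motif_sites)]
      for (lid in targets) {
        f <- frow(lid)
        w <- promoter_interval(f$start, f$end, f$strand)
        o <- sample(0:1900, 1)
        # window-string offset o -> genomic coordinate, then write in place
        if (f$strand == "+") {
          strand_sub_write(genome, w[1] + o, "+") <- consensus
        } else {
          strand_sub_write(genome, w[2] - o - MOTIF_LEN, "-") <- consensus
        }
        planted_motifs[[length(planted_motifs) + 1L]] <- data.frame(
          lncrna_id = lid, motif_id = mid, offset = as.integer(o),
          stringsAsFactors = FALSE)
      }
    }
  }

  ## ---- gene sets ----
  merged_de_mrna <- de_tab$mRNA$feature_id[de_tab$mRNA$group == "both"]
  terms <- list()
  for (ns in c("BP", "CC", "MF", "pathway")) {
    for (k in 1:5) {
      tid <- sprintf("%s:rand%02d", ns, k)
      terms[[tid]] <- list(name = sprintf("random %s set %d", ns, k),
                           namespace = ns,
                           members = sort(sample(ids$mRNA, sample(10:15, 1))))
    }
    tid <- sprintf("%s:planted01", ns)
    core <- sample(merged_de_mrna, min(8L, length(merged_de_mrna)))
    terms[[tid]] <- list(name = sprintf("planted %s set", ns), namespace = ns,
                         members = sort(unique(c(core, sample(ids$mRNA, 4)))))
  }
  gene_sets <- gene_set_collection(terms, background = ids$mRNA)

  ## ---- assemble ----
  expression <- lapply(RNA_SPECIES, function(sp)
    expression_matrix(expr[[sp]], sp, condition_of))
  names(expression) <- RNA_SPECIES

  pairs <- list()
  add_pair <- function(a, sa, b, sb, sign) {
    pairs[[length(pairs) + 1L]] <<- data.frame(
      node_a = a, species_a = sa, node_b = b, species_b = sb, sign = sign,
      stringsAsFactors = FALSE)
  }
  for (t in seq_len(nt)) {
    add_pair(sponge_ids[t], sponge_species[t], triplet_mrnas[t], "mRNA", "positive")
    add_pair(triplet_mirs[t], "miRNA", sponge_ids[t], sponge_species[t], "negative")
    add_pair(triplet_mirs[t], "miRNA", triplet_mrnas[t], "mRNA", "negative")
  }
  for (k in seq_len(nc)) {
    add_pair(cis_lncs[k], "lncRNA", cis_genes[k], "mRNA", "positive")
  }

  de_sets <- function(groups) {
    out <- lapply(RNA_SPECIES, function(sp) {
      tab <- de_tab[[sp]]
      tab <- tab[tab$group %in% groups, c("feature_id", "direction"), drop = FALSE]
      rownames(tab) <- NULL
      tab
    })
    names(out) <- RNA_SPECIES
    out
  }
  truth <- canonical_truth(list(
    planted_de = list(AvsCtrl = de_sets(c("both", "Aonly")),
                      BvsCtrl = de_sets(c("both", "Bonly")),
                      merged = de_sets("both")),
    planted_pairs = if (length(pairs)) do.call(rbind, pairs) else NULL,
    planted_triplets = if (nt > 0) data.frame(
      sponge_id = sponge_ids, sponge_species = sponge_species,
      mirna_id = triplet_mirs, mrna_id = triplet_mrnas,
      stringsAsFactors = FALSE) else NULL,
    planted_cis = if (nc > 0) data.frame(
      lncrna_id = cis_lncs, gene_id = cis_genes, category = cis_categories,
      stringsAsFactors = FALSE) else NULL,
    planted_motifs = if (length(planted_motifs)) do.call(rbind, planted_motifs) else NULL,
    planted_trans = if (length(planted_trans)) do.call(rbind, planted_trans) else NULL
  ))

  bundle <- list(
    expression = expression,
    annotation = list(features = features, introns = introns),
    sequences = list(genome = c(chrS = genome), lncRNA = lnc_seq,
                     circRNA = circ_seq, miRNA = mir_seq, utr3 = utr_seq),
    gene_sets = gene_sets,
    pwms = pwms,
    conditions = conds,
    condition_of = condition_of
  )
  structure(list(bundle = bundle, truth = truth, config = config),
            class = "cernet_dataset")
}

#' Write a generated dataset to a directory
#'
#' Emits expression TSVs, a sample sheet, one GTF, FASTA files per sequence
#' class (miRNA written with U per convention), one GMT, one JASPAR-style PWM
#' file, and a truth JSON. [read_dataset()] on the result reproduces the
#' dataset exactly.
#'
#' @param dataset a `cernet_dataset` from [generate_dataset()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "cernet_dataset"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir)
  }
  b <- dataset$bundle
  for (sp in RNA_SPECIES) {
    write_expression_tsv(b$expression[[sp]], file.path(out_dir, paste0("expr_", sp, ".tsv")))
  }
  samples <- data.frame(sample_id = names(b$condition_of),
                        condition = unname(b$condition_of),
                        stringsAsFactors = FALSE)
  write.table(samples, file.path(out_dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gtf(b$annotation$features, b$annotation$introns,
            file.path(out_dir, "annotation.gtf"))
  write_fasta(b$sequences$genome, file.path(out_dir, "genome.fa"))
  write_fasta(b$sequences$lncRNA, file.path(out_dir, "lncRNA.fa"))
  write_fasta(b$sequences$circRNA, file.path(out_dir, "circRNA.fa"))
  write_fasta(b$sequences$miRNA, file.path(out_dir, "miRNA.fa"), as_rna = TRUE)
  write_fasta(b$sequences$utr3, file.path(out_dir, "utr3.fa"))
  write_gmt(b$gene_sets, file.path(out_dir, "genesets.gmt"))
  write_pwm_file(b$pwms, file.path(out_dir, "motifs.pwm"))
  write_truth_json(dataset$truth, file.path(out_dir, "truth.json"))
  invisible(out_dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @return a `cernet_dataset` (without the generating config).
#' @export
read_dataset <- function(dir) {
  samples <- read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
  condition_of <- setNames(samples$condition, samples$sample_id)
  conditions <- unique(unname(condition_of))
  expression <- lapply(RNA_SPECIES, function(sp) {
    read_expression_tsv(file.path(dir, paste0("expr_", sp, ".tsv")), sp, condition_of)
  })
  names(expression) <- RNA_SPECIES
  annotation <- read_gtf(file.path(dir, "annotation.gtf"))
  sequences <- list(
    genome = read_fasta(file.path(dir, "genome.fa")),
    lncRNA = read_fasta(file.path(dir, "lncRNA.fa")),
    circRNA = read_fasta(file.path(dir, "circRNA.fa")),
    miRNA = read_fasta(file.path(dir, "miRNA.fa")),
    utr3 = read_fasta(file.path(dir, "utr3.fa"))
  )
  gene_sets <- read_gmt(file.path(dir, "genesets.gmt"),
                        background = rownames(expression$mRNA$values))
  pwms <- read_pwm_file(file.path(dir, "motifs.pwm"))
  truth <- read_truth_json(file.path(dir, "truth.json"))
  structure(list(
    bundle = list(expression = expression, annotation = annotation,
                  sequences = sequences, gene_sets = gene_sets, pwms = pwms,
                  conditions = conditions, condition_of = condition_of),
    truth = truth, config = NULL
  ), class = "cernet_dataset")
}
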