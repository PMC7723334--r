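edge_row <- function(a, sa, b, sb, r) {
  data.frame(node_a = a, species_a = sa, node_b = b, species_b = sb,
             r = r, p = 1e-6, sign = ifelse(r > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

site_row <- function(mir, tx, cls = "8mer") {
  data.frame(mirna_id = mir, transcript_id = tx, start = 0L,
             end = 8L, site_class = cls,
             score = c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)[[cls]],
             stringsAsFactors = FALSE)
}

test_that("triplets require all three edges and shared sites", {
  sm <- edge_row("lncA", "lncRNA", "m1", "mRNA", 0.995)
  ms <- edge_row("mirX", "miRNA", "lncA", "lncRNA", -0.992)
  mm <- edge_row("mirX", "miRNA", "m1", "mRNA", -0.991)
  sites <- rbind(site_row("mirX", "lncA"), site_row("mirX", "m1"))
  tri <- assemble_triplets(sm, ms, mm, sites)
  expect_identical(nrow(tri), 1L)
  expect_identical(tri$sponge_id, "lncA")
  expect_gt(tri$sponge_mrna_r, 0)
  expect_lt(tri$mirna_sponge_r, 0)
  expect_lt(tri$mirna_mrna_r, 0)
  expect_identical(tri$n_sites_sponge, 1L)
  # no shared miRNA sites in the mRNA -> no triplet
  expect_identical(nrow(assemble_triplets(sm, ms, mm, site_row("mirX", "lncA"))), 0L)
  # positive miRNA-mRNA correlation is rejected by the sign gate
  mm_pos <- edge_row("mirX", "miRNA", "m1", "mRNA", 0.991)
  expect_identical(nrow(assemble_triplets(sm, ms, mm_pos, sites)), 0L)
  # negative sponge-mRNA edge is never used
  sm_neg <- edge_row("lncA", "lncRNA", "m1", "mRNA", -0.995)
  expect_identical(nrow(assemble_triplets(sm_neg, ms, mm, sites)), 0L)
})

test_that("planted triplets are recovered with their sign constraints intact", {
  ds <- small_dataset()
  b <- ds$bundle
  de <- run_de_analysis(b$expression, b$conditions)$de_sets
  rule <- correlation_rule(0.99, 0.05, "any")
  rule_neg <- correlation_rule(0.99, 0.05, "negative")
  ids <- function(sp) de[[sp]]$merged$feature_id
  sm <- rbind(
    build_pair_network(b$expression$lncRNA, b$expression$mRNA,
                       ids("lncRNA"), ids("mRNA"), rule),
    build_pair_network(b$expression$circRNA, b$expression$mRNA,
                       ids("circRNA"), ids("mRNA"), rule))
  ms <- rbind(
    build_pair_network(b$expression$miRNA, b$expression$lncRNA,
                       ids("miRNA"), ids("lncRNA"), rule_neg),
    build_pair_network(b$expression$miRNA, b$expression$circRNA,
                       ids("miRNA"), ids("circRNA"), rule_neg))
  mm <- build_pair_network(b$expression$miRNA, b$expression$mRNA,
                           ids("miRNA"), ids("mRNA"), rule_neg)
  tru <- ds$truth$planted_triplets
  mirs <- b$sequences$miRNA[ids("miRNA")]
  targets <- c(b$sequences$lncRNA[ids("lncRNA")],
               b$sequences$circRNA[ids("circRNA")],
               b$sequences$utr3[ids("mRNA")])
  sites <- predict_targets(mirs, targets)
  tri <- assemble_triplets(sm, ms, mm, sites)
  key <- function(d) paste(d$sponge_id, d$mirna_id, d$mrna_id)
  expect_gte(mean(key(tru) %in% key(tri)), 0.9)   # recall
  expect_gte(mean(key(tri) %in% key(tru)), 0.9)   # precision
  # sign constraints hold on recomputation from the expression matrices
  for (i in seq_len(nrow(tri))) {
    sp_mat <- b$expression[[tri$sponge_species[i]]]$values
    expect_gt(cor(sp_mat[tri$sponge_id[i], ],
                  b$expression$mRNA$values[tri$mrna_id[i], ]), 0)
    expect_lt(cor(b$expression$miRNA$values[tri$mirna_id[i], ],
                  sp_mat[tri$sponge_id[i], ]), 0)
    expect_lt(cor(b$expression$miRNA$values[tri$mirna_id[i], ],
                  b$expression$mRNA$values[tri$mrna_id[i], ]), 0)
  }
  # tightening the targeting gate never enlarges the triplet set
  sites8 <- sites[sites$site_class == "8mer", ]
  tri8 <- assemble_triplets(sm, ms, mm, sites8)
  expect_true(all(key(tri8) %in% key(tri)))
})

test_that("triplet summaries count distinct partners deterministically", {
  tri <- rbind(
    data.frame(sponge_id = c("l1", "l2", "l3"), sponge_species = "lncRNA",
               mirna_id = "mirA", mrna_id = c("m1", "m2", "m1"),
               stringsAsFactors = FALSE))
  s <- triplet_network_summary(tri)
  expect_identical(unname(s$mirna_degree["mirA"]), 5L)  # 3 sponges + 2 mRNAs
  expect_identical(unname(s$node_degree["m1"]), 3L)     # mirA + l1 + l3
  s0 <- triplet_network_summary(tri[0, ])
  expect_length(s0$mirna_degree, 0)
})

test_that("network exports round-trip and are well-formed", {
  tri <- data.frame(
    sponge_id = c("l1", "c1"), sponge_species = c("lncRNA", "circRNA"),
    mirna_id = c("mir1", "mir2"), mrna_id = c("m1", "m2"),
    sponge_mrna_r = c(0.995, 0.993), mirna_sponge_r = c(-0.99, -0.992),
    mirna_mrna_r = c(-0.991, -0.994), n_sites_sponge = c(1L, 2L),
    n_sites_mrna = c(1L, 1L), stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  export_network(tri, tsv, "tsv")
  expect_equal(import_network(tsv), tri)
  sif <- tempfile(fileext = ".sif")
  export_network(tri, sif, "sif")
  expect_identical(length(readLines(sif)), 6L)  # 3 binary relations per triplet
  gml <- tempfile(fileext = ".graphml")
  export_network(tri, gml, "graphml")
  doc <- xml2::read_xml(gml)
  expect_identical(xml2::xml_name(doc), "graphml")
  expect_error(export_network(tri, tempfile(), "dot"), "arg")
  unlink(c(tsv, sif, gml))
})
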