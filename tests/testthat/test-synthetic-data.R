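test_that("identical config and seed give identical datasets and files", {
  cfg <- small_sim_config(seed = 11L)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_equal(d1$bundle, d2$bundle)
  expect_equal(d1$truth, d2$truth)

  dir1 <- file.path(tempdir(), "detA"); dir2 <- file.path(tempdir(), "detB")
  write_dataset(d1, dir1)
  write_dataset(d2, dir2)
  files <- list.files(dir1)
  expect_identical(files, list.files(dir2))
  h1 <- unname(tools::md5sum(file.path(dir1, files)))
  h2 <- unname(tools::md5sum(file.path(dir2, files)))
  expect_identical(h1, h2)
  unlink(c(dir1, dir2), recursive = TRUE)
})

test_that("null config yields empty truth", {
  d <- generate_dataset(null_sim_config(seed = 3L))
  for (cmp in c("AvsCtrl", "BvsCtrl", "merged")) {
    for (sp in c("lncRNA", "circRNA", "miRNA", "mRNA")) {
      expect_identical(nrow(d$truth$planted_de[[cmp]][[sp]]), 0L)
    }
  }
  expect_identical(nrow(d$truth$planted_triplets), 0L)
  expect_identical(nrow(d$truth$planted_pairs), 0L)
  expect_identical(nrow(d$truth$planted_cis), 0L)
  expect_identical(nrow(d$truth$planted_motifs), 0L)
})

test_that("config validation rejects malformed settings", {
  expect_error(simulation_config(n_replicates = 1), "replicates")
  expect_error(simulation_config(de_fraction = 1.2), "de_fraction")
  expect_error(simulation_config(de_fraction = -0.1), "de_fraction")
  expect_error(simulation_config(n_planted_triplets = -1), "planted")
  expect_error(
    simulation_config(n_features = c(lncRNA = 3L, circRNA = 10L,
                                     miRNA = 10L, mRNA = 30L)),
    "not enough lncRNA")
})

test_that("write/read round trip reproduces the dataset exactly", {
  ds <- small_dataset()
  dir <- file.path(tempdir(), "roundtrip")
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_equal(back$bundle, ds$bundle)
  expect_equal(back$truth, ds$truth)
  # truth JSON lists exactly the requested number of triplets
  truth_raw <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  expect_length(unique(truth_raw$planted_triplets$sponge_id), 4L)
  unlink(dir, recursive = TRUE)
})

test_that("GTF round trip preserves 0-based half-open internal coordinates", {
  ds <- small_dataset()
  path <- tempfile(fileext = ".gtf")
  write_gtf(ds$bundle$annotation$features, ds$bundle$annotation$introns, path)
  back <- read_gtf(path)
  expect_equal(back$features, ds$bundle$annotation$features)
  expect_equal(back$introns, ds$bundle$annotation$introns)
  # on-disk GTF is 1-based inclusive
  raw <- read.delim(path, header = FALSE, comment.char = "#", quote = "")
  tx <- raw[raw$V3 == "transcript", ]
  first <- ds$bundle$annotation$features[1, ]
  row <- tx[grepl(paste0('"', first$id, '"'), tx$V9), ][1, ]
  expect_identical(as.integer(row$V4), first$start + 1L)
  expect_identical(as.integer(row$V5), first$end)
  unlink(path)
})

test_that("planted triplets carry exact seed complements in sponge and mRNA", {
  ds <- small_dataset()
  b <- ds$bundle
  tru <- ds$truth$planted_triplets
  for (i in seq_len(nrow(tru))) {
    mir <- b$sequences$miRNA[[tru$mirna_id[i]]]
    site7 <- revcomp(substr(mir, 2, 8))
    sponge_seq <- if (tru$sponge_species[i] == "lncRNA") {
      b$sequences$lncRNA[[tru$sponge_id[i]]]
    } else {
      b$sequences$circRNA[[tru$sponge_id[i]]]
    }
    expect_true(grepl(site7, sponge_seq, fixed = TRUE))
    expect_true(grepl(site7, b$sequences$utr3[[tru$mrna_id[i]]], fixed = TRUE))
  }
})

test_that("planted expression structure matches the ceRNA sign pattern", {
  ds <- small_dataset()
  b <- ds$bundle
  ctrl <- samples_of(b$expression$mRNA, b$conditions[1])
  res <- samples_of(b$expression$mRNA, b$conditions[2:3])
  tru <- ds$truth$planted_triplets
  for (i in seq_len(nrow(tru))) {
    sp_mat <- b$expression[[tru$sponge_species[i]]]$values
    expect_gt(mean(sp_mat[tru$sponge_id[i], res]) -
                mean(sp_mat[tru$sponge_id[i], ctrl]), 1)
    expect_gt(mean(b$expression$mRNA$values[tru$mrna_id[i], res]) -
                mean(b$expression$mRNA$values[tru$mrna_id[i], ctrl]), 1)
    expect_lt(mean(b$expression$miRNA$values[tru$mirna_id[i], res]) -
                mean(b$expression$miRNA$values[tru$mirna_id[i], ctrl]), -1)
  }
})

test_that("planted pairs are near-perfectly correlated across seeds", {
  frac_high <- vapply(1:20, function(s) {
    d <- generate_dataset(small_sim_config(seed = 100L + s))
    tp <- d$truth$planted_pairs
    rs <- mapply(function(a, sa, b, sb) {
      cor(d$bundle$expression[[sa]]$values[a, ],
          d$bundle$expression[[sb]]$values[b, ])
    }, tp$node_a, tp$species_a, tp$node_b, tp$species_b)
    pos <- tp$sign == "positive"
    expect_true(all(rs[pos] > 0) && all(rs[!pos] < 0))
    mean(abs(rs) >= 0.99)
  }, numeric(1))
  expect_gte(mean(frac_high), 0.9)
})

test_that("non-planted features have uniform null p-values", {
  pooled <- unlist(lapply(1:5, function(s) {
    d <- generate_dataset(null_sim_config(seed = 600L + s))
    st <- differential_test(d$bundle$expression$mRNA,
                            d$bundle$conditions[1], d$bundle$conditions[2])
    st$p_raw
  }))
  expect_gt(stats::ks.test(pooled, "punif")$p.value, 0.01)
})

test_that("planted cis pairs sit within the window in their stated category", {
  ds <- small_dataset()
  feats <- ds$bundle$annotation$features
  introns <- ds$bundle$annotation$introns
  tru <- ds$truth$planted_cis
  for (i in seq_len(nrow(tru))) {
    lnc <- as.list(feats[feats$id == tru$lncrna_id[i], ])
    gene <- as.list(feats[feats$id == tru$gene_id[i], ])
    rel <- classify_cis_relation(
      lnc, gene, introns[introns$gene_id == gene$id, , drop = FALSE])
    expect_identical(rel$category, tru$category[i])
    expect_lte(rel$distance, 10000L)
  }
})
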