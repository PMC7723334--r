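feat <- function(start, end, strand, chrom = "chrS", id = "x") {
  list(id = id, chrom = chrom, start = start, end = end, strand = strand)
}

test_that("cis classification follows the precedence order", {
  gene <- feat(50, 1000, "+", id = "g")
  gene_introns <- data.frame(gene_id = "g", start = 60, end = 900)
  # wholly inside an intron beats overlap classes, either strand
  expect_identical(
    classify_cis_relation(feat(100, 500, "+"), gene, gene_introns)$category,
    "intronic")
  expect_identical(
    classify_cis_relation(feat(100, 500, "-"), gene, gene_introns)$category,
    "intronic")
  # same-strand overlap
  expect_identical(
    classify_cis_relation(feat(100, 500, "+"), feat(300, 900, "+"))$category,
    "sense")
  expect_identical(
    classify_cis_relation(feat(100, 500, "-"), feat(300, 900, "+"))$category,
    "antisense")
  # head-to-head: lncRNA [2000,3000) minus (TSS 2999), gene [3400,5000) plus
  # (TSS 3400), TSS gap 401 <= 1000
  d <- classify_cis_relation(feat(2000, 3000, "-"), feat(3400, 5000, "+"))
  expect_identical(d$category, "divergent")
  expect_identical(d$distance, 400L)
  # same arrangement but TSS gap beyond the divergent limit falls to neighbor
  expect_identical(
    classify_cis_relation(feat(1000, 2000, "-"), feat(3400, 5000, "+"))$category,
    "neighbor")
  # co-oriented non-overlapping neighbours are never divergent
  expect_identical(
    classify_cis_relation(feat(2000, 3000, "+"), feat(3400, 5000, "+"))$category,
    "neighbor")
  # outside the window, or on another chromosome: no relation
  expect_null(classify_cis_relation(feat(2000, 3000, "+"), feat(14000, 15000, "+")))
  expect_null(classify_cis_relation(feat(2000, 3000, "+", chrom = "chr2"),
                                    feat(3400, 5000, "+")))
  # shrinking the window never adds pairs
  wide <- classify_cis_relation(feat(0, 100, "+"), feat(5000, 6000, "+"),
                                window = 10000)
  narrow <- classify_cis_relation(feat(0, 100, "+"), feat(5000, 6000, "+"),
                                  window = 2000)
  expect_identical(wide$category, "neighbor")
  expect_null(narrow)
})

test_that("cis pair discovery gates on window, positive r and Holm p", {
  ds <- small_dataset()
  b <- ds$bundle
  feats <- b$annotation$features
  lnc_f <- feats[feats$biotype == "lncRNA", ]
  gene_f <- feats[feats$biotype == "mRNA", ]
  got <- find_cis_pairs(lnc_f, gene_f, b$annotation$introns,
                        b$expression$lncRNA, b$expression$mRNA)
  tru <- ds$truth$planted_cis
  key <- function(d) paste(d$lncrna_id, d$gene_id)
  expect_gte(mean(key(tru) %in% key(got)), 0.95)
  hit <- merge(tru, got, by = c("lncrna_id", "gene_id"))
  expect_identical(hit$category.x, hit$category.y)
  expect_true(all(got$r >= 0.99))
  expect_true(all(got$p_holm < 0.5))
  expect_true(all(got$distance <= 10000))
})

test_that("local alignment matches the dynamic-programming recurrence", {
  s <- random_seq(30)
  perfect <- local_align(s, s)
  expect_equal(perfect$score, 30)
  expect_equal(perfect$identity, 1.0)
  expect_identical(perfect$length, 30L)
  disjoint <- local_align("AAAAAAA", "CCCCCCC")
  expect_equal(disjoint$score, 0)
  expect_identical(disjoint$length, 0L)
  set.seed(10)
  for (i in 1:40) {
    a <- random_seq(sample(10:50, 1))
    b <- random_seq(sample(10:50, 1))
    expect_equal(local_align(a, b)$score, sw_oracle(a, b))
  }
  expect_error(local_align("", "ACGT"), "non-empty")
})

test_that("trans prediction requires co-expression and a high-identity segment", {
  set.seed(11)
  core <- random_seq(30)                     # exact 30-nt shared segment
  # inert flanks (A against C) guarantee the optimal segment is exactly the
  # planted copy
  utr <- paste0(strrep("C", 80), core, strrep("C", 90))
  lnc <- paste0(strrep("A", 60), core, strrep("A", 60))
  lnc_seqs <- c(lncX = lnc, lncY = random_seq(200))
  utr_seqs <- c(mrnaX = utr, mrnaY = random_seq(200))
  edges <- data.frame(node_a = c("lncX", "lncY"), node_b = c("mrnaX", "mrnaY"),
                      stringsAsFactors = FALSE)
  hits <- predict_trans_targets(lnc_seqs, utr_seqs, edges)
  expect_identical(hits$lncrna_id, "lncX")
  expect_gte(hits$length[1], 30)
  expect_gte(hits$identity[1], 0.9)
  # containment with inert flanks reports the exact segment
  expect_equal(hits$identity[1], 1.0)
  expect_identical(substr(lnc, hits$lnc_start + 1, hits$lnc_start + 30), core)
  # identical sequences that are not co-expressed are never evaluated
  lnc_seqs2 <- c(lncZ = utr)
  hits2 <- predict_trans_targets(c(lnc_seqs, lnc_seqs2), utr_seqs, edges)
  expect_false("lncZ" %in% hits2$lncrna_id)
  # unrelated random sequences rarely reach the gates
  set.seed(12)
  miss <- 0
  for (i in 1:25) {
    e <- data.frame(node_a = "l", node_b = "m", stringsAsFactors = FALSE)
    h <- predict_trans_targets(c(l = random_seq(200)), c(m = random_seq(200)), e)
    miss <- miss + (nrow(h) == 0)
  }
  expect_gte(miss, 24)
  expect_error(predict_trans_targets(lnc_seqs, utr_seqs,
                                     data.frame(node_a = "nope", node_b = "mrnaX")),
               "missing")
})

test_that("promoter windows follow strand-aware TSS arithmetic", {
  chrom <- c(chrS = random_seq(9000))
  plus <- extract_promoter_window(feat(5000, 6000, "+"), chrom)
  expect_identical(plus$start, 3000L)
  expect_identical(plus$end, 5500L)
  expect_false(plus$clipped)
  expect_identical(plus$sequence, substr(chrom[["chrS"]], 3001, 5500))
  # minus strand, TSS at 5000 (feature end 5001): genomic [4500, 7000),
  # reverse complemented
  minus <- extract_promoter_window(feat(4000, 5001, "-"), chrom)
  expect_identical(minus$start, 4500L)
  expect_identical(minus$end, 7000L)
  expect_identical(minus$sequence, revcomp(substr(chrom[["chrS"]], 4501, 7000)))
  clipped <- extract_promoter_window(feat(100, 700, "+"), chrom)
  expect_identical(clipped$start, 0L)
  expect_identical(clipped$end, 600L)
  expect_true(clipped$clipped)
  expect_error(extract_promoter_window(feat(1, 2, "+", chrom = "chrZ"), chrom),
               "absent")
})

test_that("PWM scanning matches a naive per-position scorer on both strands", {
  set.seed(13)
  consensus <- random_seq(10)
  counts <- matrix(0, 4, 10, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (p in 1:10) counts[substr(consensus, p, p), p] <- 20
  p <- pwm("TF_test", counts)
  expect_true(all(abs(colSums(p$probs) - 1) < 1e-9))
  win <- paste0(random_seq(40), consensus, random_seq(40))
  lo <- log2(p$probs / 0.25)
  max_score <- sum(apply(lo, 2, max))
  hits <- scan_pwm(win, p, threshold = 1.0)
  expect_true(any(hits$offset == 40 & hits$strand == "+"))
  expect_equal(hits$score[hits$offset == 40], max_score)
  # minus-strand occurrence is found at its forward-coordinate offset
  win_rc <- paste0(random_seq(25), revcomp(consensus), random_seq(25))
  hits_rc <- scan_pwm(win_rc, p, threshold = 1.0)
  expect_true(any(hits_rc$offset == 25 & hits_rc$strand == "-"))
  # naive oracle: per-position summation, forward strand
  naive <- vapply(1:(nchar(win) - 9), function(i) {
    sum(vapply(1:10, function(k) lo[substr(win, i + k - 1, i + k - 1), k],
               numeric(1)))
  }, numeric(1))
  all_hits <- scan_pwm(win, p, threshold = -10)  # keep every position
  fwd <- all_hits[all_hits$strand == "+", ]
  expect_equal(fwd$score, unname(naive), tolerance = 1e-12)
  # raising the threshold never adds hits
  h80 <- scan_pwm(win, p, 0.8)
  h95 <- scan_pwm(win, p, 0.95)
  expect_true(all(paste(h95$offset, h95$strand) %in% paste(h80$offset, h80$strand)))
  expect_error(scan_pwm("ACGT", p), "shorter")
})

test_that("TF network connects motifs to the promoters that contain them", {
  ds <- small_dataset()
  b <- ds$bundle
  feats <- b$annotation$features
  pm <- ds$truth$planted_motifs
  lnc_f <- feats[feats$biotype == "lncRNA" & feats$id %in% pm$lncrna_id, ]
  net <- build_tf_network(lnc_f, b$pwms, b$sequences$genome)
  key <- paste(net$edges$lncrna_id, net$edges$motif_id)
  expect_true(all(paste(pm$lncrna_id, pm$motif_id) %in% key))
  # per-TF degree equals a recount from the edge list
  for (tf in names(net$tf_degree)) {
    expect_identical(unname(net$tf_degree[tf]),
                     sum(net$edges$motif_id == tf))
  }
})
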