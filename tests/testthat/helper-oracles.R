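# Independent oracle implementations used to cross-check the package. These
# are deliberately written from the textbook definitions with plain R, not by
# calling the code paths they verify.

# Benjamini-Hochberg step-up: q_i = min_{j >= i} min(1, p_(j) * n / j)
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ranked[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Holm step-down with enforced monotonicity, capped at 1
holm_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- cummax(pmin(1, (n - seq_len(n) + 1) * ranked))
  out <- numeric(n)
  out[o] <- adj
  out
}

# hypergeometric upper tail by direct summation of the pmf
hyper_oracle <- function(k, K, n, N) {
  js <- k:min(n, K)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Smith-Waterman optimal local alignment score by the full DP recurrence
sw_oracle <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  H <- matrix(0, length(A) + 1L, length(B) + 1L)
  best <- 0
  for (i in seq_along(A)) {
    for (j in seq_along(B)) {
      s <- if (A[i] == B[j]) match else mismatch
      H[i + 1L, j + 1L] <- max(0, H[i, j] + s, H[i, j + 1L] + gap,
                               H[i + 1L, j] + gap)
      if (H[i + 1L, j + 1L] > best) best <- H[i + 1L, j + 1L]
    }
  }
  best
}

rc_oracle <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

# naive position-wise seed-site scanner: walks every position with plain
# substring comparisons; same site semantics (one site per 6mer-core
# occurrence, reported at its highest class)
seed_sites_oracle <- function(mirna, target) {
  m <- chartr("U", "T", toupper(mirna))
  t <- chartr("U", "T", toupper(target))
  core <- rc_oracle(substr(m, 2, 7))
  m8 <- rc_oracle(substr(m, 8, 8))
  rows <- list()
  for (j in seq_len(max(0, nchar(t) - 5L))) {
    if (substr(t, j, j + 5L) != core) next
    has_m8 <- j > 1L && substr(t, j - 1L, j - 1L) == m8
    has_a <- j + 6L <= nchar(t) && substr(t, j + 6L, j + 6L) == "A"
    if (has_m8 && has_a) {
      cls <- "8mer"; s0 <- j - 2L; w <- 8L
    } else if (has_m8) {
      cls <- "7mer-m8"; s0 <- j - 2L; w <- 7L
    } else if (has_a) {
      cls <- "7mer-A1"; s0 <- j - 1L; w <- 7L
    } else {
      cls <- "6mer"; s0 <- j - 1L; w <- 6L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      start = s0, end = s0 + w, site_class = cls,
      score = c("6mer" = 1, "7mer-A1" = 2, "7mer-m8" = 3, "8mer" = 4)[[cls]],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      site_class = character(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# brute-force co-expression network: double loop over all DE pairs with
# cor.test as the statistical oracle
network_oracle <- function(mat_a, mat_b, de_a, de_b, min_abs_r = 0.99,
                           alpha = 0.05, required_sign = "any",
                           samples = NULL) {
  shared <- intersect(colnames(mat_a$values), colnames(mat_b$values))
  if (!is.null(samples)) shared <- intersect(shared, samples)
  rows <- list()
  for (a in de_a) {
    for (b in de_b) {
      ct <- suppressWarnings(
        stats::cor.test(mat_a$values[a, shared], mat_b$values[b, shared]))
      r <- unname(ct$estimate)
      p <- if (abs(r) >= 1) 0 else ct$p.value
      ok <- abs(r) >= min_abs_r && p < alpha
      if (required_sign == "positive") ok <- ok && r > 0
      if (required_sign == "negative") ok <- ok && r < 0
      if (ok) {
        rows[[length(rows) + 1L]] <- data.frame(
          node_a = a, node_b = b, r = r, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(node_a = character(0), node_b = character(0),
                      r = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$node_a, out$node_b), , drop = FALSE]
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
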