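# Independent brute-force oracles used to check the implementation.
# These deliberately re-derive quantities by direct enumeration and never
# call the code paths they verify.

# Nussinov maximisation: maximum number of nested base pairs with a minimum
# hairpin loop of 3 unpaired nucleotides.
oracle_nussinov_maxpairs <- function(seq) {
  s <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(s)
  can <- function(a, b) {
    p <- paste0(s[a], s[b])
    p %in% c("AU", "UA", "CG", "GC", "GU", "UG")
  }
  M <- matrix(0L, n, n)
  for (d in 4:(n - 1)) {
    for (i in 1:(n - d)) {
      j <- i + d
      best <- M[i, j - 1]
      for (k in i:(j - 4)) {
        if (can(k, j)) {
          left <- if (k > i) M[i, k - 1] else 0L
          inner <- if (j - k >= 5) M[k + 1, j - 1] else 0L
          best <- max(best, left + inner + 1L)
        }
      }
      M[i, j] <- best
    }
  }
  if (n < 5) 0L else M[1, n]
}

# Loop decomposition by direct scan: hairpin loops are pairs (i, j) with no
# paired position strictly between them.
oracle_count_hairpin_loops <- function(pairs) {
  paired <- which(!is.na(pairs) & pairs > seq_along(pairs))
  sum(vapply(paired, function(i) {
    j <- pairs[i]
    j - i == 1L || all(is.na(pairs[(i + 1L):(j - 1L)]))
  }, logical(1)))
}

# Position-by-position counting oracles for feature values.
oracle_base_count <- function(seq, base) {
  n <- 0L
  for (ch in strsplit(seq, "", fixed = TRUE)[[1]]) if (ch == base) n <- n + 1L
  n
}

oracle_unpaired_count <- function(positions, pairs) {
  n <- 0L
  for (p in positions) if (is.na(pairs[p])) n <- n + 1L
  n
}

# Run-length scan for internal loops within interval(s).
oracle_internal_loops <- function(intervals, pairs) {
  if (is.numeric(intervals)) intervals <- list(intervals)
  runs <- integer(0)
  for (ivl in intervals) {
    if (ivl[1] > ivl[2]) next
    cur <- 0L
    for (p in ivl[1]:ivl[2]) {
      if (is.na(pairs[p])) cur <- cur + 1L
      else if (cur > 0L) { runs <- c(runs, cur); cur <- 0L }
    }
    if (cur > 0L) runs <- c(runs, cur)
  }
  c(if (length(runs)) max(runs) else 0L, length(runs))
}

oracle_gu_count <- function(intervals, pairs, seq) {
  if (is.numeric(intervals)) intervals <- list(intervals)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  seen <- character(0)
  n <- 0L
  for (ivl in intervals) {
    if (ivl[1] > ivl[2]) next
    for (p in ivl[1]:ivl[2]) {
      q <- pairs[p]
      if (is.na(q)) next
      key <- paste(min(p, q), max(p, q))
      if (key %in% seen) next
      seen <- c(seen, key)
      if (setequal(c(ch[p], ch[q]), c("G", "U"))) n <- n + 1L
    }
  }
  n
}

# Designed hairpin with a known pair table: complementary arms with optional
# bulges/internal loops, explicit structure, consistent sequence. Returns the
# sequence, structure and the single extracted hairpin.
designed_hairpin <- function(stem = 20L, loop = 6L, flank5 = 0L, flank3 = 0L,
                             bulges5 = integer(0), bulges3 = integer(0)) {
  # bulges5/bulges3: after how many stem pairs (from the base) to insert a
  # 1-nt unpaired bulge on that arm
  bases <- c("A", "C", "G", "U")
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  pair_bases <- sample(bases, stem, replace = TRUE)
  s5 <- character(0); db5 <- character(0)
  for (k in seq_len(stem)) {
    s5 <- c(s5, pair_bases[k]); db5 <- c(db5, "(")
    if (k %in% bulges5) { s5 <- c(s5, sample(bases, 1L)); db5 <- c(db5, ".") }
  }
  s3 <- character(0); db3 <- character(0)
  for (k in seq_len(stem)) {
    s3 <- c(comp[[pair_bases[k]]], s3); db3 <- c(")", db3)
    if (k %in% bulges3) { s3 <- c(sample(bases, 1L), s3); db3 <- c(".", db3) }
  }
  loopseq <- sample(c("A", "C"), loop, replace = TRUE)
  f5 <- sample(bases, flank5, replace = TRUE)
  f3 <- sample(bases, flank3, replace = TRUE)
  seq <- paste(c(f5, s5, loopseq, s3, f3), collapse = "")
  db <- paste(c(rep(".", flank5), db5, rep(".", loop), db3, rep(".", flank3)),
              collapse = "")
  st <- secondary_structure(db, mfe = -30, sequence = seq)
  hps <- extract_hairpins(st, seq)
  list(sequence = seq, structure = st, hairpin = hps[[1]])
}

# Random designed hairpin for property tests (no folding involved).
random_designed_hairpin <- function() {
  stem <- sample(15:35, 1L)
  nb5 <- sample(0:2, 1L)
  nb3 <- sample(0:2, 1L)
  designed_hairpin(
    stem = stem, loop = sample(4:10, 1L),
    flank5 = sample(0:6, 1L), flank3 = sample(0:6, 1L),
    bulges5 = if (nb5) sample(2:(stem - 2L), nb5) else integer(0),
    bulges3 = if (nb3) sample(2:(stem - 2L), nb3) else integer(0))
}

iv_len_test <- function(x) if (x[1] > x[2]) 0L else x[2] - x[1] + 1L

# A random admissible mature placement on a designed hairpin.
random_placement <- function(h, len_range = c(18L, 24L)) {
  cands <- enumerate_candidates(h, len_range = len_range)
  if (nrow(cands) == 0L) return(NULL)
  cands[sample(nrow(cands), 1L), , drop = FALSE]
}
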