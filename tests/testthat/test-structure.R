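test_that("folding a perfect stem forms all pairs and a maximal pairing", {
  toy <- "GGGGGAAAAACCCCC"
  for (be in c("rnafold", "inprocess")) {
    st <- fold(toy, backend = be, min_len = 10L)
    expect_equal(sum(!is.na(st$pairs)) / 2L, 5L)
    # loop unpaired, stem G-C paired
    expect_true(all(is.na(st$pairs[6:10])))
    expect_equal(st$pairs[1:5], 15:11)
    # pair count is maximal for this toy (independent Nussinov oracle)
    expect_equal(sum(!is.na(st$pairs)) / 2L, oracle_nussinov_maxpairs(toy))
    expect_lt(st$mfe, 0)
  }
})

test_that("a homopolymer folds to zero pairs at zero energy", {
  seqA <- strrep("A", 50)
  for (be in c("rnafold", "inprocess")) {
    st <- fold(seqA, backend = be)
    expect_true(all(is.na(st$pairs)))
    expect_equal(st$mfe, 0)
    expect_length(extract_hairpins(st, seqA), 0L)
  }
})

test_that("reversing a palindromic stem-loop yields the mirror dot-bracket", {
  toy <- "GGGGGAAAAACCCCC"
  rev_toy <- paste(rev(strsplit(toy, "")[[1]]), collapse = "")
  mirror <- function(db) chartr("()", ")(",
                                paste(rev(strsplit(db, "")[[1]]), collapse = ""))
  for (be in c("rnafold", "inprocess")) {
    st <- fold(toy, backend = be, min_len = 10L)
    str <- fold(rev_toy, backend = be, min_len = 10L)
    expect_identical(str$dotbracket, mirror(st$dotbracket))
  }
})

test_that("folding is deterministic for identical input and backend", {
  set.seed(5)
  seqs <- replicate(5, paste(sample(c("A", "C", "G", "U"), 80, TRUE),
                             collapse = ""))
  for (be in c("rnafold", "inprocess")) {
    a <- vapply(fold_many(seqs, backend = be), `[[`, character(1), "dotbracket")
    b <- vapply(fold_many(seqs, backend = be), `[[`, character(1), "dotbracket")
    expect_identical(a, b)
  }
})

test_that("pair tables are involutions without self-pairs or pseudoknots", {
  set.seed(11)
  seqs <- replicate(60, paste(sample(c("A", "C", "G", "U"),
                                     sample(50:120, 1), TRUE), collapse = ""))
  for (be in c("rnafold", "inprocess")) {
    for (st in fold_many(seqs, backend = be)) {
      pt <- st$pairs
      p <- which(!is.na(pt))
      expect_true(all(pt[pt[p]] == p))       # involution
      expect_true(all(pt[p] != p))           # no self pairs
      # nesting holds because dot-bracket parsing would fail otherwise;
      # assert the round trip explicitly
      expect_identical(pairs_to_dotbracket(pt), st$dotbracket)
    }
  }
})

test_that("fold validates backend name, alphabet and minimum length", {
  expect_error(fold("ACGUACGU", backend = "nosuch", min_len = 4),
               "unknown folding backend")
  expect_error(fold(strrep("ACGX", 20)), "outside")
  expect_error(fold("ACGU", min_len = 40L), "shorter than")
})

test_that("CT files parse to the equivalent dot-bracket structure", {
  ct <- c("15 dG = -8.6 toy",
          paste(1:15, strsplit("GGGGGAAAAACCCCC", "")[[1]],
                c(0:14), c(2:15, 0), c(15:11, rep(0, 5), 5:1), 1:15))
  f <- tempfile(fileext = ".ct")
  on.exit(unlink(f))
  writeLines(ct, f)
  parsed <- parse_ct(f)
  expect_identical(parsed$structure$dotbracket, "(((((.....)))))")
  expect_equal(parsed$structure$mfe, -8.6)
  expect_identical(parsed$sequence, "GGGGGAAAAACCCCC")
})

test_that("hairpin extraction finds single stem-loops and honours the cap", {
  set.seed(21)
  # perfect 20-bp stem-loop: one hairpin spanning the whole molecule
  d <- designed_hairpin(stem = 20L, loop = 6L)
  hps <- extract_hairpins(d$structure, d$sequence)
  expect_length(hps, 1L)
  expect_equal(hps[[1]]$span, c(1L, nchar(d$sequence)))
  expect_equal(hps[[1]]$stem_levels, 20L)

  # 70-bp stem: trimmed at the base to exactly 60 pair levels
  d70 <- designed_hairpin(stem = 70L, loop = 6L)
  h70 <- extract_hairpins(d70$structure, d70$sequence, max_stem = 60L)
  expect_length(h70, 1L)
  expect_equal(h70[[1]]$stem_levels, 60L)
  expect_true(h70[[1]]$trimmed)
  # trimmed basal region excluded from the span: span starts at pair 11
  expect_equal(h70[[1]]$span, c(11L, 70L + 6L + 60L))
})

test_that("multibranch structures yield one hairpin per apical stem only", {
  # cloverleaf: three stem-loops budding from one multiloop, all on a stem
  apical <- "((((....))))"
  db <- paste0("(((..", apical, ".", apical, "..", apical, "..)))")
  seq <- paste(sample(c("A", "C", "G", "U"), nchar(db), TRUE), collapse = "")
  st <- secondary_structure(db)
  hps <- extract_hairpins(st, seq)
  expect_length(hps, oracle_count_hairpin_loops(st$pairs))
  expect_length(hps, 3L)
  # none of the three extends below the multiloop
  for (h in hps) expect_equal(h$stem_levels, 4L)
})

test_that("stem cap is never exceeded over random designed structures", {
  set.seed(31)
  for (r in 1:30) {
    d <- random_designed_hairpin()
    for (h in extract_hairpins(d$structure, d$sequence, max_stem = 18L))
      expect_lte(h$stem_levels, 18L)
  }
})

test_that("components are segmented by an explicit pair-table walk", {
  set.seed(41)
  # 30-bp perfect stem, 4-nt loop, no flanks; miRNA at positions 5-26 on the
  # 5' arm: lower stem pairs 1-4, upper stem pairs 5-26, top stem pairs 27-30
  d <- designed_hairpin(stem = 30L, loop = 4L)
  h <- d$hairpin
  cm <- segment_components(h, c(5L, 26L))
  expect_equal(cm$lower5, c(1L, 4L))
  expect_equal(cm$upper5, c(5L, 26L))
  expect_equal(cm$top5, c(27L, 30L))
  expect_equal(cm$loop, c(31L, 34L))
  # mirror sides from the explicit pair table
  pt <- h$structure$pairs
  expect_equal(cm$top3, c(35L, pt[26] - 1L))
  expect_equal(cm$upper3, c(pt[26], pt[5]))
  expect_equal(cm$lower3, c(pt[5] + 1L, 64L))

  # miRNA flush against the loop: empty top stem
  cmf <- segment_components(h, c(9L, 30L))
  expect_equal(iv_len_test(cmf$top5), 0L)
  expect_equal(iv_len_test(cmf$top3), 0L)

  # miRNA spanning the whole arm of a perfect, flankless hairpin: only the
  # upper stem and loop remain
  cma <- segment_components(h, c(1L, 30L))
  for (nm in c("basal5", "lower5", "top5", "basal3", "lower3", "top3"))
    expect_equal(iv_len_test(cma[[nm]]), 0L)
  expect_equal(cma$upper5, c(1L, 30L))
  expect_equal(cma$upper3, c(35L, 64L))
})

test_that("component intervals tile the span disjointly for random placements", {
  set.seed(51)
  for (r in 1:40) {
    d <- random_designed_hairpin()
    h <- d$hairpin
    plc <- random_placement(h)
    if (is.null(plc)) next
    cm <- segment_components(h, c(plc$start, plc$end))
    pieces <- cm[c("basal5", "lower5", "upper5", "top5", "loop",
                   "top3", "upper3", "lower3", "basal3")]
    pos <- unlist(lapply(pieces, function(x)
      if (x[1] > x[2]) integer(0) else x[1]:x[2]), use.names = FALSE)
    expect_equal(sort(pos), h$span[1]:h$span[2])   # union = span, disjoint
    expect_equal(anyDuplicated(pos), 0L)
  }
})

test_that("pre-miRNA derivation follows the pair table and the 3' overhang", {
  set.seed(61)
  d <- designed_hairpin(stem = 25L, loop = 5L)
  h <- d$hairpin
  # miRNA = whole 5' arm: pre-miRNA covers the whole hairpin, overhang
  # clipped at the span
  pre <- derive_premirna(h, c(1L, 25L), overhang = 2L)
  expect_equal(pre, c(1L, 55L))
  # overhang 0 ends exactly at the partner of the loop-distal miRNA end
  pre0 <- derive_premirna(h, c(3L, 24L), overhang = 0L)
  expect_equal(pre0, c(3L, h$structure$pairs[3]))
  # a 3-nt bulge on the 3' arm shifts the pre-miRNA 3' end by the bulge
  db <- designed_hairpin(stem = 25L, loop = 5L, bulges3 = c(9L, 10L, 11L))
  hb <- db$hairpin
  preb <- derive_premirna(hb, c(3L, 24L), overhang = 0L)
  expect_equal(preb[2], hb$structure$pairs[3])
  expect_equal(preb[2] - pre0[2], 3L)   # hand-walked: 3 extra bulged bases
})

test_that("placements off the arms are rejected", {
  set.seed(71)
  d <- designed_hairpin(stem = 20L, loop = 8L)
  h <- d$hairpin
  # interval centred on the loop
  expect_error(segment_components(h, c(15L, 34L)), "arm")
  expect_true(is.na(hairpin_arm(h, c(15L, 34L))))
  # outside the span
  expect_error(segment_components(h, c(40L, 70L)), "arm")
})
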