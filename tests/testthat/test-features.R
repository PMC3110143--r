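test_that("the default catalog is rich enough and carries the key names", {
  cat_df <- default_catalog()
  expect_gte(sum(cat_df$svm_eligible), 42L)
  # no descriptive/categorical or ppri-scoped parameter is SVM-eligible
  expect_false(any(cat_df$svm_eligible &
                     cat_df$value_kind %in% c("text", "categorical")))
  expect_false(any(cat_df$svm_eligible & cat_df$scope == "pprimirna"))
  # the parameter names reported for example predictions all resolve
  for (nm in c("pre_gc_content", "mi_a_content", "mi_c_content",
               "mi_g_content", "mi_u_content", "mi_largest_internal_loop",
               "topstem_largest_internal_loop", "lowerstem_unpaired_bases",
               "upperstem_unpaired_bases", "mi_unpaired_rate",
               "pre_unpaired_rate", "upperstem_length", "mi_length"))
    expect_true(nm %in% cat_df$name, label = nm)
})

test_that("a catalog round-trips through its YAML configuration unchanged", {
  cat_df <- default_catalog()
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_catalog(cat_df, f)
  back <- read_catalog(f)
  expect_equal(back$name, cat_df$name)
  expect_equal(back$svm_eligible, cat_df$svm_eligible)
  expect_equal(attr(back, "version"), attr(cat_df, "version"))
})

test_that("nucleotide content matches direct counting", {
  expect_equal(nucleotide_content("GCGC", "G"), 0.5)
  expect_equal(nucleotide_content("AAAA", "U"), 0.0)
  expect_true(is.na(nucleotide_content("", "A")))
  set.seed(9)
  s <- paste(sample(c("A", "C", "G", "U"), 1000, TRUE,
                    prob = c(.4, .1, .2, .3)), collapse = "")
  for (b in c("A", "C", "G", "U"))
    expect_equal(nucleotide_content(s, b), oracle_base_count(s, b) / 1000)
})

test_that("unpaired rate matches a position-by-position scan", {
  set.seed(19)
  d <- designed_hairpin(stem = 22L, loop = 6L)
  pt <- d$structure$pairs
  expect_equal(unpaired_rate(c(1L, 22L), pt), 0.0)         # perfect duplex
  expect_equal(unpaired_rate(d$hairpin$loop, pt), 1.0)     # terminal loop
  # 22-nt window with unpaired positions from designed bulges
  db <- designed_hairpin(stem = 25L, loop = 5L, bulges5 = c(8L, 12L, 16L))
  ptb <- db$structure$pairs
  expect_equal(unpaired_rate(c(1L, 22L), ptb),
               oracle_unpaired_count(1:22, ptb) / 22)
  expect_equal(unpaired_rate(c(1L, 22L), ptb), 3 / 22)
})

test_that("internal-loop statistics match a run-length oracle", {
  set.seed(29)
  d <- designed_hairpin(stem = 20L, loop = 6L)
  expect_equal(internal_loop_stats(c(1L, 20L), d$structure$pairs), c(0L, 0L))
  # one 4-nt bulge: largest run 4, single run
  db <- paste0(strrep("(", 10), "....", strrep("(", 5), "....",
               strrep(")", 15))
  st <- secondary_structure(db)
  expect_equal(internal_loop_stats(c(1L, 19L), st$pairs), c(4L, 1L))
  for (r in 1:25) {
    dd <- random_designed_hairpin()
    ivl <- c(dd$hairpin$span[1], dd$hairpin$inner[1])
    expect_equal(internal_loop_stats(ivl, dd$structure$pairs),
                 oracle_internal_loops(ivl, dd$structure$pairs))
  }
})

test_that("GU wobbles are counted once per pair and match enumeration", {
  # perfect Watson-Crick stem: none
  set.seed(39)
  d <- designed_hairpin(stem = 15L, loop = 5L)
  expect_equal(gu_wobbles(c(1L, 15L), d$structure$pairs, d$sequence), 0L)
  # a stem of five G.U pairs
  seq <- paste0("GGGGG", "AAAA", "UUUUU")
  db <- paste0("(((((", "....", ")))))")
  st <- secondary_structure(db, sequence = seq)
  expect_equal(gu_wobbles(c(1L, 5L), st$pairs, seq), 5L)
  # counting the duplex from both sides must not double count
  expect_equal(gu_wobbles(list(c(1L, 5L), c(10L, 14L)), st$pairs, seq), 5L)
  # random sequences over a designed stem vs brute-force enumeration
  for (r in 1:25) {
    dd <- random_designed_hairpin()
    ivl <- list(c(dd$hairpin$span[1], dd$hairpin$inner[1]),
                c(dd$hairpin$inner[2], dd$hairpin$span[2]))
    expect_equal(gu_wobbles(ivl, dd$structure$pairs, dd$sequence),
                 oracle_gu_count(ivl, dd$structure$pairs, dd$sequence))
  }
})

test_that("the 3' overhang is measured at the pre-miRNA base", {
  set.seed(49)
  d <- designed_hairpin(stem = 25L, loop = 5L, flank3 = 4L)
  h <- d$hairpin
  # blunt end: miRNA = whole arm, overhang 0
  pre0 <- derive_premirna(h, c(1L, 25L), overhang = 0L)
  expect_equal(overhang_3p(pre0, h$structure$pairs), 0L)
  # canonical Drosha geometry: 2-nt protrusion
  pre2 <- derive_premirna(h, c(3L, 24L), overhang = 2L)
  expect_equal(overhang_3p(pre2, h$structure$pairs), 2L)
  # constructed 3-nt protrusion
  pre3 <- derive_premirna(h, c(3L, 24L), overhang = 3L)
  expect_equal(overhang_3p(pre3, h$structure$pairs), 3L)
})

test_that("feature vectors agree with hand-computed values on a fixture", {
  set.seed(59)
  d <- designed_hairpin(stem = 30L, loop = 4L, flank5 = 5L, flank3 = 5L)
  h <- d$hairpin
  mir <- c(10L, 31L)  # positions 5-26 of the arm, 22 nt
  fv <- compute_features("fix", d$sequence, d$structure, h, mir,
                         pre_mfe = -25.0)
  expect_equal(fv$mi_length, 22L)
  expect_equal(fv$mi_pairs, 22L)
  expect_equal(fv$mi_unpaired_bases, 0L)
  expect_equal(fv$mi_unpaired_rate, 0)
  expect_equal(fv$terminalloop_length, 4L)
  expect_equal(fv$upperstem_length, 22L)
  expect_equal(fv$lowerstem_length, 4L)  # pair levels 1-4 below the miRNA
  expect_equal(fv$topstem_length, 4L)
  expect_equal(fv$basalsegment_length, 10L)
  expect_equal(fv$ppri_length, nchar(d$sequence))
  mi_seq <- substr(d$sequence, 10, 31)
  expect_equal(fv$mi_gc_content, oracle_base_count(mi_seq, "G") / 22 +
                 oracle_base_count(mi_seq, "C") / 22)
  expect_equal(fv$mi_firstbase, substr(d$sequence, 10, 10))
  expect_equal(fv$pre_mfe, -25.0)
  expect_equal(fv$ppri_mfe, d$structure$mfe)
  # determinism: identical triple gives an identical vector
  fv2 <- compute_features("fix", d$sequence, d$structure, h, mir,
                          pre_mfe = -25.0)
  expect_identical(fv, fv2)
})

test_that("absent components take the undefined-feature marker", {
  set.seed(69)
  d <- designed_hairpin(stem = 30L, loop = 4L)
  h <- d$hairpin
  # miRNA flush to the loop: top-stem parameters are markers, others real
  fv <- compute_features("fix", d$sequence, d$structure, h, c(9L, 30L))
  expect_true(is.na(fv$topstem_length))
  expect_true(is.na(fv$topstem_unpaired_rate))
  expect_true(is.na(fv$topstem_largest_internal_loop))
  expect_false(is.na(fv$upperstem_length))
  expect_false(is.na(fv$lowerstem_length))
  # and the scaler maps markers to the component-absent value -1
  sc <- fit_scaler(data.frame(topstem_length = c(2, 6)), "topstem_length")
  expect_equal(as.numeric(apply_scaler(sc, data.frame(topstem_length = NA))),
               -1)
})

test_that("content and structure invariants hold over random triples", {
  set.seed(79)
  catalog <- default_catalog()
  for (r in 1:60) {
    d <- random_designed_hairpin()
    plc <- random_placement(d$hairpin)
    if (is.null(plc)) next
    fv <- compute_features("p", d$sequence, d$structure, d$hairpin,
                           c(plc$start, plc$end), catalog = catalog)
    for (sc in c("mi", "pre", "ppri")) {
      tot <- fv[[paste0(sc, "_a_content")]] + fv[[paste0(sc, "_c_content")]] +
        fv[[paste0(sc, "_g_content")]] + fv[[paste0(sc, "_u_content")]]
      expect_equal(tot, 1, tolerance = 1e-9)
      expect_identical(fv[[paste0(sc, "_gc_content")]],
                       fv[[paste0(sc, "_c_content")]] +
                         fv[[paste0(sc, "_g_content")]])
    }
    # rate identities: unpaired_rate * length = unpaired count, exactly
    expect_equal(fv$mi_unpaired_rate * fv$mi_length, fv$mi_unpaired_bases)
    expect_equal(fv$pre_unpaired_rate * fv$pre_length, fv$pre_unpaired_bases)
    # loop statistics consistency
    if (!is.na(fv$mi_largest_internal_loop)) {
      expect_lte(fv$mi_largest_internal_loop, max(fv$mi_unpaired_bases, 0L))
      expect_identical(fv$mi_n_internal_loops == 0L,
                       fv$mi_largest_internal_loop == 0L)
    }
    # every SVM-eligible parameter is numeric (finite or the NA marker)
    elig <- svm_eligible_params(catalog)
    vals <- fv[elig]
    expect_true(all(vapply(vals, function(v)
      is.numeric(v) && (is.na(v) || is.finite(v)), logical(1))))
  }
})
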