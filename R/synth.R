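#' Recipe for synthetic pre-miRNA hairpin records
#'
#' The generator emulates miRBase-style precursor records: a GC-biased 5'
#' arm, a reverse-complement 3' arm with injected mismatches and bulges, a
#' short terminal loop, unstructured flanks, and a mature miRNA planted a
#' few nucleotides from the loop on either arm — the geometry of a Drosha
#' substrate. Defaults give realistic precursor dimensions (arms 35-50 nt,
#' loops 4-12 nt, matures 20-24 nt, ~10% mismatch, GC 0.5).
#'
#' @param arm_len `c(min, max)` 5' arm length, nt.
#' @param loop_len `c(min, max)` terminal loop length, nt.
#' @param flank_len `c(min, max)` flank length per side, nt.
#' @param mat_len `c(min, max)` mature length, nt.
#' @param mat_dist_loop `c(min, max)` mature distance from the loop, nt.
#' @param mismatch_rate per-base probability of a mismatch on the 3' arm.
#' @param bulge_rate per-base probability of a 1-nt bulge on the 3' arm.
#' @param gc GC bias of all sampled residues.
#' @param first_base_u probability that the planted mature starts with U
#'   (real matures favour a 5' U).
#' @return list of class `hairpin_recipe`.
#' @export
hairpin_recipe <- function(arm_len = c(35L, 50L), loop_len = c(4L, 12L),
                           flank_len = c(10L, 30L), mat_len = c(20L, 24L),
                           mat_dist_loop = c(0L, 4L), mismatch_rate = 0.10,
                           bulge_rate = 0.03, gc = 0.5, first_base_u = 0.5) {
  stopifnot(mismatch_rate >= 0, mismatch_rate <= 1,
            bulge_rate >= 0, bulge_rate <= 1, gc > 0, gc < 1,
            all(arm_len > 0), all(loop_len > 2), all(mat_len > 0))
  structure(list(arm_len = arm_len, loop_len = loop_len,
                 flank_len = flank_len, mat_len = mat_len,
                 mat_dist_loop = mat_dist_loop,
                 mismatch_rate = mismatch_rate, bulge_rate = bulge_rate,
                 gc = gc, first_base_u = first_base_u),
            class = "hairpin_recipe")
}

.rbase <- function(n, gc) {
  sample(c("A", "U", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

.runif_int <- function(rng) if (rng[1] >= rng[2]) rng[1] else
  sample(seq.int(rng[1], rng[2]), 1L)

.build_hairpin_seq <- function(recipe) {
  arm_n <- .runif_int(recipe$arm_len)
  loop_n <- .runif_int(recipe$loop_len)
  fl5 <- .runif_int(recipe$flank_len)
  fl3 <- .runif_int(recipe$flank_len)
  mat_n <- .runif_int(recipe$mat_len)
  dist <- .runif_int(recipe$mat_dist_loop)
  arm5 <- .rbase(arm_n, recipe$gc)
  ## plant the mature on one arm, `dist` nt from the loop
  arm <- sample(c("5p", "3p"), 1L)
  if (stats::runif(1) < recipe$first_base_u) {
    if (arm == "5p") {
      pos_in_arm <- arm_n - dist - mat_n + 1L   # mature 5' end within arm5
      if (pos_in_arm >= 1L) arm5[pos_in_arm] <- "U"
    }
  }
  comp <- chartr("ACGU", "UGCA", paste(rev(arm5), collapse = ""))
  arm3 <- strsplit(comp, "", fixed = TRUE)[[1]]
  ## inject mismatches and bulges into the 3' arm
  mm <- stats::runif(length(arm3)) < recipe$mismatch_rate
  arm3[mm] <- vapply(arm3[mm], function(b)
    sample(setdiff(c("A", "C", "G", "U"), b), 1L), character(1))
  bulge <- stats::runif(length(arm3)) < recipe$bulge_rate
  if (any(bulge)) {
    out <- character(0)
    for (i in seq_along(arm3)) {
      out <- c(out, arm3[i])
      if (bulge[i]) out <- c(out, .rbase(1L, recipe$gc))
    }
    arm3 <- out
  }
  loop <- .rbase(loop_n, recipe$gc)
  flank5 <- .rbase(fl5, recipe$gc)
  flank3 <- .rbase(fl3, recipe$gc)
  seq <- paste(c(flank5, arm5, loop, arm3, flank3), collapse = "")
  if (arm == "5p") {
    mat_start <- fl5 + arm_n - dist - mat_n + 1L
  } else {
    mat_start <- fl5 + arm_n + loop_n + dist + 1L
    if (stats::runif(1) < recipe$first_base_u) {
      s <- strsplit(seq, "", fixed = TRUE)[[1]]
      s[mat_start] <- "U"
      seq <- paste(s, collapse = "")
    }
  }
  list(sequence = seq, mat_start = mat_start,
       mat_end = mat_start + mat_n - 1L, arm = arm)
}

#' Generate one synthetic precursor record
#'
#' Builds a hairpin per the recipe and verifies under the pinned backend that
#' the planted mature lies on one arm of a single stem-loop (the same test
#' applied by [filter_positives()]); regenerates on failure up to `retries`
#' times.
#'
#' @param recipe a [hairpin_recipe()].
#' @param accession record identifier.
#' @param backend folding backend.
#' @param retries regeneration budget.
#' @return one-row data.frame (`accession`, `sequence`, `mat_start`,
#'   `mat_end`, `group = "synthetic"`) with the folded
#'   [secondary_structure()] as attribute `structure`.
#' @export
make_hairpin <- function(recipe, accession = "synth-1", backend = "rnafold",
                         retries = 30L) {
  for (r in seq_len(retries)) {
    cand <- .build_hairpin_seq(recipe)
    struct <- fold(cand$sequence, backend = backend)
    hps <- extract_hairpins(struct, cand$sequence)
    mat <- iv(cand$mat_start, cand$mat_end)
    ok <- FALSE
    for (h in hps) {
      if (iv_contains(h$span, mat) && !is.na(hairpin_arm(h, mat))) {
        ok <- TRUE
        break
      }
    }
    if (ok) {
      rec <- data.frame(accession = accession, sequence = cand$sequence,
                        mat_start = cand$mat_start, mat_end = cand$mat_end,
                        group = "synthetic", stringsAsFactors = FALSE)
      attr(rec, "structure") <- struct
      return(rec)
    }
  }
  stop("retry budget exhausted: recipe too noisy to fold into a clean ",
       "stem-loop", call. = FALSE)
}

#' Generate a labeled synthetic training corpus
#'
#' Positives are recipe hairpins with their planted matures; negatives are
#' random-start decoys on the very same records, so class separability comes
#' only from placement geometry (distance to loop, overhang, duplex
#' structure), exactly as in real corpus construction.
#'
#' @param recipe a [hairpin_recipe()].
#' @param n_pos number of positive records (>= 20).
#' @param level positive:negative ratio 1:level.
#' @param backend folding backend.
#' @param catalog parameter catalog.
#' @return a [assemble_level()] `level_dataset`; attributes `records` and
#'   `features` give access to the underlying rows.
#' @export
make_labeled_corpus <- function(recipe, n_pos, level = 1L,
                                backend = "rnafold",
                                catalog = default_catalog()) {
  if (n_pos < 20L) stop("n_pos must be >= 20", call. = FALSE)
  recs <- do.call(rbind, lapply(seq_len(n_pos), function(i)
    make_hairpin(recipe, accession = sprintf("synth-%04d", i),
                 backend = backend)))
  filtered <- filter_positives(recs, backend = backend)
  feats <- build_training_features(filtered,
                                   n_neg_per_record = level + 1L,
                                   backend = backend, catalog = catalog)
  ds <- assemble_level(feats$positives, feats$negatives, level)
  attr(ds, "records") <- recs
  attr(ds, "features") <- feats
  ds
}

## order-2 Markov chain fitted on a seed sequence; suppresses the long-range
## complementarity that would create strong accidental hairpins
.markov2_sample <- function(seed_seq, n) {
  bases <- c("A", "C", "G", "U")
  s <- strsplit(seed_seq, "", fixed = TRUE)[[1]]
  counts <- array(1, dim = c(4, 4, 4), dimnames = list(bases, bases, bases))
  if (length(s) >= 3L)
    for (i in 3:length(s))
      counts[s[i - 2], s[i - 1], s[i]] <- counts[s[i - 2], s[i - 1], s[i]] + 1
  out <- character(n)
  out[1:2] <- sample(bases, 2L, replace = TRUE)
  for (i in 3:n)
    out[i] <- sample(bases, 1L, prob = counts[out[i - 2], out[i - 1], ])
  paste(out, collapse = "")
}

#' Generate a synthetic genome with planted precursor hairpins
#'
#' The background is sampled from an order-2 Markov model fitted to the
#' shuffled composition of the planted records, which keeps local
#' composition realistic while giving the background low hairpin propensity;
#' records are planted at non-overlapping uniform positions.
#'
#' @param recipe a [hairpin_recipe()].
#' @param n_plants number of precursors to plant.
#' @param genome_len total genome length, nt.
#' @param backend folding backend.
#' @return list with `sequence`, `truth` (data.frame `id`, `start`, `end`,
#'   `strand`, mature coordinates in genome space), `records`, and
#'   `plant_starts`.
#' @export
make_genome <- function(recipe, n_plants, genome_len, backend = "rnafold") {
  recs <- if (n_plants > 0L)
    do.call(rbind, lapply(seq_len(n_plants), function(i)
      make_hairpin(recipe, accession = sprintf("plant-%03d", i),
                   backend = backend)))
  else NULL
  lens <- if (is.null(recs)) integer(0) else nchar(recs$sequence)
  if (sum(lens) + 10L * n_plants > genome_len)
    stop("genome too short for ", n_plants, " plants (overcrowding)",
         call. = FALSE)
  seed_seq <- if (is.null(recs))
    paste(.rbase(2000L, recipe$gc), collapse = "")
  else paste(sample(strsplit(paste(recs$sequence, collapse = ""), "",
                             fixed = TRUE)[[1]]), collapse = "")
  genome <- .markov2_sample(seed_seq, genome_len)
  truth <- data.frame(id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      accession = character(0), stringsAsFactors = FALSE)
  starts <- integer(0)
  if (n_plants > 0L) {
    ## draw non-overlapping start positions uniformly (rejection sampling)
    for (tries in seq_len(1000L)) {
      starts <- sort(sample.int(genome_len - max(lens) - 1L, n_plants))
      if (n_plants == 1L || all(diff(starts) > max(lens) + 10L)) break
      starts <- integer(0)
    }
    if (length(starts) == 0L)
      stop("could not place plants without overlap (overcrowding)",
           call. = FALSE)
    g <- strsplit(genome, "", fixed = TRUE)[[1]]
    for (k in seq_len(n_plants)) {
      rec <- recs[k, , drop = FALSE]
      at <- starts[k]
      g[at:(at + nchar(rec$sequence) - 1L)] <-
        strsplit(rec$sequence, "", fixed = TRUE)[[1]]
      truth <- rbind(truth, data.frame(
        id = "synthetic_genome", start = at + rec$mat_start - 1L,
        end = at + rec$mat_end - 1L, strand = "+",
        accession = rec$accession, stringsAsFactors = FALSE))
    }
    genome <- paste(g, collapse = "")
  }
  list(sequence = genome, truth = truth, records = recs,
       plant_starts = starts)
}

#' Write a synthetic genome and its truth annotations
#'
#' @param genome result of [make_genome()].
#' @param prefix output prefix; writes `<prefix>.fa`, `<prefix>.truth.gff3`
#'   and `<prefix>.manifest.json`.
#' @param manifest named list recorded alongside (recipe, seed, sizes).
#' @return invisible character vector of files written.
#' @export
write_genome_outputs <- function(genome, prefix, manifest = list()) {
  fa <- paste0(prefix, ".fa")
  gff <- paste0(prefix, ".truth.gff3")
  mf <- paste0(prefix, ".manifest.json")
  write_fasta(stats::setNames(genome$sequence, "synthetic_genome"), fa)
  if (nrow(genome$truth) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = genome$truth$id,
      ranges = IRanges::IRanges(genome$truth$start, genome$truth$end),
      strand = genome$truth$strand)
    S4Vectors::mcols(gr)$type <- "miRNA"
    S4Vectors::mcols(gr)$ID <- genome$truth$accession
    rtracklayer::export(gr, gff, format = "gff3")
  } else writeLines("##gff-version 3", gff)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE), mf)
  invisible(c(fa, gff, mf))
}
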