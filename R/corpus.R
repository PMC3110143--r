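.default_kingdom_table <- c(Metazoa = "animal", Viridiplantae = "plant",
                            Viruses = "virus")

.map_group <- function(taxon, kingdom_table = .default_kingdom_table) {
  hit <- kingdom_table[names(kingdom_table) %in% taxon]
  if (length(hit)) unname(hit[1]) else "other"
}

#' Load precursor records with mature-miRNA annotations
#'
#' Supported formats:
#' \describe{
#'   \item{`tsv`}{columns `accession`, `sequence`, `mat_start`, `mat_end`,
#'     `group` (1-based inclusive mature coordinates).}
#'   \item{`annotated-fasta`}{description line tokens `mature=START-END`
#'     (repeatable) and `group=animal|plant|virus|other`.}
#'   \item{`mirbase-dat`}{EMBL-style records: `ID` line, optional `OC`
#'     taxonomy lines (mapped through `kingdom_table`), `FT miRNA a..b`
#'     features, `SQ` sequence block, `//` terminator.}
#' }
#' A precursor with several matures yields one record row per mature.
#' Records whose mature coordinates fall outside the sequence are rejected
#' and reported in the `rejected` attribute.
#'
#' @param path input file.
#' @param format one of `"tsv"`, `"annotated-fasta"`, `"mirbase-dat"`.
#' @param kingdom_table named map from taxonomy term to group label.
#' @return data.frame with columns `accession`, `sequence` (RNA, uppercase),
#'   `mat_start`, `mat_end`, `group`; attribute `rejected`.
#' @export
load_records <- function(path, format = c("tsv", "annotated-fasta", "mirbase-dat"),
                         kingdom_table = .default_kingdom_table) {
  format <- match.arg(format)
  recs <- switch(format,
    "tsv" = {
      df <- utils::read.delim(path, stringsAsFactors = FALSE)
      data.frame(accession = as.character(df$accession),
                 sequence = df$sequence,
                 mat_start = as.integer(df$mat_start),
                 mat_end = as.integer(df$mat_end),
                 group = as.character(df$group), stringsAsFactors = FALSE)
    },
    "annotated-fasta" = {
      ss <- Biostrings::readBStringSet(path)
      rows <- lapply(seq_along(ss), function(k) {
        desc <- names(ss)[k]
        acc <- sub("\\s.*$", "", desc)
        mats <- regmatches(desc, gregexpr("mature=\\d+-\\d+", desc))[[1]]
        grp <- regmatches(desc, regexpr("group=\\S+", desc))
        grp <- if (length(grp)) sub("group=", "", grp) else "other"
        if (length(mats) == 0L) return(NULL)
        se <- do.call(rbind, lapply(mats, function(m) {
          as.integer(strsplit(sub("mature=", "", m), "-")[[1]])
        }))
        data.frame(accession = acc, sequence = as.character(ss[[k]]),
                   mat_start = se[, 1], mat_end = se[, 2], group = grp,
                   stringsAsFactors = FALSE)
      })
      do.call(rbind, rows)
    },
    "mirbase-dat" = {
      lines <- readLines(path)
      breaks <- c(0L, which(lines == "//"))
      rows <- list()
      for (b in seq_len(length(breaks) - 1L)) {
        blk <- lines[(breaks[b] + 1L):(breaks[b + 1L] - 1L)]
        idl <- grep("^ID\\s", blk, value = TRUE)
        if (!length(idl)) next
        acc <- strsplit(trimws(sub("^ID\\s+", "", idl[1])), "\\s+")[[1]][1]
        oc <- paste(sub("^OC\\s+", "", grep("^OC\\s", blk, value = TRUE)),
                    collapse = " ")
        taxa <- trimws(strsplit(gsub("\\.", "", oc), ";")[[1]])
        grp <- .map_group(taxa, kingdom_table)
        ft <- grep("^FT\\s+miRNA\\s+\\d+\\.\\.\\d+", blk, value = TRUE)
        sq_at <- grep("^SQ", blk)
        if (!length(sq_at)) next
        sq <- gsub("[^A-Za-z]", "", paste(blk[(sq_at + 1L):length(blk)],
                                          collapse = ""))
        for (f in ft) {
          m <- regmatches(f, regexpr("\\d+\\.\\.\\d+", f))
          se <- as.integer(strsplit(m, "\\.\\.")[[1]])
          rows[[length(rows) + 1L]] <- data.frame(
            accession = acc, sequence = sq, mat_start = se[1], mat_end = se[2],
            group = grp, stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    })
  if (is.null(recs) || nrow(recs) == 0L)
    stop("no records parsed from ", path, call. = FALSE)
  recs$sequence <- normalize_rna(recs$sequence)
  bad <- recs$mat_start < 1L | recs$mat_end > nchar(recs$sequence) |
    recs$mat_start > recs$mat_end
  rejected <- recs[bad, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- "mature coordinates out of bounds"
    message(nrow(rejected), " record(s) rejected: coordinates out of bounds")
  }
  recs <- recs[!bad, , drop = FALSE]
  rownames(recs) <- NULL
  attr(recs, "rejected") <- rejected
  recs
}

#' Filter positive records on refolded structure
#'
#' Each precursor is refolded with the pinned backend. A record is kept only
#' if its mature miRNA lies on one arm of a single stem-loop: records whose
#' mature cannot be covered by a simple hairpin (budding stems / multibranch)
#' or whose mature overlaps the terminal loop by more than
#' `loop_overlap_max` nucleotides are rejected.
#'
#' The function is idempotent: filtering the kept set again changes nothing.
#'
#' @param records data.frame from [load_records()].
#' @param backend folding backend name.
#' @param max_stem stem-depth cap in pair levels.
#' @param loop_overlap_max tolerated mature/loop overlap, nucleotides.
#' @return list with `kept` (records plus columns `arm`, `hairpin_index`),
#'   `rejected` (records plus `reason`), and `structures` (named list of
#'   [secondary_structure()] keyed by accession).
#' @export
filter_positives <- function(records, backend = "rnafold", max_stem = 60L,
                             loop_overlap_max = 3L) {
  useq <- !duplicated(records$accession)
  structs <- tryCatch(
    fold_many(records$sequence[useq], backend = backend),
    error = function(e) stop("folding failed: ", conditionMessage(e),
                             call. = FALSE))
  names(structs) <- records$accession[useq]

  arm <- character(nrow(records))
  hidx <- integer(nrow(records))
  reason <- character(nrow(records))
  hp_cache <- list()
  for (i in seq_len(nrow(records))) {
    acc <- records$accession[i]
    if (is.null(hp_cache[[acc]]))
      hp_cache[[acc]] <- extract_hairpins(structs[[acc]], records$sequence[i],
                                          max_stem = max_stem)
    hps <- hp_cache[[acc]]
    mat <- iv(records$mat_start[i], records$mat_end[i])
    arm[i] <- NA_character_
    reason[i] <- "no hairpin covers the mature miRNA (budding stems)"
    for (k in seq_along(hps)) {
      h <- hps[[k]]
      if (!iv_contains(h$span, mat)) next
      a <- hairpin_arm(h, mat, loop_overlap_max)
      if (!is.na(a)) {
        arm[i] <- a
        hidx[i] <- k
        reason[i] <- ""
        break
      }
      reason[i] <- "mature miRNA located in the terminal loop"
    }
  }
  keep <- !is.na(arm) & reason == ""
  kept <- records[keep, , drop = FALSE]
  kept$arm <- arm[keep]
  kept$hairpin_index <- hidx[keep]
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) rejected$reason <- reason[!keep]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected, structures = structs)
}

#' Generate random-start decoy candidates for one record
#'
#' Decoys share the positive record's ppri-miRNA sequence byte-for-byte; only
#' the putative mature start moves. Starts are drawn uniformly without
#' replacement from positions on the same arm whose interval stays inside the
#' hairpin and which differ from the true start by at least `min_shift`
#' nucleotides.
#'
#' @param record one-row data.frame (a kept record from [filter_positives()]).
#' @param hairpin the hairpin hosting the true mature.
#' @param n number of decoys requested.
#' @param min_shift minimum start shift (>= 1; default 5).
#' @param loop_overlap_max tolerated candidate/loop overlap.
#' @return data.frame with columns `accession`, `start`, `end`, `shift`,
#'   `arm`; fewer than `n` rows (with a message) if the ppri admits fewer.
#' @export
make_random_start_negatives <- function(record, hairpin, n, min_shift = 5L,
                                        loop_overlap_max = 3L) {
  min_shift <- stopifnot_scalar_int(min_shift, "min_shift")
  if (min_shift < 1L)
    stop("min_shift must be >= 1 (a zero shift reproduces the positive)",
         call. = FALSE)
  s <- record$mat_start
  len <- record$mat_end - record$mat_start + 1L
  arm <- record$arm %||% hairpin_arm(hairpin, iv(s, record$mat_end),
                                     loop_overlap_max)
  pt <- hairpin$structure$pairs
  span <- hairpin$span
  cand_starts <- seq.int(span[1], span[2] - len + 1L)
  adm <- cand_starts[abs(cand_starts - s) >= min_shift]
  ok <- vapply(adm, function(ss) {
    a <- hairpin_arm(hairpin, iv(ss, ss + len - 1L), loop_overlap_max)
    identical(a, arm) && any(!is.na(pt[seq.int(ss, ss + len - 1L)]))
  }, logical(1))
  adm <- adm[ok]
  if (length(adm) == 0L) {
    message("record ", record$accession, ": no admissible decoy start")
    return(data.frame(accession = character(0), start = integer(0),
                      end = integer(0), shift = integer(0),
                      arm = character(0), stringsAsFactors = FALSE))
  }
  k <- min(n, length(adm))
  if (k < n)
    message("record ", record$accession, ": only ", k, " of ", n,
            " decoys available")
  starts <- if (length(adm) == 1L) adm else sample(adm, k)
  data.frame(accession = record$accession, start = starts,
             end = starts + len - 1L, shift = starts - s,
             arm = arm, stringsAsFactors = FALSE)
}

#' Assemble a level-k training dataset
#'
#' A level-k dataset pairs every positive example with k decoys: negatives
#' are sampled without replacement to exactly `level` times the positive
#' count, then positives and negatives are shuffled together. Sampling is
#' deterministic under the caller's RNG state.
#'
#' @param positives data.frame of positive feature rows (see
#'   [build_training_features()]).
#' @param negatives data.frame of negative feature rows.
#' @param level positive:negative ratio 1:level (integer 1-20).
#' @return object of class `level_dataset`: list with `level`, `data`
#'   (feature rows plus `label` factor with levels `negative`, `positive`),
#'   `n_pos`, `n_neg`.
#' @export
assemble_level <- function(positives, negatives, level) {
  level <- stopifnot_scalar_int(level, "level")
  need <- level * nrow(positives)
  if (nrow(negatives) < need)
    stop("insufficient negatives: need ", need, ", have ", nrow(negatives),
         " (shortfall ", need - nrow(negatives), ")", call. = FALSE)
  neg <- negatives[sample(nrow(negatives), need), , drop = FALSE]
  pos <- positives
  pos$label <- "positive"
  neg$label <- "negative"
  common <- intersect(names(pos), names(neg))
  dat <- rbind(pos[, common, drop = FALSE], neg[, common, drop = FALSE])
  dat <- dat[sample(nrow(dat)), , drop = FALSE]
  rownames(dat) <- NULL
  dat$label <- factor(dat$label, levels = c("negative", "positive"))
  structure(list(level = level, data = dat, n_pos = nrow(pos),
                 n_neg = nrow(neg)), class = "level_dataset")
}

#' @export
print.level_dataset <- function(x, ...) {
  cat(sprintf("level_dataset: level %d, %d positives + %d negatives\n",
              x$level, x$n_pos, x$n_neg))
  invisible(x)
}

#' Compute labeled feature rows for a filtered corpus
#'
#' For every kept record the true mature placement yields one positive row
#' and `n_neg_per_record` random-start decoys yield negative rows, all
#' computed on the same folding of the shared ppri-miRNA. Provenance columns
#' `accession` and `shift` (0 for positives) are retained.
#'
#' @param filtered result of [filter_positives()].
#' @param n_neg_per_record decoys per record (>= the highest level you plan
#'   to assemble).
#' @param backend folding backend (for pre-miRNA refolds).
#' @param catalog parameter catalog.
#' @param min_shift minimum decoy shift.
#' @param loop_overlap_max tolerated candidate/loop overlap.
#' @return list with data.frames `positives` and `negatives`.
#' @export
build_training_features <- function(filtered, n_neg_per_record = 2L,
                                    backend = "rnafold",
                                    catalog = default_catalog(),
                                    min_shift = 5L, loop_overlap_max = 3L) {
  kept <- filtered$kept
  pos_rows <- list()
  neg_rows <- list()
  for (i in seq_len(nrow(kept))) {
    rec <- kept[i, , drop = FALSE]
    struct <- filtered$structures[[rec$accession]]
    hps <- extract_hairpins(struct, rec$sequence)
    h <- hps[[rec$hairpin_index]]
    negs <- make_random_start_negatives(rec, h, n_neg_per_record,
                                        min_shift = min_shift,
                                        loop_overlap_max = loop_overlap_max)
    cands <- data.frame(start = c(rec$mat_start, negs$start),
                        end = c(rec$mat_end, negs$end))
    mfe_fun <- function(pres) {
      subseqs <- substr(rep(rec$sequence, nrow(pres)), pres[, 1], pres[, 2])
      vapply(fold_many(subseqs, backend = backend, min_len = 10L),
             `[[`, numeric(1), "mfe")
    }
    ft <- candidate_feature_table(rec$accession, rec$sequence, struct, h,
                                  cands, pre_mfe_fun = mfe_fun,
                                  catalog = catalog,
                                  loop_overlap_max = loop_overlap_max)
    ft$accession <- rec$accession
    ft$shift <- c(0L, negs$shift)
    ft$group <- rec$group
    pos_rows[[length(pos_rows) + 1L]] <- ft[1, , drop = FALSE]
    if (nrow(ft) > 1L)
      neg_rows[[length(neg_rows) + 1L]] <- ft[-1, , drop = FALSE]
  }
  list(positives = do.call(rbind, pos_rows),
       negatives = do.call(rbind, neg_rows))
}
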