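#' Split a long sequence into overlapping analysis windows
#'
#' Sequences no longer than `window` are returned whole; otherwise fragments
#' start every `window - overlap` nucleotides and the final fragment ends at
#' the sequence end, so every position is covered and any structure shorter
#' than `overlap` appears intact in at least one fragment.
#'
#' @param seq sequence string.
#' @param window fragment length (default 500).
#' @param overlap fragment overlap (default 200); `window > overlap > 0`.
#' @return data.frame with `start`, `end` (1-based closed, parent
#'   coordinates) and `fragment` (the subsequence).
#' @export
split_sequence <- function(seq, window = 500L, overlap = 200L) {
  if (!(window > overlap && overlap > 0L))
    stop("require window > overlap > 0", call. = FALSE)
  n <- nchar(seq)
  if (n <= window)
    return(data.frame(start = 1L, end = n, fragment = seq,
                      stringsAsFactors = FALSE))
  step <- window - overlap
  starts <- seq.int(1L, n, by = step)
  starts <- starts[starts == 1L | starts < n - overlap + 1L]
  ends <- pmin(starts + window - 1L, n)
  data.frame(start = starts, end = ends,
             fragment = substring(seq, starts, ends),
             stringsAsFactors = FALSE)
}

#' Enumerate every candidate mature-miRNA placement in a hairpin
#'
#' Slides windows of every length in `len_range` along both arms one
#' nucleotide at a time. A candidate must lie inside the hairpin span (the
#' basal trim is already excluded from the span), overlap the terminal loop
#' by at most `loop_overlap_max` nucleotides, and contain at least one
#' paired base (otherwise no duplex geometry exists to segment).
#'
#' @param h hairpin.
#' @param len_range `c(min, max)` candidate lengths (default 18-26 nt).
#' @param loop_overlap_max tolerated candidate/loop overlap.
#' @return data.frame with `start`, `end`, `arm`.
#' @export
enumerate_candidates <- function(h, len_range = c(18L, 26L),
                                 loop_overlap_max = 3L) {
  pt <- h$structure$pairs
  p <- h$inner[1]; q <- h$inner[2]
  rows <- list()
  for (len in seq.int(len_range[1], len_range[2])) {
    ## 5' arm: end may protrude into the loop by <= loop_overlap_max
    e_max <- min(p + loop_overlap_max, h$span[2])
    if (e_max - len + 1L >= h$span[1]) {
      starts <- seq.int(h$span[1], e_max - len + 1L)
      ends <- starts + len - 1L
      keep <- ends - p <= loop_overlap_max & ends <= h$span[2]
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          start = starts[keep], end = ends[keep], arm = "5p",
          stringsAsFactors = FALSE)
    }
    ## 3' arm: start may protrude into the loop
    s_min <- max(q - loop_overlap_max, h$span[1])
    if (s_min + len - 1L <= h$span[2]) {
      starts <- seq.int(s_min, h$span[2] - len + 1L)
      keep <- q - starts <= loop_overlap_max
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          start = starts[keep], end = starts[keep] + len - 1L, arm = "3p",
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      arm = character(0), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  ## require at least one paired base and a valid arm assignment
  ok <- vapply(seq_len(nrow(out)), function(i) {
    ivl <- iv(out$start[i], out$end[i])
    !is.na(hairpin_arm(h, ivl, loop_overlap_max)) &&
      any(!is.na(pt[iv_seq(ivl)]))
  }, logical(1))
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Do a predicted and a true mature interval match?
#'
#' A prediction matches when each of its ends deviates from the truth by at
#' most `tol` nucleotides (predictions missing up to `tol` nucleotides from
#' either end still count).
#'
#' @param predicted,truth intervals `c(start, end)` on the same parent and
#'   strand.
#' @param tol per-end tolerance in nucleotides (default 3).
#' @return logical.
#' @export
match_positive <- function(predicted, truth, tol = 3L) {
  abs(predicted[1] - truth[1]) <= tol && abs(predicted[2] - truth[2]) <= tol
}

#' Consolidate positive placements into miRNA coding regions
#'
#' Overlapping positive mature intervals on the same parent, strand and arm
#' are merged by single linkage; each resulting region is the exact union of
#' its members and reports the supporting placement count, the best decision
#' value and the best-scoring representative placement. The result is
#' invariant to input order.
#'
#' @param placements data.frame of positive placements with columns `id`,
#'   `strand`, `arm`, `mi_start`, `mi_end`, `svm_score`.
#' @return data.frame with `id`, `strand`, `arm`, `start`, `end`,
#'   `n_support`, `best_score`, `rep_start`, `rep_end`.
#' @export
consolidate_regions <- function(placements) {
  if (nrow(placements) == 0L)
    return(data.frame(id = character(0), strand = character(0),
                      arm = character(0), start = integer(0),
                      end = integer(0), n_support = integer(0),
                      best_score = numeric(0), rep_start = integer(0),
                      rep_end = integer(0), stringsAsFactors = FALSE))
  out <- list()
  for (key in unique(paste(placements$id, placements$strand, placements$arm))) {
    sel <- paste(placements$id, placements$strand, placements$arm) == key
    sub <- placements[sel, , drop = FALSE]
    sub <- sub[order(sub$mi_start, sub$mi_end), , drop = FALSE]
    grp <- integer(nrow(sub))
    g <- 1L; grp[1] <- 1L
    hi <- sub$mi_end[1]
    if (nrow(sub) > 1L) for (i in 2:nrow(sub)) {
      if (sub$mi_start[i] > hi) g <- g + 1L
      grp[i] <- g
      hi <- max(hi, sub$mi_end[i])
    }
    for (gg in seq_len(g)) {
      m <- sub[grp == gg, , drop = FALSE]
      best <- which.max(m$svm_score)
      out[[length(out) + 1L]] <- data.frame(
        id = m$id[1], strand = m$strand[1], arm = m$arm[1],
        start = min(m$mi_start), end = max(m$mi_end),
        n_support = nrow(m), best_score = m$svm_score[best],
        rep_start = m$mi_start[best], rep_end = m$mi_end[best],
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$id, res$start, res$arm), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.scan_strand <- function(id, seq, bundle, strand, window, overlap, len_range,
                         loop_overlap_max, flank, context, max_stem,
                         min_hairpin_arm, catalog, backend) {
  frags <- split_sequence(seq, window, overlap)
  structs <- fold_many(frags$fragment, backend = backend)
  ## collect hairpin spans in parent coordinates; deduplicate so each
  ## stem-loop is analysed once with full parent-sequence context
  spans <- list()
  for (f in seq_len(nrow(frags))) {
    off <- frags$start[f] - 1L
    for (h in extract_hairpins(structs[[f]], frags$fragment[f],
                               max_stem = max_stem)) {
      if (iv_len(h$arm5) < min_hairpin_arm ||
          iv_len(h$arm3) < min_hairpin_arm) next
      spans[[length(spans) + 1L]] <- c(h$span[1] + off, h$span[2] + off)
    }
  }
  if (length(spans) == 0L) return(NULL)
  spans <- unique(do.call(rbind, spans))
  ## refine each span to a fixed point under refolding in parent-sequence
  ## context: spans discovered in different fragments converge to the same
  ## canonical anchor, making results independent of window boundaries
  n <- nchar(seq)
  current <- spans
  keep_h <- vector("list", nrow(spans))
  keep_ws <- integer(nrow(spans))
  keep_struct <- vector("list", nrow(spans))
  keep_seq <- character(nrow(spans))
  active <- rep(TRUE, nrow(spans))
  for (iter in 1:3) {
    if (!any(active)) break
    ws <- pmax(1L, current[active, 1] - flank)
    we <- pmin(n, current[active, 2] + flank)
    wseqs <- substring(seq, ws, we)
    wstructs <- fold_many(wseqs, backend = backend, min_len = 10L)
    idx <- which(active)
    for (j in seq_along(idx)) {
      k <- idx[j]
      hps <- extract_hairpins(wstructs[[j]], wseqs[j], max_stem = max_stem)
      local_span <- c(current[k, 1] - ws[j] + 1L, current[k, 2] - ws[j] + 1L)
      ovl <- if (length(hps))
        vapply(hps, function(h) iv_overlap(h$span, local_span), integer(1))
      else integer(0)
      if (length(ovl) == 0L || max(ovl) == 0L) {
        active[k] <- FALSE
        keep_h[k] <- list(NULL)
        next
      }
      h <- hps[[which.max(ovl)]]
      new_span <- c(h$span[1] + ws[j] - 1L, h$span[2] + ws[j] - 1L)
      keep_h[[k]] <- h
      keep_ws[k] <- ws[j]
      keep_struct[[k]] <- wstructs[[j]]
      keep_seq[k] <- wseqs[j]
      if (all(new_span == current[k, ])) active[k] <- FALSE
      else current[k, ] <- new_span
    }
  }
  ## drop lost spans and duplicates that converged to the same anchor
  ok <- !vapply(keep_h, is.null, logical(1))
  dup <- duplicated(current)
  sel_idx <- which(ok & !dup)
  ## enumerate candidate placements + their pre intervals (parent coords)
  cand_rows <- list()
  for (k in sel_idx) {
    h <- keep_h[[k]]
    if (iv_len(h$arm5) < min_hairpin_arm ||
        iv_len(h$arm3) < min_hairpin_arm) next
    cands <- enumerate_candidates(h, len_range, loop_overlap_max)
    if (nrow(cands) == 0L) next
    pres <- t(vapply(seq_len(nrow(cands)), function(i)
      derive_premirna(h, iv(cands$start[i], cands$end[i]),
                      loop_overlap_max = loop_overlap_max), integer(2)))
    off <- keep_ws[k] - 1L
    cand_rows[[length(cand_rows) + 1L]] <- data.frame(
      mi_s = cands$start + off, mi_e = cands$end + off,
      pre_s = pres[, 1] + off, pre_e = pres[, 2] + off)
  }
  if (length(cand_rows) == 0L) return(NULL)
  cand <- unique(do.call(rbind, cand_rows))
  ## feature context anchored on each candidate's pre-miRNA: the pre plus
  ## `context` nt per side, the flank a typical precursor record carries;
  ## this makes features comparable with record-based training corpora and
  ## independent of how deep the discovered stem happens to run
  cand$win_s <- pmax(1L, cand$pre_s - context)
  cand$win_e <- pmin(nchar(seq), cand$pre_e + context)
  wkey <- paste(cand$win_s, cand$win_e)
  uw <- !duplicated(wkey)
  wins <- cand[uw, c("win_s", "win_e"), drop = FALSE]
  wstructs <- fold_many(substring(seq, wins$win_s, wins$win_e),
                        backend = backend, min_len = 10L)
  names(wstructs) <- wkey[uw]
  rows <- list()
  for (key in unique(wkey)) {
    sel <- cand[wkey == key, , drop = FALSE]
    ws <- sel$win_s[1]; we <- sel$win_e[1]
    wseq <- substring(seq, ws, we)
    st <- wstructs[[key]]
    hps <- extract_hairpins(st, wseq, max_stem = max_stem)
    if (length(hps) == 0L) next
    pre_local <- c(sel$pre_s[1] - ws + 1L, sel$pre_e[1] - ws + 1L)
    ovl <- vapply(hps, function(h) iv_overlap(h$span, pre_local), integer(1))
    if (max(ovl) == 0L) next
    h <- hps[[which.max(ovl)]]
    mi_local <- data.frame(start = sel$mi_s - ws + 1L,
                           end = sel$mi_e - ws + 1L)
    ok <- vapply(seq_len(nrow(mi_local)), function(i)
      !is.na(hairpin_arm(h, iv(mi_local$start[i], mi_local$end[i]),
                         loop_overlap_max)) &&
        any(!is.na(h$structure$pairs[seq.int(mi_local$start[i],
                                             mi_local$end[i])])),
      logical(1))
    if (!any(ok)) next
    mfe_fun <- function(pres) {
      subseqs <- substring(wseq, pres[, 1], pres[, 2])
      vapply(fold_many(subseqs, backend = backend, min_len = 10L),
             `[[`, numeric(1), "mfe")
    }
    ft <- candidate_feature_table(id, wseq, st, h,
                                  mi_local[ok, , drop = FALSE],
                                  pre_mfe_fun = mfe_fun, catalog = catalog,
                                  loop_overlap_max = loop_overlap_max)
    ft$mi_start <- ft$mi_start + ws - 1L
    ft$mi_end <- ft$mi_end + ws - 1L
    ft$pre_start <- ft$pre_start + ws - 1L
    ft$pre_end <- ft$pre_end + ws - 1L
    rows[[length(rows) + 1L]] <- ft
  }
  if (length(rows) == 0L) return(NULL)
  plc <- do.call(rbind, rows)
  plc$strand <- strand
  if (strand == "-") {
    n <- nchar(seq)
    tmp_s <- n - plc$mi_end + 1L
    plc$mi_end <- n - plc$mi_start + 1L
    plc$mi_start <- tmp_s
    tmp_s <- n - plc$pre_end + 1L
    plc$pre_end <- n - plc$pre_start + 1L
    plc$pre_start <- tmp_s
  }
  plc
}

#' Predict probable miRNA coding regions in query sequences
#'
#' The full scanning pipeline: long sequences are cut into overlapping
#' windows and folded to discover stem-loops; each unique stem-loop is
#' re-examined in a ppri context window cut from the parent sequence (so
#' results do not depend on where window boundaries fell); every possible
#' mature placement is enumerated and scored with the full parameter
#' catalog; placements must pass the bundle's range filter and obtain a
#' positive SVM decision value to be called positive; and positive
#' placements are consolidated into most probable miRNA coding regions.
#'
#' @param seqs named character vector of query sequences (DNA or RNA), or a
#'   data.frame from [read_fasta()].
#' @param bundle a trained [train_svm()] model bundle (pins the backend).
#' @param window,overlap windowing parameters (500/200 nt defaults).
#' @param len_range candidate mature length range.
#' @param loop_overlap_max tolerated candidate/loop overlap.
#' @param flank refold flank around a discovered stem-loop during candidate
#'   enumeration, nucleotides.
#' @param context ppri feature context per side of a candidate's pre-miRNA,
#'   nucleotides (mirrors the flanking sequence a precursor record carries).
#' @param max_stem stem-depth cap in pair levels.
#' @param min_hairpin_arm minimum arm length for a scanned stem-loop.
#' @param both_strands also scan the reverse complement.
#' @param catalog parameter catalog (must match the bundle's).
#' @return list with `placements` (all scored candidates: coordinates,
#'   feature values, `svm_score`, `range_pass`, `verdict`) and `regions`
#'   (consolidated coding regions of the positive placements).
#' @export
predict_mirnas <- function(seqs, bundle, window = 500L, overlap = 200L,
                           len_range = c(18L, 26L), loop_overlap_max = 3L,
                           flank = 20L, context = 40L, max_stem = 60L,
                           min_hairpin_arm = 18L, both_strands = FALSE,
                           catalog = default_catalog()) {
  if (is.data.frame(seqs)) seqs <- stats::setNames(seqs$sequence, seqs$id)
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  seqs <- normalize_rna(seqs)
  all_rows <- list()
  for (id in names(seqs)) {
    sq <- seqs[[id]]
    if (nchar(sq) < 40L) {
      warning("sequence '", id, "' shorter than 40 nt; skipped")
      next
    }
    strands <- if (both_strands) c("+", "-") else "+"
    for (st in strands) {
      s_used <- if (st == "+") sq else revcomp_rna(sq)
      r <- .scan_strand(id, s_used, bundle, st, window, overlap, len_range,
                        loop_overlap_max, flank, context, max_stem,
                        min_hairpin_arm, catalog, bundle$backend)
      if (!is.null(r)) all_rows[[length(all_rows) + 1L]] <- r
    }
  }
  empty_placements <- data.frame(
    id = character(0), strand = character(0), arm = character(0),
    mi_start = integer(0), mi_end = integer(0), svm_score = numeric(0),
    range_pass = logical(0), verdict = logical(0), stringsAsFactors = FALSE)
  if (length(all_rows) == 0L)
    return(list(placements = empty_placements,
                regions = consolidate_regions(empty_placements)))
  plc <- do.call(rbind, all_rows)
  ## duplicates across overlapping windows: identical (parent interval, arm)
  key <- paste(plc$id, plc$strand, plc$arm, plc$mi_start, plc$mi_end)
  rf <- if (!is.null(bundle$range_filter))
    apply_range_filter(bundle$range_filter, plc)
  else data.frame(pass = rep(TRUE, nrow(plc)),
                  violations = character(nrow(plc)))
  plc$svm_score <- decision_values(bundle, plc)
  plc$range_pass <- rf$pass
  plc$range_violations <- rf$violations
  ord <- order(key, -plc$svm_score)
  plc <- plc[ord[!duplicated(key[ord])], , drop = FALSE]
  plc$verdict <- plc$range_pass & plc$svm_score > 0
  plc <- plc[order(plc$id, plc$strand, plc$mi_start, plc$mi_end), ,
             drop = FALSE]
  rownames(plc) <- NULL
  regions <- consolidate_regions(plc[plc$verdict, , drop = FALSE])
  list(placements = plc, regions = regions)
}

#' Evaluate predictions against truth annotations
#'
#' Every scored placement is labeled true/false by [match_positive()] against
#' the truth set; metrics use the pipeline's verdicts, and an ROC curve is
#' traced by sweeping the SVM decision threshold over the range-passing
#' placements. Truth matures never matched by any placement count as false
#' negatives at every threshold.
#'
#' @param placements placement data.frame from [predict_mirnas()].
#' @param truth data.frame with `id`, `start`, `end` (true mature intervals;
#'   optional `strand`, default "+").
#' @param tol per-end match tolerance.
#' @return list with `metrics` (at the verdict operating point), `roc`
#'   (data.frame `threshold`, `tpr`, `fpr`) and `auc` (trapezoidal).
#' @export
evaluate_predictions <- function(placements, truth, tol = 3L) {
  if (is.null(truth$strand)) truth$strand <- "+"
  if (nrow(truth) == 0L)
    return(list(metrics = NULL, roc = NULL, auc = NA_real_,
                note = "empty truth set; sensitivity undefined"))
  lab <- logical(nrow(placements))
  matched_any <- rep(FALSE, nrow(truth))
  hit_of <- rep(NA_integer_, nrow(placements))
  for (i in seq_len(nrow(placements))) {
    for (t in seq_len(nrow(truth))) {
      if (placements$id[i] == truth$id[t] &&
          placements$strand[i] == truth$strand[t] &&
          match_positive(c(placements$mi_start[i], placements$mi_end[i]),
                         c(truth$start[t], truth$end[t]), tol)) {
        lab[i] <- TRUE
        hit_of[i] <- t
        break
      }
    }
  }
  pos_called <- placements$verdict
  for (t in seq_len(nrow(truth)))
    matched_any[t] <- any(lab & pos_called & hit_of == t, na.rm = TRUE)
  tp <- sum(matched_any)
  fn <- sum(!matched_any)
  fp <- sum(pos_called & !lab)
  tn <- sum(!pos_called & !lab)
  metrics <- compute_metrics(tp, tn, fp, fn)
  ## candidate-level ROC over range-passing placements
  sc <- placements$svm_score[placements$range_pass]
  sl <- lab[placements$range_pass]
  roc <- NULL
  auc <- NA_real_
  if (length(sc) && any(sl) && any(!sl)) {
    thr <- c(Inf, sort(unique(sc), decreasing = TRUE), -Inf)
    tpr <- vapply(thr, function(th) mean(sc[sl] > th), numeric(1))
    fpr <- vapply(thr, function(th) mean(sc[!sl] > th), numeric(1))
    roc <- data.frame(threshold = thr, tpr = tpr, fpr = fpr)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  }
  list(metrics = metrics, roc = roc, auc = auc)
}

#' Write placements as TSV and coding regions as GFF3
#'
#' @param result list from [predict_mirnas()].
#' @param prefix output path prefix; writes `<prefix>.placements.tsv` and
#'   `<prefix>.regions.gff3`.
#' @return invisible character vector of the files written.
#' @export
write_prediction_outputs <- function(result, prefix) {
  tsv <- paste0(prefix, ".placements.tsv")
  gff <- paste0(prefix, ".regions.gff3")
  utils::write.table(result$placements, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  rg <- result$regions
  if (nrow(rg) > 0L) {
    gr <- GenomicRanges::GRanges(
      seqnames = rg$id,
      ranges = IRanges::IRanges(start = rg$start, end = rg$end),
      strand = rg$strand)
    S4Vectors::mcols(gr)$type <- "miRNA_coding_region"
    S4Vectors::mcols(gr)$source <- "mircand"
    S4Vectors::mcols(gr)$score <- rg$best_score
    S4Vectors::mcols(gr)$ID <- sprintf("region%03d", seq_len(nrow(rg)))
    S4Vectors::mcols(gr)$n_support <- rg$n_support
    S4Vectors::mcols(gr)$best_score <- rg$best_score
    S4Vectors::mcols(gr)$arm <- rg$arm
    rtracklayer::export(gr, gff, format = "gff3")
  } else {
    writeLines("##gff-version 3", gff)
  }
  invisible(c(tsv, gff))
}
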