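#' Fraction of a given base in a sequence
#' @param seq residue string over `{A,C,G,U}`.
#' @param base one of `"A"`, `"C"`, `"G"`, `"U"`.
#' @return `count(base)/nchar(seq)`; `NA` for an empty string (the
#'   undefined-feature marker for absent components).
#' @export
nucleotide_content <- function(seq, base) {
  if (is.na(seq) || nchar(seq) == 0L) return(NA_real_)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum(ch == base) / length(ch)
}

.iv_positions <- function(intervals) {
  if (!is.null(intervals) && is.numeric(intervals)) intervals <- list(intervals)
  unlist(lapply(intervals, iv_seq), use.names = FALSE)
}

#' Proportion of unpaired bases within a feature
#' @param intervals an interval `c(start, end)` or list of intervals.
#' @param pairs pair table (see [secondary_structure()]).
#' @return fraction in `[0,1]`; `NA` for an empty feature.
#' @export
unpaired_rate <- function(intervals, pairs) {
  pos <- .iv_positions(intervals)
  if (length(pos) == 0L) return(NA_real_)
  sum(is.na(pairs[pos])) / length(pos)
}

#' Internal-loop statistics of a duplex-scoped feature
#'
#' Internal loops are maximal runs of consecutive unpaired positions on
#' either strand within the feature.
#'
#' @inheritParams unpaired_rate
#' @return integer vector `c(largest_loop, n_loops)`; `(0,0)` for a perfect
#'   duplex, `c(NA,NA)` for an empty feature.
#' @export
internal_loop_stats <- function(intervals, pairs) {
  if (!is.null(intervals) && is.numeric(intervals)) intervals <- list(intervals)
  intervals <- Filter(Negate(iv_empty), intervals)
  if (length(intervals) == 0L) return(c(NA_integer_, NA_integer_))
  largest <- 0L
  nloops <- 0L
  for (ivl in intervals) {
    unp <- is.na(pairs[iv_seq(ivl)])
    r <- rle(unp)
    runs <- r$lengths[r$values]
    if (length(runs)) {
      nloops <- nloops + length(runs)
      largest <- max(largest, max(runs))
    }
  }
  c(as.integer(largest), as.integer(nloops))
}

#' Count G·U wobble pairs within a feature
#'
#' Pairs with at least one end inside the feature are examined; each pair is
#' counted once.
#'
#' @inheritParams unpaired_rate
#' @param seq the folded sequence.
#' @return integer count.
#' @export
gu_wobbles <- function(intervals, pairs, seq) {
  pos <- .iv_positions(intervals)
  pos <- pos[!is.na(pairs[pos])]
  if (length(pos) == 0L) return(0L)
  i <- pmin(pos, pairs[pos])
  j <- pmax(pos, pairs[pos])
  keep <- !duplicated(i)
  i <- i[keep]; j <- j[keep]
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  sum((ch[i] == "G" & ch[j] == "U") | (ch[i] == "U" & ch[j] == "G"))
}

#' 3' overhang length at the pre-miRNA base
#'
#' Number of unpaired 3'-side nucleotides protruding past the basal duplex of
#' the pre-miRNA (where the lower stem meets the miRNA start); 0 for a blunt
#' end, canonically 2 for a Drosha product.
#'
#' @param pre pre-miRNA interval.
#' @param pairs pair table.
#' @return integer; `NA` if the pre-miRNA contains no internal pair.
#' @export
overhang_3p <- function(pre, pairs) {
  for (a in iv_seq(pre)) {
    b <- pairs[a]
    if (!is.na(b) && b > a && b <= pre[2]) return(as.integer(pre[2] - b))
  }
  NA_integer_
}

.content_block <- function(seq, prefix) {
  out <- list()
  for (b in c("A", "C", "G", "U"))
    out[[paste0(prefix, "_", tolower(b), "_content")]] <-
      nucleotide_content(seq, b)
  out[[paste0(prefix, "_gc_content")]] <-
    if (is.na(seq) || nchar(seq) == 0L) NA_real_ else
      out[[paste0(prefix, "_c_content")]] + out[[paste0(prefix, "_g_content")]]
  out
}

## remove terminal-loop positions from a list of intervals (splitting where
## necessary); internal-loop runs must not absorb the terminal loop
.exclude_loop <- function(intervals, loop) {
  if (!is.null(intervals) && is.numeric(intervals)) intervals <- list(intervals)
  if (iv_empty(loop)) return(intervals)
  out <- list()
  for (x in intervals) {
    if (iv_empty(x)) next
    if (iv_overlap(x, loop) == 0L) { out[[length(out) + 1L]] <- x; next }
    left <- iv(x[1], min(x[2], loop[1] - 1L))
    right <- iv(max(x[1], loop[2] + 1L), x[2])
    if (!iv_empty(left)) out[[length(out) + 1L]] <- left
    if (!iv_empty(right)) out[[length(out) + 1L]] <- right
  }
  out
}

.struct_block <- function(prefix, intervals, pairs, seq, loop) {
  out <- list()
  pos <- .iv_positions(intervals)
  if (length(pos) == 0L) {
    for (suf in c("unpaired_bases", "gu_wobbles", "largest_internal_loop",
                  "n_internal_loops"))
      out[[paste0(prefix, "_", suf)]] <- NA_integer_
    out[[paste0(prefix, "_unpaired_rate")]] <- NA_real_
    return(out)
  }
  out[[paste0(prefix, "_unpaired_bases")]] <- sum(is.na(pairs[pos]))
  out[[paste0(prefix, "_unpaired_rate")]] <- unpaired_rate(intervals, pairs)
  out[[paste0(prefix, "_gu_wobbles")]] <- gu_wobbles(intervals, pairs, seq)
  il <- internal_loop_stats(.exclude_loop(intervals, loop), pairs)
  out[[paste0(prefix, "_largest_internal_loop")]] <- il[1]
  out[[paste0(prefix, "_n_internal_loops")]] <- il[2]
  out
}

#' Compute the full feature vector for one candidate placement
#'
#' Evaluates every catalog parameter on a (ppri-miRNA, pre-miRNA, miRNA)
#' triple sharing one folding. Parameters of absent components (e.g. a
#' missing top stem when the miRNA is flush against the loop) take the
#' undefined-feature marker `NA`, which the SVM scaler later maps to the
#' component-absent value -1.
#'
#' @param id record identifier.
#' @param seq the ppri-miRNA sequence.
#' @param struct its [secondary_structure()].
#' @param h the hairpin hosting the candidate (from [extract_hairpins()],
#'   same folding).
#' @param mirna candidate mature interval.
#' @param pre pre-miRNA interval; computed by [derive_premirna()] if `NULL`.
#' @param pre_mfe folding free energy of the pre-miRNA subsequence (computed
#'   by the caller, typically batch-folded; `NA` if not available).
#' @param catalog parameter catalog.
#' @param loop_overlap_max tolerated miRNA/loop overlap.
#' @return named list, one element per catalog parameter, with attributes
#'   `mirna`, `pre`, `arm`.
#' @export
compute_features <- function(id, seq, struct, h, mirna, pre = NULL,
                             pre_mfe = NA_real_, catalog = default_catalog(),
                             loop_overlap_max = 3L) {
  if (nchar(seq) != struct$length)
    stop("sequence and structure lengths differ", call. = FALSE)
  if (is.null(pre))
    pre <- derive_premirna(h, mirna, loop_overlap_max = loop_overlap_max)
  comps <- segment_components(h, mirna, loop_overlap_max = loop_overlap_max)
  pt <- struct$pairs
  n <- nchar(seq)
  arm <- comps$arm
  mi_seq <- substr(seq, mirna[1], mirna[2])
  pre_seq <- substr(seq, pre[1], pre[2])

  side <- function(base) comps[[paste0(base, if (arm == "5p") "5" else "3")]]
  pair_levels <- function(ivl) {
    pos <- iv_seq(ivl)
    sum(!is.na(pt[pos]) & pt[pos] > pos & pt[pos] <= ivl[2])
  }
  stem_pairs <- function(c5) {
    pos <- iv_seq(c5)
    sum(!is.na(pt[pos]))
  }
  comp_len <- function(base) {
    a <- comps[[paste0(base, "5")]]
    b <- comps[[paste0(base, "3")]]
    if (iv_empty(a) && iv_empty(b)) return(NA_integer_)
    iv_len(side(base))
  }

  v <- list(
    id = id,
    mi_sequence = mi_seq,
    pre_sequence = pre_seq,
    ppri_sequence = seq,
    ppri_structure = struct$dotbracket,

    mi_length = iv_len(mirna),
    pre_length = iv_len(pre),
    ppri_length = n,
    basalsegment_length = {
      bl <- iv_len(comps$basal5) + iv_len(comps$basal3)
      if (bl == 0L) NA_integer_ else bl
    },
    lowerstem_length = comp_len("lower"),
    upperstem_length = comp_len("upper"),
    topstem_length = comp_len("top"),
    terminalloop_length = iv_len(comps$loop),
    mi_pairs = sum(!is.na(pt[iv_seq(mirna)])),
    pre_pairs = pair_levels(pre),
    ppri_pairs = pair_levels(iv(1L, n)),
    lowerstem_pairs = if (iv_empty(comps$lower5) && iv_empty(comps$lower3))
      NA_integer_ else stem_pairs(comps$lower5),
    upperstem_pairs = stem_pairs(comps$upper5),
    topstem_pairs = if (iv_empty(comps$top5) && iv_empty(comps$top3))
      NA_integer_ else stem_pairs(comps$top5),

    pre_mfe = pre_mfe,
    ppri_mfe = struct$mfe
  )
  v <- c(v, .content_block(mi_seq, "mi"), .content_block(pre_seq, "pre"),
         .content_block(seq, "ppri"))
  fb <- substr(seq, mirna[1], mirna[1])
  v$mi_firstbase <- fb
  for (b in c("A", "C", "G", "U"))
    v[[paste0("mi_firstbase_", tolower(b))]] <- as.integer(fb == b)

  loop <- comps$loop
  v <- c(v,
    .struct_block("mi", mirna, pt, seq, loop),
    .struct_block("pre", pre, pt, seq, loop),
    .struct_block("ppri", iv(1L, n), pt, seq, loop),
    .struct_block("lowerstem",
                  Filter(Negate(iv_empty), list(comps$lower5, comps$lower3)),
                  pt, seq, loop),
    .struct_block("upperstem", list(comps$upper5, comps$upper3), pt, seq, loop),
    .struct_block("topstem",
                  Filter(Negate(iv_empty), list(comps$top5, comps$top3)),
                  pt, seq, loop))
  v$overhang_3p <- overhang_3p(pre, pt)

  v <- v[catalog$name]
  attr(v, "mirna") <- mirna
  attr(v, "pre") <- pre
  attr(v, "arm") <- arm
  v
}

#' Compute feature rows for many candidates on one folded record
#'
#' @param id record identifier.
#' @param seq,struct,h as in [compute_features()].
#' @param candidates data.frame with columns `start`, `end` (mature interval).
#' @param pre_mfe_fun function mapping a matrix of unique pre intervals to
#'   MFEs (e.g. a batched fold), or `NULL` to leave `pre_mfe` as `NA`.
#' @param catalog parameter catalog.
#' @param loop_overlap_max tolerated miRNA/loop overlap.
#' @return data.frame: one row per candidate, columns `id`, `mi_start`,
#'   `mi_end`, `arm`, `pre_start`, `pre_end` plus every catalog parameter.
#' @export
candidate_feature_table <- function(id, seq, struct, h, candidates,
                                    pre_mfe_fun = NULL,
                                    catalog = default_catalog(),
                                    loop_overlap_max = 3L) {
  if (nrow(candidates) == 0L) return(NULL)
  pres <- t(vapply(seq_len(nrow(candidates)), function(i)
    derive_premirna(h, iv(candidates$start[i], candidates$end[i]),
                    loop_overlap_max = loop_overlap_max), integer(2)))
  key <- paste(pres[, 1], pres[, 2])
  mfe_map <- NULL
  if (!is.null(pre_mfe_fun)) {
    uk <- !duplicated(key)
    mfes <- pre_mfe_fun(pres[uk, , drop = FALSE])
    mfe_map <- stats::setNames(mfes, key[uk])
  }
  rows <- lapply(seq_len(nrow(candidates)), function(i) {
    mir <- iv(candidates$start[i], candidates$end[i])
    fv <- compute_features(id, seq, struct, h, mir, pre = pres[i, ],
                           pre_mfe = if (is.null(mfe_map)) NA_real_
                                     else unname(mfe_map[key[i]]),
                           catalog = catalog,
                           loop_overlap_max = loop_overlap_max)
    c(list(mi_start = mir[1], mi_end = mir[2], arm = attr(fv, "arm"),
           pre_start = pres[i, 1], pre_end = pres[i, 2]), fv)
  })
  nm <- names(rows[[1]])
  df <- as.data.frame(lapply(stats::setNames(nm, nm), function(col)
    unlist(lapply(rows, function(r) r[[col]] %||% NA), use.names = FALSE)),
    stringsAsFactors = FALSE, optional = TRUE)
  df
}
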