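#' Extract single stem-loops (hairpins) from a folded structure
#'
#' Walks the pair table outward from every terminal (hairpin) loop, extending
#' through stacked pairs, bulges and internal loops, and stopping where a
#' multibranch loop begins ("budding stems") or the exterior loop is reached.
#' Each terminal loop therefore yields at most one maximal simple stem-loop;
#' cloverleaf-like structures yield one hairpin per apical stem and none at
#' the multiloop level.
#'
#' Stems deeper than `max_stem` pair levels are trimmed by discarding pairs
#' at the base of the stem (where pairing is least reliable) until the cap is
#' met; the discarded region is excluded from the hairpin span. Untrimmed
#' hairpins extend their span over the flanking unpaired (exterior) residues
#' up to the nearest paired base, which become the basal segment.
#'
#' @param struct a [secondary_structure()].
#' @param sequence the folded sequence (same length).
#' @param max_stem maximum stem depth in pair levels (default 60).
#' @return list of `hairpin` objects with elements `sequence`, `structure`,
#'   `span`, `outer` (outermost retained pair), `inner` (loop-closing pair),
#'   `loop`, `arm5`, `arm3`, `stem_levels`, `trimmed`.
#' @export
extract_hairpins <- function(struct, sequence, max_stem = 60L) {
  pt <- struct$pairs
  n <- length(pt)
  paired <- !is.na(pt)
  ## terminal loops: pairs (p,q), p<q, nothing paired strictly inside
  res <- list()
  for (p in which(paired & pt > seq_len(n))) {
    q <- pt[p]
    if (q - p > 1L && any(paired[(p + 1L):(q - 1L)])) next
    ## walk outward collecting the simple stem
    stem5 <- p
    stem3 <- q
    i <- p; j <- q
    repeat {
      a <- i - 1L
      while (a >= 1L && !paired[a]) a <- a - 1L
      if (a < 1L) break                       # exterior reached
      b <- pt[a]
      if (b < j) break                        # sibling branch to the left
      ## all residues between j and b must be unpaired, else multibranch
      if (b - j > 1L && any(paired[(j + 1L):(b - 1L)])) break
      if (a < i - 1L - 30L || b > j + 31L) { } # no size limit on walk
      stem5 <- c(stem5, a)
      stem3 <- c(stem3, b)
      i <- a; j <- b
    }
    levels <- length(stem5)
    trimmed <- levels > max_stem
    if (trimmed) {
      ## stem5/stem3 ordered innermost -> outermost; keep innermost max_stem
      stem5 <- stem5[seq_len(max_stem)]
      stem3 <- stem3[seq_len(max_stem)]
      levels <- max_stem
    }
    o5 <- stem5[levels]
    o3 <- stem3[levels]
    if (trimmed) {
      span <- iv(o5, o3)
    } else {
      s <- o5
      while (s > 1L && !paired[s - 1L]) s <- s - 1L
      e <- o3
      while (e < n && !paired[e + 1L]) e <- e + 1L
      span <- iv(s, e)
    }
    res[[length(res) + 1L]] <- structure(list(
      sequence = sequence, structure = struct, span = span,
      outer = iv(o5, o3), inner = iv(p, q),
      loop = iv(p + 1L, q - 1L),
      arm5 = iv(span[1], p), arm3 = iv(q, span[2]),
      stem_levels = levels, trimmed = trimmed), class = "hairpin")
  }
  res
}

#' @export
print.hairpin <- function(x, ...) {
  cat(sprintf(
    "hairpin: span [%d,%d], %d pair levels%s, loop [%d,%d] (%d nt)\n",
    x$span[1], x$span[2], x$stem_levels, if (x$trimmed) " (trimmed)" else "",
    x$loop[1], x$loop[2], iv_len(x$loop)))
  invisible(x)
}

#' Which arm of a hairpin does an interval lie on?
#' @param h hairpin.
#' @param mirna interval `c(start, end)`.
#' @param loop_overlap_max maximum nucleotides tolerated inside the loop.
#' @return `"5p"`, `"3p"`, or `NA` if the placement is inadmissible.
#' @export
hairpin_arm <- function(h, mirna, loop_overlap_max = 3L) {
  if (!iv_contains(h$span, mirna)) return(NA_character_)
  ov <- iv_overlap(mirna, h$loop)
  if (ov > loop_overlap_max) return(NA_character_)
  on5 <- mirna[1] <= h$inner[1]
  on3 <- mirna[2] >= h$inner[2]
  if (on5 && !on3) return("5p")
  if (on3 && !on5) return("3p")
  NA_character_
}

.empty_if_rev <- function(x) if (x[1] > x[2]) iv(x[1], x[1] - 1L) else x

#' Segment a hairpin into its five structural components
#'
#' Relative to a candidate mature miRNA on one arm, partitions the hairpin
#' span into Basal Segment (unpaired residues below the outermost retained
#' pair), Lower Stem (duplex between basal segment and the miRNA), Upper Stem
#' (duplex spanned by the miRNA and its partner region), Top Stem (duplex
#' between the miRNA and the terminal loop) and Terminal Loop. Only Upper
#' Stem and Terminal Loop are guaranteed non-empty. Two-sided components
#' carry one interval per strand; the intervals tile the span disjointly.
#'
#' @param h hairpin from [extract_hairpins()].
#' @param mirna interval `c(start, end)` on one arm of `h` (sequence
#'   coordinates, 1-based closed).
#' @param loop_overlap_max tolerated miRNA/loop overlap, nucleotides.
#' @return object of class `hairpin_components`: list of intervals `basal5`,
#'   `lower5`, `upper5`, `top5`, `loop`, `top3`, `upper3`, `lower3`,
#'   `basal3`, plus `arm` ("5p"/"3p") and `mirna`.
#' @export
segment_components <- function(h, mirna, loop_overlap_max = 3L) {
  arm <- hairpin_arm(h, mirna, loop_overlap_max)
  if (is.na(arm))
    stop("miRNA interval [", mirna[1], ",", mirna[2],
         "] does not lie on one arm of the hairpin", call. = FALSE)
  pt <- h$structure$pairs
  p <- h$inner[1]; q <- h$inner[2]
  o5 <- h$outer[1]; o3 <- h$outer[2]
  s <- h$span[1]; e <- h$span[2]
  loop <- h$loop

  if (arm == "5p") {
    ms <- mirna[1]; me <- mirna[2]
    pos <- iv_seq(mirna)
    pp <- pos[!is.na(pt[pos])]
    if (length(pp) == 0L)
      stop("miRNA interval contains no paired base; cannot segment",
           call. = FALSE)
    y_hi <- pt[min(pp)]   # partner of basal-most paired miRNA position
    y_lo <- pt[max(pp)]   # partner of loop-most paired miRNA position
    b1 <- min(o5, ms)
    basal5 <- iv(s, b1 - 1L)
    lower5 <- .empty_if_rev(iv(b1, ms - 1L))
    upper5 <- iv(ms, me)
    if (me >= p) {        # miRNA reaches into the loop
      top5 <- iv(p + 1L, p)                 # empty
      loop <- .empty_if_rev(iv(me + 1L, q - 1L))
    } else {
      top5 <- .empty_if_rev(iv(me + 1L, p))
    }
    top3 <- .empty_if_rev(iv(q, y_lo - 1L))
    upper3 <- iv(y_lo, y_hi)
    lower3 <- .empty_if_rev(iv(y_hi + 1L, o3))
    basal3 <- .empty_if_rev(iv(o3 + 1L, e))
  } else {
    ms <- mirna[1]; me <- mirna[2]
    pos <- iv_seq(mirna)
    pp <- pos[!is.na(pt[pos])]
    if (length(pp) == 0L)
      stop("miRNA interval contains no paired base; cannot segment",
           call. = FALSE)
    y_lo <- pt[min(pp)]   # partner of loop-most paired miRNA position (5' arm)
    y_hi <- pt[max(pp)]   # partner of basal-most paired miRNA position
    b1 <- max(o3, me)
    basal3 <- .empty_if_rev(iv(b1 + 1L, e))
    lower3 <- .empty_if_rev(iv(me + 1L, b1))
    upper3 <- iv(ms, me)
    if (ms <= q) {        # miRNA reaches into the loop
      top3 <- iv(q, q - 1L)                 # empty
      loop <- .empty_if_rev(iv(p + 1L, ms - 1L))
    } else {
      top3 <- .empty_if_rev(iv(q, ms - 1L))
    }
    top5 <- .empty_if_rev(iv(y_lo + 1L, p))
    upper5 <- iv(y_hi, y_lo)
    lower5 <- .empty_if_rev(iv(o5, y_hi - 1L))
    basal5 <- .empty_if_rev(iv(s, o5 - 1L))
  }
  structure(list(basal5 = basal5, lower5 = lower5, upper5 = upper5,
                 top5 = top5, loop = loop, top3 = top3, upper3 = upper3,
                 lower3 = lower3, basal3 = basal3, arm = arm, mirna = mirna),
            class = "hairpin_components")
}

#' Derive a pre-miRNA interval from a mature miRNA placement
#'
#' The pre-miRNA runs from the loop-distal end of the miRNA, across the
#' terminal loop, to the position paired with that end on the opposite arm,
#' then is extended by `overhang` nucleotides on the 3' side (the ~2-nt
#' Drosha 3' overhang) and clipped to the hairpin span.
#'
#' @param h hairpin.
#' @param mirna interval on one arm of `h`.
#' @param overhang 3'-side extension in nucleotides (default 2).
#' @param loop_overlap_max tolerated miRNA/loop overlap.
#' @return interval `c(start, end)` in sequence coordinates.
#' @export
derive_premirna <- function(h, mirna, overhang = 2L, loop_overlap_max = 3L) {
  arm <- hairpin_arm(h, mirna, loop_overlap_max)
  if (is.na(arm))
    stop("miRNA interval does not lie on one arm of the hairpin", call. = FALSE)
  pt <- h$structure$pairs
  pos <- iv_seq(mirna)
  pp <- pos[!is.na(pt[pos])]
  if (length(pp) == 0L)
    stop("miRNA interval contains no paired base", call. = FALSE)
  if (arm == "5p") {
    anchor <- min(pp)          # loop-distal (basal) end on 5' arm
    start <- mirna[1]
    end <- pt[anchor] + overhang
  } else {
    anchor <- max(pp)          # loop-distal end on 3' arm
    start <- pt[anchor]
    end <- mirna[2] + overhang
  }
  iv(max(start, h$span[1]), min(end, h$span[2]))
}
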