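#' Secondary structure objects
#'
#' A `secondary_structure` holds a dot-bracket string, the equivalent pair
#' table (`pairs[i]` is the partner of position `i`, `NA` if unpaired) and
#' the minimum free energy in kcal/mol. Pair tables are validated to be
#' involutions without self-pairs; dot-bracket notation enforces the
#' no-pseudoknot (nested) property by construction.
#'
#' @param dotbracket dot-bracket string using `(`, `)` and `.`.
#' @param mfe minimum free energy, kcal/mol.
#' @param sequence optional sequence the structure belongs to (length check).
#' @return object of class `secondary_structure` with elements `dotbracket`,
#'   `pairs`, `mfe`, `length`.
#' @export
secondary_structure <- function(dotbracket, mfe = NA_real_, sequence = NULL) {
  if (!is.null(sequence) && nchar(sequence) != nchar(dotbracket))
    stop("dot-bracket length does not match sequence length", call. = FALSE)
  pairs <- dotbracket_to_pairs(dotbracket)
  structure(list(dotbracket = dotbracket, pairs = pairs,
                 mfe = as.numeric(mfe), length = nchar(dotbracket)),
            class = "secondary_structure")
}

#' @export
print.secondary_structure <- function(x, ...) {
  cat(sprintf("secondary_structure: %d nt, %d pairs, MFE %.2f kcal/mol\n",
              x$length, sum(!is.na(x$pairs)) %/% 2L, x$mfe))
  if (x$length <= 120) cat(x$dotbracket, "\n")
  invisible(x)
}

#' Convert dot-bracket notation to a pair table
#' @param db dot-bracket string.
#' @return integer vector; `pairs[i]` = partner of `i` or `NA`.
#' @export
dotbracket_to_pairs <- function(db) {
  ch <- strsplit(db, "", fixed = TRUE)[[1]]
  n <- length(ch)
  pairs <- rep(NA_integer_, n)
  stack <- integer(n)
  top <- 0L
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      top <- top + 1L
      stack[top] <- i
    } else if (ch[i] == ")") {
      if (top == 0L) stop("unbalanced dot-bracket string", call. = FALSE)
      j <- stack[top]
      top <- top - 1L
      pairs[i] <- j
      pairs[j] <- i
    } else if (ch[i] != ".") {
      stop("dot-bracket characters must be one of '(', ')', '.'", call. = FALSE)
    }
  }
  if (top != 0L) stop("unbalanced dot-bracket string", call. = FALSE)
  pairs
}

#' Convert a pair table to dot-bracket notation
#' @param pairs integer pair table (involution, nested).
#' @return dot-bracket string.
#' @export
pairs_to_dotbracket <- function(pairs) {
  ch <- rep(".", length(pairs))
  p <- which(!is.na(pairs))
  ch[p[pairs[p] > p]] <- "("
  ch[p[pairs[p] < p]] <- ")"
  paste(ch, collapse = "")
}

#' Parse a CT-format structure file
#'
#' CT is the connectivity-table format emitted by UNAFold-family folders:
#' a header line `N dG = E ...` followed by one row per base with the
#' partner index in column 5 (0 = unpaired).
#'
#' @param path CT file, first structure only.
#' @return list with `sequence` and a [secondary_structure()].
#' @export
parse_ct <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- as.integer(hdr[1])
  mfe <- suppressWarnings(as.numeric(hdr[which(hdr == "=") + 1]))
  if (length(mfe) == 0L) mfe <- NA_real_
  rows <- strsplit(trimws(lines[2:(n + 1)]), "\\s+")
  base <- vapply(rows, `[`, character(1), 2)
  partner <- as.integer(vapply(rows, `[`, character(1), 5))
  pairs <- ifelse(partner == 0L, NA_integer_, partner)
  db <- pairs_to_dotbracket(pairs)
  list(sequence = normalize_rna(paste(base, collapse = "")),
       structure = secondary_structure(db, mfe))
}

## ---- folding backends -----------------------------------------------------

fold_backend_registry <- new.env(parent = emptyenv())

register_fold_backend <- function(name, fun) {
  assign(name, fun, envir = fold_backend_registry)
}

#' List available folding backend names
#' @return character vector of backend names.
#' @export
fold_backends <- function() sort(ls(fold_backend_registry))

fold_rnafold <- function(seqs, rnafold = getOption("mircand.rnafold", "RNAfold")) {
  if (Sys.which(rnafold) == "")
    stop("RNAfold executable not found on PATH; set options(mircand.rnafold=)",
         call. = FALSE)
  ids <- paste0("s", seq_along(seqs))
  input <- paste0(">", ids, "\n", seqs, collapse = "\n")
  out <- suppressWarnings(
    system2(rnafold, c("--noPS"), input = input, stdout = TRUE, stderr = FALSE))
  hdr <- grep("^>", out)
  if (length(hdr) != length(seqs))
    stop("RNAfold returned ", length(hdr), " records for ", length(seqs),
         " sequences", call. = FALSE)
  lapply(seq_along(seqs), function(k) {
    sline <- out[hdr[k] + 2L]
    m <- regmatches(sline, regexpr("\\(\\s*-?[0-9.]+\\)$", sline))
    mfe <- as.numeric(gsub("[()\\s]", "", m, perl = TRUE))
    db <- trimws(sub("\\s*\\(\\s*-?[0-9.]+\\)$", "", sline))
    secondary_structure(db, mfe, seqs[k])
  })
}

fold_inprocess <- function(seqs, ...) {
  lapply(seqs, function(s) {
    res <- fold_zuker_cpp(s)
    secondary_structure(res$dotbracket, res$mfe, s)
  })
}

.onLoad <- function(libname, pkgname) {
  register_fold_backend("rnafold", fold_rnafold)
  register_fold_backend("inprocess", fold_inprocess)
}

#' Fold RNA sequences to their minimum-free-energy structure
#'
#' Batch interface over pluggable backends. Identical sequence + backend +
#' backend version gives an identical dot-bracket; trained model bundles pin
#' the backend because all downstream feature values depend on it.
#'
#' Backends: `"rnafold"` (external ViennaRNA `RNAfold` executable, the
#' default) and `"inprocess"` (a built-in simplified nearest-neighbour
#' thermodynamic folder; no external dependency).
#'
#' @param seqs character vector of RNA sequences (use [normalize_rna()]).
#' @param backend backend name, see [fold_backends()].
#' @param min_len minimum sequence length accepted; shorter sequences cannot
#'   host a pre-miRNA in the scanning pipeline. Lower it for toy inputs.
#' @return `fold_many()`: list of [secondary_structure()]; `fold()`: one.
#' @export
fold_many <- function(seqs, backend = "rnafold", min_len = 40L) {
  if (!backend %in% fold_backends())
    stop("unknown folding backend '", backend, "'; available: ",
         paste(fold_backends(), collapse = ", "), call. = FALSE)
  if (length(seqs) == 0L) return(list())
  seqs <- normalize_rna(seqs)
  short <- nchar(seqs) < min_len
  if (any(short))
    stop("sequence(s) shorter than min_len=", min_len, ": ",
         paste(which(short), collapse = ", "), call. = FALSE)
  get(backend, envir = fold_backend_registry)(seqs)
}

#' @rdname fold_many
#' @param seq single RNA sequence.
#' @export
fold <- function(seq, backend = "rnafold", min_len = 40L) {
  fold_many(seq, backend = backend, min_len = min_len)[[1]]
}
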