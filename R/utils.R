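`%||%` <- function(a, b) if (is.null(a)) b else a

## Closed 1-based intervals c(start, end); start > end encodes the empty
## interval. NULL is also treated as empty.
iv <- function(start, end) c(as.integer(start), as.integer(end))

iv_empty <- function(x) is.null(x) || length(x) == 0L || x[1] > x[2]

iv_len <- function(x) if (iv_empty(x)) 0L else x[2] - x[1] + 1L

iv_seq <- function(x) if (iv_empty(x)) integer(0) else seq.int(x[1], x[2])

iv_overlap <- function(a, b) {
  if (iv_empty(a) || iv_empty(b)) return(0L)
  max(0L, min(a[2], b[2]) - max(a[1], b[1]) + 1L)
}

iv_contains <- function(a, b) {
  !iv_empty(a) && !iv_empty(b) && b[1] >= a[1] && b[2] <= a[2]
}

## Derive a 32-bit safe stream seed from a base seed and a stream index.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103L + stream * 7919L) %% 2147483647)
}

stopifnot_scalar_int <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
  as.integer(x)
}
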