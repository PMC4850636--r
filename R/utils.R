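# internal assertion helpers shared across modules

.assert <- function(ok, ..., call. = FALSE) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = call.)
}

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == as.integer(x) && x >= min
}

.is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# column minima without matrixStats; M must have >= 1 row
.col_mins <- function(M) {
  if (nrow(M) == 1L) return(as.vector(M))
  do.call(pmin, lapply(seq_len(nrow(M)), function(i) M[i, ]))
}
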