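# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_fctopo <- function(...) stop(sprintf(...), call. = FALSE)

check_square_symmetric <- function(m, what = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_fctopo("%s must be a square matrix", what)
  if (max(abs(m - t(m))) > 1e-8)
    stop_fctopo("%s must be symmetric", what)
  invisible(TRUE)
}

# canonical community labels: consecutive integers in order of first appearance,
# so partitions can be compared with identical()
canonical_labels <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

# derive a stream of child seeds from one integer seed, staying within .Machine$integer.max
derive_seeds <- function(seed, n) {
  (as.integer(seed) + 1013L * seq_len(n)) %% 2147483546L + 1L
}
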