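# Internal helpers shared across modules.

DNA_STATES <- c("A", "C", "G", "T")

# Character sequences -> integer state matrix (0 = A, 1 = C, 2 = G, 3 = T).
# All sequences must have equal length and contain only A/C/G/T.
seq_to_matrix <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1) abort("all sequences must have the same length")
  L <- lens[1]
  codes <- vapply(seqs, function(s) {
    x <- utf8ToInt(s)
    out <- integer(L)
    out[x == 65L] <- 0L  # A
    out[x == 67L] <- 1L  # C
    out[x == 71L] <- 2L  # G
    out[x == 84L] <- 3L  # T
    bad <- !(x %in% c(65L, 67L, 71L, 84L))
    if (any(bad)) abort(paste0("invalid nucleotide '", intToUtf8(x[which(bad)[1]]),
                               "' (only A/C/G/T are supported)"))
    out
  }, integer(L))
  if (L == 1L) codes <- matrix(codes, nrow = 1L)
  t(codes)
}

matrix_to_seq <- function(mat) {
  apply(mat, 1L, function(r) paste(DNA_STATES[r + 1L], collapse = ""))
}

# Weighted quantile (step interpolation on the sorted sample).
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  w <- w[ord]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1]], numeric(1))
}

weighted_mean <- function(x, w) sum(x * w) / sum(w)

`%||%` <- function(a, b) if (is.null(a)) b else a
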