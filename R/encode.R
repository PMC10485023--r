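#' One-hot encode a DNA sequence
#'
#' Returns the 4-by-N binary matrix used as model input: rows in fixed order
#' A, C, G, T, a single 1 per column. Ambiguous bases are rejected; guides
#' containing N must be filtered upstream.
#'
#' @param seq DNA string over A/C/G/T.
#' @return 4 x nchar(seq) integer matrix with rownames A,C,G,T.
#' @export
encode_onehot <- function(seq) {
  check_dna(seq, what = "input sequence")
  ch <- strsplit(seq, "")[[1]]
  m <- matrix(0L, nrow = 4, ncol = length(ch), dimnames = list(BASES, NULL))
  m[cbind(match(ch, BASES), seq_along(ch))] <- 1L
  m
}

#' Decode a one-hot matrix back to a DNA string
#' @param m 4 x N one-hot matrix (rows A,C,G,T).
#' @return DNA string.
#' @export
decode_onehot <- function(m) {
  if (nrow(m) != 4 || !all(colSums(m) == 1)) {
    stop("not a one-hot 4xN matrix")
  }
  paste(BASES[apply(m, 2, which.max)], collapse = "")
}

#' One-hot encode a set of equal-length sequences for the model
#'
#' @param seqs character vector of equal-length DNA sequences.
#' @return numeric array of dim `c(n, 4, N)` (sample, channel A/C/G/T,
#'   position), the layout consumed by [build_model()] networks.
#' @export
encode_dataset <- function(seqs) {
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("sequences must share one length")
  N <- lens[1]
  n <- length(seqs)
  check_dna(seqs, what = "input sequences")
  x <- array(0, dim = c(n, 4, N))
  ch <- matrix(unlist(strsplit(seqs, ""), use.names = FALSE),
               nrow = n, byrow = TRUE)
  for (b in seq_along(BASES)) {
    x[, b, ][ch == BASES[b]] <- 1
  }
  x
}
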