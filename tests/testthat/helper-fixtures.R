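# Shared fixtures, all generated in code.

# scaled-down network: same topology as the default, sized for CPU test runs
tiny_spec <- function(input_len = 28L, dropout = 0) {
  model_spec(input_len = input_len, conv_filters = 8L, conv_kernel = 5L,
             branch_filters = c(6L, 5L), branch_kernel = 3L, pool = 2L,
             dense_a = 8L, gru_units = 5L, dense_b = 8L,
             merge_dense = c(10L, 6L), dropout = dropout)
}

small_spec <- function(input_len = 28L, dropout = 0.2) {
  model_spec(input_len = input_len, conv_filters = 32L, conv_kernel = 5L,
             branch_filters = c(16L, 16L, 16L), branch_kernel = 3L,
             pool = 2L, dense_a = 32L, gru_units = 16L, dense_b = 32L,
             merge_dense = c(64L, 32L), dropout = dropout)
}

random_dna <- function(n, len, seed) {
  guidescreen::random_contexts(n, seed = seed, len = len)
}

# a genome with a single unambiguous +-strand PAM site: A/T everywhere
# except one planted GG
one_pam_genome <- function() {
  s <- strsplit(paste(rep("AT", 30), collapse = ""), "")[[1]]  # 60 nt, no G/C
  s[36] <- "G"; s[37] <- "G"   # PAM NGG at 35..37 => protospacer at 15..34
  genome_sequence("onepam", paste(s, collapse = ""))
}

# independent brute-force PAM scan used as an oracle (substring enumeration,
# no shared code with scan_pam_sites)
brute_pam_starts <- function(seq, L = nchar(seq)) {
  plus <- integer(); minus <- integer()
  for (i in 11:(L - 32)) {
    if (substr(seq, i + 21, i + 22) == "GG") plus <- c(plus, i - 1L)
  }
  rc <- guidescreen::revcomp(seq)
  for (j in 11:(L - 32)) {
    if (substr(rc, j + 21, j + 22) == "GG") minus <- c(minus, L - j - 19L)
  }
  list(plus = plus, minus = minus)
}

# simple enrichment counts with one guide at a planted fold change
planted_fold_counts <- function(n_guides, fold, depth, reps, seed) {
  p0 <- rep(1, n_guides)
  p1 <- p0; p1[1] <- fold
  p0 <- p0 / sum(p0); p1 <- p1 / sum(p1)
  withr::with_seed(seed, {
    cm <- cbind(
      matrix(unlist(lapply(seq_len(reps), function(i) rmultinom(1, depth, p0))),
             ncol = reps),
      matrix(unlist(lapply(seq_len(reps), function(i) rmultinom(1, depth, p1))),
             ncol = reps))
  })
  rownames(cm) <- sprintf("g%03d", seq_len(n_guides))
  colnames(cm) <- c(paste0("rep_", seq_len(reps)), paste0("ind_", seq_len(reps)))
  count_matrix(cm, condition = rep(c("repressed", "induced"), each = reps),
               replicate = rep(seq_len(reps), 2))
}
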