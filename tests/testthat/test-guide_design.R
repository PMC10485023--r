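test_that("scan_pam_sites finds a single planted +-strand site", {
  g <- one_pam_genome()
  sites <- scan_pam_sites(g)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$strand, "+")
  expect_equal(sites$protospacer_start, 14L)  # 0-based; protospacer 15..34
  expect_equal(sites$pam, "AGG")
  expect_equal(nchar(sites$protospacer), 20L)
})

test_that("scanning a reverse complement swaps strands and reflects coords", {
  seq <- random_dna(1, 400, seed = 31)
  a <- scan_pam_sites(genome_sequence("fwd", seq))
  b <- scan_pam_sites(genome_sequence("rev", revcomp(seq)))
  expect_equal(nrow(a), nrow(b))
  key <- function(s) sort(paste(s$protospacer, s$pam))
  expect_equal(key(a), key(b))
  flip <- setNames(c("-", "+"), c("+", "-"))
  L <- nchar(seq)
  mapped <- data.frame(strand = unname(flip[a$strand]),
                       protospacer_start = L - (a$protospacer_start + 20L))
  o1 <- mapped[order(mapped$protospacer_start, mapped$strand), ]
  o2 <- b[order(b$protospacer_start, b$strand), c("strand", "protospacer_start")]
  expect_equal(o1$protospacer_start, o2$protospacer_start)
  expect_equal(o1$strand, o2$strand)
})

test_that("site counts match an independent brute-force scan on 3.2 kb", {
  seq <- random_dna(1, 3200, seed = 77)
  sites <- scan_pam_sites(genome_sequence("chr", seq))
  oracle <- brute_pam_starts(seq)
  expect_equal(sum(sites$strand == "+"), length(oracle$plus))
  expect_equal(sum(sites$strand == "-"), length(oracle$minus))
  expect_equal(sort(sites$protospacer_start[sites$strand == "+"]),
               sort(oracle$plus))
  expect_equal(sort(sites$protospacer_start[sites$strand == "-"]),
               sort(oracle$minus))
})

test_that("windows wrap on circular sequences and drop on linear ones", {
  # place a PAM so the 43-nt window must wrap the origin
  s <- strsplit(paste(rep("AT", 25), collapse = ""), "")[[1]]  # 50 nt
  s[24] <- "G"; s[25] <- "G"   # PAM at 23..25 (1-based), protospacer 3..22
  seq <- paste(s, collapse = "")
  lin <- scan_pam_sites(genome_sequence("lin", seq, circular = FALSE))
  circ <- scan_pam_sites(genome_sequence("circ", seq, circular = TRUE))
  expect_equal(nrow(lin), 0L)      # upstream 10 nt does not fit linearly
  expect_equal(nrow(circ), 1L)
  expect_equal(circ$protospacer_start, 2L)
  # reconstruction: 43-nt window carries the PAM at positions 31-33
  win <- build_input_window(circ, 10, 13)
  expect_equal(nchar(win), 43L)
  expect_equal(substr(win, 31, 33), circ$pam)
  # too-short linear sequence warns, returns empty
  expect_warning(empty <- scan_pam_sites(genome_sequence("s", "ACGTACGT")),
                 "shorter")
  expect_equal(nrow(empty), 0L)
})

test_that("I-TevI motif detection honours offsets and context length", {
  # G at offset 13 requires 12 characters after it in the context
  ctx_hit <- paste0("CAAAG", strrep("A", 12))      # C..G with G at offset 13
  expect_true(has_tev_motif(ctx_hit, c(13L, 17L)))
  expect_false(has_tev_motif(strrep("A", 21), c(13L, 17L)))
  expect_error(has_tev_motif("CAAAG", c(13L, 17L)), "too short")
  # planted-count recovery: 73 of 304 contexts carry the motif
  base <- random_dna(304, 21, seed = 5)
  base <- gsub("[CG]", "T", base)                  # scrub all C and G
  withr::with_seed(8, {
    hit <- sample.int(304, 73)
    for (i in hit) {
      d <- sample(13:17, 1)
      ch <- strsplit(base[i], "")[[1]]
      ch[21 - d + 1] <- "G"; ch[21 - d - 3] <- "C"
      base[i] <- paste(ch, collapse = "")
    }
  })
  flags <- vapply(base, has_tev_motif, logical(1), spacer_range = c(13L, 17L))
  expect_equal(sum(flags), 73L)
})

test_that("detect_tev_motif extends context from the genome on both strands", {
  # plant a motif upstream of the only + site of the one-PAM genome
  g <- one_pam_genome()
  ch <- strsplit(g$sequence, "")[[1]]
  # protospacer starts at 1-based 15; offset 13 => G at position 2, C at -2:
  # too short upstream on a linear genome -> use circular so context wraps
  ch[2] <- "G"; ch[58] <- "C"  # wrapped: positions ...58,59,60,1,2 => C..G
  gc <- genome_sequence("onepam", paste(ch, collapse = ""), circular = TRUE)
  sites <- scan_pam_sites(gc)
  sites <- sites[sites$strand == "+" & sites$protospacer_start == 14L, ]
  out <- detect_tev_motif(sites, gc, spacer_range = c(13L, 17L))
  expect_true(out$tev_site[1])
})

test_that("tile_transversions yields 20 singles then 19 adjacent doubles", {
  tv <- tile_transversions("AAAAAAAAAAAAAAAAAAAA")
  expect_equal(nrow(tv), 39L)
  expect_equal(tv$n_mut, c(rep(1L, 20), rep(2L, 19)))
  n_c <- vapply(strsplit(tv$variant, ""), function(x) sum(x == "C"),
                integer(1))
  expect_equal(n_c, c(rep(1L, 20), rep(2L, 19)))
  # doubles mutate adjacent positions
  for (i in 21:39) {
    pos <- as.integer(strsplit(tv$mutated_positions[i], ",")[[1]])
    expect_equal(diff(pos), 1L)
    idx <- 21L - pos           # PAM-proximal numbering -> string index
    ch <- strsplit(tv$variant[i], "")[[1]]
    expect_true(all(ch[idx] == "C"))
    expect_true(all(ch[-idx] == "A"))
  }
  # position numbering: position 1 is PAM-proximal = string index 20
  v1 <- tile_transversions("ACGTACGTACGTACGTACGT")$variant[1]
  expect_equal(substr(v1, 20, 20), "G")   # T -> G at index 20
  expect_equal(substr(v1, 1, 19), "ACGTACGTACGTACGTACG")
  expect_error(tile_transversions("ACGTACGTACGTACGTACGN"))
})

test_that("mPool arithmetic: 28 parents x 40 + 20 non-targeting = 1140", {
  parents <- random_dna(28, 20, seed = 12)
  nt <- random_dna(20, 20, seed = 13)
  pool <- build_mpool(parents, nt)
  expect_equal(nrow(pool), 1140L)
  expect_equal(as.vector(table(pool$category)[c("exact", "mismatch",
                                                "non_targeting")]),
               c(28L, 28L * 39L, 20L))
  # category counts conserved through TSV serialization
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pool_tsv(pool, f)
  back <- read_pool_tsv(f)
  expect_equal(table(back$category), table(pool$category))
  # oligos carry the cloning flanks
  ol <- oligo_sequences(pool)
  expect_true(all(startsWith(ol, "CCTGGTTCTTGGTCTCTCACG")))
  expect_true(all(endsWith(ol, "GTTTTAGAGACCGCTGCCAGTTCATTTCTTAGGG")))
})

test_that("guide_pool validates mismatch positions against parents", {
  entries <- data.frame(
    name = c("p_exact", "p_mm1"),
    guide20 = c("AAAAAAAAAAAAAAAAAAAA", "AAAAAAAAAAAAAAAAAAAC"),
    category = c("exact", "mismatch"),
    parent = c(NA, "p_exact"),
    mutated_positions = c(NA, "1"), stringsAsFactors = FALSE)
  expect_s3_class(guide_pool(entries), "guide_pool")
  entries$mutated_positions[2] <- "2"
  expect_error(guide_pool(entries), "declared positions")
})

test_that("filter_offtargets removes PAM-adjacent k-mer duplicates only", {
  # build a genome where one site's PAM-proximal 15-mer + NGG recurs
  seq <- random_dna(1, 1500, seed = 21)
  g <- genome_sequence("chr", seq)
  sites <- scan_pam_sites(g)
  stopifnot(nrow(sites) > 3)
  dup <- sites[1, ]
  insert <- paste0(substr(dup$protospacer, 6, 20), "TGG")
  seq2 <- paste0(seq, strrep("A", 10), insert, strrep("A", 15))
  g2 <- genome_sequence("chr", seq2)
  sites2 <- scan_pam_sites(g2)
  kept <- filter_offtargets(sites2, g2, k = 15)
  # the duplicated guide is gone, and so is the planted copy
  expect_false(dup$protospacer %in% kept$protospacer)
  # idempotent and monotone
  again <- filter_offtargets(kept, g2, k = 15)
  expect_equal(nrow(again), nrow(kept))
  expect_lte(nrow(kept), nrow(sites2))
  # oracle: brute-force exclusion by scanning every PAM-adjacent 15-mer
  occ <- c()
  for (s in c(seq2, revcomp(seq2))) {
    L <- nchar(s)
    for (i in 1:(L - 17)) {
      if (substr(s, i + 16, i + 17) == "GG") occ <- c(occ, substr(s, i, i + 14))
    }
  }
  dup_kmers <- names(which(table(occ) >= 2))
  expect_equal(sort(kept$protospacer),
               sort(sites2$protospacer[
                 !substr(sites2$protospacer, 6, 20) %in% dup_kmers]))
})

test_that("input windows honour the length contract", {
  g <- genome_sequence("chr", random_dna(1, 500, seed = 41))
  sites <- scan_pam_sites(g)
  w28 <- build_input_window(sites, 0, 8)
  expect_true(all(nchar(w28) == 28))
  expect_equal(substr(w28, 1, 20), sites$protospacer)
  expect_equal(substr(w28, 21, 23), sites$pam)
  expect_equal(build_input_window(sites, 0, 0), sites$protospacer)
  w43 <- build_input_window(sites, 10, 13)
  expect_equal(w43, paste0(sites$upstream, sites$protospacer, sites$pam,
                           sites$downstream))
  expect_error(build_input_window(sites, 11, 0), "upstream")
  expect_error(build_input_window(sites, 0, 14), "downstream")
})

test_that("one-hot encoding is exact and invertible", {
  expect_equal(unname(encode_onehot("ACGT")), diag(4))
  s <- random_dna(1, 37, seed = 3)
  m <- encode_onehot(s)
  expect_true(all(colSums(m) == 1))
  expect_equal(decode_onehot(m), s)
  expect_error(encode_onehot("ACGN"), "outside")
  x <- encode_dataset(c("ACGT", "TTTT"))
  expect_equal(dim(x), c(2, 4, 4))
  expect_equal(x[1, , ], diag(4))
  expect_equal(x[2, 4, ], rep(1, 4))
})
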