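#' Genome or plasmid sequence for guide design
#'
#' Light container for a single DNA sequence. Circular sequences (plasmids)
#' allow target-site windows to wrap across the origin; linear sequences
#' drop sites whose 43-nt window would run off an end.
#'
#' @param id sequence name.
#' @param sequence DNA string over A/C/G/T/N (lower case accepted).
#' @param circular is the molecule circular?
#' @return an object of class `genome_sequence`.
#' @export
genome_sequence <- function(id, sequence, circular = FALSE) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("sequence must be non-empty")
  check_dna(sequence, allow_n = TRUE)
  structure(list(id = id, sequence = sequence, circular = circular,
                 length = nchar(sequence)),
            class = "genome_sequence")
}

#' Read sequences from a FASTA file as genome_sequence objects
#'
#' @param path FASTA file (gz accepted).
#' @param circular logical, recycled across records.
#' @return list of [genome_sequence()] objects.
#' @export
read_genome_fasta <- function(path, circular = FALSE) {
  ss <- Biostrings::readDNAStringSet(path)
  circular <- rep_len(circular, length(ss))
  lapply(seq_along(ss), function(i) {
    genome_sequence(names(ss)[i], as.character(ss[[i]]), circular[i])
  })
}

# circular-aware 1-based substring; from1 may be < 1 or beyond length
substr_circ <- function(s, from1, len, circular) {
  L <- nchar(s)
  if (!circular) {
    if (from1 < 1 || from1 + len - 1 > L) {
      stop("requested window [", from1, ", ", from1 + len - 1,
           "] falls outside a linear sequence of length ", L)
    }
    return(substr(s, from1, from1 + len - 1))
  }
  idx <- ((seq(from1, length.out = len) - 1) %% L) + 1
  paste(strsplit(s, "")[[1]][idx], collapse = "")
}

scan_one_strand <- function(s, circular, pam_regex, pam_len = 3L,
                            proto_len = 20L, up_len = 10L, down_len = 10L) {
  L <- nchar(s)
  win <- up_len + proto_len + pam_len + down_len
  if (circular) {
    ext <- paste0(substr(s, L - up_len + 1, L), s,
                  substr(s, 1, proto_len + pam_len + down_len - 1))
    starts1 <- seq_len(L)              # protospacer start, original coords
    off <- up_len
  } else {
    if (L < win) return(NULL)
    ext <- s
    starts1 <- seq(up_len + 1, L - (proto_len + pam_len + down_len) + 1)
    off <- 0L
  }
  ie <- starts1 + off
  pam <- substring(ext, ie + proto_len, ie + proto_len + pam_len - 1)
  hit <- grepl(pam_regex, pam)
  if (!any(hit)) return(NULL)
  ie <- ie[hit]
  starts1 <- starts1[hit]
  proto <- substring(ext, ie, ie + proto_len - 1)
  up <- substring(ext, ie - up_len, ie - 1)
  down <- substring(ext, ie + proto_len + pam_len,
                    ie + proto_len + pam_len + down_len - 1)
  ok <- !grepl("N", paste0(up, proto, pam[hit], down))
  data.frame(start1 = starts1[ok], protospacer = proto[ok],
             pam = pam[hit][ok], upstream = up[ok], downstream = down[ok],
             stringsAsFactors = FALSE)
}

#' Scan a sequence for PAM-adjacent target sites
#'
#' Finds every 20-nt protospacer followed by a 3-nt PAM matching
#' `pam_pattern` (IUPAC codes; default the SpCas9 5'-NGG-3') on both strands.
#' A site is reported only if its full 43-nt window -- 10 nt upstream,
#' 20-nt protospacer, 3-nt PAM, 10 nt downstream -- fits in the sequence
#' (windows may wrap on circular sequences). Reverse-strand sites are stored
#' in guide orientation: `protospacer`, `pam`, `upstream`, `downstream` all
#' read 5'->3' on the targeted (guide) strand, while `protospacer_start` is
#' the 0-based, half-open start of the protospacer interval on the + strand.
#'
#' @param genome a [genome_sequence()] (or plain DNA string, treated as
#'   linear).
#' @param pam_pattern 3-letter IUPAC PAM pattern.
#' @return data.frame of class `target_sites` with columns `contig`,
#'   `strand`, `protospacer_start`, `protospacer`, `pam`, `upstream`,
#'   `downstream`, `tev_site` (NA until [detect_tev_motif()] is run),
#'   sorted by (contig, protospacer_start, strand).
#' @export
scan_pam_sites <- function(genome, pam_pattern = "NGG") {
  if (is.character(genome)) genome <- genome_sequence("seq", genome)
  if (nchar(pam_pattern) != 3) stop("pam_pattern must have length 3")
  pam_regex <- iupac_regex(pam_pattern)
  s <- genome$sequence
  L <- genome$length
  if (L < 43 && !genome$circular) {
    warning("sequence shorter than the 43-nt site window; no sites")
    return(empty_sites())
  }
  plus <- scan_one_strand(s, genome$circular, pam_regex)
  minus <- scan_one_strand(revcomp(s), genome$circular, pam_regex)
  rows <- list()
  if (!is.null(plus)) {
    rows$p <- data.frame(contig = genome$id, strand = "+",
                         protospacer_start = plus$start1 - 1L,
                         protospacer = plus$protospacer, pam = plus$pam,
                         upstream = plus$upstream, downstream = plus$downstream,
                         stringsAsFactors = FALSE)
  }
  if (!is.null(minus)) {
    st <- L - minus$start1 - 19L
    if (genome$circular) st <- st %% L
    rows$m <- data.frame(contig = genome$id, strand = "-",
                         protospacer_start = st,
                         protospacer = minus$protospacer, pam = minus$pam,
                         upstream = minus$upstream,
                         downstream = minus$downstream,
                         stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0) empty_sites() else do.call(rbind, rows)
  out$tev_site <- rep(NA, nrow(out))
  out <- out[order(out$contig, out$protospacer_start, out$strand), ]
  rownames(out) <- NULL
  class(out) <- c("target_sites", "data.frame")
  out
}

empty_sites <- function() {
  out <- data.frame(contig = character(), strand = character(),
                    protospacer_start = integer(), protospacer = character(),
                    pam = character(), upstream = character(),
                    downstream = character(), tev_site = logical(),
                    stringsAsFactors = FALSE)
  class(out) <- c("target_sites", "data.frame")
  out
}

# guide-strand upstream context of length `len` ending at the protospacer
# 5' end, re-extracted from the genome (the stored window holds only 10 nt)
guide_upstream <- function(genome, strand, protospacer_start, len) {
  s <- genome$sequence
  if (strand == "+") {
    substr_circ(s, protospacer_start + 1 - len, len, genome$circular)
  } else {
    end1 <- protospacer_start + 20
    revcomp(substr_circ(s, end1 + 1, len, genome$circular))
  }
}

#' Test an upstream context for the I-TevI 5'-CNNNG-3' cleavage motif
#'
#' The motif G must sit `d` nucleotides upstream of the protospacer 5' end
#' for some `d` in `spacer_range`, with the motif C four positions further
#' upstream (C-N-N-N-G), all read on the guide strand.
#'
#' @param upstream_ctx guide-strand sequence ending immediately before the
#'   protospacer 5' end.
#' @param spacer_range integer `c(min_offset, max_offset)` for the G offset.
#' @return logical.
#' @export
has_tev_motif <- function(upstream_ctx, spacer_range = c(13L, 17L)) {
  lo <- spacer_range[1]; hi <- spacer_range[2]
  Lc <- nchar(upstream_ctx)
  if (Lc < lo + 4) {
    stop("upstream context of length ", Lc, " is too short; need at least ",
         lo + 4, " nt to test the minimal offset ", lo)
  }
  ch <- strsplit(upstream_ctx, "")[[1]]
  for (d in lo:min(hi, Lc - 4L)) {
    if (ch[Lc - d + 1] == "G" && ch[Lc - d - 3] == "C") return(TRUE)
  }
  FALSE
}

#' Flag target sites carrying an upstream I-TevI cleavage motif
#'
#' TevSpCas9 additionally requires a 5'-CNNNG-3' I-TevI site at the correct
#' spacing upstream of the Cas9-bound protospacer. This re-extracts extended
#' upstream context from the genome (wrapping on circular sequences) and
#' fills the `tev_site` column.
#'
#' @param sites a `target_sites` data.frame from [scan_pam_sites()].
#' @param genome the [genome_sequence()] the sites came from.
#' @param spacer_range allowed offsets of the motif G upstream of the
#'   protospacer 5' end.
#' @return `sites` with `tev_site` populated.
#' @export
detect_tev_motif <- function(sites, genome, spacer_range = c(13L, 17L)) {
  need <- spacer_range[2] + 4L
  sites$tev_site <- vapply(seq_len(nrow(sites)), function(i) {
    ctx <- guide_upstream(genome, sites$strand[i],
                          sites$protospacer_start[i], need)
    has_tev_motif(ctx, spacer_range)
  }, logical(1))
  sites
}

#' Exclude guides with PAM-proximal off-target matches
#'
#' Removes any site whose PAM-proximal `k`-mer (protospacer positions
#' 1..k counted from the PAM) occurs adjacent to an NGG PAM at more than
#' one locus in the genome, on either strand. Matches without a PAM are
#' ignored (they cannot be cleaved).
#'
#' @param sites `target_sites` data.frame.
#' @param genome the [genome_sequence()] to search for off-targets.
#' @param k length of the PAM-proximal match (default 15).
#' @return the retained sites, unchanged, with attribute `removed` giving
#'   the number of excluded sites.
#' @export
filter_offtargets <- function(sites, genome, k = 15L) {
  if (k > 20) stop("k must be <= 20")
  occ <- pam_adjacent_kmers(genome, k)
  tab <- table(occ)
  kmer <- substr(sites$protospacer, 21L - k, 20L)
  n_occ <- as.integer(tab[kmer])
  n_occ[is.na(n_occ)] <- 0L
  keep <- n_occ < 2L
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("target_sites", "data.frame")
  attr(out, "removed") <- sum(!keep)
  out
}

# all k-mers immediately 5' of an NGG PAM, both strands
pam_adjacent_kmers <- function(genome, k) {
  grab <- function(s) {
    L <- nchar(s)
    if (genome$circular) {
      ext <- paste0(s, substr(s, 1, k + 2))
      starts1 <- seq_len(L)
    } else {
      if (L < k + 3) return(character())
      ext <- s
      starts1 <- seq_len(L - k - 2)
    }
    gg <- substring(ext, starts1 + k + 1, starts1 + k + 2) == "GG"
    substring(ext, starts1, starts1 + k - 1)[gg]
  }
  c(grab(genome$sequence), grab(revcomp(genome$sequence)))
}

#' Extract the model input window for target sites
#'
#' Builds the contiguous guide-strand sequence used as model input:
#' the 20-nt protospacer always, plus `upstream_nt` nucleotides 5' of it and
#' `downstream_nt` nucleotides 3' of it. Downstream counts the PAM first, so
#' `downstream_nt = 3` appends exactly the PAM and the default
#' `(0, 8)` yields the 28-nt input: protospacer + PAM + 5 nt.
#'
#' @param sites `target_sites` data.frame.
#' @param upstream_nt 0..10.
#' @param downstream_nt 0..13 (PAM = first 3).
#' @return character vector of windows, length `nrow(sites)`.
#' @export
build_input_window <- function(sites, upstream_nt = 0L, downstream_nt = 8L) {
  if (upstream_nt < 0 || upstream_nt > 10) stop("upstream_nt must be in 0..10")
  if (downstream_nt < 0 || downstream_nt > 13) {
    stop("downstream_nt must be in 0..13")
  }
  up <- if (upstream_nt > 0) {
    substr(sites$upstream, 11L - upstream_nt, 10L)
  } else ""
  down <- if (downstream_nt > 0) {
    substr(paste0(sites$pam, sites$downstream), 1L, downstream_nt)
  } else ""
  paste0(up, sites$protospacer, down)
}

#' Write a target-site table as TSV
#' @param sites `target_sites` data.frame.
#' @param path output file.
#' @export
write_sites_tsv <- function(sites, path) {
  df <- as.data.frame(sites)
  df$end <- df$protospacer_start + 20L
  df <- df[, c("contig", "protospacer_start", "end", "strand", "protospacer",
               "pam", "upstream", "downstream", "tev_site")]
  names(df)[2] <- "start"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write target sites as BED6
#' @param sites `target_sites` data.frame.
#' @param path output file.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- data.frame(chrom = sites$contig, start = sites$protospacer_start,
                    end = sites$protospacer_start + 20L,
                    name = sites$protospacer, score = 0L,
                    strand = sites$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
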