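# Golden-Gate cloning flanks appended to every emitted oligo
FLANK5_DEFAULT <- "CCTGGTTCTTGGTCTCTCACG"
FLANK3_DEFAULT <- "GTTTTAGAGACCGCTGCCAGTTCATTTCTTAGGG"

DEFAULT_TRANSVERSION <- c(A = "C", C = "A", G = "T", T = "G")

#' Tile single and adjacent-double transversions along a guide
#'
#' Produces the mismatch series used in mutant-pool design: one variant per
#' protospacer position with that base transverted (20 variants), followed
#' by one variant per adjacent position pair (19 variants), 39 in total.
#' Positions are numbered 1 (PAM-proximal) to 20 (PAM-distal); position `p`
#' is character `21 - p` of the 5'->3' guide string.
#'
#' @param guide20 a 20-nt guide (5'->3', PAM-distal first).
#' @param transversion_map named character vector sending each purine to a
#'   pyrimidine and vice versa.
#' @return data.frame with `variant` (20-nt sequence), `mutated_positions`
#'   (comma-separated PAM-proximal position numbers), `n_mut`.
#' @export
tile_transversions <- function(guide20,
                               transversion_map = DEFAULT_TRANSVERSION) {
  if (nchar(guide20) != 20) stop("guide must be 20 nt")
  check_dna(guide20, what = "guide")
  pur <- c("A", "G"); pyr <- c("C", "T")
  for (b in names(transversion_map)) {
    tgt <- transversion_map[[b]]
    swap <- (b %in% pur && tgt %in% pyr) || (b %in% pyr && tgt %in% pur)
    if (!swap) stop("transversion map must swap purines and pyrimidines: ",
                    b, "->", tgt)
  }
  ch <- strsplit(guide20, "")[[1]]
  mutate_at <- function(pos) {
    # pos in PAM-proximal numbering
    v <- ch
    for (p in pos) {
      i <- 21L - p
      v[i] <- transversion_map[[v[i]]]
    }
    paste(v, collapse = "")
  }
  singles <- data.frame(
    variant = vapply(1:20, function(p) mutate_at(p), character(1)),
    mutated_positions = as.character(1:20),
    n_mut = 1L, stringsAsFactors = FALSE)
  doubles <- data.frame(
    variant = vapply(1:19, function(p) mutate_at(c(p, p + 1L)), character(1)),
    mutated_positions = paste(1:19, 2:20, sep = ","),
    n_mut = 2L, stringsAsFactors = FALSE)
  rbind(singles, doubles)
}

#' Construct a guide pool object
#'
#' @param entries data.frame with columns `name`, `guide20`, `category`
#'   (one of exact, mismatch, non_targeting), `parent` (NA for exact and
#'   non-targeting), `mutated_positions` (comma-separated, NA if none).
#' @param flank5,flank3 cloning flanks added when emitting oligos.
#' @return data.frame of class `guide_pool`.
#' @export
guide_pool <- function(entries, flank5 = FLANK5_DEFAULT,
                       flank3 = FLANK3_DEFAULT) {
  stopifnot(all(c("name", "guide20", "category", "parent",
                  "mutated_positions") %in% names(entries)))
  if (anyDuplicated(entries$name)) stop("guide names must be unique")
  if (!all(entries$category %in% c("exact", "mismatch", "non_targeting"))) {
    stop("unknown category")
  }
  check_dna(entries$guide20, what = "guide")
  # mismatch entries must differ from their parent exactly at the
  # declared positions (PAM-proximal numbering)
  mm <- which(entries$category == "mismatch" & !is.na(entries$parent))
  parent_seq <- setNames(entries$guide20, entries$name)
  for (i in mm) {
    p <- parent_seq[entries$parent[i]]
    if (is.na(p)) next  # parent not carried in the pool (e.g. oPool spike-ins)
    a <- strsplit(entries$guide20[i], "")[[1]]
    b <- strsplit(p, "")[[1]]
    differ <- sort(21L - which(a != b))
    declared <- sort(as.integer(strsplit(entries$mutated_positions[i],
                                         ",")[[1]]))
    if (!identical(differ, declared)) {
      stop("entry ", entries$name[i],
           " does not differ from its parent at the declared positions")
    }
  }
  structure(entries, class = c("guide_pool", "data.frame"),
            flank5 = flank5, flank3 = flank3)
}

#' Build a mismatch-tiled mutant pool (mPool)
#'
#' For each parent guide: the exact-match guide plus its 39 transversion
#' variants from [tile_transversions()]; plus a set of non-targeting
#' controls. With 28 parents and 20 non-targeting guides this yields
#' 28 x 40 + 20 = 1140 oligos.
#'
#' @param parents named character vector of 20-nt parent guides.
#' @param non_targeting character vector of non-targeting control guides
#'   (named or not).
#' @param transversion_map see [tile_transversions()].
#' @param flank5,flank3 cloning flanks.
#' @return a [guide_pool()].
#' @export
build_mpool <- function(parents, non_targeting,
                        transversion_map = DEFAULT_TRANSVERSION,
                        flank5 = FLANK5_DEFAULT, flank3 = FLANK3_DEFAULT) {
  if (is.null(names(parents))) {
    names(parents) <- sprintf("parent%02d", seq_along(parents))
  }
  blocks <- lapply(names(parents), function(nm) {
    tv <- tile_transversions(parents[[nm]], transversion_map)
    rbind(
      data.frame(name = paste0(nm, "_exact"), guide20 = parents[[nm]],
                 category = "exact", parent = NA_character_,
                 mutated_positions = NA_character_, stringsAsFactors = FALSE),
      data.frame(name = paste0(nm, "_mm", gsub(",", "_",
                                               tv$mutated_positions)),
                 guide20 = tv$variant, category = "mismatch",
                 parent = paste0(nm, "_exact"),
                 mutated_positions = tv$mutated_positions,
                 stringsAsFactors = FALSE))
  })
  nt_names <- if (is.null(names(non_targeting))) {
    sprintf("nt%02d", seq_along(non_targeting))
  } else names(non_targeting)
  nt <- data.frame(name = nt_names, guide20 = unname(non_targeting),
                   category = "non_targeting", parent = NA_character_,
                   mutated_positions = NA_character_, stringsAsFactors = FALSE)
  guide_pool(do.call(rbind, c(blocks, list(nt))), flank5, flank3)
}

#' Oligo sequences for a pool (guides with cloning flanks)
#' @param pool a [guide_pool()].
#' @return named character vector of oligos.
#' @export
oligo_sequences <- function(pool) {
  setNames(paste0(attr(pool, "flank5"), pool$guide20, attr(pool, "flank3")),
           pool$name)
}

#' Write a guide pool as TSV (categories and counts survive round-trip)
#' @param pool a [guide_pool()].
#' @param path output file.
#' @export
write_pool_tsv <- function(pool, path) {
  write.table(as.data.frame(pool), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "")
  invisible(path)
}

#' Read a guide pool written by [write_pool_tsv()]
#' @param path TSV file.
#' @param flank5,flank3 cloning flanks to attach.
#' @return a [guide_pool()].
#' @export
read_pool_tsv <- function(path, flank5 = FLANK5_DEFAULT,
                          flank3 = FLANK3_DEFAULT) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "")
  guide_pool(df, flank5, flank3)
}

#' Write pool oligos as FASTA
#' @param pool a [guide_pool()].
#' @param path output file.
#' @export
write_pool_fasta <- function(pool, path) {
  ol <- oligo_sequences(pool)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ol), path)
  invisible(path)
}
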