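#' Guide-by-sample count matrix with experimental design
#'
#' @param counts non-negative integer matrix, guides in rows (rownames
#'   required), samples in columns (colnames required).
#' @param condition per-sample condition label, e.g. "induced", "repressed",
#'   "control_dead", "initial_pool".
#' @param replicate per-sample replicate index.
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, condition, replicate) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) stop("counts needs guide rownames")
  if (anyDuplicated(rownames(counts))) stop("guide names must be unique")
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0(condition, "_", replicate)
  }
  if (length(condition) != ncol(counts) || length(replicate) != ncol(counts)) {
    stop("condition/replicate must have one entry per sample")
  }
  structure(list(counts = counts, condition = as.character(condition),
                 replicate = as.integer(replicate)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "guides x", ncol(x$counts),
      "samples\n")
  cat("conditions:", paste(sprintf("%s(%d)", names(table(x$condition)),
                                   table(x$condition)), collapse = ", "), "\n")
  invisible(x)
}

#' Demultiplex barcoded amplicon reads into guide counts
#'
#' Reads have the fixed layout
#' `[random prefix][replicate barcode][guide flank][20-nt guide]...`.
#' Both the barcode and the guide are matched exactly; any read failing
#' either lookup (including single-nucleotide barcode errors) is counted as
#' discarded. Read order does not affect the result.
#'
#' @param reads FASTQ path (gz accepted) or a `Biostrings::DNAStringSet` /
#'   character vector of read sequences.
#' @param design list with `random_prefix_len` (default 4), `barcode_len`
#'   (default 12), `barcodes` (named character vector barcode -> sample id),
#'   `sample_condition` and `sample_replicate` (named by sample id),
#'   `guide_flank5` (fixed sequence between barcode and guide, may be ""),
#'   `guide_len` (default 20).
#' @param pool a [guide_pool()] or character vector of guide sequences.
#' @return [count_matrix()] with attribute `discarded` (number of unmatched
#'   reads).
#' @export
demultiplex <- function(reads, design, pool) {
  design <- amplicon_design(design)
  if (anyDuplicated(names(design$barcodes))) {
    stop("duplicate barcodes in design")
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- as.character(Biostrings::readDNAStringSet(reads,
                                                       format = "fastq"))
  } else {
    reads <- as.character(reads)
  }
  guides <- if (inherits(pool, "guide_pool")) {
    setNames(pool$guide20, pool$name)
  } else if (!is.null(names(pool))) pool else setNames(pool, pool)
  samples <- unname(design$barcodes)
  cm <- matrix(0L, nrow = length(guides), ncol = length(samples),
               dimnames = list(names(guides), samples))
  if (length(reads) > 0) {
    b0 <- design$random_prefix_len
    bc <- substr(reads, b0 + 1, b0 + design$barcode_len)
    g0 <- b0 + design$barcode_len + nchar(design$guide_flank5)
    flank <- substr(reads, b0 + design$barcode_len + 1, g0)
    gd <- substr(reads, g0 + 1, g0 + design$guide_len)
    sample_id <- design$barcodes[bc]
    guide_name <- names(guides)[match(gd, guides)]
    ok <- !is.na(sample_id) & !is.na(guide_name) &
      (nchar(design$guide_flank5) == 0 | flank == design$guide_flank5)
    tab <- table(factor(guide_name[ok], levels = names(guides)),
                 factor(sample_id[ok], levels = samples))
    cm <- cm + unclass(as.matrix(tab))
    dimnames(cm) <- list(names(guides), samples)
    discarded <- sum(!ok)
  } else {
    discarded <- 0L
  }
  out <- count_matrix(cm,
                      condition = design$sample_condition[samples],
                      replicate = design$sample_replicate[samples])
  attr(out, "discarded") <- discarded
  out
}

#' Amplicon design descriptor
#'
#' @param x list of design fields; missing fields take defaults
#'   (4-nt random prefix, 12-mer barcodes, 20-nt guide).
#' @return validated design list.
#' @export
amplicon_design <- function(x) {
  d <- list(random_prefix_len = 4L, barcode_len = 12L, guide_flank5 = "",
            guide_len = 20L)
  d[names(x)] <- x
  if (is.null(d$barcodes)) stop("design needs a barcodes map")
  if (any(nchar(names(d$barcodes)) != d$barcode_len)) {
    stop("all barcodes must have length ", d$barcode_len)
  }
  if (is.null(d$sample_condition) || is.null(d$sample_replicate)) {
    stop("design needs sample_condition and sample_replicate, named by sample")
  }
  d
}

#' Remove guides with low counts in control samples
#'
#' Drops any guide whose count is below `min_count` in *any* sample of the
#' control condition (the "less than 20 in either replicate" rule: a guide
#' with counts (20, 20) is retained, (19, 500) is removed).
#'
#' @param cm a [count_matrix()].
#' @param control_condition condition label of the control samples (e.g. the
#'   catalytically dead nuclease).
#' @param min_count strict lower threshold (default 20).
#' @return filtered [count_matrix()] with attribute `removed` (guide names).
#' @export
filter_low_counts <- function(cm, control_condition, min_count = 20L) {
  ctrl <- which(cm$condition == control_condition)
  if (length(ctrl) == 0) stop("no samples with condition ", control_condition)
  low <- apply(cm$counts[, ctrl, drop = FALSE] < min_count, 1, any)
  out <- count_matrix(cm$counts[!low, , drop = FALSE], cm$condition,
                      cm$replicate)
  attr(out, "removed") <- rownames(cm$counts)[low]
  out
}
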