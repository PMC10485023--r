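BASES <- c("A", "C", "G", "T")

IUPAC_CLASS <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
  K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
  H = "[ACT]", V = "[ACG]", N = "[ACGT]"
)

#' Reverse complement of DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

iupac_regex <- function(pattern) {
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(IUPAC_CLASS))
  if (length(bad) > 0) {
    stop("not an IUPAC nucleotide code: ", paste(bad, collapse = ", "))
  }
  paste0("^", paste(IUPAC_CLASS[chars], collapse = ""), "$")
}

check_dna <- function(x, allow_n = FALSE, what = "sequence") {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  if (!all(grepl(pat, x))) {
    stop(what, " contains characters outside {A,C,G,T",
         if (allow_n) ",N" else "", "}")
  }
  invisible(x)
}

#' Seed-scoped random number generation
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not perturb the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
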