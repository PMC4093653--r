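#' @importFrom stats rbinom runif setNames
#' @importFrom utils head tail write.table read.delim
#' @importFrom methods is
#' @import data.table
NULL

utils::globalVariables(c("kmer", "pos", "n", "i", "j", "d", "cl", "qpos",
                         "spos", "rck", "rec", "lo", "hi", "n_seeds", "w",
                         ".N", "."))

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Round half away from zero
#'
#' Decimal rounding where .5 always rounds up in magnitude, matching the
#' printed precision of the summary tables this package emulates (base R's
#' `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## run body with the global RNG seeded, restoring the caller's RNG state
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  if (n <= 0) return(character(0))
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

## character-vector reverse complement (keeps N)
revcomp_chars <- function(x) {
  rev(chartr("ACGTN", "TGCAN", x))
}

#' Reverse-complement a nucleotide string
#'
#' @param x single nucleotide string over A/C/G/T/N.
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## validate a genome given as a named character vector of A/C/G/T/N strings
check_genome <- function(genome) {
  if (is(genome, "DNAStringSet")) {
    genome <- setNames(as.character(genome), names(genome))
  }
  if (!is.character(genome) || is.null(names(genome)) ||
      anyDuplicated(names(genome)) || any(!nzchar(names(genome)))) {
    stop("genome must be a uniquely named character vector of sequences")
  }
  if (any(grepl("[^ACGTN]", genome))) {
    stop("genome sequences may contain only A, C, G, T, N")
  }
  genome
}

check_peptide <- function(x, what = "peptide") {
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the amino-acid alphabet: %s",
                 what, paste(head(which(bad)), collapse = ", ")))
  }
  invisible(x)
}

## 0-based half-open substring of a sequence string
substr0 <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1, end)
}

## substitution matrix shipped with Biostrings, fixed for all protein work
protein_matrix <- function() {
  get(utils::data("BLOSUM62", package = "Biostrings", envir = environment()))
}

#' Alignment bit score and E-value
#'
#' The package uses a deliberately simple, deterministic E-value: for a raw
#' local-alignment score converted to bits, `E = m * n * 2^(-bits)` where `m`
#' is the searched database size (total residues) and `n` the query length.
#' This is a conservative bound rather than a fitted Karlin-Altschul
#' statistic; thresholds remain user-configurable.
#'
#' Protein scores under BLOSUM62 are treated as half-bit units
#' (`bits = score / 2`); nucleotide scores under the +1/-2 scheme are taken
#' as bits directly.
#'
#' @param score raw alignment score.
#' @param m database size in residues.
#' @param n query length in residues.
#' @param bits_per_score conversion from raw score to bits.
#' @return E-value (numeric).
#' @export
alignment_evalue <- function(score, m, n, bits_per_score = 0.5) {
  bits <- score * bits_per_score
  m * n * 2^(-bits)
}

## exact k-mer start positions shared between two sequences, as a
## data.table(qpos, spos) of 1-based starts
shared_kmers <- function(query, subject, k) {
  nq <- nchar(query) - k + 1
  ns <- nchar(subject) - k + 1
  if (nq < 1 || ns < 1) {
    return(data.table::data.table(qpos = integer(0), spos = integer(0)))
  }
  qk <- data.table::data.table(kmer = substring(query, 1:nq, k:(nq + k - 1)),
                               qpos = 1:nq)
  sk <- data.table::data.table(kmer = substring(subject, 1:ns, k:(ns + k - 1)),
                               spos = 1:ns)
  m <- merge(qk, sk, by = "kmer", allow.cartesian = TRUE)
  m[, c("qpos", "spos")]
}

## longest A-run (or T-run) ending inside [from, to] (1-based inclusive);
## returns list(start, end) of the run or NULL
polya_run <- function(chars, min_len = 10) {
  r <- rle(chars == "A")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values & r$lengths >= min_len
  if (!any(ok)) return(NULL)
  data.frame(start = starts[ok], end = ends[ok], len = r$lengths[ok])
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name))
  }
}
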