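## Thin wrappers around Biostrings dynamic-programming alignment, fixing the
## scoring schemes used throughout the package:
##   nucleotide: match +1, mismatch -2, gap open 2, gap extend 1
##   protein:    BLOSUM62 (shipped with Biostrings), gap open 11, extend 1

NT_MAT <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                   baseOnly = FALSE)

#' Local nucleotide alignment
#'
#' Smith-Waterman local alignment under the package's fixed nucleotide
#' scoring (+1/-2, affine gaps 2/1).
#'
#' @param pattern,subject nucleotide strings.
#' @return list with `score`, `nmatch`, `aligned_len` (alignment columns),
#'   1-based `pattern_start`, `pattern_end`, `subject_start`, `subject_end`.
#' @export
nt_local_align <- function(pattern, subject) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = NT_MAT,
    gapOpening = 2, gapExtension = 1)
  summarize_alignment(al)
}

#' Local protein alignment
#'
#' Smith-Waterman under BLOSUM62 with affine gaps 11/1.
#'
#' @inheritParams nt_local_align
#' @return see [nt_local_align()].
#' @export
aa_local_align <- function(pattern, subject) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    type = "local", substitutionMatrix = protein_matrix(),
    gapOpening = 11, gapExtension = 1)
  summarize_alignment(al)
}

#' Global protein alignment
#'
#' Needleman-Wunsch under BLOSUM62 with affine gaps 11/1. Used for
#' reverse-transcriptase domain distances.
#'
#' @inheritParams nt_local_align
#' @return list with `score` and the two aligned strings (`pattern_aln`,
#'   `subject_aln`, gap character `-`).
#' @export
aa_global_align <- function(pattern, subject) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(pattern), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = protein_matrix(),
    gapOpening = 11, gapExtension = 1)
  list(score = Biostrings::score(al),
       pattern_aln = as.character(Biostrings::alignedPattern(al)),
       subject_aln = as.character(Biostrings::alignedSubject(al)))
}

summarize_alignment <- function(al) {
  list(
    score = Biostrings::score(al),
    nmatch = Biostrings::nmatch(al),
    aligned_len = Biostrings::nchar(al),
    pattern_start = IRanges::start(Biostrings::pattern(al)),
    pattern_end = IRanges::end(Biostrings::pattern(al)),
    subject_start = IRanges::start(Biostrings::subject(al)),
    subject_end = IRanges::end(Biostrings::subject(al))
  )
}
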