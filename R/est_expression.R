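## EST classification against the representative library and the
## per-superfamily expression summary.

#' Map ESTs to the representative library
#'
#' Nucleotide seeded local alignment (both strands, +1/-2 scoring, affine
#' gaps 2/1) of each EST against each library representative; candidate
#' pairs are prefiltered on a shared exact k-mer. The best hit per EST with
#' E-value below the cutoff assigns the representative's superfamily
#' (`E = m * n * 2^(-score)`, `m` total library nt, `n` EST length); ties on
#' bit score go to the first representative in library order and are
#' reported in a message. ESTs with no qualifying hit stay unassigned
#' (`NA`). Assignment does not depend on EST input order.
#'
#' @param ests data.frame with `est_id`, `seq` (e.g. [simulate_ests()]).
#' @param library result of [build_library()], or a data.frame with
#'   `family_id`, `superfamily`, `seq`.
#' @param evalue_cutoff assignment threshold.
#' @param prefilter_kmer exact k-mer length for the seed prefilter.
#' @return data.frame with `est_id`, `family_id`, `superfamily`,
#'   `bit_score`, `evalue`, `strand` (`NA` rows = unassigned).
#' @export
map_ests <- function(ests, library, evalue_cutoff = 1e-5,
                     prefilter_kmer = 11) {
  records <- if (is.data.frame(library)) library else library$records
  if (is.null(records) || nrow(records) == 0) stop("library must be non-empty")
  if (nrow(ests) == 0) {
    return(data.frame(est_id = character(0), family_id = character(0),
                      superfamily = character(0), bit_score = numeric(0),
                      evalue = numeric(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  m_total <- sum(nchar(records$seq))
  k <- prefilter_kmer
  lib_kmers <- data.table::rbindlist(lapply(seq_len(nrow(records)), function(r) {
    s <- records$seq[r]
    nk <- nchar(s) - k + 1
    if (nk < 1) return(NULL)
    data.table::data.table(kmer = unique(substring(s, 1:nk, k:nchar(s))),
                           rec = r)
  }))
  data.table::setkey(lib_kmers, kmer)

  n_ties <- 0L
  rows <- lapply(seq_len(nrow(ests)), function(i) {
    est <- ests$seq[i]
    out <- data.frame(est_id = ests$est_id[i], family_id = NA_character_,
                      superfamily = NA_character_, bit_score = NA_real_,
                      evalue = NA_real_, strand = NA_character_,
                      stringsAsFactors = FALSE)
    best <- NULL
    ## per strand, count shared words per library record; align each
    ## candidate record on its better-seeded strand only
    seed_counts <- list()
    for (strand in c("+", "-")) {
      s <- if (strand == "+") est else revcomp(est)
      nk <- nchar(s) - k + 1
      if (nk < 1) next
      ek <- unique(substring(s, 1:nk, k:nchar(s)))
      hits_dt <- lib_kmers[data.table::data.table(kmer = ek), nomatch = NULL]
      seed_counts[[strand]] <- if (nrow(hits_dt)) table(hits_dt$rec) else NULL
    }
    cands <- unique(c(names(seed_counts[["+"]]), names(seed_counts[["-"]])))
    for (rc_ in sort(as.integer(cands))) {
      np <- seed_counts[["+"]][as.character(rc_)]
      nm <- seed_counts[["-"]][as.character(rc_)]
      np <- if (is.na(np) || is.null(np)) 0L else np
      nm <- if (is.na(nm) || is.null(nm)) 0L else nm
      strand <- if (nm > np) "-" else "+"
      s <- if (strand == "+") est else revcomp(est)
      al <- nt_local_align(s, records$seq[rc_])
      bits <- al$score
      ev <- m_total * nchar(est) * 2^(-bits)
      if (ev >= evalue_cutoff) next
      if (is.null(best) || bits > best$bits) {
        best <- list(bits = bits, ev = ev, rec = rc_, strand = strand)
      } else if (bits == best$bits && rc_ != best$rec) {
        n_ties <<- n_ties + 1L   # keep the earlier record in library order
      }
    }
    if (!is.null(best)) {
      out$family_id <- records$family_id[best$rec]
      out$superfamily <- records$superfamily[best$rec]
      out$bit_score <- best$bits
      out$evalue <- best$ev
      out$strand <- best$strand
    }
    out
  })
  if (n_ties > 0) {
    message(n_ties, " EST(s) had tied best hits; first library record kept")
  }
  do.call(rbind, rows)
}

EST_DNA_SUPERFAMILIES <- c("Helitron", "CACTA", "MULE", "hAT", "PIF/Harbinger")

#' Summarise EST hits per superfamily
#'
#' Percentages are computed against the supplied total and rounded half-up
#' to one decimal; the DNA-transposon subtotal sums Helitron, CACTA, MULE,
#' hAT and PIF/Harbinger. The per-superfamily counts are not required to
#' reach the total (a total may include ESTs outside the tabulated
#' categories).
#'
#' @param x either an assignment data.frame from [map_ests()] (counts are
#'   the non-`NA` assignments) or a named count vector.
#' @param total denominator for the percentages; defaults to the number of
#'   assigned ESTs when `x` is an assignment data.frame. Must be positive.
#' @return list with `total_te_ests`, `per_superfamily` (data.frame
#'   `superfamily`, `count`, `percent`), `dna_te_subtotal` (list `count`,
#'   `percent`).
#' @export
summarize_est_hits <- function(x, total = NULL) {
  if (is.data.frame(x)) {
    counts <- table(x$superfamily[!is.na(x$superfamily)])
    counts <- setNames(as.numeric(counts), names(counts))
    if (is.null(total)) total <- sum(counts)
  } else {
    counts <- x
    if (is.null(total)) stop("total must be supplied with a count vector")
  }
  if (is.null(total) || total <= 0) stop("total must be positive")
  per <- data.frame(
    superfamily = names(counts),
    count = as.numeric(counts),
    percent = round_half_up(100 * as.numeric(counts) / total, 1),
    stringsAsFactors = FALSE)
  dna <- sum(counts[names(counts) %in% EST_DNA_SUPERFAMILIES])
  list(total_te_ests = total, per_superfamily = per,
       dna_te_subtotal = list(count = dna,
                              percent = round_half_up(100 * dna / total, 1)))
}

#' Stacked-bar figure of the EST summary
#'
#' @param summary result of [summarize_est_hits()].
#' @param file optional path; when given, a PDF is written.
#' @return invisibly, the plotted counts.
#' @export
plot_est_summary <- function(summary, file = NULL) {
  per <- summary$per_superfamily
  per <- per[order(-per$count), , drop = FALSE]
  if (!is.null(file)) {
    grDevices::pdf(file, width = 7, height = 4.5)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mar = c(9, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  bp <- graphics::barplot(per$count, names.arg = per$superfamily, las = 2,
                          ylab = "TE-related ESTs",
                          main = "ESTs with similarity to transposons")
  graphics::text(bp, per$count, labels = sprintf("%.1f%%", per$percent),
                 pos = 3, cex = 0.7, xpd = NA)
  invisible(setNames(per$count, per$superfamily))
}
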