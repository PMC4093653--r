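## Six-frame translated homology search against conserved transposase /
## reverse-transcriptase domain peptides: the in-package equivalent of a
## TBLASTN screen, with k-mer seeded, stop-bounded local alignment and a
## deterministic E-value, plus 10-kb flank extraction around hits.

empty_hits <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             frame = integer(0), strand = character(0), score = numeric(0),
             bit_score = numeric(0), evalue = numeric(0),
             query_id = character(0), superfamily = character(0),
             flank_start = integer(0), flank_end = integer(0),
             stringsAsFactors = FALSE)
}

## translate one frame; returns list(aa, frame, strand) with frame in 1..3
frame_translations <- function(seq) {
  L <- nchar(seq)
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  out <- list()
  for (strand in c("+", "-")) {
    x <- if (strand == "+") fwd else rev
    for (f in 1:3) {
      n_cod <- (L - f + 1) %/% 3
      if (n_cod < 1) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::subseq(x, f, f + 3 * n_cod - 1),
        if.fuzzy.codon = "solve", no.init.codon = TRUE)))
      out[[length(out) + 1]] <- list(aa = aa, frame = f, strand = strand)
    }
  }
  out
}

#' Translated search of a genome against domain peptides
#'
#' Translates the genome in all six frames (stop codons bound alignable
#' segments), seeds on exact 4-aa words shared with each query, and runs
#' local alignment (BLOSUM62, affine gaps 11/1) of the query against the
#' stop-free subject segments around each seed cluster. E-values use the
#' package's deterministic bound `E = m * n * 2^(-bits)` with `bits =
#' score/2`, `m` the total translated residues and `n` the query length
#' (see [alignment_evalue()]). Overlapping hits to the same query are merged
#' keeping the best; results are sorted by bit score, descending.
#'
#' @param genome named character vector of sequences.
#' @param queries data.frame with columns `query_id`, `superfamily`,
#'   `peptide` (at least 30 aa; see [domain_core_queries()]).
#' @param evalue_cutoff report hits with E-value below this.
#' @param flank flank size recorded for later extraction, bp per side.
#' @return data.frame of hits: `seq_id`, nucleotide `start`/`end` (0-based
#'   half-open, length divisible by 3), `frame` (-3..-1, +1..+3), `strand`,
#'   raw `score`, `bit_score`, `evalue`, `query_id`, `superfamily`, and the
#'   clipped `flank_start`/`flank_end`.
#' @export
translated_search <- function(genome, queries, evalue_cutoff = 1e-20,
                              flank = 10000) {
  genome <- check_genome(genome)
  if (is.null(queries) || nrow(queries) == 0) stop("queries must be non-empty")
  check_peptide(queries$peptide, "query peptide")
  if (any(nchar(queries$peptide) < 30)) {
    stop("query peptides must be at least 30 aa")
  }
  if (length(genome) == 0 || all(nchar(genome) == 0)) return(empty_hits())

  frames <- lapply(genome, frame_translations)
  m_total <- sum(vapply(frames, function(fs) {
    sum(vapply(fs, function(f) nchar(f$aa), integer(1)))
  }, numeric(1)))

  hits <- list()
  for (sid in names(genome)) {
    L <- nchar(genome[[sid]])
    for (fr in frames[[sid]]) {
      ## subject word index built once per frame, shared by all queries
      ns <- nchar(fr$aa) - 3L
      if (ns < 1) next
      sdt <- data.table::data.table(
        kmer = substring(fr$aa, 1:ns, 4:(ns + 3L)), spos = 1:ns)
      data.table::setkey(sdt, kmer)
      for (q in seq_len(nrow(queries))) {
        hits[[length(hits) + 1]] <- scan_frame(
          fr, queries[q, ], sid, L, m_total, evalue_cutoff, sdt)
      }
    }
  }
  res <- do.call(rbind, c(hits, list(empty_hits())))
  if (nrow(res) == 0) return(res)
  res <- merge_query_hits(res)
  res$flank_start <- pmax(0L, res$start - as.integer(flank))
  ends <- vapply(res$seq_id, function(s) nchar(genome[[s]]), integer(1))
  res$flank_end <- pmin(ends, res$end + as.integer(flank))
  res <- res[order(-res$bit_score), , drop = FALSE]
  rownames(res) <- NULL
  res
}

scan_frame <- function(fr, query, sid, L, m_total, cutoff, sdt) {
  pep <- query$peptide
  qlen <- nchar(pep)
  nq <- qlen - 3L
  if (nq < 1) return(empty_hits())
  qdt <- data.table::data.table(kmer = substring(pep, 1:nq, 4:(nq + 3L)),
                                qpos = 1:nq)
  seeds <- merge(qdt, sdt, by = "kmer", allow.cartesian = TRUE)
  if (nrow(seeds) == 0) return(empty_hits())
  seeds[, d := spos - qpos]
  data.table::setorder(seeds, d, spos)
  seeds[, cl := cumsum(c(TRUE, diff(d) > 6 | diff(spos) > 90))]
  ## two-hit policy: isolated random words never trigger an alignment
  clusters <- seeds[, .(lo = min(spos), hi = max(spos) + 3L, n_seeds = .N),
                    by = cl]
  clusters <- clusters[n_seeds >= 2]
  if (nrow(clusters) == 0) return(empty_hits())

  alen <- nchar(fr$aa)
  rows <- list()
  done_windows <- character(0)
  for (r in seq_len(nrow(clusters))) {
    w_lo <- max(1L, clusters$lo[r] - qlen)
    w_hi <- min(alen, clusters$hi[r] + qlen)
    wkey <- paste(w_lo, w_hi)
    if (wkey %in% done_windows) next
    done_windows <- c(done_windows, wkey)
    win <- substr(fr$aa, w_lo, w_hi)
    seed_lo <- clusters$lo[r] - w_lo + 1L
    seed_hi <- clusters$hi[r] - w_lo + 1L
    ## stop codons bound the alignable segments
    segs <- strsplit(win, "*", fixed = TRUE)[[1]]
    off <- 0L
    for (sg in segs) {
      if (nchar(sg) >= 10 &&
          off + 1L <= seed_hi && off + nchar(sg) >= seed_lo) {
        al <- aa_local_align(pep, sg)
        bits <- al$score / 2
        ev <- m_total * qlen * 2^(-bits)
        if (ev < cutoff) {
          aa_s <- w_lo + off + al$subject_start - 1L   # 1-based frame aa pos
          aa_e <- w_lo + off + al$subject_end - 1L
          f <- fr$frame
          nt0 <- f + 3L * (aa_s - 1L) - 1L             # 0-based
          nt1 <- f + 3L * aa_e - 1L
          if (fr$strand == "+") {
            g0 <- nt0; g1 <- nt1
          } else {
            g0 <- L - nt1; g1 <- L - nt0
          }
          rows[[length(rows) + 1]] <- data.frame(
            seq_id = sid, start = g0, end = g1,
            frame = if (fr$strand == "+") f else -f,
            strand = fr$strand, score = al$score, bit_score = bits,
            evalue = ev, query_id = query$query_id,
            superfamily = query$superfamily,
            flank_start = NA_integer_, flank_end = NA_integer_,
            stringsAsFactors = FALSE)
        }
      }
      off <- off + nchar(sg) + 1L
    }
  }
  do.call(rbind, c(rows, list(empty_hits())))
}

## drop hits overlapping a better-scoring kept hit to the same query
merge_query_hits <- function(res) {
  res <- res[order(-res$bit_score), , drop = FALSE]
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    ki <- which(keep)
    same <- ki[res$query_id[ki] == res$query_id[i] &
                 res$seq_id[ki] == res$seq_id[i] &
                 res$start[ki] < res$end[i] & res$end[ki] > res$start[i]]
    keep[i] <- length(same) == 0
  }
  res[keep, , drop = FALSE]
}

#' Extract hit flanks
#'
#' One record per hit: the hit region plus up to `flank` bp on each side,
#' clipped at the sequence ends. Record ids encode the original coordinates
#' (`seqid:start-end`, 0-based half-open hit span) for later lift-back; no
#' merging of overlapping flanks.
#'
#' @param genome named character vector of sequences.
#' @param hits data.frame from [translated_search()].
#' @param flank bp per side.
#' @return data.frame with `record_id`, `seq_id`, hit `start`/`end`,
#'   `flank_start`, `flank_end`, `seq`.
#' @export
extract_flanks <- function(genome, hits, flank = 10000) {
  genome <- check_genome(genome)
  if (nrow(hits) == 0) {
    return(data.frame(record_id = character(0), seq_id = character(0),
                      start = integer(0), end = integer(0),
                      flank_start = integer(0), flank_end = integer(0),
                      seq = character(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    L <- nchar(genome[[h$seq_id]])
    fs <- max(0L, h$start - as.integer(flank))
    fe <- min(L, h$end + as.integer(flank))
    data.frame(
      record_id = sprintf("%s:%d-%d", h$seq_id, h$start, h$end),
      seq_id = h$seq_id, start = h$start, end = h$end,
      flank_start = fs, flank_end = fe,
      seq = substr0(genome[[h$seq_id]], fs, fe), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
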