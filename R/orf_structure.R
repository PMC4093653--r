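## ORF annotation of LTR-element internal regions and the three-way layout
## classification: retrotransposase-only, envelope-like extra ORF on the
## sense strand, or an extra ORF2 antisense between the retrotransposase and
## the 3' LTR. ORF calling is stop-to-stop (ATG-initiated, no splicing);
## TE coding regions are treated as intronless.

empty_orfs <- function() {
  data.frame(start = integer(0), end = integer(0), strand = character(0),
             frame = integer(0), aa_len = integer(0), stringsAsFactors = FALSE)
}

#' Find ORFs in a nucleotide region
#'
#' Scans all six reading frames for ATG-to-stop open reading frames of at
#' least `min_len_aa` codons (the stop codon is included in the span, so
#' `aa_len = span/3 - 1`). Within a stop-to-stop segment only the longest
#' ATG-initiated ORF (the first ATG) is reported; results are sorted by
#' start.
#'
#' @param region nucleotide string.
#' @param min_len_aa minimum ORF length in amino acids.
#' @return data.frame with 0-based half-open `start`/`end` (within the
#'   region), `strand`, `frame` (1..3 on either strand), `aa_len`.
#' @export
find_orfs <- function(region, min_len_aa = 150) {
  L <- nchar(region)
  if (L < 3 * min_len_aa) return(empty_orfs())
  rows <- list()
  for (strand in c("+", "-")) {
    seq <- if (strand == "+") region else revcomp(region)
    for (f in 1:3) {
      n_cod <- (L - f + 1) %/% 3
      if (n_cod < min_len_aa) next
      aa <- suppressWarnings(as.character(Biostrings::translate(
        Biostrings::subseq(Biostrings::DNAString(seq), f, f + 3 * n_cod - 1),
        if.fuzzy.codon = "solve", no.init.codon = TRUE)))
      ## stop positions bound segments; an ORF needs a terminating stop
      stops <- c(0L, which(strsplit(aa, "")[[1]] == "*"))
      for (si in seq_len(length(stops) - 1)) {
        seg_lo <- stops[si] + 1L           # first aa index of segment
        seg_hi <- stops[si + 1] - 1L       # last aa before the stop
        if (seg_hi - seg_lo + 1L < min_len_aa) next
        seg <- substr(aa, seg_lo, seg_hi)
        m <- regexpr("M", seg, fixed = TRUE)
        if (m < 0) next
        pm <- seg_lo + as.integer(m) - 1L  # aa index of the ATG
        aa_len <- seg_hi - pm + 1L
        if (aa_len < min_len_aa) next
        nt0 <- f - 1L + 3L * (pm - 1L)               # 0-based, this strand
        nt1 <- f - 1L + 3L * (seg_hi + 1L)           # includes the stop codon
        if (strand == "+") {
          s0 <- nt0; s1 <- nt1
        } else {
          s0 <- L - nt1; s1 <- L - nt0
        }
        rows[[length(rows) + 1]] <- data.frame(
          start = s0, end = s1, strand = strand, frame = f,
          aa_len = aa_len, stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, c(rows, list(empty_orfs())))
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Classify the ORF layout of an LTR element
#'
#' Assigns each ORF a role (`retrotransposase` when it overlaps a
#' reverse-transcriptase domain hit — or, lacking domain evidence, the
#' longest ORF is taken as the putative retrotransposase — otherwise
#' `extra`) and classifies the element: an extra ORF on the retrotransposase
#' strand downstream of it is `env_like_sense`; an extra ORF on the opposite
#' strand between the retrotransposase ORF and the 3' LTR is
#' `orf2_antisense`; otherwise `retrotransposase_only`, or `no_coding` when
#' nothing codes. A retrotransposase split over several ORFs (frameshifted)
#' classifies by the union span. "Between the retrotransposase and the
#' 3' LTR" is operationalised as: the extra ORF's midpoint lies downstream
#' of the retrotransposase ORF's 3' end in element-sense coordinates.
#'
#' @param element one-row data.frame with element `start`, `end`,
#'   `ltr1_end`, `ltr2_start` (genome coordinates, 0-based half-open) and
#'   optionally `element_id`.
#' @param orfs data.frame from [find_orfs()] run on the internal region, in
#'   element-local coordinates (0 = element start).
#' @param rt_hits optional data.frame of domain hits (genome coordinates)
#'   providing retrotransposase evidence.
#' @return one-row data.frame: `element_id`, `te_size`, `ltr_size`,
#'   `retrotransposase_aa` (comma-separated segment sizes), `extra_aa`,
#'   `layout_class`.
#' @export
classify_layout <- function(element, orfs, rt_hits = NULL) {
  stopifnot(nrow(element) == 1)
  el_len <- element$end - element$start
  int_lo <- element$ltr1_end - element$start
  int_hi <- element$ltr2_start - element$start
  if (nrow(orfs)) {
    if (any(orfs$start < int_lo - 3 | orfs$end > int_hi + 3)) {
      stop("ORFs lie outside the element's internal region")
    }
  }
  id <- if ("element_id" %in% names(element)) element$element_id else NA_character_
  base <- data.frame(element_id = id, te_size = el_len,
                     ltr_size = element$ltr1_end - element$start,
                     retrotransposase_aa = "", extra_aa = "",
                     layout_class = "no_coding", stringsAsFactors = FALSE)
  if (nrow(orfs) == 0) return(base)

  role <- rep("extra", nrow(orfs))
  if (!is.null(rt_hits) && nrow(rt_hits)) {
    h_lo <- rt_hits$start - element$start
    h_hi <- rt_hits$end - element$start
    for (i in seq_len(nrow(orfs))) {
      if (any(orfs$start[i] < h_hi & orfs$end[i] > h_lo)) {
        role[i] <- "retrotransposase"
      }
    }
  }
  if (!any(role == "retrotransposase")) {
    role[which.max(orfs$aa_len)] <- "retrotransposase"
  }
  rt <- orfs[role == "retrotransposase", , drop = FALSE]
  extra <- orfs[role == "extra", , drop = FALSE]
  sense <- rt$strand[which.max(rt$aa_len)]
  rt_union_hi <- max(rt$end); rt_union_lo <- min(rt$start)

  base$retrotransposase_aa <- paste(rt$aa_len[order(rt$start)], collapse = ",")
  base$layout_class <- "retrotransposase_only"
  if (nrow(extra)) {
    mid <- (extra$start + extra$end) / 2
    downstream <- if (sense == "+") mid > rt_union_hi else mid < rt_union_lo
    env <- which(extra$strand == sense & downstream)
    orf2 <- which(extra$strand != sense & downstream)
    if (length(env)) {
      base$layout_class <- "env_like_sense"
      base$extra_aa <- paste(extra$aa_len[env], collapse = ",")
    } else if (length(orf2)) {
      base$layout_class <- "orf2_antisense"
      base$extra_aa <- paste(extra$aa_len[orf2], collapse = ",")
    }
  }
  base
}

#' Annotate the ORF layout of an accepted LTR element
#'
#' Convenience wrapper: extracts the internal region (between the LTRs),
#' calls [find_orfs()], lifts coordinates to element-local space and
#' classifies the layout with [classify_layout()].
#'
#' @param genome named character vector of sequences.
#' @param element one-row accepted candidate from [inspect_candidates()]
#'   (needs `seq_id`, `start`, `end`, `ltr1_end`, `ltr2_start`).
#' @param hits optional domain hits for retrotransposase evidence.
#' @param min_len_aa minimum ORF length, aa.
#' @return list with `annotation` (see [classify_layout()]) and `orfs`
#'   (element-local coordinates, with roles).
#' @export
annotate_element_orfs <- function(genome, element, hits = NULL,
                                  min_len_aa = 150) {
  genome <- check_genome(genome)
  seq <- genome[[element$seq_id]]
  internal <- substr0(seq, element$ltr1_end, element$ltr2_start)
  orfs <- find_orfs(internal, min_len_aa)
  if (nrow(orfs)) {
    off <- element$ltr1_end - element$start
    orfs$start <- orfs$start + off
    orfs$end <- orfs$end + off
  }
  rt <- NULL
  if (!is.null(hits) && nrow(hits)) {
    rt <- hits[hits$seq_id == element$seq_id &
                 hits$start < element$end & hits$end > element$start, ,
               drop = FALSE]
  }
  list(annotation = classify_layout(element, orfs, rt), orfs = orfs)
}

#' Per-superfamily ORF-layout census
#'
#' For each group (typically the Ty1-copia and Ty3-gypsy superfamilies)
#' reports the fraction of elements or families whose layout is
#' `retrotransposase_only`, as a percent rounded half-up to one decimal.
#' Empty groups are omitted.
#'
#' @param annotations data.frame with columns `superfamily` and
#'   `layout_class` (one row per element or family).
#' @return data.frame with `superfamily`, `n`, `n_retrotransposase_only`,
#'   `pct_retrotransposase_only`.
#' @export
layout_census <- function(annotations) {
  stopifnot(all(c("superfamily", "layout_class") %in% names(annotations)))
  groups <- split(annotations, annotations$superfamily)
  rows <- lapply(names(groups), function(g) {
    x <- groups[[g]]
    if (nrow(x) == 0) return(NULL)
    k <- sum(x$layout_class == "retrotransposase_only")
    data.frame(superfamily = g, n = nrow(x), n_retrotransposase_only = k,
               pct_retrotransposase_only = round_half_up(100 * k / nrow(x), 1),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
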