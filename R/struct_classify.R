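## Superfamily classification by structure: terminal motifs, terminal
## inverted repeats (TIRs), target-site duplications (TSDs) and polyA tails.
## This codifies the manual inspection rules used to sort homology and
## MITE-style candidates into superfamilies.

#' Superfamily structural rule table
#'
#' One row per supported superfamily: terminal motifs (empty when none),
#' minimum TIR length, TSD length range, whether a 3' polyA tail is
#' required, and a maximum element length (SINEs only). Helitrons have no
#' structural rule here (no TSD; classified by domain homology only).
#'
#' @param cacta_three_prime the CACTA 3' terminal motif. The described
#'   terminal structure is "CACTA...ATGTG"; `"TAGTG"` (the reverse
#'   complement of CACTA) is available as an alternative since the two are
#'   mutually inconsistent and the intended one is ambiguous.
#' @return data.frame rule table.
#' @export
superfamily_rules <- function(cacta_three_prime = c("ATGTG", "TAGTG")) {
  cacta_three_prime <- match.arg(cacta_three_prime)
  data.frame(
    superfamily = c("CACTA", "hAT", "MULE", "PIF/Harbinger", "LINE", "SINE",
                    "Helitron", "Ty1-copia", "Ty3-gypsy"),
    five_prime_motif = c("CACTA", "", "", "", "", "", "", "TG", "TG"),
    three_prime_motif = c(cacta_three_prime, "", "", "", "", "", "", "CA", "CA"),
    tir_min_len = c(0L, 10L, 40L, 10L, 0L, 0L, 0L, 0L, 0L),
    tsd_min = c(2L, 8L, 9L, 3L, 5L, 5L, 0L, 4L, 4L),
    tsd_max = c(3L, 8L, 11L, 3L, 29L, 20L, 0L, 6L, 6L),
    requires_polyA = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE,
                       FALSE, FALSE, FALSE),
    max_len = c(NA, NA, NA, NA, NA, 700L, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

## unchecked TSD scan: longest k in [lo, hi] with suffix(left) == prefix(right)
tsd_scan <- function(left_flank, right_flank, lo, hi) {
  hi <- min(hi, nchar(left_flank), nchar(right_flank))
  if (lo > hi || lo < 1) return("")
  for (k in hi:lo) {
    cand <- substr(right_flank, 1, k)
    if (substr(left_flank, nchar(left_flank) - k + 1, nchar(left_flank)) == cand) {
      return(cand)
    }
  }
  ""
}

#' Find a target-site duplication
#'
#' The TSD is the longest exact string, with length inside `len_range`, that
#' is simultaneously a suffix of the left flank and a prefix of the right
#' flank (both flanks read toward/away from the element boundary, so the two
#' candidate copies are anchored at the boundaries and there is exactly one
#' candidate per length).
#'
#' @param left_flank sequence immediately left of the element start.
#' @param right_flank sequence immediately right of the element end.
#' @param len_range (min, max) allowed TSD length, bp.
#' @return the TSD string, or `""` when no length in range matches.
#' @export
find_tsd <- function(left_flank, right_flank, len_range = c(4, 6)) {
  if (length(len_range) != 2 || len_range[1] > len_range[2]) {
    stop("len_range must be (min, max)")
  }
  if (nchar(left_flank) < len_range[2] || nchar(right_flank) < len_range[2]) {
    stop("flank windows must be at least max(len_range) long")
  }
  tsd_scan(left_flank, right_flank, len_range[1], len_range[2])
}

empty_classified <- function() {
  data.frame(element_id = character(0), seq_id = character(0),
             start = integer(0), end = integer(0), strand = character(0),
             class = integer(0), superfamily = character(0),
             tsd = character(0), evidence = character(0),
             complete = logical(0), stringsAsFactors = FALSE)
}

classified_row <- function(seq_id, start, end, strand, superfamily, tsd,
                           evidence, complete) {
  class1 <- c("Ty1-copia", "Ty3-gypsy", "LINE", "SINE")
  data.frame(element_id = NA_character_, seq_id = seq_id,
             start = as.integer(start), end = as.integer(end),
             strand = strand,
             class = if (superfamily == "unclassified") NA_integer_
                     else if (superfamily %in% class1) 1L else 2L,
             superfamily = superfamily, tsd = tsd,
             evidence = paste(evidence, collapse = ","),
             complete = complete, stringsAsFactors = FALSE)
}

## TSD-consistent boundary pairs: all (s, e, tsd) with s in s_range, e in
## e_range (0-based boundaries) and an exact duplication of length in
## [lo, hi] anchored at both. Returned sorted by tsd length (desc), then
## closeness to the range centres.
tsd_boundary_pairs <- function(seq, s_range, e_range, lo, hi) {
  L <- nchar(seq)
  s_range <- s_range[s_range - hi >= 0 & s_range >= 0]
  e_range <- e_range[e_range + hi <= L]
  if (!length(s_range) || !length(e_range) || lo < 1) {
    return(data.frame(s = integer(0), e = integer(0), tsd = character(0)))
  }
  out <- list()
  for (k in hi:lo) {
    left <- substring(seq, s_range - k + 1, s_range)         # suffix ending at s
    right <- substring(seq, e_range + 1, e_range + k)        # prefix starting at e
    m <- outer(left, right, "==")
    idx <- which(m, arr.ind = TRUE)
    if (nrow(idx)) {
      out[[length(out) + 1]] <- data.frame(
        s = s_range[idx[, 1]], e = e_range[idx[, 2]],
        tsd = right[idx[, 2]], stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(s = integer(0), e = integer(0), tsd = character(0)))
  }
  res <- do.call(rbind, out)
  res <- res[!duplicated(res[, c("s", "e")]), , drop = FALSE]
  cs <- mean(range(s_range)); ce <- mean(range(e_range))
  res[order(-nchar(res$tsd), abs(res$s - cs) + abs(res$e - ce)), , drop = FALSE]
}

## TIR check: identity of the two terminal inverted arms of [s, e), computed
## as the longest prefix during which running identity stays >= min_ident
tir_arm_length <- function(seq, s, e, max_arm, min_ident = 0.8) {
  arm <- min(max_arm, (e - s) %/% 2)
  if (arm < 1) return(0L)
  left <- strsplit(substr0(seq, s, s + arm), "")[[1]]
  right <- revcomp_chars(strsplit(substr0(seq, e - arm, e), "")[[1]])
  m <- left == right
  run <- cumsum(m) / seq_along(m)
  ok <- which(run >= min_ident & m)      # arm must end on a match
  if (!length(ok)) 0L else max(ok)
}

## structural fit of one rule at approximate boundaries, plus strand only.
## Returns list(s, e, tsd, evidence) or NULL.
fit_rule_plus <- function(seq, rule, start, end, slide) {
  L <- nchar(seq)
  s_range <- max(0, start - slide):min(L - 1, start + slide)
  e_range <- max(1, end - slide):min(L, end + slide)
  if (nzchar(rule$five_prime_motif) && rule$superfamily == "CACTA") {
    five <- rule$five_prime_motif; three <- rule$three_prime_motif
    s_hits <- s_range[substring(seq, s_range + 1,
                                s_range + nchar(five)) == five]
    e_hits <- e_range[substring(seq, e_range - nchar(three) + 1,
                                e_range) == three]
    if (!length(s_hits) || !length(e_hits)) return(NULL)
    pairs <- tsd_boundary_pairs(seq, s_hits, e_hits, rule$tsd_min, rule$tsd_max)
    if (!nrow(pairs)) return(NULL)
    p <- pairs[1, ]
    return(list(s = p$s, e = p$e, tsd = p$tsd,
                evidence = c("terminal_motif", "tsd")))
  }
  if (rule$tir_min_len > 0) {
    pairs <- tsd_boundary_pairs(seq, s_range, e_range, rule$tsd_min, rule$tsd_max)
    for (r in seq_len(nrow(pairs))) {
      arm <- tir_arm_length(seq, pairs$s[r], pairs$e[r], max_arm = 200)
      if (arm >= rule$tir_min_len) {
        return(list(s = pairs$s[r], e = pairs$e[r], tsd = pairs$tsd[r],
                    evidence = c("tir", "tsd")))
      }
    }
    return(NULL)
  }
  if (rule$requires_polyA) {
    win_lo <- max(1, end - slide); win_hi <- min(L, end + slide + 30)
    chars <- strsplit(substr(seq, win_lo, win_hi), "")[[1]]
    runs <- polya_run(chars, min_len = 10)
    if (is.null(runs)) return(NULL)
    for (re in rev(sort(unique(runs$end + win_lo - 1)))) {   # 1-based run end
      for (e0 in re:max(re - 5, 1)) {                        # allow A-TSD creep
        if (e0 < end - slide || e0 > end + slide) next
        pairs <- tsd_boundary_pairs(seq, s_range, e0, rule$tsd_min, rule$tsd_max)
        if (nrow(pairs)) {
          p <- pairs[1, ]
          if (!is.na(rule$max_len) && p$e - p$s > rule$max_len) next
          return(list(s = p$s, e = p$e, tsd = p$tsd,
                      evidence = c("polyA", "tsd")))
        }
      }
    }
    return(NULL)
  }
  NULL
}

#' Classify a candidate region into a TE superfamily
#'
#' Slides each boundary of an approximate element region by up to `slide` bp
#' to maximise the joint structural evidence demanded by each superfamily
#' rule (terminal motif or TIR plus an exact TSD of the rule's length;
#' polyA plus TSD for LINE/SINE), testing both strands. Structural evidence
#' (motif/TIR + TSD) takes precedence over domain homology alone; if two
#' different superfamilies fit structurally the element is left unclassified
#' with a warning, never silently picked. LINE is preferred over SINE when
#' domain homology supports coding capacity; regions at most 700 bp with
#' polyA+TSD and no domain evidence classify as SINE.
#'
#' @param genome named character vector of sequences.
#' @param seq_id sequence the region lies on.
#' @param start,end approximate element boundaries (0-based half-open).
#' @param hits optional data.frame of domain hits from [translated_search()]
#'   (used for `domain_homology` evidence and strand).
#' @param rules rule table from [superfamily_rules()].
#' @param slide maximum boundary adjustment, bp.
#' @return one-row classified-element data.frame: boundaries, strand,
#'   class (1/2), superfamily (or `"unclassified"`), TSD, evidence labels,
#'   completeness.
#' @export
classify_candidate <- function(genome, seq_id, start, end, hits = NULL,
                               rules = superfamily_rules(), slide = 50) {
  genome <- check_genome(genome)
  seq <- genome[[seq_id]]
  if (is.null(seq)) stop("seq_id not present in genome")
  L <- nchar(seq)
  if (start < 0 || end > L || start >= end) {
    stop("region lies outside the genome sequence")
  }
  over <- NULL
  if (!is.null(hits) && nrow(hits)) {
    over <- hits[hits$seq_id == seq_id & hits$start < end & hits$end > start, ,
                 drop = FALSE]
  }
  has_domain <- !is.null(over) && nrow(over) > 0
  domain_sf <- if (has_domain) unique(over$superfamily) else character(0)
  hit_strand <- if (has_domain) over$strand[which.max(over$bit_score)] else NA

  rc <- revcomp(seq)
  fits <- list()
  for (r in seq_len(nrow(rules))) {
    rule <- rules[r, ]
    if (rule$superfamily %in% c("Ty1-copia", "Ty3-gypsy", "Helitron")) next
    if (rule$requires_polyA && rule$superfamily == "SINE" && has_domain) next
    if (rule$requires_polyA && rule$superfamily == "LINE" && !has_domain &&
        (end - start) <= 700) next
    fit <- fit_rule_plus(seq, rule, start, end, slide)
    if (!is.null(fit)) {
      fit$strand <- "+"
    } else {
      fit <- fit_rule_plus(rc, rule, L - end, L - start, slide)
      if (!is.null(fit)) {
        tmp <- fit$s
        fit$s <- L - fit$e; fit$e <- L - tmp
        fit$strand <- "-"
        ## the TSD is a genome-strand feature; map it back
        fit$tsd <- revcomp(fit$tsd)
      }
    }
    if (!is.null(fit)) {
      fit$superfamily <- rule$superfamily
      fits[[length(fits) + 1]] <- fit
    }
  }

  if (length(fits) > 1) {
    ## a longer exact TSD is more specific evidence (a short-TSD rule can
    ## fire spuriously on the prefix of a longer duplication)
    tsd_lens <- vapply(fits, function(f) nchar(f$tsd), integer(1))
    if (sum(tsd_lens == max(tsd_lens)) == 1) {
      fits <- fits[which.max(tsd_lens)]
    } else {
      sfs <- vapply(fits, `[[`, "", "superfamily")
      ## domain homology arbitrates an otherwise ambiguous structural tie
      backed <- fits[sfs %in% domain_sf]
      if (length(backed) == 1) {
        fits <- backed
      } else {
        warning("ambiguous structural classification (",
                paste(sfs, collapse = " vs "), ") at ", seq_id, ":", start,
                "-", end, "; left unclassified")
        fits <- list()
      }
    }
  }

  if (length(fits) == 1) {
    f <- fits[[1]]
    ev <- f$evidence
    if (f$superfamily %in% domain_sf) ev <- c(ev, "domain_homology")
    return(classified_row(seq_id, f$s, f$e, f$strand, f$superfamily,
                          f$tsd, ev, complete = TRUE))
  }

  if (has_domain) {
    sf <- domain_sf[1]
    ev <- "domain_homology"
    ## LINEs keep polyA evidence even when the TSD was not recovered
    chars <- strsplit(substr0(seq, max(0, end - 60), min(L, end + 30)), "")[[1]]
    if (sf == "LINE" && !is.null(polya_run(chars))) ev <- c(ev, "polyA")
    return(classified_row(seq_id, start, end,
                          if (is.na(hit_strand)) "+" else hit_strand,
                          sf, "", ev, complete = FALSE))
  }
  classified_row(seq_id, start, end, "+", "unclassified", "", character(0),
                 complete = FALSE)
}

#' Find MITE-like candidates (short TIR elements without coding capacity)
#'
#' Genome-wide scan for elements of at most `max_len` bp whose ends form a
#' terminal inverted repeat (seeded on exact reverse-complement k-mer
#' matches, arms at least `tir_min` bp at >= 80% identity) flanked by an
#' exact TSD in any superfamily's length range. Deduplicated by span.
#'
#' @param genome named character vector of sequences.
#' @param max_len maximum element length, bp.
#' @param min_len minimum element length, bp.
#' @param seed_kmer seed k-mer length for the inverted-repeat scan.
#' @param tir_min minimum TIR arm length, bp.
#' @param tsd_range TSD length range accepted, bp (union over rules).
#' @return data.frame of intervals: `seq_id`, `start`, `end`, `tir_len`,
#'   `tsd`.
#' @export
find_mite_like <- function(genome, max_len = 2000, min_len = 80,
                           seed_kmer = 12, tir_min = 14,
                           tsd_range = c(2, 29)) {
  genome <- check_genome(genome)
  out <- list()
  for (sid in names(genome)) {
    seq <- genome[[sid]]
    L <- nchar(seq)
    k <- seed_kmer
    if (L < min_len) next
    n_k <- L - k + 1
    km <- substring(seq, 1:n_k, k:L)
    dt <- data.table::data.table(kmer = km, pos = 1:n_k)
    dt <- dt[!grepl("N", kmer, fixed = TRUE)]
    rcdt <- data.table::data.table(
      rck = vapply(dt$kmer, function(x) {
        paste(revcomp_chars(strsplit(x, "")[[1]]), collapse = "")
      }, "", USE.NAMES = FALSE),
      pos = dt$pos)
    pairs <- merge(dt[, .(w = kmer, i = pos)],
                   rcdt[, .(w = rck, j = pos)],
                   by = "w", allow.cartesian = TRUE)
    pairs <- pairs[j + k - i >= min_len & j + k - i <= max_len & j > i]
    if (!nrow(pairs)) next
    seen <- list()
    for (r in order(pairs$i, pairs$j)) {
      s <- pairs$i[r] - 1L          # 0-based element start
      e <- pairs$j[r] + k - 1L      # 0-based element end
      arm <- tir_arm_length(seq, s, e, max_arm = 200)
      if (arm < tir_min) next
      tsd <- tsd_scan(substr0(seq, max(0, s - 30), s),
                      substr0(seq, e, min(L, e + 30)),
                      tsd_range[1], tsd_range[2])
      if (!nzchar(tsd)) next
      key <- paste(s, e)
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      out[[length(out) + 1]] <- data.frame(
        seq_id = sid, start = s, end = e, tir_len = arm, tsd = tsd,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), tir_len = integer(0),
                      tsd = character(0), stringsAsFactors = FALSE))
  }
  res <- unique(do.call(rbind, out))
  ## nested seed variants of one element: keep the candidate with the
  ## strongest evidence (longest TSD, then longest TIR, then widest span)
  res <- res[order(-nchar(res$tsd), -res$tir_len, -(res$end - res$start)), ,
             drop = FALSE]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(res)) > i)
    clash <- later[res$seq_id[later] == res$seq_id[i] &
                     res$start[later] < res$end[i] &
                     res$end[later] > res$start[i]]
    keep[clash] <- FALSE
  }
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
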