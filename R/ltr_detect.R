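## De novo discovery of LTR-retrotransposon candidates: k-mer seeded search
## for paired direct repeats on a shared diagonal, followed by an automated
## version of the manual inspection step (TG...CA termini, TSD scan, tandem
## filter). Coordinates are 0-based half-open.

#' LTR detection configuration
#'
#' @param min_ltr_len minimum LTR length, bp.
#' @param min_internal minimum distance between the two LTRs, bp.
#' @param max_element_len maximum whole-element length, bp.
#' @param min_ltr_identity minimum identity between the two LTRs, percent.
#' @param tsd_len TSD length range (min, max), bp.
#' @param tsd_search_window flank window scanned for the TSD, bp.
#' @param seed_kmer exact k-mer seed length for repeat pairing.
#' @param max_kmer_occ k-mers occurring more often than this are skipped as
#'   low-complexity/high-copy noise.
#' @return a `detect_config` list.
#' @export
detect_config <- function(min_ltr_len = 50, min_internal = 50,
                          max_element_len = 15000, min_ltr_identity = 80,
                          tsd_len = c(4, 6), tsd_search_window = 20,
                          seed_kmer = 15, max_kmer_occ = 30) {
  if (min_ltr_len < seed_kmer) stop("min_ltr_len must be >= seed_kmer")
  if (max_element_len <= 2 * min_ltr_len + min_internal) {
    stop("max_element_len must exceed 2*min_ltr_len + min_internal")
  }
  if (length(tsd_len) != 2 || tsd_len[1] > tsd_len[2]) {
    stop("tsd_len must be (min, max)")
  }
  structure(list(min_ltr_len = as.integer(min_ltr_len),
                 min_internal = as.integer(min_internal),
                 max_element_len = as.integer(max_element_len),
                 min_ltr_identity = min_ltr_identity,
                 tsd_len = as.integer(tsd_len),
                 tsd_search_window = as.integer(tsd_search_window),
                 seed_kmer = as.integer(seed_kmer),
                 max_kmer_occ = as.integer(max_kmer_occ)),
            class = "detect_config")
}

empty_ltr_candidates <- function() {
  data.frame(seq_id = character(0), start = integer(0), end = integer(0),
             ltr1_start = integer(0), ltr1_end = integer(0),
             ltr2_start = integer(0), ltr2_end = integer(0),
             ltr_identity = numeric(0), tsd = character(0),
             has_tg_ca = logical(0), status = character(0),
             stringsAsFactors = FALSE)
}

#' Find paired direct repeats (LTR candidates)
#'
#' Seeds on exact k-mers repeated on the same diagonal within the allowed
#' element-length window, extends each seed cluster in both directions under
#' an identity-aware maximal-segment criterion, and reports repeat pairs with
#' both copies at least `min_ltr_len` long, identity at least
#' `min_ltr_identity`, separated by at least `min_internal` bp and spanning
#' at most `max_element_len`. Redundant variants of the same repeat pair
#' (both repeat intervals overlapping a better-scoring candidate's) are
#' collapsed, keeping the highest (identity, element length), ties leftmost.
#'
#' @param genome named character vector of sequences.
#' @param cfg a [detect_config()].
#' @return data.frame of candidates (`status` unset, `NA`): `seq_id`,
#'   element `start`/`end`, the two LTR spans, `ltr_identity` (percent).
#'   Sorted by (`seq_id`, `start`).
#' @export
find_direct_repeat_pairs <- function(genome, cfg = detect_config()) {
  genome <- check_genome(genome)
  out <- lapply(names(genome), function(sid) {
    find_pairs_one(genome[[sid]], sid, cfg)
  })
  res <- do.call(rbind, c(out, list(empty_ltr_candidates())))
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

find_pairs_one <- function(seq, sid, cfg) {
  L <- nchar(seq)
  k <- cfg$seed_kmer
  if (L < 2 * cfg$min_ltr_len + cfg$min_internal) return(empty_ltr_candidates())
  chars <- strsplit(seq, "")[[1]]
  n_k <- L - k + 1
  kmers <- substring(seq, 1:n_k, k:L)
  dt <- data.table::data.table(kmer = kmers, pos = 1:n_k)
  dt <- dt[!grepl("N", kmer, fixed = TRUE)]
  dt[, n := .N, by = kmer]
  dt <- dt[n >= 2 & n <= cfg$max_kmer_occ]
  if (nrow(dt) == 0) return(empty_ltr_candidates())
  ## drop low-complexity seeds (fewer than 3 distinct bases)
  uk <- unique(dt$kmer)
  cplx <- vapply(strsplit(uk, ""), function(x) length(unique(x)), integer(1))
  dt <- dt[kmer %in% uk[cplx >= 3]]
  if (nrow(dt) == 0) return(empty_ltr_candidates())

  d_min <- cfg$min_internal + cfg$min_ltr_len
  d_max <- cfg$max_element_len - cfg$min_ltr_len
  pairs <- merge(dt[, .(kmer, i = pos)], dt[, .(kmer, j = pos)],
                 by = "kmer", allow.cartesian = TRUE)
  pairs <- pairs[j - i >= d_min & j - i <= d_max]
  if (nrow(pairs) == 0) return(empty_ltr_candidates())
  seeds <- unique(pairs[, .(i, d = j - i)])
  data.table::setorder(seeds, d, i)
  ## cluster seeds sharing a diagonal, split at gaps > 200 bp
  seeds[, cl := cumsum(c(TRUE, diff(d) != 0 | diff(i) > 200))]
  clusters <- seeds[, .(imin = min(i), imax = max(i)), by = .(d, cl)]

  thr <- cfg$min_ltr_identity / 100
  cands <- vector("list", nrow(clusters))
  for (r in seq_len(nrow(clusters))) {
    d <- clusters$d[r]
    ext <- extend_repeat(chars, L, d, clusters$imin[r],
                         clusters$imax[r] + k - 1L, thr, cfg)
    if (!is.null(ext)) {
      cands[[r]] <- data.frame(
        seq_id = sid, start = ext$a - 1L, end = ext$b + d,
        ltr1_start = ext$a - 1L, ltr1_end = ext$b,
        ltr2_start = ext$a - 1L + d, ltr2_end = ext$b + d,
        ltr_identity = ext$identity, tsd = NA_character_,
        has_tg_ca = NA, status = NA_character_, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, c(cands[!vapply(cands, is.null, TRUE)],
                          list(empty_ltr_candidates())))
  if (nrow(res) == 0) return(res)
  res <- unique(res)
  resolve_overlaps(res)
}

## maximal identity-aware extension of a seed span on diagonal d.
## Positions are 1-based; repeat copies are [a, b] and [a + d, b + d].
extend_repeat <- function(chars, L, d, seed_lo, seed_hi, thr, cfg) {
  lo <- max(1L, seed_lo - d)
  hi <- min(L - d, seed_hi + d)
  if (seed_hi > L - d) seed_hi <- L - d
  idx <- lo:hi
  m <- chars[idx] == chars[idx + d]
  si <- seed_lo - lo + 1L
  sj <- seed_hi - lo + 1L
  if (thr >= 1) {
    ## exact mode: maximal all-match run through the seeds
    left_ext <- 0L
    while (si - left_ext > 1 && m[si - left_ext - 1L]) left_ext <- left_ext + 1L
    right_ext <- 0L
    while (sj + right_ext < length(m) && m[sj + right_ext + 1L]) {
      right_ext <- right_ext + 1L
    }
  } else {
    ## X-drop extension (match +1, mismatch -2), settle at the maximum
    xdrop <- 40
    left_ext <- xdrop_extend(m, si, -1L, xdrop)
    right_ext <- xdrop_extend(m, sj, 1L, xdrop)
  }
  a <- lo + si - 1L - left_ext
  b <- lo + sj - 1L + right_ext
  ## tandem-style overlap: trim the repeat so an internal region remains
  max_len <- d - cfg$min_internal
  if (b - a + 1L > max_len) b <- a + max_len - 1L
  len <- b - a + 1L
  if (len < cfg$min_ltr_len) return(NULL)
  mm <- chars[a:b] == chars[(a + d):(b + d)]
  ## trim mismatching ends left over from the trim above
  while (len > 0 && !mm[1]) { a <- a + 1L; mm <- mm[-1]; len <- len - 1L }
  while (len > 0 && !mm[length(mm)]) { b <- b - 1L; mm <- mm[-length(mm)]; len <- len - 1L }
  if (len < cfg$min_ltr_len) return(NULL)
  identity <- 100 * mean(mm)
  if (identity < cfg$min_ltr_identity) return(NULL)
  if (d + len > cfg$max_element_len) return(NULL)
  list(a = a, b = b, identity = identity)
}

## greedy X-drop: walk from position `from` in direction `dir`, score match
## +1 / mismatch -2, stop when the running score drops `xdrop` below its
## maximum; returns the extension length to the maximum-score point
xdrop_extend <- function(m, from, dir, xdrop) {
  ext <- 0L
  best <- 0; best_ext <- 0L; score <- 0
  p <- from + dir
  while (p >= 1 && p <= length(m)) {
    score <- score + if (m[p]) 1 else -2
    ext <- ext + 1L
    if (score > best) { best <- score; best_ext <- ext }
    if (best - score > xdrop) break
    p <- p + dir
  }
  best_ext
}

## collapse redundant variants of the same repeat pair: a candidate whose
## both repeat intervals overlap those of a better-ranked kept candidate is
## discarded; ranking (identity desc, element length desc, start asc)
resolve_overlaps <- function(res) {
  o <- order(-res$ltr_identity, -(res$end - res$start), res$start)
  res <- res[o, , drop = FALSE]
  keep <- logical(nrow(res))
  for (i in seq_len(nrow(res))) {
    ki <- which(keep)
    redundant <- FALSE
    for (j in ki) {
      o1 <- res$ltr1_start[i] < res$ltr1_end[j] & res$ltr1_end[i] > res$ltr1_start[j]
      o2 <- res$ltr2_start[i] < res$ltr2_end[j] & res$ltr2_end[i] > res$ltr2_start[j]
      if (o1 && o2) { redundant <- TRUE; break }
    }
    keep[i] <- !redundant
  }
  res <- res[keep, , drop = FALSE]
  res[order(res$seq_id, res$start), , drop = FALSE]
}

#' Inspect an LTR candidate (automated boundary/TSD/tandem check)
#'
#' Automates the manual inspection step: allows boundary shifts of up to
#' 10 bp when they improve the joint TG...CA + TSD evidence (both repeat
#' copies move together, preserving their diagonal), scans the flanks for a
#' target-site duplication, and rejects tandem arrays (internal region
#' sharing at least 50% identity with the LTR). A candidate is `accepted`
#' only when a TSD is found and it is not a tandem; otherwise the status
#' records why it was discarded (`rejected_tandem`, `rejected_no_tsd`,
#' `rejected_structure`).
#'
#' @param genome named character vector of sequences.
#' @param cand one-row data.frame from [find_direct_repeat_pairs()].
#' @param cfg a [detect_config()].
#' @return the candidate row with `tsd`, `has_tg_ca` and `status` set.
#' @export
inspect_candidate <- function(genome, cand, cfg = detect_config()) {
  genome <- check_genome(genome)
  stopifnot(nrow(cand) == 1)
  seq <- genome[[cand$seq_id]]
  if (is.null(seq)) stop("candidate seq_id not in genome")
  L <- nchar(seq)
  if (cand$start < 0 || cand$end > L) {
    stop("candidate span lies outside the genome sequence")
  }
  w <- cfg$tsd_search_window

  ## boundary refinement: the two repeat copies sit on one diagonal, so a
  ## left-boundary shift moves both LTR starts and a right-boundary shift
  ## moves both LTR ends; shifts up to 10 bp are tried (the extension can
  ## undershoot a terminal stretch dense in substitutions), scored by
  ## TG...CA termini plus TSD evidence, longer TSDs preferred, and the
  ## smallest shift wins ties
  best <- NULL
  for (sl in -10:10) {
    for (sr in -10:10) {
      s <- cand$start + sl
      e <- cand$end + sr
      if (s < 0 || e > L || s >= e) next
      if (s - cfg$tsd_len[2] < 0 || e + cfg$tsd_len[2] > L) next
      tg <- substr0(seq, s, s + 2) == "TG"
      ca <- substr0(seq, e - 2, e) == "CA"
      tsd <- tsd_scan(substr0(seq, max(0, s - w), s),
                      substr0(seq, e, min(L, e + w)),
                      cfg$tsd_len[1], cfg$tsd_len[2])
      ## a TSD found at shifted boundaries only counts when the shift also
      ## restores the TG...CA termini; otherwise a wide shift search would
      ## dredge up chance duplications for structureless candidates
      if (!(tg && ca) && !(sl == 0 && sr == 0)) tsd <- ""
      score <- tg + ca + 2 * nzchar(tsd) + 0.1 * nchar(tsd)
      shift_cost <- abs(sl) + abs(sr)
      if (is.null(best) || score > best$score ||
          (score == best$score && shift_cost < best$cost)) {
        best <- list(score = score, cost = shift_cost, sl = sl, sr = sr,
                     tg = tg, ca = ca, tsd = tsd)
      }
    }
  }
  cand$start <- cand$start + best$sl
  cand$ltr1_start <- cand$ltr1_start + best$sl
  cand$ltr2_start <- cand$ltr2_start + best$sl
  cand$end <- cand$end + best$sr
  cand$ltr1_end <- cand$ltr1_end + best$sr
  cand$ltr2_end <- cand$ltr2_end + best$sr
  cand$has_tg_ca <- best$tg && best$ca
  cand$tsd <- best$tsd

  ltr_seq <- substr0(seq, cand$ltr1_start, cand$ltr1_end)
  internal <- substr0(seq, cand$ltr1_end, cand$ltr2_start)
  ## a repeat pair whose copies (nearly) abut is a tandem array, not an
  ## element: true LTR pairs enclose a coding-capable internal region
  tandem <- nchar(internal) < cfg$min_internal + 21
  if (!tandem) {
    al <- nt_local_align(ltr_seq, internal)
    tandem <- al$nmatch / min(nchar(ltr_seq), nchar(internal)) >= 0.5
  }
  ltr_ok <- (cand$ltr1_end - cand$ltr1_start) >= cfg$min_ltr_len &&
    (cand$ltr2_end - cand$ltr2_start) >= cfg$min_ltr_len &&
    (cand$ltr2_start - cand$ltr1_end) >= cfg$min_internal

  cand$status <- if (tandem) "rejected_tandem"
  else if (!nzchar(cand$tsd)) "rejected_no_tsd"
  else if (!ltr_ok) "rejected_structure"
  else "accepted"
  cand
}

#' Inspect all candidates
#'
#' Applies [inspect_candidate()] to each row.
#'
#' @param genome named character vector of sequences.
#' @param cands data.frame from [find_direct_repeat_pairs()].
#' @param cfg a [detect_config()].
#' @return the candidate data.frame with statuses set.
#' @export
inspect_candidates <- function(genome, cands, cfg = detect_config()) {
  if (nrow(cands) == 0) return(cands)
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    inspect_candidate(genome, cands[i, , drop = FALSE], cfg)
  })
  res <- do.call(rbind, rows)
  ## an accepted candidate overlapping a better accepted one is a chimera of
  ## neighbouring insertions or an internal sub-repeat: keep the highest
  ## (identity, element length), demote the rest
  acc <- which(res$status == "accepted")
  acc <- acc[order(-res$ltr_identity[acc],
                   -(res$end[acc] - res$start[acc]), res$start[acc])]
  kept <- integer(0)
  for (i in acc) {
    clash <- any(res$seq_id[kept] == res$seq_id[i] &
                   res$start[kept] < res$end[i] & res$end[kept] > res$start[i])
    if (clash) res$status[i] <- "rejected_structure" else kept <- c(kept, i)
  }
  rownames(res) <- NULL
  res
}

#' LTR identity report
#'
#' Tabulates LTR-to-LTR identity for accepted candidates and flags elements
#' with exactly identical LTRs as recent-insertion candidates.
#'
#' @param cands accepted candidates from [inspect_candidates()].
#' @return data.frame with `seq_id`, `start`, `end`, `ltr_identity`,
#'   `recent_insertion`.
#' @export
ltr_identity_report <- function(cands) {
  if (nrow(cands) == 0) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), ltr_identity = numeric(0),
                      recent_insertion = logical(0), stringsAsFactors = FALSE))
  }
  if (any(!is.na(cands$status) & cands$status != "accepted")) {
    stop("ltr_identity_report expects accepted candidates only")
  }
  data.frame(seq_id = cands$seq_id, start = cands$start, end = cands$end,
             ltr_identity = cands$ltr_identity,
             recent_insertion = cands$ltr_identity == 100,
             stringsAsFactors = FALSE)
}
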