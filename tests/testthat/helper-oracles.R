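# Independent oracles used to cross-check the package's heuristics, plus
# small fixture builders. Oracles are deliberately brute-force.

rand_seq <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# brute-force enumeration of maximal exact direct-repeat pairs on every
# diagonal, subject to the detector's length constraints
oracle_exact_repeat_pairs <- function(seq, min_len = 50, min_gap = 50,
                                      max_span = 15000) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- list()
  for (d in seq(min_gap + min_len, max_span - min_len)) {
    if (d >= L) break
    m <- chars[1:(L - d)] == chars[(1 + d):L]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= min_len)) {
      len <- r$lengths[k]
      if (len > d - min_gap) len <- d - min_gap       # keep an internal gap
      if (len < min_len) next
      if (d + len > max_span) next
      out[[length(out) + 1]] <- data.frame(
        start = starts[k] - 1L, ltr_len = len, d = d)
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), ltr_len = integer(0), d = integer(0)))
  }
  do.call(rbind, out)
}

# exhaustive Smith-Waterman via Biostrings on the full sequences (no
# seeding): the full-DP reference for the seeded heuristics
oracle_best_local_protein <- function(query, subject_aa) {
  segs <- strsplit(subject_aa, "*", fixed = TRUE)[[1]]
  best <- 0
  for (sg in segs) {
    if (nchar(sg) < 2) next
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(query), Biostrings::AAString(sg),
      type = "local",
      substitutionMatrix = "BLOSUM62", gapOpening = 11, gapExtension = 1)
    best <- max(best, Biostrings::score(al))
  }
  best
}

# codon-walk ORF caller: walk every frame on both strands codon by codon
oracle_orfs <- function(region, min_len_aa = 150) {
  L <- nchar(region)
  codon_of <- function(s, p) substr(s, p, p + 2)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") region else beanTE::revcomp(region)
    for (f in 1:3) {
      p <- f
      orf_start <- NA
      while (p + 2 <= L) {
        cod <- codon_of(s, p)
        if (is.na(orf_start) && cod == "ATG") orf_start <- p
        if (cod %in% c("TAA", "TAG", "TGA")) {
          if (!is.na(orf_start)) {
            aa_len <- (p - orf_start) / 3
            if (aa_len >= min_len_aa) {
              nt0 <- orf_start - 1L
              nt1 <- p + 2L
              if (strand == "+") {
                out[[length(out) + 1]] <- data.frame(
                  start = nt0, end = nt1, strand = strand, aa_len = aa_len)
              } else {
                out[[length(out) + 1]] <- data.frame(
                  start = L - nt1, end = L - nt0, strand = strand,
                  aa_len = aa_len)
              }
            }
          }
          orf_start <- NA
        }
        p <- p + 3
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), aa_len = integer(0)))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}

# transitive closure by repeated sweeps: single-linkage components
oracle_components <- function(ids, edges) {
  comp <- seq_along(ids)
  names(comp) <- ids
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$from[k]; b <- edges$to[k]
      if (comp[a] != comp[b]) {
        comp[comp == comp[b]] <- comp[a]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# O(n^2) pair-counting Rand index
oracle_rand_index <- function(a, b) {
  n <- length(a)
  if (n < 2) return(1)
  agree <- 0; total <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      total <- total + 1
      if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
    }
  }
  agree / total
}

# all suffix/prefix TSD candidates by explicit enumeration
oracle_tsd <- function(left, right, lo, hi) {
  best <- ""
  for (k in lo:min(hi, nchar(left), nchar(right))) {
    suf <- substr(left, nchar(left) - k + 1, nchar(left))
    pre <- substr(right, 1, k)
    if (suf == pre && k > nchar(best)) best <- suf
  }
  best
}

# path-length matrix of a phylo tree
tree_path_dists <- function(tree) {
  d <- stats::cophenetic(tree)
  d[order(rownames(d)), order(colnames(d))]
}

# additive distance matrix from a random topology with positive branch
# lengths; returns list(dist, tree)
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tree <- ape::rtree(n, rooted = FALSE, br = function(k) runif(k, 0.2, 1.5))
  tree$tip.label <- sort(tree$tip.label)
  list(dist = cophenetic(tree), tree = tree)
}

# a small simulated genome shared by several tests (cached per session)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(genome_length = 2e5,
                       n_elements = c("Ty1-copia" = 3, "Ty3-gypsy" = 3,
                                      "CACTA" = 2, "hAT" = 2, "MULE" = 2,
                                      "PIF/Harbinger" = 2, "Helitron" = 1,
                                      "LINE" = 2, "SINE" = 2),
                       n_mites = 2, n_env_like = 1, n_orf2 = 1,
                       est_count = 200, rng_seed = 417)
      cache <<- list(cfg = cfg, sim = simulate_genome(cfg))
    }
    cache
  }
})
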