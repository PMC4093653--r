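## Truth-tracked synthetic genomes.
##
## The generator plants intact transposable elements of every supported
## superfamily into an i.i.d. background sequence and records exactly what it
## planted (coordinates, TSD, terminal structure, ORF layout, family), so the
## detection, classification, clustering and expression stages can all be
## scored against ground truth. Coordinates are 0-based half-open throughout.

SUPERFAMILIES <- c("Ty1-copia", "Ty3-gypsy", "CACTA", "hAT", "MULE",
                   "PIF/Harbinger", "Helitron", "LINE", "SINE")

## TSD length rule table used both when planting and when classifying
TSD_RULES <- list(
  "Ty1-copia" = c(4, 6), "Ty3-gypsy" = c(4, 6),
  "CACTA" = c(2, 3), "hAT" = c(8, 8), "MULE" = c(9, 11),
  "PIF/Harbinger" = c(3, 3), "Helitron" = c(0, 0),
  "LINE" = c(5, 29), "SINE" = c(5, 20)
)

#' Simulation configuration
#'
#' Defines a synthetic genome: an i.i.d. nucleotide background at a fixed GC
#' content with intact transposable elements of every supported superfamily
#' planted at known positions. Elements are drawn from per-family consensus
#' sequences mutated by substitutions only, flanked by superfamily-appropriate
#' target-site duplications (TSDs) and terminal structures (TG...CA termini
#' for LTR retrotransposons, terminal motifs or TIRs for DNA transposons,
#' polyA tails for LINEs/SINEs).
#'
#' @param genome_length total genome length in bp.
#' @param n_elements named integer vector of planted copies per superfamily
#'   (names from `Ty1-copia`, `Ty3-gypsy`, `CACTA`, `hAT`, `MULE`,
#'   `PIF/Harbinger`, `Helitron`, `LINE`, `SINE`).
#' @param n_mites additional short non-coding TIR elements (hAT-like MITEs,
#'   8-bp TSD) planted alongside the autonomous elements.
#' @param n_env_like number of Ty1-copia families whose consensus carries an
#'   extra sense-strand ORF (envelope-like) between the retrotransposase ORF
#'   and the 3' LTR.
#' @param n_orf2 number of Ty3-gypsy families whose consensus carries an
#'   extra antisense ORF (ORF2) between the retrotransposase ORF and the
#'   3' LTR.
#' @param gc_content background GC fraction.
#' @param ltr_length range (min, max) of LTR lengths in bp.
#' @param ltr_divergence range of per-site divergence between the two LTRs of
#'   a planted copy (0 = exactly identical LTRs, i.e. a recent insertion).
#' @param element_divergence range of per-site divergence of each planted
#'   copy from its family consensus.
#' @param members_per_family target family size; each superfamily's copies
#'   are split over `ceiling(n / members_per_family)` consensus families.
#' @param min_spacing minimum background gap between planted elements, bp.
#' @param cacta_three_prime 3' terminal motif planted for CACTA elements;
#'   either the literal `"ATGTG"` or the reverse-complement-consistent
#'   `"TAGTG"`.
#' @param est_count,est_length,est_te_fraction,est_error EST pool settings:
#'   number of reads, read-length range, fraction of reads drawn from planted
#'   element bodies, and per-base error-rate range applied to reads.
#' @param rng_seed integer seed; a fixed seed gives byte-identical output.
#' @return a `sim_config` list, validated.
#' @export
sim_config <- function(genome_length = 1e6,
                       n_elements = c("Ty1-copia" = 10, "Ty3-gypsy" = 10,
                                      "CACTA" = 4, "hAT" = 4, "MULE" = 4,
                                      "PIF/Harbinger" = 4, "Helitron" = 3,
                                      "LINE" = 4, "SINE" = 3),
                       n_mites = 3,
                       n_env_like = 2,
                       n_orf2 = 3,
                       gc_content = 0.40,
                       ltr_length = c(150, 400),
                       ltr_divergence = c(0, 0.10),
                       element_divergence = c(0, 0.10),
                       members_per_family = 3,
                       min_spacing = 1000,
                       cacta_three_prime = c("ATGTG", "TAGTG"),
                       est_count = 600,
                       est_length = c(200, 500),
                       est_te_fraction = 0.3,
                       est_error = c(0.01, 0.02),
                       rng_seed = 1) {
  cacta_three_prime <- match.arg(cacta_three_prime)
  full <- setNames(integer(length(SUPERFAMILIES)), SUPERFAMILIES)
  if (length(n_elements)) {
    bad <- setdiff(names(n_elements), SUPERFAMILIES)
    if (length(bad)) stop("unknown superfamily in n_elements: ",
                          paste(bad, collapse = ", "))
    full[names(n_elements)] <- as.integer(n_elements)
  }
  frac_ok <- function(x) all(x >= 0 & x <= 1)
  if (!frac_ok(gc_content) || !frac_ok(ltr_divergence) ||
      !frac_ok(element_divergence) || !frac_ok(est_te_fraction) ||
      !frac_ok(est_error)) {
    stop("all fractions must lie in [0, 1]")
  }
  rng2 <- function(x, name) {
    if (length(x) != 2 || x[1] > x[2]) stop(sprintf("'%s' must be (min, max)", name))
    x
  }
  cfg <- list(
    genome_length = as.integer(genome_length),
    n_elements = full,
    n_mites = as.integer(n_mites),
    n_env_like = as.integer(n_env_like),
    n_orf2 = as.integer(n_orf2),
    gc_content = gc_content,
    ltr_length = rng2(ltr_length, "ltr_length"),
    ltr_divergence = rng2(ltr_divergence, "ltr_divergence"),
    element_divergence = rng2(element_divergence, "element_divergence"),
    members_per_family = as.integer(members_per_family),
    min_spacing = as.integer(min_spacing),
    cacta_three_prime = cacta_three_prime,
    est_count = as.integer(est_count),
    est_length = rng2(as.integer(est_length), "est_length"),
    est_te_fraction = est_te_fraction,
    est_error = rng2(est_error, "est_error"),
    rng_seed = as.integer(rng_seed)
  )
  n_fam <- function(sf) ceiling(cfg$n_elements[[sf]] / cfg$members_per_family)
  if (cfg$n_env_like > n_fam("Ty1-copia")) {
    stop("n_env_like exceeds the number of Ty1-copia families")
  }
  if (cfg$n_orf2 > n_fam("Ty3-gypsy")) {
    stop("n_orf2 exceeds the number of Ty3-gypsy families")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Bundled synthetic domain-core peptides
#'
#' The 180-aa peptides used by the generator as conserved-domain cores of the
#' planted coding elements (reverse transcriptase for the retroelement
#' superfamilies, transposase/replicase cores for the DNA-transposon
#' superfamilies). They are synthetic stand-ins, not real protein sequences;
#' the same file is the default query set for [translated_search()], which
#' keeps the homology stage self-contained.
#'
#' @return data.frame with columns `query_id`, `superfamily`, `peptide`.
#' @export
domain_core_queries <- function() {
  path <- system.file("extdata", "domain_cores_synthetic.fa",
                      package = "beanTE", mustWork = TRUE)
  x <- read_fasta(path)
  ids <- fasta_ids(names(x))
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(
    query_id = vapply(parts, `[`, "", 1),
    superfamily = vapply(parts, `[`, "", 2),
    peptide = unname(x),
    stringsAsFactors = FALSE
  )
}

## ---- internal sequence builders -------------------------------------------

## reverse-translate a peptide with uniformly drawn synonymous codons
CODON_TABLE <- local({
  codons <- as.character(Biostrings::DNA_ALPHABET[1:4])
  all3 <- expand.grid(codons, codons, codons, stringsAsFactors = FALSE)
  cods <- paste0(all3[[3]], all3[[2]], all3[[1]])
  aa <- as.character(Biostrings::translate(Biostrings::DNAStringSet(cods),
                                           no.init.codon = TRUE))
  split(cods, aa)
})

reverse_translate <- function(peptide) {
  aas <- strsplit(peptide, "")[[1]]
  codons <- vapply(aas, function(a) {
    choices <- CODON_TABLE[[a]]
    choices[sample.int(length(choices), 1)]
  }, "")
  paste(codons, collapse = "")
}

## an ATG-initiated ORF (nt) encoding M + pre + core + post, with stop codon
make_orf <- function(core_peptide, n_pre, n_post) {
  aa <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]]
  pep <- paste0(paste(sample(aa, n_pre, replace = TRUE), collapse = ""),
                core_peptide,
                paste(sample(aa, n_post, replace = TRUE), collapse = ""))
  paste0("ATG", reverse_translate(pep), sample(STOP_CODONS, 1))
}

rand_str <- function(n, gc) paste(random_dna(n, gc), collapse = "")

## consensus for one family; returns list(seq, orfs = data.frame(start, end,
## strand, role) in element-local 0-based coords, ltr_len, extra fields)
build_consensus <- function(superfamily, cfg, cores, layout_role = "none") {
  gc <- cfg$gc_content
  orfs <- data.frame(start = integer(0), end = integer(0),
                     strand = character(0), role = character(0))
  ltr_len <- 0L
  tir_len <- 0L
  if (superfamily %in% c("Ty1-copia", "Ty3-gypsy")) {
    ltr_len <- as.integer(round(runif(1, cfg$ltr_length[1], cfg$ltr_length[2])))
    ltr <- paste0("TG", rand_str(ltr_len - 4, gc), "CA")
    core <- cores[[if (superfamily == "Ty1-copia") "Ty1-copia" else "Ty3-gypsy"]]
    rt <- make_orf(core, 250, 250)
    pad1 <- rand_str(150, gc); pad2 <- rand_str(150, gc)
    extra <- ""
    pad3 <- ""
    if (layout_role != "none") {
      extra_orf <- make_orf("", 0, sample(350:450, 1))
      extra <- if (layout_role == "orf2") revcomp(extra_orf) else extra_orf
      pad3 <- rand_str(150, gc)
    }
    internal <- paste0(pad1, rt, pad2, extra, pad3)
    seq <- paste0(ltr, internal, ltr)
    rt_start <- ltr_len + 150L
    orfs <- data.frame(start = rt_start, end = rt_start + nchar(rt),
                       strand = "+", role = "retrotransposase")
    if (layout_role != "none") {
      ex_start <- rt_start + nchar(rt) + 150L
      orfs <- rbind(orfs, data.frame(
        start = ex_start, end = ex_start + nchar(extra),
        strand = if (layout_role == "orf2") "-" else "+",
        role = if (layout_role == "orf2") "orf2" else "env-like"))
    }
  } else if (superfamily == "LINE") {
    orf <- make_orf(cores[["LINE"]], 150, 100)
    pre <- rand_str(300, gc); post <- rand_str(150, gc)
    seq <- paste0(pre, orf, post, strrep("A", 25))
    orfs <- data.frame(start = 300L, end = 300L + nchar(orf),
                       strand = "+", role = "retrotransposase")
  } else if (superfamily == "SINE") {
    seq <- paste0(rand_str(sample(150:400, 1), gc), strrep("A", 15))
  } else if (superfamily == "CACTA") {
    orf <- make_orf(cores[["CACTA"]], 150, 100)
    seq <- paste0("CACTA", rand_str(300, gc), orf, rand_str(300, gc),
                  cfg$cacta_three_prime)
    orfs <- data.frame(start = 305L, end = 305L + nchar(orf),
                       strand = "+", role = "transposase")
  } else if (superfamily %in% c("hAT", "MULE", "PIF/Harbinger")) {
    tir_len <- switch(superfamily, "hAT" = 15L, "MULE" = 60L,
                      "PIF/Harbinger" = 14L)
    tir <- rand_str(tir_len, gc)
    orf <- make_orf(cores[[superfamily]], 150, 100)
    pre <- rand_str(250, gc); post <- rand_str(250, gc)
    seq <- paste0(tir, pre, orf, post, revcomp(tir))
    orfs <- data.frame(start = tir_len + 250L,
                       end = tir_len + 250L + nchar(orf),
                       strand = "+", role = "transposase")
  } else if (superfamily == "Helitron") {
    orf <- make_orf(cores[["Helitron"]], 150, 100)
    seq <- paste0("TC", rand_str(200, gc), orf, rand_str(200, gc),
                  "CT", sample(c("A", "G"), 1), sample(c("A", "G"), 1))
    orfs <- data.frame(start = 202L, end = 202L + nchar(orf),
                       strand = "+", role = "transposase")
  } else {
    stop("unknown superfamily: ", superfamily)
  }
  list(seq = seq, orfs = orfs, ltr_len = ltr_len, tir_len = tir_len)
}

## MITE consensus: short non-coding element with perfect TIRs (hAT-like)
build_mite_consensus <- function(cfg) {
  tir <- rand_str(25, cfg$gc_content)
  list(seq = paste0(tir, rand_str(sample(250:350, 1), cfg$gc_content),
                    revcomp(tir)),
       orfs = data.frame(start = integer(0), end = integer(0),
                         strand = character(0), role = character(0)),
       ltr_len = 0L, tir_len = 25L)
}

## ---- mutation --------------------------------------------------------------

## substitute at `rate` per site, never touching `protect` indices; positions
## inside ORFs that would create a premature stop are reverted (selection-
## style constraint so planted coding capacity survives divergence)
mutate_chars <- function(chars, rate, protect = integer(0),
                         orfs = NULL) {
  n <- length(chars)
  eligible <- setdiff(seq_len(n), protect)
  k <- rbinom(1, length(eligible), rate)
  if (k == 0) return(chars)
  pos <- sample(eligible, k)
  orig <- chars
  for (p in pos) {
    chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1)
  }
  if (!is.null(orfs) && nrow(orfs)) {
    for (i in seq_len(nrow(orfs))) {
      s <- orfs$start[i]; e <- orfs$end[i]  # 0-based half-open, local
      region <- chars[(s + 1):e]
      if (orfs$strand[i] == "-") region <- revcomp_chars(region)
      ncod <- length(region) %/% 3
      codons <- vapply(seq_len(ncod), function(j) {
        paste(region[(3 * j - 2):(3 * j)], collapse = "")
      }, "")
      bad <- which(codons %in% STOP_CODONS & seq_len(ncod) < ncod)
      if (length(bad)) {
        for (j in bad) {
          idx_local <- (3 * j - 2):(3 * j)
          if (orfs$strand[i] == "-") {
            idx <- e - idx_local + 1       # map back through revcomp
          } else {
            idx <- s + idx_local
          }
          hit <- idx[idx %in% pos]
          chars[hit] <- orig[hit]
        }
      }
    }
  }
  chars
}

## mutate a consensus element into one planted copy; LTR retros get mirrored
## mutations in both LTRs plus extra right-LTR divergence so that the
## LTR-to-LTR divergence is exactly the drawn ltr rate
mutate_copy <- function(consensus, superfamily, cfg) {
  chars <- strsplit(consensus$seq, "")[[1]]
  n <- length(chars)
  d_elem <- runif(1, cfg$element_divergence[1], cfg$element_divergence[2])
  protect <- unique(c(1:min(5, n), max(1, n - 4):n))
  ## terminal repeats/motifs are under selection: keep TIRs intact
  if (consensus$tir_len > 0) {
    tl <- consensus$tir_len
    protect <- unique(c(protect, 1:tl, (n - tl + 1):n))
  }
  ## keep planted start/stop codons and polyA tails intact
  if (nrow(consensus$orfs)) {
    for (i in seq_len(nrow(consensus$orfs))) {
      s <- consensus$orfs$start[i]; e <- consensus$orfs$end[i]
      protect <- c(protect, (s + 1):(s + 3), (e - 2):e)
    }
  }
  if (superfamily %in% c("LINE", "SINE")) {
    r <- rle(rev(chars) == "A")
    tail_len <- if (r$values[1]) r$lengths[1] else 0L
    if (tail_len > 0) protect <- c(protect, (n - tail_len + 1L):n)
  }
  ltr_len <- consensus$ltr_len
  d_ltr <- NA_real_
  if (ltr_len > 0) {
    ## element-level mutations applied to internal + left LTR, left LTR's
    ## pattern mirrored onto the right LTR
    body_idx <- seq_len(n - ltr_len)
    ## the left LTR is mirrored onto the right one, so protect its TG...CA
    prot_body <- unique(c(intersect(protect, body_idx), 1:2,
                          (ltr_len - 1):ltr_len))
    body <- mutate_chars(chars[body_idx], d_elem, prot_body, consensus$orfs)
    right <- body[1:ltr_len]                       # mirror of mutated left LTR
    d_ltr <- runif(1, cfg$ltr_divergence[1], cfg$ltr_divergence[2])
    right <- mutate_chars(right, d_ltr, protect = c(1:2, (ltr_len - 1):ltr_len))
    chars <- c(body, right)
  } else {
    chars <- mutate_chars(chars, d_elem, protect, consensus$orfs)
  }
  list(seq = paste(chars, collapse = ""), divergence = d_elem,
       ltr_divergence = d_ltr)
}

## ---- the generator ---------------------------------------------------------

#' Simulate a truth-tracked genome
#'
#' Builds family consensus sequences for every requested superfamily, mutates
#' per-copy at the drawn divergence (substitutions only), flanks each copy
#' with its superfamily's TSD, and embeds the copies in an i.i.d. background
#' at the configured GC content with at least `min_spacing` bp between
#' elements. Every planted copy is described exactly by one truth record.
#'
#' @param config a [sim_config()].
#' @return list with components:
#'   \describe{
#'     \item{genome}{named character vector of sequences (one `chr1`).}
#'     \item{truth}{data.frame of truth records: `element_id`, `superfamily`,
#'       `seq_id`, `start`, `end` (0-based half-open), `strand`, `tsd`,
#'       `family`, `divergence`, `ltr_divergence`, and the LTR spans
#'       `ltr1_start`, `ltr1_end`, `ltr2_start`, `ltr2_end` (NA for
#'       non-LTR elements).}
#'     \item{orfs}{data.frame of planted ORFs in genome coordinates:
#'       `element_id`, `start`, `end`, `strand`, `role`.}
#'     \item{config}{the input configuration.}
#'   }
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, {
    cores <- setNames(domain_core_queries()$peptide,
                      domain_core_queries()$superfamily)
    ## family plan: superfamily, family label, layout role, member count
    plan <- list()
    for (sf in SUPERFAMILIES) {
      n <- config$n_elements[[sf]]
      if (n == 0) next
      nf <- ceiling(n / config$members_per_family)
      sizes <- rep(n %/% nf, nf)
      if (n %% nf) sizes[seq_len(n %% nf)] <- sizes[seq_len(n %% nf)] + 1
      prefix <- gsub("[^A-Za-z0-9]", "", sf)
      for (f in seq_len(nf)) {
        role <- "none"
        if (sf == "Ty1-copia" && f <= config$n_env_like) role <- "env-like"
        if (sf == "Ty3-gypsy" && f <= config$n_orf2) role <- "orf2"
        plan[[length(plan) + 1]] <- list(
          superfamily = sf, family = paste0(prefix, "_fam", f),
          role = role, size = sizes[f])
      }
    }
    if (config$n_mites > 0) {
      plan[[length(plan) + 1]] <- list(superfamily = "hAT",
                                       family = "hAT_mite1", role = "mite",
                                       size = config$n_mites)
    }

    ## build consensus per family, then per-copy mutated sequences
    copies <- list()
    for (fam in plan) {
      consensus <- if (identical(fam$role, "mite")) {
        build_mite_consensus(config)
      } else {
        build_consensus(fam$superfamily, config, cores, fam$role)
      }
      for (m in seq_len(fam$size)) {
        cp <- mutate_copy(consensus, fam$superfamily, config)
        tsd_rng <- TSD_RULES[[fam$superfamily]]
        if (identical(fam$role, "mite")) tsd_rng <- TSD_RULES[["hAT"]]
        tsd_len <- if (tsd_rng[2] == 0) 0L else if (tsd_rng[1] == tsd_rng[2]) {
          as.integer(tsd_rng[1])
        } else {
          as.integer(sample(seq(tsd_rng[1], tsd_rng[2]), 1))
        }
        strand <- sample(c("+", "-"), 1)
        copies[[length(copies) + 1]] <- list(
          superfamily = fam$superfamily, family = fam$family,
          seq = cp$seq, strand = strand,
          tsd = paste(random_dna(tsd_len, config$gc_content), collapse = ""),
          divergence = cp$divergence, ltr_divergence = cp$ltr_divergence,
          ltr_len = consensus$ltr_len, orfs = consensus$orfs)
      }
    }

    ## placement with >= min_spacing background between and around elements
    n_el <- length(copies)
    truth <- data.frame()
    orf_truth <- data.frame()
    if (n_el == 0) {
      genome <- c(chr1 = rand_str(config$genome_length, config$gc_content))
      return(list(genome = genome,
                  truth = empty_truth(), orfs = empty_orf_truth(),
                  config = config))
    }
    copies <- copies[sample.int(n_el)]   # shuffle placement order
    footprint <- vapply(copies, function(cp) {
      nchar(cp$seq) + 2L * nchar(cp$tsd)
    }, integer(1))
    bg_total <- config$genome_length - sum(footprint)
    if (bg_total < (n_el + 1L) * config$min_spacing) {
      stop("genome too small: ", config$genome_length,
           " bp cannot hold ", n_el, " elements (", sum(footprint),
           " bp) with ", config$min_spacing, " bp spacing")
    }
    extra <- bg_total - (n_el + 1L) * config$min_spacing
    w <- diff(c(0, sort(runif(n_el)), 1))
    gaps <- config$min_spacing + floor(extra * w)
    gaps[n_el + 1] <- bg_total - sum(gaps[seq_len(n_el)])

    pieces <- character(2 * n_el + 1)
    pos <- 0L
    rows <- vector("list", n_el)
    orf_rows <- list()
    for (i in seq_len(n_el)) {
      cp <- copies[[i]]
      pieces[2 * i - 1] <- rand_str(gaps[i], config$gc_content)
      pos <- pos + gaps[i]
      tsd <- cp$tsd
      el_seq <- if (cp$strand == "-") revcomp(cp$seq) else cp$seq
      pieces[2 * i] <- paste0(tsd, el_seq, tsd)
      start <- pos + nchar(tsd)
      end <- start + nchar(el_seq)
      id <- sprintf("te%03d", i)
      ltr <- cp$ltr_len
      rows[[i]] <- data.frame(
        element_id = id, superfamily = cp$superfamily, seq_id = "chr1",
        start = start, end = end, strand = cp$strand, tsd = tsd,
        family = cp$family, divergence = cp$divergence,
        ltr_divergence = cp$ltr_divergence,
        ltr1_start = if (ltr > 0) start else NA_integer_,
        ltr1_end = if (ltr > 0) start + ltr else NA_integer_,
        ltr2_start = if (ltr > 0) end - ltr else NA_integer_,
        ltr2_end = if (ltr > 0) end else NA_integer_,
        stringsAsFactors = FALSE)
      if (nrow(cp$orfs)) {
        o <- cp$orfs
        if (cp$strand == "+") {
          g_start <- start + o$start; g_end <- start + o$end
          g_strand <- o$strand
        } else {
          g_start <- end - o$end; g_end <- end - o$start
          g_strand <- ifelse(o$strand == "+", "-", "+")
        }
        orf_rows[[length(orf_rows) + 1]] <- data.frame(
          element_id = id, start = g_start, end = g_end,
          strand = g_strand, role = o$role, stringsAsFactors = FALSE)
      }
      pos <- pos + nchar(tsd) * 2L + nchar(el_seq)
    }
    pieces[2 * n_el + 1] <- rand_str(gaps[n_el + 1], config$gc_content)
    genome <- c(chr1 = paste(pieces, collapse = ""))
    stopifnot(nchar(genome) == config$genome_length)
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$start), ]
    rownames(truth) <- NULL
    orf_truth <- if (length(orf_rows)) do.call(rbind, orf_rows) else empty_orf_truth()
    list(genome = genome, truth = truth, orfs = orf_truth, config = config)
  })
}

empty_truth <- function() {
  data.frame(element_id = character(0), superfamily = character(0),
             seq_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), tsd = character(0), family = character(0),
             divergence = numeric(0), ltr_divergence = numeric(0),
             ltr1_start = integer(0), ltr1_end = integer(0),
             ltr2_start = integer(0), ltr2_end = integer(0),
             stringsAsFactors = FALSE)
}

empty_orf_truth <- function() {
  data.frame(element_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), role = character(0),
             stringsAsFactors = FALSE)
}

#' Simulate an EST pool from a synthetic genome
#'
#' Draws `est_count` single-pass reads: a Bernoulli(`est_te_fraction`) choice
#' per read between a planted-element body and the non-element background,
#' with a per-base substitution error drawn from `est_error`. Each record
#' carries its true source in its description for truth-checking.
#'
#' @param config the [sim_config()] used for the genome.
#' @param genome named character vector from [simulate_genome()].
#' @param truth truth data.frame from [simulate_genome()].
#' @return data.frame with columns `est_id`, `source` (element_id or
#'   `"background"`), `seq`.
#' @export
simulate_ests <- function(config, genome, truth) {
  stopifnot(inherits(config, "sim_config"))
  genome <- check_genome(genome)
  glen <- nchar(genome[[1]])
  if (config$est_length[2] > glen) {
    stop("est_length exceeds genome length")
  }
  with_seed(config$rng_seed + 104729L, {
    n <- config$est_count
    if (n == 0) {
      return(data.frame(est_id = character(0), source = character(0),
                        seq = character(0), stringsAsFactors = FALSE))
    }
    from_te <- runif(n) < config$est_te_fraction & nrow(truth) > 0
    ## background mask: anything outside planted element spans (incl. TSDs)
    seq1 <- genome[[1]]
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      len <- sample(seq(config$est_length[1], config$est_length[2]), 1)
      if (from_te[i]) {
        j <- sample.int(nrow(truth), 1)
        el_len <- truth$end[j] - truth$start[j]
        l <- min(len, el_len)
        off <- sample.int(el_len - l + 1L, 1) - 1L
        s <- truth$start[j] + off
        src <- truth$element_id[j]
        read <- substr0(seq1, s, s + l)
      } else {
        repeat {
          s <- sample.int(glen - len + 1L, 1) - 1L
          if (nrow(truth) == 0 ||
              !any(s < truth$end & (s + len) > truth$start)) break
        }
        src <- "background"
        read <- substr0(seq1, s, s + len)
      }
      chars <- strsplit(read, "")[[1]]
      if (runif(1) < 0.5) chars <- revcomp_chars(chars)
      err <- runif(1, config$est_error[1], config$est_error[2])
      chars <- mutate_chars(chars, err)
      rows[[i]] <- data.frame(est_id = sprintf("est%04d", i), source = src,
                              seq = paste(chars, collapse = ""),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
}

#' Write simulation outputs to disk
#'
#' Writes the genome FASTA (60-column), the EST FASTA (source in the header
#' description), the truth as GFF3 (`transposable_element` features, 1-based
#' closed coordinates with superfamily/family/TSD/LTR attributes) and as TSV.
#'
#' @param sim result of [simulate_genome()].
#' @param dir output directory (created if needed).
#' @param ests optional result of [simulate_ests()].
#' @return named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, ests = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             truth_gff = file.path(dir, "truth.gff3"),
             truth_tsv = file.path(dir, "truth.tsv"))
  write_fasta(sim$genome, paths[["genome"]])
  tr <- sim$truth
  gff_df <- data.frame(seq_id = tr$seq_id, start = tr$start, end = tr$end,
                       strand = tr$strand, ID = tr$element_id,
                       superfamily = tr$superfamily, family = tr$family,
                       TSD = tr$tsd, stringsAsFactors = FALSE)
  write_gff3(gff_df, paths[["truth_gff"]], type = "transposable_element",
             seqlengths = setNames(nchar(sim$genome), names(sim$genome)))
  write_tsv(tr, paths[["truth_tsv"]])
  if (!is.null(ests)) {
    paths["ests"] <- file.path(dir, "ests.fa")
    write_fasta(setNames(ests$seq, ests$est_id), paths[["ests"]],
                desc = paste0("source=", ests$source))
  }
  invisible(paths)
}
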