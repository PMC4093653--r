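## End-to-end orchestration: simulate -> LTR detection -> homology scan ->
## structural classification -> family clustering -> library -> EST/ORF/
## phylogeny stages, with per-stage outputs, a run manifest and simple
## parameter-aware caching. Every numeric threshold defaults to the values
## the annotation workflow is built around (50 bp minimum LTR length and
## internal distance, homology E < 1e-20 with 10-kb flanks, family identity
## > 70%, EST E < 1e-5, 150-aa minimum ORF, 100-kb windows).

#' Pipeline configuration
#'
#' @param out_dir output directory for stage results and the manifest.
#' @param sim a [sim_config()] (the genome is simulated) or `NULL` when
#'   `genome` is supplied directly.
#' @param genome optional named character vector of sequences (skips the
#'   simulation stage).
#' @param stages character vector of stages to run, a subset of
#'   `simulate`, `ltr`, `homology`, `classify`, `families`, `est`, `orf`,
#'   `phylo`.
#' @param min_ltr_len,min_internal LTR detection thresholds, bp.
#' @param homology_evalue translated-search cutoff.
#' @param flank flank extraction size, bp per side.
#' @param family_identity family-clustering identity threshold, percent.
#' @param est_evalue EST assignment cutoff.
#' @param min_orf_aa minimum ORF length, aa.
#' @param window distribution-profile window, bp.
#' @param rng_seed seed for the run (passed to the simulation).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir,
                            sim = sim_config(),
                            genome = NULL,
                            stages = c("simulate", "ltr", "homology",
                                       "classify", "families", "est",
                                       "orf", "phylo"),
                            min_ltr_len = 50, min_internal = 50,
                            homology_evalue = 1e-20, flank = 10000,
                            family_identity = 70, est_evalue = 1e-5,
                            min_orf_aa = 150, window = 100000,
                            rng_seed = NULL) {
  known <- c("simulate", "ltr", "homology", "classify", "families", "est",
             "orf", "phylo")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  for (v in c(min_ltr_len, min_internal, homology_evalue, flank,
              family_identity, est_evalue, min_orf_aa, window)) {
    if (!is.numeric(v) || v <= 0) stop("thresholds must be positive")
  }
  if (!is.null(rng_seed) && !is.null(sim)) sim$rng_seed <- as.integer(rng_seed)
  structure(list(out_dir = out_dir, sim = sim, genome = genome,
                 stages = stages, min_ltr_len = min_ltr_len,
                 min_internal = min_internal,
                 homology_evalue = homology_evalue, flank = flank,
                 family_identity = family_identity, est_evalue = est_evalue,
                 min_orf_aa = min_orf_aa, window = window),
            class = "pipeline_config")
}

## parameter-aware stage cache: recompute only when params changed
stage_cached <- function(dir, name, params, compute) {
  path <- file.path(dir, paste0(name, ".rds"))
  if (file.exists(path)) {
    stored <- readRDS(path)
    if (identical(stored$params, params)) {
      return(list(value = stored$value, cached = TRUE))
    }
  }
  value <- compute()
  saveRDS(list(params = params, value = value), path)
  list(value = value, cached = FALSE)
}

#' Run the annotation pipeline
#'
#' Executes the configured stages in dependency order, writing each stage's
#' outputs (FASTA/GFF3/TSV) plus a JSON manifest recording the parameters
#' used, element counts and output checksums. Re-running against the same
#' output directory reuses cached stage results when parameters are
#' unchanged; skipped stages are noted in the manifest.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the stage results (`sim`, `ltr_candidates`,
#'   `ltr_accepted`, `hits`, `classified`, `clustering`, `library`, `ests`,
#'   `est_assignments`, `est_summary`, `orf_annotations`, `tree`) and the
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(parameters = config[setdiff(names(config),
                                               c("out_dir", "genome"))],
                   stages = list())
  res <- list()
  note <- function(name, cached, counts, files = character(0)) {
    manifest$stages[[name]] <<- list(
      run = TRUE, cached = cached, counts = counts,
      outputs = as.list(tools::md5sum(files[file.exists(files)])))
  }
  skip <- function(name) manifest$stages[[name]] <<- list(run = FALSE)
  on_stage <- function(s) s %in% config$stages

  ## --- genome -------------------------------------------------------------
  if (on_stage("simulate") && !is.null(config$sim)) {
    st <- stage_cached(config$out_dir, "simulate", config$sim, function() {
      sim <- simulate_genome(config$sim)
      ests <- simulate_ests(config$sim, sim$genome, sim$truth)
      write_simulation(sim, file.path(config$out_dir, "sim"), ests)
      list(sim = sim, ests = ests)
    })
    res$sim <- st$value$sim
    res$ests <- st$value$ests
    genome <- res$sim$genome
    note("simulate", st$cached, list(elements = nrow(res$sim$truth),
                                     ests = nrow(res$ests)),
         file.path(config$out_dir, "sim",
                   c("genome.fa", "truth.gff3", "truth.tsv", "ests.fa")))
  } else {
    skip("simulate")
    genome <- check_genome(config$genome)
  }

  dcfg <- detect_config(min_ltr_len = config$min_ltr_len,
                        min_internal = config$min_internal)

  ## --- LTR detection -------------------------------------------------------
  if (on_stage("ltr")) {
    st <- stage_cached(config$out_dir, "ltr",
                       list(dcfg, genome_hash = digest_strings(genome)),
                       function() {
      cands <- find_direct_repeat_pairs(genome, dcfg)
      inspected <- inspect_candidates(genome, cands, dcfg)
      accepted <- inspected[inspected$status == "accepted", , drop = FALSE]
      write_tsv(inspected, file.path(config$out_dir, "ltr_candidates.tsv"))
      if (nrow(accepted)) {
        gff <- data.frame(seq_id = accepted$seq_id, start = accepted$start,
                          end = accepted$end, strand = "+",
                          ID = sprintf("ltr%03d", seq_len(nrow(accepted))),
                          TSD = accepted$tsd,
                          ltr_identity = accepted$ltr_identity)
        write_gff3(gff, file.path(config$out_dir, "ltr_accepted.gff3"),
                   type = "LTR_retrotransposon")
      }
      list(candidates = inspected, accepted = accepted)
    })
    res$ltr_candidates <- st$value$candidates
    res$ltr_accepted <- st$value$accepted
    note("ltr", st$cached,
         list(candidates = nrow(res$ltr_candidates),
              accepted = nrow(res$ltr_accepted)),
         file.path(config$out_dir, c("ltr_candidates.tsv",
                                     "ltr_accepted.gff3")))
  } else skip("ltr")

  ## --- homology scan -------------------------------------------------------
  if (on_stage("homology")) {
    queries <- domain_core_queries()
    st <- stage_cached(config$out_dir, "homology",
                       list(config$homology_evalue, config$flank, queries,
                            genome_hash = digest_strings(genome)),
                       function() {
      hits <- translated_search(genome, queries,
                                evalue_cutoff = config$homology_evalue,
                                flank = config$flank)
      write_tsv(hits, file.path(config$out_dir, "domain_hits.tsv"))
      hits
    })
    res$hits <- st$value
    note("homology", st$cached, list(hits = nrow(res$hits)),
         file.path(config$out_dir, "domain_hits.tsv"))
  } else skip("homology")

  ## --- structural classification ------------------------------------------
  if (on_stage("classify")) {
    if (is.null(res$hits)) stop("stage 'classify' requires stage 'homology'")
    st <- stage_cached(config$out_dir, "classify",
                       list(res$hits, res$ltr_accepted,
                            genome_hash = digest_strings(genome)),
                       function() {
      classified <- classify_elements(genome, res$hits, res$ltr_accepted)
      write_tsv(classified, file.path(config$out_dir, "classified.tsv"))
      classified
    })
    res$classified <- st$value
    note("classify", st$cached,
         list(elements = nrow(res$classified)),
         file.path(config$out_dir, "classified.tsv"))
  } else skip("classify")

  ## --- families + library ---------------------------------------------------
  if (on_stage("families")) {
    if (is.null(res$classified)) stop("stage 'families' requires 'classify'")
    st <- stage_cached(config$out_dir, "families",
                       list(res$classified, config$family_identity,
                            genome_hash = digest_strings(genome)),
                       function() {
      seqs <- element_sequences(genome, res$classified)
      clustering <- cluster_families(res$classified, seqs,
                                     identity_threshold = config$family_identity)
      lib <- build_library(clustering, res$classified, seqs)
      write_fasta(setNames(lib$records$seq, lib$records$header),
                  file.path(config$out_dir, "library.fa"))
      write_tsv(lib$summary, file.path(config$out_dir, "library_summary.tsv"))
      list(clustering = clustering, library = lib)
    })
    res$clustering <- st$value$clustering
    res$library <- st$value$library
    note("families", st$cached,
         list(families = nrow(res$clustering$families),
              library_records = nrow(res$library$records),
              total_bp = res$library$total_bp),
         file.path(config$out_dir, c("library.fa", "library_summary.tsv")))
  } else skip("families")

  ## --- EST expression --------------------------------------------------------
  if (on_stage("est")) {
    if (is.null(res$library) || is.null(res$ests)) {
      stop("stage 'est' requires 'families' and simulated ESTs")
    }
    st <- stage_cached(config$out_dir, "est",
                       list(res$library$records$header, config$est_evalue,
                            nrow(res$ests)),
                       function() {
      asg <- map_ests(res$ests, res$library, evalue_cutoff = config$est_evalue)
      smry <- summarize_est_hits(asg)
      write_tsv(asg, file.path(config$out_dir, "est_assignments.tsv"))
      write_tsv(smry$per_superfamily,
                file.path(config$out_dir, "est_summary.tsv"))
      list(assignments = asg, summary = smry)
    })
    res$est_assignments <- st$value$assignments
    res$est_summary <- st$value$summary
    note("est", st$cached,
         list(assigned = sum(!is.na(res$est_assignments$superfamily))),
         file.path(config$out_dir, c("est_assignments.tsv",
                                     "est_summary.tsv")))
  } else skip("est")

  ## --- ORF layout -------------------------------------------------------------
  if (on_stage("orf")) {
    if (is.null(res$ltr_accepted)) stop("stage 'orf' requires 'ltr'")
    st <- stage_cached(config$out_dir, "orf",
                       list(res$ltr_accepted, res$hits, config$min_orf_aa,
                            genome_hash = digest_strings(genome)),
                       function() {
      ann <- annotate_ltr_layouts(genome, res$ltr_accepted, res$hits,
                                  config$min_orf_aa)
      write_tsv(ann, file.path(config$out_dir, "orf_annotations.tsv"))
      ann
    })
    res$orf_annotations <- st$value
    note("orf", st$cached, list(annotated = nrow(res$orf_annotations)),
         file.path(config$out_dir, "orf_annotations.tsv"))
  } else skip("orf")

  ## --- RT phylogeny -----------------------------------------------------------
  if (on_stage("phylo")) {
    if (is.null(res$hits)) stop("stage 'phylo' requires 'homology'")
    st <- stage_cached(config$out_dir, "phylo",
                       list(res$hits, genome_hash = digest_strings(genome)),
                       function() {
      peps <- rt_hit_peptides(genome, res$hits)
      if (length(peps) >= 3) {
        tree <- neighbor_joining(rt_distances(peps))
        ape::write.tree(tree, file.path(config$out_dir, "rt_tree.nwk"))
        tree
      } else NULL
    })
    res$tree <- st$value
    note("phylo", st$cached,
         list(leaves = if (is.null(res$tree)) 0 else
           length(res$tree$tip.label)),
         file.path(config$out_dir, "rt_tree.nwk"))
  } else skip("phylo")

  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  res$manifest <- manifest
  invisible(res)
}

digest_strings <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(names(x), unname(x)), f)
  unname(tools::md5sum(f))
}

## classify non-LTR homology hits + MITE candidates, merge with accepted LTR
## candidates (labelled by overlapping RT domain hits), assign element ids
classify_elements <- function(genome, hits, ltr_accepted = NULL,
                              rules = superfamily_rules()) {
  out <- list()

  ## accepted LTR candidates: superfamily from overlapping RT hits
  if (!is.null(ltr_accepted) && nrow(ltr_accepted)) {
    rt_hits <- hits[hits$superfamily %in% c("Ty1-copia", "Ty3-gypsy"), ,
                    drop = FALSE]
    for (i in seq_len(nrow(ltr_accepted))) {
      cand <- ltr_accepted[i, ]
      over <- rt_hits[rt_hits$seq_id == cand$seq_id &
                        rt_hits$start < cand$end &
                        rt_hits$end > cand$start, , drop = FALSE]
      if (nrow(over)) {
        sf <- over$superfamily[which.max(over$bit_score)]
        strand <- over$strand[which.max(over$bit_score)]
        ev <- c("tsd", "domain_homology")
      } else {
        sf <- "LTR-unclassified"; strand <- "+"; ev <- "tsd"
      }
      row <- classified_row(cand$seq_id, cand$start, cand$end, strand, sf,
                            cand$tsd, ev, complete = TRUE)
      row$class <- 1L
      row$ltr1_end <- cand$ltr1_end
      row$ltr2_start <- cand$ltr2_start
      out[[length(out) + 1]] <- row
    }
  }

  ## non-LTR homology hits -> locate boundaries -> classify
  other <- hits[!hits$superfamily %in% c("Ty1-copia", "Ty3-gypsy"), ,
                drop = FALSE]
  if (nrow(other)) {
    for (i in seq_len(nrow(other))) {
      h <- other[i, ]
      ## skip hits already inside a classified element
      if (length(out)) {
        prev <- do.call(rbind, lapply(out, function(r) r[, c("seq_id", "start", "end")]))
        if (any(prev$seq_id == h$seq_id & prev$start <= h$start &
                  prev$end >= h$end)) next
      }
      region <- locate_element(genome, h, rules)
      row <- classify_candidate(genome, h$seq_id, region[1], region[2],
                                hits = hits, rules = rules, slide = 50)
      ## a Helitron has no structural rule: trust the homology span
      if (row$superfamily == "unclassified" && h$superfamily == "Helitron") {
        row <- classified_row(h$seq_id, region[1], region[2], h$strand,
                              "Helitron", "", "domain_homology",
                              complete = FALSE)
      }
      row$ltr1_end <- NA_integer_; row$ltr2_start <- NA_integer_
      out[[length(out) + 1]] <- row
    }
  }

  ## MITE-style candidates not overlapping anything classified yet
  mites <- find_mite_like(genome)
  if (nrow(mites)) {
    for (i in seq_len(nrow(mites))) {
      m <- mites[i, ]
      prev <- if (length(out)) {
        do.call(rbind, lapply(out, function(r) r[, c("seq_id", "start", "end")]))
      } else NULL
      if (!is.null(prev) && any(prev$seq_id == m$seq_id &
                                  prev$start < m$end & prev$end > m$start)) next
      row <- classify_candidate(genome, m$seq_id, m$start, m$end,
                                hits = hits, rules = rules, slide = 10)
      row$ltr1_end <- NA_integer_; row$ltr2_start <- NA_integer_
      out[[length(out) + 1]] <- row
    }
  }

  res <- do.call(rbind, c(out, list(cbind(empty_classified(),
                                          data.frame(ltr1_end = integer(0),
                                                     ltr2_start = integer(0))))))
  if (nrow(res) == 0) return(res)
  ## drop duplicate spans, assign stable ids by position
  res <- res[!duplicated(res[, c("seq_id", "start", "end")]), , drop = FALSE]
  res <- res[order(res$seq_id, res$start), , drop = FALSE]
  res$element_id <- sprintf("el%03d", seq_len(nrow(res)))
  rownames(res) <- NULL
  res
}

## narrow a homology hit to an approximate element region using the rule's
## anchors (terminal motifs / TIR seeds / polyA), searched within the flank
locate_element <- function(genome, hit, rules, window = 4000) {
  seq <- genome[[hit$seq_id]]
  L <- nchar(seq)
  sf <- hit$superfamily
  rule <- rules[rules$superfamily == sf, , drop = FALSE]
  lo <- max(0, hit$start - window)
  hi <- min(L, hit$end + window)
  default <- c(max(0, hit$start - 500), min(L, hit$end + 500))
  if (nrow(rule) == 0 || sf == "Helitron") return(default)

  strands <- unique(c(hit$strand, "+", "-"))
  for (strand in strands) {
    if (sf == "CACTA") {
      five <- rule$five_prime_motif; three <- rule$three_prime_motif
      if (strand == "-") {
        tmp <- five; five <- revcomp(three); three <- revcomp(tmp)
      }
      up <- window_matches(seq, five, lo, hit$start)
      down <- window_matches(seq, three, hit$end, hi, at_end = TRUE)
      if (length(up) && length(down)) {
        ## prefer the innermost motif pair that also shows the rule's TSD
        ## (outer pairs pick up chance motif occurrences in the flanks)
        combos <- expand.grid(s = up, e = down)
        combos <- combos[order(combos$e - combos$s), , drop = FALSE]
        for (r in seq_len(nrow(combos))) {
          tsd <- tsd_scan(substr0(seq, max(0, combos$s[r] - 30), combos$s[r]),
                          substr0(seq, combos$e[r], min(L, combos$e[r] + 30)),
                          rule$tsd_min, rule$tsd_max)
          if (nzchar(tsd)) return(c(combos$s[r], combos$e[r]))
        }
        return(c(max(up), min(down)))
      }
    } else if (rule$tir_min_len > 0) {
      pr <- inverted_seed_pairs(seq, lo, hit$start, hit$end, hi, k = 10)
      if (nrow(pr)) {
        for (r in seq_len(nrow(pr))) {
          arm <- tir_arm_length(seq, pr$s[r], pr$e[r], max_arm = 200)
          if (arm < max(rule$tir_min_len, 12)) next
          tsd <- tsd_scan(substr0(seq, max(0, pr$s[r] - 30), pr$s[r]),
                          substr0(seq, pr$e[r], min(L, pr$e[r] + 30)),
                          rule$tsd_min, rule$tsd_max)
          if (nzchar(tsd)) return(c(pr$s[r], pr$e[r]))
        }
      }
    } else if (rule$requires_polyA) {
      reg <- locate_line(seq, hit, rule, lo, hi, strand)
      if (!is.null(reg)) return(reg)
    }
  }
  default
}

## 0-based start boundaries of motif occurrences in [lo, hi); with at_end,
## 0-based end boundaries instead
window_matches <- function(seq, motif, lo, hi, at_end = FALSE) {
  if (!nzchar(motif) || hi <= lo) return(integer(0))
  win <- substr0(seq, lo, hi)
  m <- gregexpr(motif, win, fixed = TRUE)[[1]]
  if (m[1] < 0) return(integer(0))
  if (at_end) lo + as.integer(m) - 1L + nchar(motif) else lo + as.integer(m) - 1L
}

## inverted-repeat seed pairs bracketing a hit: upstream k-mers matching the
## reverse complement of downstream k-mers
inverted_seed_pairs <- function(seq, up_lo, up_hi, dn_lo, dn_hi, k = 10) {
  none <- data.frame(s = integer(0), e = integer(0))
  if (up_hi - up_lo < k || dn_hi - dn_lo < k) return(none)
  up <- substr0(seq, up_lo, up_hi)
  dn <- substr0(seq, dn_lo, dn_hi)
  n_u <- nchar(up) - k + 1; n_d <- nchar(dn) - k + 1
  du <- data.table::data.table(w = substring(up, 1:n_u, k:nchar(up)),
                               s = up_lo + 0:(n_u - 1))
  dnk <- substring(dn, 1:n_d, k:nchar(dn))
  dd <- data.table::data.table(
    w = vapply(dnk, function(x) paste(revcomp_chars(strsplit(x, "")[[1]]),
                                      collapse = ""), "", USE.NAMES = FALSE),
    e = dn_lo + k + 0:(n_d - 1))
  pr <- merge(du, dd, by = "w", allow.cartesian = TRUE)
  if (!nrow(pr)) return(none)
  pr <- pr[order(-(pr$e - pr$s)), c("s", "e")]   # outermost pair first
  as.data.frame(pr)
}

## LINE/SINE boundaries: polyA tail on the element strand, then the TSD
## anchors the 5' boundary
locate_line <- function(seq, hit, rule, lo, hi, strand) {
  L <- nchar(seq)
  if (strand == "+") {
    win_lo <- hit$end; win_hi <- hi
    chars <- strsplit(substr0(seq, win_lo, win_hi), "")[[1]]
    runs <- polya_run(chars)
    if (is.null(runs)) return(NULL)
    e0 <- win_lo + runs$end[1]               # 0-based end after first run
    for (e in e0:max(e0 - 5, hit$end)) {
      for (k in rule$tsd_max:rule$tsd_min) {
        if (e + k > L) next
        tsd <- substr0(seq, e, e + k)
        occ <- window_matches(seq, tsd, lo, hit$start, at_end = TRUE)
        if (length(occ)) return(c(max(occ), e))
      }
    }
    NULL
  } else {
    ## element on the minus strand: polyA appears as a leading T-run
    win_lo <- lo; win_hi <- hit$start
    chars <- strsplit(substr0(seq, win_lo, win_hi), "")[[1]]
    r <- rle(chars == "T")
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    ok <- which(r$values & r$lengths >= 10)
    if (!length(ok)) return(NULL)
    s0 <- win_lo + starts[ok[length(ok)]] - 1L    # 0-based start of last run
    for (s in s0:min(s0 + 5, hit$start)) {
      for (k in rule$tsd_max:rule$tsd_min) {
        if (s - k < 0) next
        tsd <- substr0(seq, s - k, s)
        occ <- window_matches(seq, tsd, hit$end, hi)
        if (length(occ)) return(c(s, min(occ)))
      }
    }
    NULL
  }
}

element_sequences <- function(genome, elements) {
  setNames(vapply(seq_len(nrow(elements)), function(i) {
    substr0(genome[[elements$seq_id[i]]], elements$start[i], elements$end[i])
  }, ""), elements$element_id)
}

## ORF-layout annotation for every accepted LTR element
annotate_ltr_layouts <- function(genome, accepted, hits, min_orf_aa = 150) {
  rt_hits <- hits[hits$superfamily %in% c("Ty1-copia", "Ty3-gypsy"), ,
                  drop = FALSE]
  rows <- lapply(seq_len(nrow(accepted)), function(i) {
    el <- accepted[i, ]
    el$element_id <- sprintf("ltr%03d", i)
    ann <- annotate_element_orfs(genome, el, rt_hits, min_orf_aa)$annotation
    over <- rt_hits[rt_hits$seq_id == el$seq_id & rt_hits$start < el$end &
                      rt_hits$end > el$start, , drop = FALSE]
    ann$superfamily <- if (nrow(over)) {
      over$superfamily[which.max(over$bit_score)]
    } else "LTR-unclassified"
    ann$start <- el$start; ann$end <- el$end; ann$seq_id <- el$seq_id
    ann
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(element_id = character(0), te_size = integer(0),
                      ltr_size = integer(0), retrotransposase_aa = character(0),
                      extra_aa = character(0), layout_class = character(0),
                      superfamily = character(0), start = integer(0),
                      end = integer(0), seq_id = character(0),
                      stringsAsFactors = FALSE)
  }
  res
}

## translated peptides of the best RT hits, for the phylogeny stage
rt_hit_peptides <- function(genome, hits) {
  rt <- hits[hits$superfamily %in% c("Ty1-copia", "Ty3-gypsy"), , drop = FALSE]
  if (nrow(rt) == 0) return(character(0))
  peps <- vapply(seq_len(nrow(rt)), function(i) {
    h <- rt[i, ]
    nt <- substr0(genome[[h$seq_id]], h$start, h$end)
    if (h$strand == "-") nt <- revcomp(nt)
    suppressWarnings(as.character(Biostrings::translate(
      Biostrings::DNAString(nt), if.fuzzy.codon = "solve",
      no.init.codon = TRUE)))
  }, "")
  names(peps) <- sprintf("%s_%d_%d_%s", rt$seq_id, rt$start, rt$end,
                         gsub("[^A-Za-z0-9]", "", rt$superfamily))
  peps <- peps[!grepl("*", peps, fixed = TRUE)]
  peps[!duplicated(names(peps))]
}
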