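test_that("a zero-element config yields a pure background genome", {
  cfg <- sim_config(genome_length = 5e4, n_elements = c("Ty1-copia" = 0),
                    n_mites = 0, n_env_like = 0, n_orf2 = 0, rng_seed = 1)
  sim <- simulate_genome(cfg)
  expect_equal(nrow(sim$truth), 0)
  expect_equal(nchar(sim$genome[["chr1"]]), 5e4)
  expect_false(grepl("[^ACGT]", sim$genome[["chr1"]]))
})

test_that("the same seed reproduces the genome and EST pool byte for byte", {
  cfg <- sim_config(genome_length = 8e4,
                    n_elements = c("Ty1-copia" = 2, "CACTA" = 1, "LINE" = 1),
                    n_mites = 1, n_env_like = 1, n_orf2 = 0, est_count = 50,
                    rng_seed = 99)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth, s2$truth)
  e1 <- simulate_ests(cfg, s1$genome, s1$truth)
  expect_identical(e1, simulate_ests(cfg, s2$genome, s2$truth))
  ## and a different seed gives a different genome
  cfg2 <- sim_config(genome_length = 8e4,
                     n_elements = c("Ty1-copia" = 2, "CACTA" = 1, "LINE" = 1),
                     n_mites = 1, n_env_like = 1, n_orf2 = 0, est_count = 50,
                     rng_seed = 100)
  expect_false(identical(simulate_genome(cfg2)$genome, s1$genome))
})

test_that("every planted element satisfies its own truth record", {
  sm <- small_sim()
  g <- sm$sim$genome[["chr1"]]
  tr <- sm$sim$truth
  expect_gt(nrow(tr), 20)
  for (i in seq_len(nrow(tr))) {
    t <- tr[i, ]
    k <- nchar(t$tsd)
    ## TSD flanks the element on both sides
    if (t$superfamily == "Helitron") {
      expect_identical(t$tsd, "")
    } else {
      expect_gt(k, 0)
      expect_identical(substr(g, t$start - k + 1, t$start), t$tsd)
      expect_identical(substr(g, t$end + 1, t$end + k), t$tsd)
    }
    ## spans nested in the genome, LTR spans nested in the element
    expect_true(t$start >= 0 && t$end <= nchar(g) && t$start < t$end)
    if (!is.na(t$ltr1_start)) {
      expect_equal(t$ltr1_start, t$start)
      expect_equal(t$ltr2_end, t$end)
      expect_equal(t$ltr1_end - t$ltr1_start, t$ltr2_end - t$ltr2_start)
      ## LTR retrotransposon termini: TG ... CA
      expect_identical(substr(g, t$start + 1, t$start + 2), "TG")
      expect_identical(substr(g, t$end - 1, t$end), "CA")
    }
  }
  ## planted ORFs are nested inside their elements
  for (i in seq_len(nrow(sm$sim$orfs))) {
    o <- sm$sim$orfs[i, ]
    t <- tr[tr$element_id == o$element_id, ]
    expect_true(o$start >= t$start && o$end <= t$end)
  }
})

test_that("zero LTR divergence plants exactly identical LTRs", {
  cfg <- sim_config(genome_length = 6e4, n_elements = c("Ty1-copia" = 1),
                    n_mites = 0, n_env_like = 0, n_orf2 = 0,
                    ltr_divergence = c(0, 0), rng_seed = 5)
  sim <- simulate_genome(cfg)
  t <- sim$truth[1, ]
  g <- sim$genome[["chr1"]]
  expect_identical(substr(g, t$ltr1_start + 1, t$ltr1_end),
                   substr(g, t$ltr2_start + 1, t$ltr2_end))
})

test_that("an overfull genome fails loudly instead of truncating", {
  cfg <- sim_config(genome_length = 2e4,
                    n_elements = c("Ty1-copia" = 5, "Ty3-gypsy" = 5),
                    n_env_like = 0, n_orf2 = 0, rng_seed = 2)
  expect_error(simulate_genome(cfg), "genome too small")
})

test_that("EST source labels are truthful across te fractions", {
  base <- function(frac, seed) {
    sim_config(genome_length = 1e5, n_elements = c("LINE" = 1),
               n_mites = 0, n_env_like = 0, n_orf2 = 0, est_count = 200,
               est_te_fraction = frac, rng_seed = seed)
  }
  cfg0 <- base(0, 31)
  sim <- simulate_genome(cfg0)
  ests0 <- simulate_ests(cfg0, sim$genome, sim$truth)
  expect_true(all(ests0$source == "background"))
  ## background reads never overlap the planted element (checked via label)
  cfg1 <- base(1, 32)
  sim1 <- simulate_genome(cfg1)
  ests1 <- simulate_ests(cfg1, sim1$genome, sim1$truth)
  expect_true(all(ests1$source == sim1$truth$element_id[1]))

  ## 1,000 reads at fraction 0.3: the labelled TE count is binomial
  cfg3 <- sim_config(genome_length = 2e5,
                     n_elements = c("Ty1-copia" = 2, "LINE" = 2),
                     n_mites = 0, n_env_like = 0, n_orf2 = 0,
                     est_count = 1000, est_te_fraction = 0.3, rng_seed = 33)
  sim3 <- simulate_genome(cfg3)
  ests3 <- simulate_ests(cfg3, sim3$genome, sim3$truth)
  n_te <- sum(ests3$source != "background")
  expect_gt(n_te, 300 - 4 * sqrt(1000 * 0.3 * 0.7))
  expect_lt(n_te, 300 + 4 * sqrt(1000 * 0.3 * 0.7))
})

test_that("EST reads longer than the genome are rejected", {
  cfg <- sim_config(genome_length = 1e5, n_elements = c("LINE" = 1),
                    n_mites = 0, n_env_like = 0, n_orf2 = 0,
                    est_length = c(200, 500), rng_seed = 7)
  sim <- simulate_genome(cfg)
  tiny <- sim$genome
  tiny[["chr1"]] <- substr(tiny[["chr1"]], 1, 100)
  expect_error(simulate_ests(cfg, tiny, sim$truth[0, ]), "est_length")
})

test_that("simulation files round-trip through FASTA", {
  sm <- small_sim()
  dir <- withr::local_tempdir()
  ests <- simulate_ests(sm$cfg, sm$sim$genome, sm$sim$truth)
  paths <- write_simulation(sm$sim, dir, ests)
  g <- read_fasta(paths[["genome"]])
  expect_identical(unname(g[1]), sm$sim$genome[["chr1"]])
  e <- read_fasta(paths[["ests"]])
  expect_equal(length(e), nrow(ests))
  expect_match(names(e)[1], "source=")
  expect_true(file.exists(paths[["truth_gff"]]))
  gff <- readLines(paths[["truth_gff"]])
  expect_equal(sum(grepl("transposable_element", gff)), nrow(sm$sim$truth))
})
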