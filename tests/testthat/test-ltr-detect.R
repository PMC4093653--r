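test_that("a random genome with no long repeats yields no candidate pairs", {
  g <- c(chr1 = rand_seq(10000, seed = 71))
  expect_equal(nrow(find_direct_repeat_pairs(g)), 0)
})

test_that("a planted identical-LTR element is found with exact spans", {
  set.seed(81)
  ltr <- paste0("TG", rand_seq(296), "CA")
  internal <- rand_seq(4000)
  tsd <- "ACGTA"
  g <- c(chr1 = paste0(rand_seq(2000), tsd, ltr, internal, ltr, tsd,
                       rand_seq(2000)))
  cands <- find_direct_repeat_pairs(g)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$ltr_identity, 100)
  ## pre-inspection spans may carry a couple of chance-match bases
  expect_lte(abs(cands$start - 2005), 3)
  expect_lte(abs(cands$end - (2005 + 300 + 4000 + 300)), 3)

  ## inspection pins the boundaries exactly via TG...CA and the TSD
  insp <- inspect_candidate(g, cands, detect_config())
  expect_equal(insp$status, "accepted")
  expect_equal(insp$tsd, "ACGTA")
  expect_true(insp$has_tg_ca)
  expect_equal(insp$start, 2005)
  expect_equal(insp$end, 2005 + 300 + 4000 + 300)
  expect_equal(insp$ltr1_end - insp$ltr1_start, 300)
  expect_equal(insp$ltr2_end - insp$ltr2_start, 300)
})

test_that("repeats shorter than the minimum LTR length are not reported", {
  set.seed(82)
  cfg <- detect_config(min_ltr_identity = 100)
  ## distinct bases flank each copy so the exact repeat cannot extend by
  ## chance beyond the planted unit
  unit49 <- rand_seq(49)
  g <- c(chr1 = paste0(rand_seq(1500), "A", unit49, "G", rand_seq(3000),
                       "C", unit49, "T", rand_seq(1500)))
  expect_equal(nrow(find_direct_repeat_pairs(g, cfg)), 0)
  ## the same construction one base longer is found
  unit50 <- rand_seq(50)
  g2 <- c(chr1 = paste0(rand_seq(1500), "A", unit50, "G", rand_seq(3000),
                        "C", unit50, "T", rand_seq(1500)))
  cands <- find_direct_repeat_pairs(g2, cfg)
  expect_equal(nrow(cands), 1)
  expect_equal(cands$ltr1_end - cands$ltr1_start, 50)
  ## under the default fuzzy identity threshold every reported repeat still
  ## honours the 50-bp minimum
  fuzzy <- find_direct_repeat_pairs(g)
  expect_true(all(fuzzy$ltr1_end - fuzzy$ltr1_start >= 50))
})

test_that("pairing at 100% identity matches the exhaustive diagonal oracle", {
  ## several exact repeat pairs planted in < 20 kb, detector in exact mode
  set.seed(83)
  u1 <- rand_seq(120); u2 <- rand_seq(80); u3 <- rand_seq(300)
  g <- c(chr1 = paste0(rand_seq(1200), u1, rand_seq(900), u1,
                       rand_seq(2500), u2, rand_seq(400), u2,
                       rand_seq(3000), u3, rand_seq(5000), u3,
                       rand_seq(1500)))
  cfg <- detect_config(min_ltr_identity = 100)
  cands <- find_direct_repeat_pairs(g, cfg)
  oracle <- oracle_exact_repeat_pairs(g[[1]], min_len = 50, min_gap = 50,
                                      max_span = 15000)
  ## the oracle enumerates every diagonal; keep its maximal pairs and compare
  expect_equal(nrow(cands), 3)
  for (i in seq_len(nrow(cands))) {
    len <- cands$ltr1_end[i] - cands$ltr1_start[i]
    hit <- oracle[oracle$start == cands$ltr1_start[i] &
                    oracle$ltr_len == len &
                    oracle$d == cands$ltr2_start[i] - cands$ltr1_start[i], ]
    expect_equal(nrow(hit), 1)
  }
  ## and every oracle repeat of >= 50 bp is covered by a reported candidate
  for (k in seq_len(nrow(oracle))) {
    covered <- any(cands$ltr1_start <= oracle$start[k] &
                     cands$ltr1_end >= oracle$start[k] + oracle$ltr_len[k] &
                     cands$ltr2_start - cands$ltr1_start == oracle$d[k])
    expect_true(covered)
  }
})

test_that("a perfect tandem dimer is rejected as tandem", {
  set.seed(84)
  unit <- rand_seq(2000)
  g <- c(chr1 = paste0(rand_seq(2000), unit, unit, rand_seq(2000)))
  cands <- find_direct_repeat_pairs(g)
  expect_gt(nrow(cands), 0)
  insp <- inspect_candidates(g, cands)
  expect_true(all(insp$status == "rejected_tandem"))
})

test_that("a repeat pair without a target-site duplication is rejected", {
  set.seed(85)
  ltr <- paste0("TG", rand_seq(200), "CA")
  g <- c(chr1 = paste0(rand_seq(2000), ltr, rand_seq(1500), ltr,
                       rand_seq(2000)))
  insp <- inspect_candidates(g, find_direct_repeat_pairs(g))
  expect_equal(nrow(insp), 1)
  expect_equal(insp$status, "rejected_no_tsd")
  expect_identical(insp$tsd, "")
})

test_that("identity report flags recent insertions and tracks divergence", {
  expect_equal(nrow(ltr_identity_report(beanTE:::empty_ltr_candidates())), 0)

  cfg <- sim_config(genome_length = 1.2e5,
                    n_elements = c("Ty1-copia" = 2),
                    n_mites = 0, n_env_like = 0, n_orf2 = 0,
                    ltr_divergence = c(0.05, 0.05),
                    element_divergence = c(0, 0), rng_seed = 86)
  sim <- simulate_genome(cfg)
  insp <- inspect_candidates(sim$genome, find_direct_repeat_pairs(sim$genome))
  acc <- insp[insp$status == "accepted", ]
  rep <- ltr_identity_report(acc)
  expect_equal(nrow(rep), 2)
  expect_false(any(rep$recent_insertion))
  expect_true(all(abs(rep$ltr_identity - 95) <= 2))

  cfg0 <- sim_config(genome_length = 1.2e5, n_elements = c("Ty1-copia" = 2),
                     n_mites = 0, n_env_like = 0, n_orf2 = 0,
                     ltr_divergence = c(0, 0), element_divergence = c(0, 0),
                     rng_seed = 87)
  sim0 <- simulate_genome(cfg0)
  insp0 <- inspect_candidates(sim0$genome,
                              find_direct_repeat_pairs(sim0$genome))
  rep0 <- ltr_identity_report(insp0[insp0$status == "accepted", ])
  expect_true(all(rep0$recent_insertion))
})

test_that("planted LTR elements are recovered with exact boundaries and TSDs", {
  sm <- small_sim()
  insp <- inspect_candidates(sm$sim$genome,
                             find_direct_repeat_pairs(sm$sim$genome))
  st <- ltr_recovery_stats(insp[insp$status == "accepted", ], sm$sim$truth)
  expect_equal(st$n_truth, 6)
  expect_gte(st$recall, 0.95)
  expect_gte(st$tsd_exact_rate, 0.95)
})

test_that("a candidate span outside the genome is a contract violation", {
  g <- c(chr1 = rand_seq(1000, seed = 88))
  cand <- data.frame(seq_id = "chr1", start = 500, end = 2000,
                     ltr1_start = 500, ltr1_end = 600, ltr2_start = 1900,
                     ltr2_end = 2000, ltr_identity = 100,
                     tsd = NA_character_, has_tg_ca = NA,
                     status = NA_character_)
  expect_error(inspect_candidate(g, cand), "outside")
})
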