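test_that("find_tsd returns the longest boundary-anchored duplication", {
  expect_equal(find_tsd("TACGATAGC", "TAGCGGTAA", c(4, 6)), "TAGC")
  ## a full-length 29-bp duplication is recovered in the 5-29 range
  set.seed(101)
  tsd29 <- rand_seq(29)
  left <- paste0(rand_seq(10), tsd29)
  right <- paste0(tsd29, rand_seq(10))
  expect_equal(find_tsd(left, right, c(5, 29)), tsd29)
  ## nothing shared -> empty
  expect_identical(find_tsd("AAAAACCCCC", "GGGGGTTTTT", c(4, 6)), "")
  ## window shorter than the range maximum is an input error
  expect_error(find_tsd("ACG", "ACG", c(4, 6)), "flank windows")
})

test_that("find_tsd agrees with brute-force enumeration on random flanks", {
  set.seed(102)
  for (rep in 1:200) {
    k <- sample(2:10, 1)
    dup <- rand_seq(k)
    left <- paste0(rand_seq(20), dup)
    right <- paste0(dup, rand_seq(20))
    lo <- sample(2:4, 1); hi <- sample(6:12, 1)
    expect_identical(find_tsd(left, right, c(lo, hi)),
                     oracle_tsd(left, right, lo, hi))
  }
})

test_that("a planted CACTA is classified by motif and TSD", {
  set.seed(103)
  body <- rand_seq(1200)
  el <- paste0("CACTA", body, "ATGTG")
  tsd <- "TAG"
  g <- c(chr1 = paste0(rand_seq(3000), tsd, el, tsd, rand_seq(3000)))
  cl <- classify_candidate(g, "chr1", 3003, 3003 + nchar(el) + 6)
  expect_equal(cl$superfamily, "CACTA")
  expect_equal(cl$class, 2)
  expect_equal(cl$start, 3003)
  expect_equal(cl$end, 3003 + nchar(el))
  expect_equal(cl$tsd, "TAG")
  expect_true(cl$complete)
  expect_setequal(strsplit(cl$evidence, ",")[[1]], c("terminal_motif", "tsd"))
})

test_that("a planted LINE with polyA tail and domain hit is a complete LINE", {
  set.seed(104)
  core <- domain_core_queries()
  line_pep <- core$peptide[core$superfamily == "LINE"]
  orf <- paste0("ATG", beanTE:::reverse_translate(line_pep), "TAA")
  ## edge bases chosen so no longer duplication straddles the boundaries
  el <- paste0("C", rand_seq(299), orf, rand_seq(100), strrep("A", 35))
  tsd <- paste0("T", rand_seq(10), "G")
  g <- c(chr1 = paste0(rand_seq(4000), "A", tsd, el, tsd, "T",
                       rand_seq(3999)))
  hits <- translated_search(g, core[core$superfamily == "LINE", ,
                                    drop = FALSE])
  expect_equal(nrow(hits), 1)
  cl <- classify_candidate(g, "chr1", 4013, 4013 + nchar(el), hits = hits)
  expect_equal(cl$superfamily, "LINE")
  expect_equal(cl$class, 1)
  expect_true(cl$complete)
  expect_equal(cl$tsd, tsd)
  ev <- strsplit(cl$evidence, ",")[[1]]
  expect_true(all(c("polyA", "tsd", "domain_homology") %in% ev))
})

test_that("a repeat with no motif and no protein stays unclassified", {
  g <- c(chr1 = rand_seq(5000, seed = 105))
  cl <- classify_candidate(g, "chr1", 2000, 2600)
  expect_equal(cl$superfamily, "unclassified")
  expect_false(cl$complete)
  ev <- strsplit(cl$evidence, ",")[[1]]
  expect_false(any(c("terminal_motif", "domain_homology") %in% ev))
})

test_that("MITE scan recovers a planted TIR element with its exact span", {
  set.seed(106)
  tir <- rand_seq(30)
  el <- paste0(tir, rand_seq(340), revcomp(tir))
  tsd <- rand_seq(8)
  g <- c(chr1 = paste0(rand_seq(5000), tsd, el, tsd, rand_seq(5000)))
  m <- find_mite_like(g)
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 5008)
  expect_equal(m$end, 5008 + nchar(el))
  expect_equal(m$tsd, tsd)
  expect_gte(m$tir_len, 30)
})

test_that("a palindromic tandem array without TSD is excluded from MITEs", {
  set.seed(107)
  half <- rand_seq(60)
  pal <- paste0(half, revcomp(half))           # perfect palindrome
  arr <- strrep(pal, 3)
  g <- c(chr1 = paste0(rand_seq(4000), arr, rand_seq(4000)))
  m <- find_mite_like(g)
  ## every reported span must carry a TSD by construction; the palindrome
  ## array has none at its outer boundaries
  if (nrow(m) > 0) {
    expect_true(all(nzchar(m$tsd)))
    expect_false(any(m$start <= 4000 & m$end >= 4000 + nchar(arr)))
  } else {
    succeed()
  }
  expect_equal(nrow(find_mite_like(c(chr1 = rand_seq(200, seed = 1)))), 0)
})

test_that("stored TSDs are idempotent under re-extraction", {
  sm <- small_sim()
  g <- sm$sim$genome[["chr1"]]
  hits <- translated_search(sm$sim$genome, domain_core_queries())
  insp <- inspect_candidates(sm$sim$genome,
                             find_direct_repeat_pairs(sm$sim$genome))
  cl <- beanTE:::classify_elements(sm$sim$genome, hits,
                                   insp[insp$status == "accepted", ])
  complete <- cl[cl$complete & nzchar(cl$tsd), ]
  expect_gt(nrow(complete), 10)
  for (i in seq_len(nrow(complete))) {
    e <- complete[i, ]
    k <- nchar(e$tsd)
    refound <- beanTE:::tsd_scan(substr(g, e$start - 29, e$start),
                                 substr(g, e$end + 1, e$end + 30), k, k)
    expect_identical(refound, e$tsd)
  }
})

test_that("superfamily calls match truth for planted class-2 elements", {
  sm <- small_sim()
  hits <- translated_search(sm$sim$genome, domain_core_queries())
  insp <- inspect_candidates(sm$sim$genome,
                             find_direct_repeat_pairs(sm$sim$genome))
  cl <- beanTE:::classify_elements(sm$sim$genome, hits,
                                   insp[insp$status == "accepted", ])
  tr <- sm$sim$truth
  class2 <- tr[tr$superfamily %in% c("CACTA", "hAT", "MULE", "PIF/Harbinger",
                                     "Helitron"), ]
  calls <- vapply(seq_len(nrow(class2)), function(j) {
    t <- class2[j, ]
    over <- cl[cl$start < t$end & cl$end > t$start, ]
    if (nrow(over) == 0) NA_character_ else over$superfamily[1]
  }, "")
  ok <- !is.na(calls) & calls == class2$superfamily
  expect_gte(mean(ok), 0.9)
  ## motif rules are mutually exclusive: no CACTA is ever called hAT or MULE
  cacta <- class2[class2$superfamily == "CACTA", ]
  for (j in seq_len(nrow(cacta))) {
    t <- cacta[j, ]
    over <- cl[cl$start < t$end & cl$end > t$start, ]
    expect_false(any(over$superfamily %in% c("hAT", "MULE")))
  }
})

test_that("classification is symmetric under reverse complement", {
  set.seed(108)
  body <- rand_seq(1200)
  el <- paste0("CACTA", body, "ATGTG")
  tsd <- "GAT"
  g <- c(chr1 = paste0(rand_seq(2000), tsd, el, tsd, rand_seq(2500)))
  L <- nchar(g[[1]])
  cl_fwd <- classify_candidate(g, "chr1", 2003, 2003 + nchar(el))
  grc <- c(chr1 = revcomp(g[[1]]))
  cl_rev <- classify_candidate(grc, "chr1", L - (2003 + nchar(el)), L - 2003)
  expect_equal(cl_rev$superfamily, cl_fwd$superfamily)
  expect_equal(cl_rev$strand, "-")
  expect_equal(cl_fwd$strand, "+")
  expect_equal(cl_rev$start, L - cl_fwd$end)
  expect_equal(cl_rev$end, L - cl_fwd$start)
  expect_equal(cl_rev$tsd, revcomp(cl_fwd$tsd))
})
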