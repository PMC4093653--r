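make_elements <- function(seqs, complete = TRUE, superfamily = "Ty1-copia") {
  n <- length(seqs)
  data.frame(element_id = names(seqs), seq_id = "chr1",
             start = seq(0, by = 10000, length.out = n),
             end = seq(0, by = 10000, length.out = n) + nchar(seqs),
             strand = "+", class = 1L, superfamily = superfamily,
             tsd = "ACGT", evidence = "tsd",
             complete = rep_len(complete, n), stringsAsFactors = FALSE)
}

mutated <- function(seq, rate, seed) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  paste(beanTE:::mutate_chars(chars, rate), collapse = "")
}

test_that("one element forms one family and is its own representative", {
  set.seed(111)
  seqs <- c(a = rand_seq(2000))
  cl <- cluster_families(make_elements(seqs), seqs)
  expect_equal(nrow(cl$families), 1)
  expect_equal(cl$families$representative_id, "a")
  expect_equal(cl$families$n_members, 1)
})

test_that("single-linkage chains A-B-C even when A and C are dissimilar", {
  set.seed(112)
  base <- rand_seq(3000)
  ## A-B ~ 85%, B-C ~ 85%, A-C ~ 72% pairwise identity
  seqs <- c(a = mutated(base, 0.08, 1), b = base, c = mutated(base, 0.08, 2))
  els <- make_elements(seqs)
  cl <- cluster_families(els, seqs, identity_threshold = 80)
  expect_equal(nrow(cl$families), 1)
  expect_equal(sort(cl$members$element_id), c("a", "b", "c"))
  ## brute-force transitive closure gives the same partition from the edges
  edges <- data.frame(from = c("a", "b"), to = c("b", "c"))
  comp <- oracle_components(c("a", "b", "c"), edges)
  expect_equal(length(unique(comp)), 1)
})

test_that("dissimilar elements stay in separate families", {
  set.seed(113)
  seqs <- c(a = rand_seq(2500), b = rand_seq(2500))
  cl <- cluster_families(make_elements(seqs), seqs)
  expect_equal(nrow(cl$families), 2)
})

test_that("family membership ignores element orientation", {
  set.seed(114)
  base <- rand_seq(2500)
  seqs <- c(a = base, b = revcomp(mutated(base, 0.05, 3)))
  cl <- cluster_families(make_elements(seqs), seqs)
  expect_equal(nrow(cl$families), 1)
})

test_that("representative choice prefers intactness, then length, then id", {
  els <- data.frame(element_id = c("x1", "x2"), seq_id = "chr1",
                    start = c(0, 10000), end = c(5000, 19000),
                    complete = c(TRUE, FALSE))
  expect_equal(pick_representative(c("x1", "x2"), els), "x1")
  els$complete <- c(FALSE, FALSE)
  els$end <- c(3000, 14000)
  expect_equal(pick_representative(c("x1", "x2"), els), "x2")
  els$complete <- c(TRUE, TRUE)
  els$end <- c(4000, 14000)
  els$start <- c(0, 10000)
  expect_equal(pick_representative(c("x2", "x1"), els), "x1")  # tie -> id
  ## adding a shorter incomplete member never changes the representative
  els3 <- rbind(els, data.frame(element_id = "x0", seq_id = "chr1",
                                start = 20000, end = 21000,
                                complete = FALSE))
  expect_equal(pick_representative(c("x1", "x2", "x0"), els3), "x1")
})

test_that("library summary totals are computed, never stored", {
  counts <- c("Ty1-copia" = 4, "Ty3-gypsy" = 5, "LINE" = 2, "CACTA" = 3,
              "unclassified" = 1)
  s <- summarize_library(counts)
  expect_equal(s$count[s$category == "Total"], 15)
  expect_equal(s$count[s$category == "Class 1"], 11)
  expect_equal(s$count[s$category == "Class 2"], 3)
  expect_equal(s$count[s$category == "LTR retrotransposons"], 9)
  empty <- summarize_library(setNames(numeric(0), character(0)))
  expect_equal(empty$count[empty$category == "Total"], 0)
  expect_error(summarize_library(c(bogus = 3)), "unknown categories")
})

test_that("build_library emits RepeatMasker-style headers and true totals", {
  set.seed(115)
  seqs <- c(a = rand_seq(2000), b = rand_seq(1500))
  els <- make_elements(seqs)
  els$superfamily <- c("Ty1-copia", "CACTA")
  els$class <- c(1L, 2L)
  cl <- cluster_families(els, seqs)
  lib <- build_library(cl, els, seqs)
  expect_equal(nrow(lib$records), 2)
  expect_equal(lib$total_bp, 3500)
  expect_match(lib$records$header[lib$records$superfamily == "Ty1-copia"],
               "#Class1/Ty1-copia")
  expect_equal(lib$summary$count[lib$summary$category == "Total"], 2)
})

test_that("clustering recovers the planted family partition exactly", {
  ## families diverged <= 15% within and unrelated between, the regime the
  ## 70%-identity single-linkage rule is built for
  cfg <- sim_config(genome_length = 2.5e5,
                    n_elements = c("Ty1-copia" = 6, "Ty3-gypsy" = 6,
                                   "CACTA" = 4, "MULE" = 4),
                    n_mites = 0, n_env_like = 1, n_orf2 = 1,
                    element_divergence = c(0, 0.075), rng_seed = 116)
  sim <- simulate_genome(cfg)
  tr <- sim$truth
  tr$element_id <- tr$element_id
  tr$complete <- TRUE
  seqs <- beanTE:::element_sequences(sim$genome, tr)
  cl <- cluster_families(tr, seqs)
  fam_pred <- cl$members$family_id[match(tr$element_id,
                                         cl$members$element_id)]
  expect_equal(rand_index(fam_pred, tr$family), 1)
  expect_equal(nrow(cl$families), length(unique(tr$family)))
})

test_that("clustering is invariant under input order", {
  set.seed(117)
  base1 <- rand_seq(2000); base2 <- rand_seq(2000)
  seqs <- c(a = base1, b = mutated(base1, 0.05, 4), c = base2,
            d = mutated(base2, 0.05, 5))
  els <- make_elements(seqs)
  cl1 <- cluster_families(els, seqs)
  perm <- c(3, 1, 4, 2)
  cl2 <- cluster_families(els[perm, ], seqs[perm])
  m1 <- cl1$members[order(cl1$members$element_id), ]
  m2 <- cl2$members[order(cl2$members$element_id), ]
  expect_equal(m1$family_id, m2$family_id)
})

test_that("distribution profiles bin midpoints and conserve counts", {
  members <- data.frame(seq_id = "chr1",
                        start = c(5000, 15000, 250000, 990000),
                        end = c(6000, 16000, 251000, 991000))
  prof <- distribution_profile(members, c(chr1 = 1e6), window = 1e5)
  expect_equal(sum(prof$count), 4)
  expect_equal(prof$count[1], 2)      # midpoints 5500 and 15500
  expect_equal(prof$count[3], 1)      # midpoint 250500
  expect_equal(prof$count[10], 1)     # midpoint 990500
  ## absent sequence -> all zeros
  prof2 <- distribution_profile(members[0, ], c(chr2 = 5e5), window = 1e5)
  expect_true(all(prof2$count == 0))
  ## window larger than the sequence -> one bin holding everything
  prof3 <- distribution_profile(members, c(chr1 = 1e6), window = 2e6)
  expect_equal(nrow(prof3), 1)
  expect_equal(prof3$count, 4)
  expect_error(distribution_profile(members, c(chr1 = 1e6), window = 0),
               "positive")
})
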