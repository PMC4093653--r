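test_that("a region of stop codons in every frame has no ORFs", {
  region <- strrep("TAATGATAG", 200)       # stops tile all frames
  expect_equal(nrow(find_orfs(region, min_len_aa = 50)), 0)
})

test_that("a planted minus-strand ORF is called with its exact length", {
  set.seed(131)
  pep <- paste(sample(strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]], 399,
                      replace = TRUE), collapse = "")
  orf_nt <- paste0("ATG", beanTE:::reverse_translate(pep), "TGA")
  ## an in-frame stop right before the ATG bounds the stop-to-stop segment,
  ## so the planted ATG is the segment's first start codon
  region <- paste0(rand_seq(700), revcomp(paste0("TAA", orf_nt)),
                   rand_seq(700))
  orfs <- find_orfs(region, min_len_aa = 150)
  minus <- orfs[orfs$strand == "-", ]
  expect_equal(nrow(minus), 1)
  expect_equal(minus$aa_len, 400)
  expect_equal(minus$start, 700)
  expect_equal(minus$end, 700 + nchar(orf_nt))
  expect_equal(minus$end - minus$start, 3 * (minus$aa_len + 1))
})

test_that("the minimum-length threshold is a sharp boundary", {
  set.seed(132)
  mk <- function(n_aa) {
    pep <- paste(sample(strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]], n_aa - 1,
                        replace = TRUE), collapse = "")
    paste0("ATG", beanTE:::reverse_translate(pep), "TAA")
  }
  pad <- function(x) paste0(strrep("TAA", 160), x, strrep("TAA", 160))
  expect_equal(nrow(find_orfs(pad(mk(149)), min_len_aa = 150)), 0)
  hit <- find_orfs(pad(mk(150)), min_len_aa = 150)
  expect_equal(sum(hit$aa_len == 150 & hit$strand == "+"), 1)
})

test_that("ORF calling equals the codon-walk oracle on random regions", {
  for (seed in 1:6) {
    region <- rand_seq(6000, seed = 300 + seed)
    got <- find_orfs(region, min_len_aa = 60)
    want <- oracle_orfs(region, min_len_aa = 60)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$strand, want$strand)
    expect_equal(got$aa_len, want$aa_len)
  }
})

element_fixture <- function(layout = c("rt", "env", "orf2"), seed = 133) {
  layout <- match.arg(layout)
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]]
  rt_pep <- paste(sample(aa, 700, replace = TRUE), collapse = "")
  ## leading in-frame stops pin the first ATG to the planted one
  rt <- paste0("TAA", "ATG", beanTE:::reverse_translate(rt_pep), "TAA")
  extra_pep <- paste(sample(aa, 390, replace = TRUE), collapse = "")
  extra_orf <- paste0("TAA", "ATG", beanTE:::reverse_translate(extra_pep),
                      "TAA")
  extra <- switch(layout, rt = "", env = extra_orf,
                  orf2 = revcomp(extra_orf))
  ltr <- paste0("TG", rand_seq(300), "CA")
  internal <- paste0(rand_seq(150), rt, rand_seq(150), extra, rand_seq(150))
  seq <- paste0(ltr, internal, ltr)
  list(seq = seq, ltr_len = nchar(ltr), rt_start = nchar(ltr) + 150,
       rt_len = nchar(rt))
}

annotate_fixture <- function(seq, ltr_len, rt_span = NULL) {
  g <- c(el = seq)
  el <- data.frame(element_id = "el1", seq_id = "el", start = 0,
                   end = nchar(seq), ltr1_start = 0, ltr1_end = ltr_len,
                   ltr2_start = nchar(seq) - ltr_len, ltr2_end = nchar(seq))
  hits <- NULL
  if (!is.null(rt_span)) {
    hits <- data.frame(seq_id = "el", start = rt_span[1], end = rt_span[2],
                       strand = "+", bit_score = 500,
                       superfamily = "Ty3-gypsy")
  }
  annotate_element_orfs(g, el, hits)
}

test_that("sense extra ORFs downstream of the retrotransposase are
          envelope-like", {
  fx <- element_fixture("env")
  ann <- annotate_fixture(fx$seq, fx$ltr_len,
                          c(fx$rt_start, fx$rt_start + fx$rt_len))
  expect_equal(ann$annotation$layout_class, "env_like_sense")
  expect_equal(ann$annotation$extra_aa, "391")       # M + 390 residues
  expect_equal(ann$annotation$retrotransposase_aa, "701")
})

test_that("antisense extra ORFs before the 3' LTR are ORF2", {
  fx <- element_fixture("orf2")
  ann <- annotate_fixture(fx$seq, fx$ltr_len,
                          c(fx$rt_start, fx$rt_start + fx$rt_len))
  expect_equal(ann$annotation$layout_class, "orf2_antisense")
  expect_equal(ann$annotation$extra_aa, "391")
})

test_that("single-ORF elements are retrotransposase-only; empty internal
          regions are non-coding", {
  fx <- element_fixture("rt")
  ann <- annotate_fixture(fx$seq, fx$ltr_len,
                          c(fx$rt_start, fx$rt_start + fx$rt_len))
  expect_equal(ann$annotation$layout_class, "retrotransposase_only")
  ## without domain evidence, the longest ORF is the putative
  ## retrotransposase and the call is unchanged
  ann2 <- annotate_fixture(fx$seq, fx$ltr_len)
  expect_equal(ann2$annotation$layout_class, "retrotransposase_only")
  ## no ORF at all
  set.seed(134)
  ltr <- paste0("TG", rand_seq(200), "CA")
  bare <- paste0(ltr, strrep("TAA", 300), ltr)
  ann3 <- annotate_fixture(bare, nchar(ltr))
  expect_equal(ann3$annotation$layout_class, "no_coding")
})

test_that("layout classification is invariant under reverse complement", {
  for (layout in c("rt", "env", "orf2")) {
    fx <- element_fixture(layout, seed = 135)
    fwd <- annotate_fixture(fx$seq, fx$ltr_len,
                            c(fx$rt_start, fx$rt_start + fx$rt_len))
    L <- nchar(fx$seq)
    rev <- annotate_fixture(revcomp(fx$seq), fx$ltr_len,
                            c(L - fx$rt_start - fx$rt_len, L - fx$rt_start))
    expect_equal(rev$annotation$layout_class, fwd$annotation$layout_class)
    ## every ORF strand flips and spans mirror
    if (nrow(fwd$orfs)) {
      f <- fwd$orfs[order(fwd$orfs$start), ]
      r <- rev$orfs[order(rev$orfs$start), ]
      expect_equal(nrow(r), nrow(f))
      expect_equal(r$start, sort(L - f$end))
      expect_true(all(r$strand != f$strand[match(L - r$end, f$start)]))
    }
  }
})

test_that("a frameshifted retrotransposase classifies by its union span", {
  set.seed(136)
  aa <- strsplit("ACDEFGHIKLNPQRSTVWY", "")[[1]]
  seg <- function(n) paste0("TAA", "ATG", beanTE:::reverse_translate(
    paste(sample(aa, n, replace = TRUE), collapse = "")), "TAA")
  ltr <- paste0("TG", rand_seq(250), "CA")
  s1 <- seg(300); s2 <- seg(200)
  extra <- revcomp(seg(250))
  internal <- paste0(rand_seq(90), s1, rand_seq(31), s2, rand_seq(60),
                     extra, rand_seq(60))
  seq <- paste0(ltr, internal, ltr)
  rt_lo <- nchar(ltr) + 90
  rt_hi <- rt_lo + nchar(s1) + 31 + nchar(s2)
  ann <- annotate_fixture(seq, nchar(ltr), c(rt_lo, rt_hi))
  expect_equal(ann$annotation$layout_class, "orf2_antisense")
  expect_equal(ann$annotation$retrotransposase_aa, "301,201")
})

test_that("the layout census reports one-decimal percentages per group", {
  ann <- data.frame(
    superfamily = c(rep("Ty1-copia", 5), rep("Ty3-gypsy", 4)),
    layout_class = c(rep("retrotransposase_only", 0), rep("env_like_sense", 5),
                     rep("retrotransposase_only", 3), "orf2_antisense"))
  cs <- layout_census(ann)
  expect_equal(cs$pct_retrotransposase_only[cs$superfamily == "Ty1-copia"], 0)
  expect_equal(cs$pct_retrotransposase_only[cs$superfamily == "Ty3-gypsy"], 75)
  ## two of three -> 66.7 (one decimal, half up)
  cs2 <- layout_census(data.frame(
    superfamily = "Ty3-gypsy",
    layout_class = c("retrotransposase_only", "retrotransposase_only",
                     "orf2_antisense")))
  expect_equal(cs2$pct_retrotransposase_only, 66.7)
})

test_that("ORFs outside the internal region violate the contract", {
  fx <- element_fixture("rt")
  el <- data.frame(element_id = "e", start = 0, end = nchar(fx$seq),
                   ltr1_end = fx$ltr_len,
                   ltr2_start = nchar(fx$seq) - fx$ltr_len)
  bad <- data.frame(start = 10, end = 700, strand = "+", frame = 1,
                    aa_len = 229)
  expect_error(classify_layout(el, bad), "internal region")
})
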