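## Reverse-transcriptase-domain phylogenetics: pairwise-alignment
## p-distances, an in-package neighbor-joining implementation with a
## deterministic tie-break, and clade reports over the resulting unrooted
## tree.

#' Pairwise RT-domain distances
#'
#' Distance between two peptides = 1 - identities / aligned positions,
#' from global alignment (BLOSUM62, affine 11/1) with terminal-gap columns
#' excluded; internal gap columns count as aligned, non-identical
#' positions. Symmetric with a zero diagonal by construction.
#'
#' @param peptides named character vector of amino-acid sequences
#'   (at least 2, each at least 50 aa).
#' @return symmetric numeric distance matrix with the peptide names as
#'   dimnames.
#' @export
rt_distances <- function(peptides) {
  if (length(peptides) < 2) stop("need at least 2 peptides")
  if (is.null(names(peptides)) || anyDuplicated(names(peptides))) {
    stop("peptides must be uniquely named")
  }
  check_peptide(peptides, "peptide")
  if (any(nchar(peptides) < 50)) stop("peptides must be at least 50 aa")
  n <- length(peptides)
  d <- matrix(0, n, n, dimnames = list(names(peptides), names(peptides)))
  for (a in 1:(n - 1)) {
    for (b in (a + 1):n) {
      al <- aa_global_align(peptides[[a]], peptides[[b]])
      p <- strsplit(al$pattern_aln, "")[[1]]
      s <- strsplit(al$subject_aln, "")[[1]]
      ## exclude terminal-gap columns of either sequence
      lead <- max(min(which(p != "-")), min(which(s != "-")))
      tail_ <- min(max(which(p != "-")), max(which(s != "-")))
      cols <- lead:tail_
      ident <- sum(p[cols] == s[cols] & p[cols] != "-")
      d[a, b] <- d[b, a] <- 1 - ident / length(cols)
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard neighbor joining (Q-criterion minimisation, iterative
#' agglomeration). Ties in Q are broken by the lexicographically smallest
#' label pair (each internal node is identified by its smallest leaf
#' label). Negative branch-length estimates are clamped to zero and the
#' total clamped amount reported in a message. The result is an unrooted
#' `ape::phylo` (trifurcating root node).
#'
#' @param d symmetric distance matrix with labelled dimnames (>= 3 taxa).
#' @return an `ape` `phylo` object.
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || !isSymmetric(unname(d))) {
    stop("distance matrix must be symmetric")
  }
  if (any(!is.finite(d))) stop("distances must be finite")
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")

  clamp_total <- 0
  fmt <- function(x) {
    x2 <- max(0, x)
    clamp_total <<- clamp_total + (x2 - x) * (x < 0)
    sprintf("%.10g", x2)
  }
  nwk <- labels                 # growing newick fragment per active node
  tie_lab <- labels             # smallest leaf label per active node
  D <- d
  active <- seq_len(n)
  while (length(active) > 3) {
    r <- length(active)
    Da <- D[active, active, drop = FALSE]
    rs <- rowSums(Da)
    Q <- (r - 2) * Da - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    ## deterministic tie-break on the sorted label pair
    keys <- apply(cand, 1, function(ij) {
      lab <- sort(c(tie_lab[active[ij[1]]], tie_lab[active[ij[2]]]))
      paste(lab, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- active[pick[1]]; j <- active[pick[2]]
    dij <- D[i, j]
    li <- dij / 2 + (rs[pick[1]] - rs[pick[2]]) / (2 * (r - 2))
    lj <- dij - li
    ## new node u replaces slot i
    new_d <- (D[i, active] + D[j, active] - dij) / 2
    D[i, active] <- new_d
    D[active, i] <- new_d
    D[i, i] <- 0
    nwk[i] <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    tie_lab[i] <- min(tie_lab[i], tie_lab[j])
    active <- setdiff(active, j)
  }
  a <- active
  l1 <- (D[a[1], a[2]] + D[a[1], a[3]] - D[a[2], a[3]]) / 2
  l2 <- (D[a[1], a[2]] + D[a[2], a[3]] - D[a[1], a[3]]) / 2
  l3 <- (D[a[1], a[3]] + D[a[2], a[3]] - D[a[1], a[2]]) / 2
  text <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[a[1]], fmt(l1),
                  nwk[a[2]], fmt(l2), nwk[a[3]], fmt(l3))
  if (clamp_total > 0) {
    message("negative NJ branch lengths clamped to 0 (total ",
            signif(clamp_total, 4), ")")
  }
  ape::read.tree(text = text)
}

#' Clade report for annotated leaves
#'
#' For each annotation value, finds the minimal edge-bounded cluster (a side
#' of some bipartition of the unrooted tree) containing all annotated
#' leaves, and reports whether the annotated set is exclusive (the cluster
#' contains nothing else). Single annotated leaves are trivially exclusive.
#'
#' @param tree an `ape` `phylo` object.
#' @param groups named character vector: leaf label -> annotation.
#' @return data.frame with `annotation`, `n_annotated`, `cluster_size`,
#'   `exclusive`.
#' @export
clade_report <- function(tree, groups) {
  tips <- tree$tip.label
  unknown <- setdiff(names(groups), tips)
  if (length(unknown)) {
    stop("unknown leaf labels: ", paste(unknown, collapse = ", "))
  }
  n <- length(tips)
  ## bipartition sides: every clade of the (arbitrarily rooted) tree and its
  ## complement, plus the trivial single-leaf sides
  parts <- ape::prop.part(tree)
  sides <- lapply(parts, function(p) tips[p])
  sides <- c(sides, lapply(sides, function(s) setdiff(tips, s)),
             as.list(tips))
  sides <- unique(lapply(sides, sort))
  sides <- sides[vapply(sides, length, integer(1)) > 0]

  rows <- lapply(unique(groups), function(ann) {
    set <- sort(names(groups)[groups == ann])
    containing <- sides[vapply(sides, function(s) all(set %in% s), TRUE)]
    sizes <- vapply(containing, length, integer(1))
    best <- min(sizes)
    data.frame(annotation = ann, n_annotated = length(set),
               cluster_size = best, exclusive = best == length(set),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
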