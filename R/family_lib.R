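## Family clustering and the representative library: all-against-all local
## alignment (k-mer prefiltered), single-linkage components over the
## similarity graph, representative selection, the Table-1-style category
## summary, and per-family chromosomal distribution profiles.

#' Cluster classified elements into families
#'
#' Pairwise similarity from local alignment of full element sequences (both
#' orientations; identity over the aligned region, coverage relative to the
#' shorter sequence). Edges join pairs with identity strictly above
#' `identity_threshold` and coverage at least `coverage_threshold`; families
#' are the connected components (single linkage). Family ids are the
#' superfamily prefix plus an ordinal by descending member count, ties by
#' leftmost coordinate. Input order does not matter: elements are sorted
#' canonically before clustering.
#'
#' @param elements classified-element data.frame (needs `element_id`,
#'   `seq_id`, `start`, `end`, `superfamily`, `complete`).
#' @param sequences named character vector, `element_id` -> sequence.
#' @param identity_threshold percent identity; edges require strictly more.
#' @param coverage_threshold percent of the shorter sequence that must be
#'   aligned.
#' @param prefilter_kmer,prefilter_min only pairs sharing at least
#'   `prefilter_min` exact k-mers (either orientation) are aligned.
#' @return list with `families` (data.frame `family_id`, `superfamily`,
#'   `n_members`, `representative_id`) and `members` (data.frame
#'   `element_id`, `family_id`).
#' @export
cluster_families <- function(elements, sequences, identity_threshold = 70,
                             coverage_threshold = 80, prefilter_kmer = 12,
                             prefilter_min = 3) {
  if (nrow(elements) == 0) stop("cluster_families needs at least one element")
  stopifnot(all(elements$element_id %in% names(sequences)))
  elements <- elements[order(elements$seq_id, elements$start,
                             elements$element_id), , drop = FALSE]
  ids <- elements$element_id
  n <- length(ids)

  kmer_sets <- lapply(ids, function(id) {
    s <- sequences[[id]]
    nk <- nchar(s) - prefilter_kmer + 1
    if (nk < 1) return(character(0))
    unique(substring(s, 1:nk, prefilter_kmer:nchar(s)))
  })
  rc_sets <- lapply(ids, function(id) {
    s <- revcomp(sequences[[id]])
    nk <- nchar(s) - prefilter_kmer + 1
    if (nk < 1) return(character(0))
    unique(substring(s, 1:nk, prefilter_kmer:nchar(s)))
  })

  edges <- list()
  if (n > 1) {
    for (a in 1:(n - 1)) {
      for (b in (a + 1):n) {
        fwd_shared <- length(intersect(kmer_sets[[a]], kmer_sets[[b]]))
        rc_shared <- length(intersect(kmer_sets[[a]], rc_sets[[b]]))
        if (max(fwd_shared, rc_shared) < prefilter_min) next
        sa <- sequences[[ids[a]]]
        sb <- if (rc_shared > fwd_shared) revcomp(sequences[[ids[b]]]) else
          sequences[[ids[b]]]
        short_len <- min(nchar(sa), nchar(sb))
        al <- if (nchar(sa) <= nchar(sb)) nt_local_align(sa, sb) else
          nt_local_align(sb, sa)
        identity <- 100 * al$nmatch / al$aligned_len
        coverage <- 100 * (al$pattern_end - al$pattern_start + 1) / short_len
        if (identity > identity_threshold && coverage >= coverage_threshold) {
          edges[[length(edges) + 1]] <- data.frame(from = ids[a], to = ids[b])
        }
      }
    }
  }
  g <- igraph::graph_from_data_frame(
    if (length(edges)) do.call(rbind, edges) else
      data.frame(from = character(0), to = character(0)),
    directed = FALSE, vertices = data.frame(name = ids))
  membership <- igraph::components(g)$membership[ids]

  fam_of <- split(ids, membership)
  sizes <- vapply(fam_of, length, integer(1))
  leftmost <- vapply(fam_of, function(m) {
    min(elements$start[match(m, elements$element_id)])
  }, numeric(1))
  sf_of <- vapply(fam_of, function(m) {
    sfs <- elements$superfamily[match(m, elements$element_id)]
    names(sort(table(sfs), decreasing = TRUE))[1]
  }, "")
  ord <- order(-sizes, leftmost)

  prefix <- gsub("[^A-Za-z0-9]", "", sf_of)
  fam_id <- character(length(fam_of))
  counter <- list()
  for (k in ord) {
    p <- prefix[k]
    counter[[p]] <- (counter[[p]] %||% 0L) + 1L
    fam_id[k] <- sprintf("%s_F%02d", p, counter[[p]])
  }

  members <- data.frame(
    element_id = unlist(fam_of, use.names = FALSE),
    family_id = rep(fam_id, sizes), stringsAsFactors = FALSE)
  reps <- vapply(seq_along(fam_of), function(k) {
    pick_representative(fam_of[[k]], elements)
  }, "")
  families <- data.frame(family_id = fam_id, superfamily = sf_of,
                         n_members = sizes, representative_id = reps,
                         stringsAsFactors = FALSE)
  families <- families[ord, , drop = FALSE]
  rownames(families) <- NULL
  list(families = families, members = members)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pick a family's representative element
#'
#' Intactness first: the complete element with the longest span; when no
#' member is complete, the longest fragment; ties broken by the
#' lexicographically smallest element id.
#'
#' @param member_ids element ids in the family.
#' @param elements classified-element data.frame (needs `element_id`,
#'   `start`, `end`, `complete`).
#' @return the representative element id.
#' @export
pick_representative <- function(member_ids, elements) {
  stopifnot(length(member_ids) >= 1)
  x <- elements[match(member_ids, elements$element_id), , drop = FALSE]
  x$len <- x$end - x$start
  pool <- if (any(x$complete)) x[x$complete, , drop = FALSE] else x
  pool <- pool[order(-pool$len, pool$element_id), , drop = FALSE]
  pool$element_id[1]
}

LIB_CATEGORIES <- c("Ty1-copia", "Ty3-gypsy", "LTR-unclassified", "LINE",
                    "SINE", "CACTA", "hAT", "MULE", "Helitron",
                    "PIF/Harbinger", "unclassified")

#' Library category summary (Table-1 layout)
#'
#' Given per-category representative counts, computes the class subtotals
#' and the grand total. Categories: class 1 LTR retrotransposons
#' (`Ty1-copia`, `Ty3-gypsy`, `LTR-unclassified`), class 1 non-LTR (`LINE`,
#' `SINE`), class 2 (`CACTA`, `hAT`, `MULE`, `Helitron`, `PIF/Harbinger`),
#' plus `unclassified`. Totals are always computed from the inputs, never
#' stored independently.
#'
#' @param counts named numeric vector; names from the categories above,
#'   missing categories count 0.
#' @return data.frame with `category`, `count`, and a `level` column
#'   marking subtotal rows (`class`, `group`, `total`).
#' @export
summarize_library <- function(counts) {
  bad <- setdiff(names(counts), LIB_CATEGORIES)
  if (length(bad)) stop("unknown categories: ", paste(bad, collapse = ", "))
  full <- setNames(numeric(length(LIB_CATEGORIES)), LIB_CATEGORIES)
  full[names(counts)] <- counts
  ltr <- sum(full[c("Ty1-copia", "Ty3-gypsy", "LTR-unclassified")])
  nonltr <- sum(full[c("LINE", "SINE")])
  class1 <- ltr + nonltr
  class2 <- sum(full[c("CACTA", "hAT", "MULE", "Helitron", "PIF/Harbinger")])
  total <- class1 + class2 + full[["unclassified"]]
  data.frame(
    category = c("Class 1", "LTR retrotransposons", "Ty1-copia", "Ty3-gypsy",
                 "LTR-unclassified", "Non-LTR retrotransposon", "LINE",
                 "SINE", "Class 2", "CACTA", "hAT", "MULE", "Helitron",
                 "PIF/Harbinger", "Unclassified", "Total"),
    count = c(class1, ltr, full[["Ty1-copia"]], full[["Ty3-gypsy"]],
              full[["LTR-unclassified"]], nonltr, full[["LINE"]],
              full[["SINE"]], class2, full[["CACTA"]], full[["hAT"]],
              full[["MULE"]], full[["Helitron"]], full[["PIF/Harbinger"]],
              full[["unclassified"]], total),
    level = c("class", "group", "item", "item", "item", "group", "item",
              "item", "class", "item", "item", "item", "item", "item",
              "item", "total"),
    stringsAsFactors = FALSE)
}

#' Build the representative library
#'
#' One FASTA record per family (the representative), with
#' RepeatMasker-style headers `family_id#Class/Superfamily`, the total
#' library size in bp, and the Table-1-style category summary.
#'
#' @param clustering result of [cluster_families()].
#' @param elements classified-element data.frame.
#' @param sequences named character vector, `element_id` -> sequence.
#' @return list with `records` (data.frame `family_id`, `superfamily`,
#'   `class`, `length`, `representative_id`, `header`, `seq`), `total_bp`,
#'   and `summary` (see [summarize_library()]).
#' @export
build_library <- function(clustering, elements, sequences) {
  fam <- clustering$families
  if (nrow(fam) == 0 || anyDuplicated(fam$representative_id)) {
    if (nrow(fam) && anyDuplicated(fam$representative_id)) {
      stop("duplicate representative ids")
    }
  }
  class1 <- c("Ty1-copia", "Ty3-gypsy", "LTR-unclassified", "LINE", "SINE")
  records <- do.call(rbind, lapply(seq_len(nrow(fam)), function(k) {
    f <- fam[k, ]
    seq <- sequences[[f$representative_id]]
    cls <- if (f$superfamily %in% class1) "Class1"
    else if (f$superfamily == "unclassified") "Unknown" else "Class2"
    data.frame(family_id = f$family_id, superfamily = f$superfamily,
               class = cls, length = nchar(seq),
               representative_id = f$representative_id,
               header = sprintf("%s#%s/%s", f$family_id, cls,
                                gsub("[^A-Za-z0-9-]", "_", f$superfamily)),
               seq = seq, stringsAsFactors = FALSE)
  }))
  if (is.null(records)) {
    records <- data.frame(family_id = character(0), superfamily = character(0),
                          class = character(0), length = integer(0),
                          representative_id = character(0),
                          header = character(0), seq = character(0),
                          stringsAsFactors = FALSE)
  }
  counts <- table(factor(records$superfamily, levels = LIB_CATEGORIES))
  list(records = records, total_bp = sum(records$length),
       summary = summarize_library(setNames(as.numeric(counts),
                                            names(counts))))
}

#' Chromosomal distribution profile of a family
#'
#' Counts family-member midpoints in non-overlapping windows along each
#' sequence; counts sum to the number of members.
#'
#' @param member_elements data.frame of the family's members (`seq_id`,
#'   `start`, `end`).
#' @param seqlengths named integer vector of sequence lengths.
#' @param window window size, bp.
#' @return data.frame with `seq_id`, `win_start`, `win_end`, `count`.
#' @export
distribution_profile <- function(member_elements, seqlengths, window = 100000) {
  if (window <= 0) stop("window must be positive")
  rows <- lapply(names(seqlengths), function(sid) {
    L <- seqlengths[[sid]]
    starts <- seq(0, L - 1, by = window)
    ends <- pmin(starts + window, L)
    mids <- with(member_elements[member_elements$seq_id == sid, , drop = FALSE],
                 (start + end) / 2)
    counts <- vapply(seq_along(starts), function(w) {
      sum(mids >= starts[w] & mids < ends[w])
    }, integer(1))
    data.frame(seq_id = sid, win_start = starts, win_end = ends,
               count = counts, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
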