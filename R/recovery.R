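## Scoring predictions against the synthetic generator's ground truth:
## element-level precision/recall with a boundary tolerance, TSD exact-match
## rates, LTR-specific boundary recovery, and the Rand index between the
## predicted and planted family partitions.

#' Rand index between two labelings
#'
#' Fraction of element pairs on which two partitions agree (same-cluster or
#' different-cluster in both), computed from the contingency table.
#'
#' @param a,b label vectors of equal length.
#' @return the Rand index in `[0, 1]` (1 for `n < 2`).
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  agree <- ch2(n) + 2 * sum(ch2(tab)) - sum(ch2(rowSums(tab))) -
    sum(ch2(colSums(tab)))
  agree / ch2(n)
}

## greedy one-to-one matching of predictions to truth within tolerance
match_predictions <- function(pred, truth, tol = 3) {
  matched_pred <- rep(NA_integer_, nrow(pred))
  used <- logical(nrow(truth))
  if (nrow(pred)) {
    for (i in seq_len(nrow(pred))) {
      j <- which(!used & truth$seq_id == pred$seq_id[i] &
                   abs(truth$start - pred$start[i]) <= tol &
                   abs(truth$end - pred$end[i]) <= tol)
      if (length(j)) {
        matched_pred[i] <- j[1]
        used[j[1]] <- TRUE
      }
    }
  }
  matched_pred
}

#' Recovery report against the planted truth
#'
#' Element-level precision and recall per superfamily, with predicted
#' elements matched one-to-one to truth records when both boundaries agree
#' within `tol` bp; the TSD exact-match rate among matched elements; and,
#' when a family clustering is supplied, the Rand index between the
#' predicted and planted family partitions of the matched elements.
#'
#' @param pred predicted elements (`seq_id`, `start`, `end`, `superfamily`,
#'   `tsd`, optionally `element_id`).
#' @param truth truth data.frame from [simulate_genome()].
#' @param clustering optional result of [cluster_families()].
#' @param tol boundary tolerance, bp.
#' @return list with `per_superfamily` (data.frame `superfamily`,
#'   `n_truth`, `n_pred`, `matched`, `precision`, `recall`),
#'   `tsd_exact_rate`, and `family_rand_index` (`NA` without clustering).
#' @export
recovery_report <- function(pred, truth, clustering = NULL, tol = 3) {
  m <- match_predictions(pred, truth, tol)
  sfs <- sort(unique(c(pred$superfamily, truth$superfamily)))
  per <- do.call(rbind, lapply(sfs, function(sf) {
    p_idx <- which(pred$superfamily == sf)
    t_idx <- which(truth$superfamily == sf)
    mi <- m[p_idx]
    mi <- mi[!is.na(mi)]
    ok <- sum(truth$superfamily[mi] == sf)
    data.frame(superfamily = sf, n_truth = length(t_idx),
               n_pred = length(p_idx), matched = ok,
               precision = if (length(p_idx)) ok / length(p_idx) else NA_real_,
               recall = if (length(t_idx)) ok / length(t_idx) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  hit <- !is.na(m)
  tsd_rate <- if (any(hit)) {
    mean(pred$tsd[hit] == truth$tsd[m[hit]])
  } else NA_real_
  ri <- NA_real_
  if (!is.null(clustering) && any(hit) && "element_id" %in% names(pred)) {
    ids <- pred$element_id[hit]
    fam_pred <- clustering$members$family_id[
      match(ids, clustering$members$element_id)]
    fam_true <- truth$family[m[hit]]
    keep <- !is.na(fam_pred)
    if (sum(keep) >= 2) ri <- rand_index(fam_pred[keep], fam_true[keep])
  }
  list(per_superfamily = per, tsd_exact_rate = tsd_rate,
       family_rand_index = ri)
}

#' LTR recovery statistics
#'
#' Matches accepted LTR candidates to the planted LTR truth records and
#' scores boundary exactness (all four LTR boundaries within `tol` bp) and
#' exact TSD string recovery.
#'
#' @param accepted accepted candidates from [inspect_candidates()].
#' @param truth truth data.frame (only LTR superfamilies are considered).
#' @param tol boundary tolerance, bp.
#' @return list with `n_truth`, `n_recovered` (boundary-exact within
#'   tolerance), `n_tsd_exact`, `recall`, `tsd_exact_rate`,
#'   `false_positives` (accepted candidates matching no planted element).
#' @export
ltr_recovery_stats <- function(accepted, truth, tol = 3) {
  lt <- truth[truth$superfamily %in% c("Ty1-copia", "Ty3-gypsy"), ,
              drop = FALSE]
  n_rec <- 0L; n_tsd <- 0L
  matched_cand <- rep(FALSE, nrow(accepted))
  for (j in seq_len(nrow(lt))) {
    t <- lt[j, ]
    hit <- which(accepted$seq_id == t$seq_id &
                   abs(accepted$start - t$start) <= tol &
                   abs(accepted$end - t$end) <= tol &
                   abs(accepted$ltr1_end - t$ltr1_end) <= tol &
                   abs(accepted$ltr2_start - t$ltr2_start) <= tol)
    if (length(hit)) {
      n_rec <- n_rec + 1L
      matched_cand[hit] <- TRUE
      if (any(accepted$tsd[hit] == t$tsd)) n_tsd <- n_tsd + 1L
    }
  }
  list(n_truth = nrow(lt), n_recovered = n_rec, n_tsd_exact = n_tsd,
       recall = if (nrow(lt)) n_rec / nrow(lt) else NA_real_,
       tsd_exact_rate = if (nrow(lt)) n_tsd / nrow(lt) else NA_real_,
       false_positives = sum(!matched_cand))
}
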