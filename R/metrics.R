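# External clustering evaluation: accuracy under optimal one-to-one label
# matching, normalized mutual information, adjusted Rand index.

#' Contingency table between two labelings
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @return List: `counts` (k_true x k_pred), `row_sums`, `col_sums`, `n`.
#' @export
contingency_table <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels)) {
    stop(sprintf("label vectors differ in length: %d vs %d",
                 length(true_labels), length(pred_labels)), call. = FALSE)
  }
  counts <- unclass(table(true = true_labels, pred = pred_labels))
  list(counts = counts, row_sums = rowSums(counts),
       col_sums = colSums(counts), n = length(true_labels))
}

# Min-cost assignment on a square cost matrix via shortest augmenting paths
# with potentials (O(n^3) Hungarian). Returns the column assigned to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  # index shift: positions 1..(n+1) represent 0..n (0 = virtual row/column)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)     # p[j+1] = row matched to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}

#' Clustering accuracy with optimal label matching
#'
#' The fraction of cells whose predicted label, after the best one-to-one
#' mapping of predicted cluster names onto true cluster names (optimal
#' assignment on the contingency table, padded square when cluster counts
#' differ), equals the true label.
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @return Accuracy in `[0, 1]`.
#' @export
clustering_accuracy <- function(true_labels, pred_labels) {
  ct <- contingency_table(true_labels, pred_labels)
  counts <- ct$counts
  k <- max(dim(counts))
  padded <- matrix(0, k, k)
  padded[seq_len(nrow(counts)), seq_len(ncol(counts))] <- counts
  assignment <- solve_assignment(max(padded) - padded)
  matched <- sum(padded[cbind(seq_len(k), assignment)])
  matched / ct$n
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Normalized mutual information
#'
#' `2 MI(U, V) / (H(U) + H(V))` with natural-log entropies (the ratio is
#' base-invariant). When both labelings are constant the partitions are
#' identical by construction and the value is defined as 1.
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @return NMI in `[0, 1]`.
#' @export
nmi <- function(true_labels, pred_labels) {
  ct <- contingency_table(true_labels, pred_labels)
  pu <- ct$row_sums / ct$n
  pv <- ct$col_sums / ct$n
  hu <- entropy_nat(pu); hv <- entropy_nat(pv)
  if (hu == 0 && hv == 0) return(1)
  pij <- ct$counts / ct$n
  mi <- 0
  for (i in seq_len(nrow(pij))) {
    for (j in seq_len(ncol(pij))) {
      if (pij[i, j] > 0) {
        mi <- mi + pij[i, j] * log(pij[i, j] / (pu[i] * pv[j]))
      }
    }
  }
  unname(2 * mi / (hu + hv))
}

#' Adjusted Rand index
#'
#' The Rand index corrected for chance, evaluated exactly with binomial
#' coefficients over the contingency table:
#' `[sum_ij C(n_ij,2) - E] / [ (sum_i C(a_i,2) + sum_j C(b_j,2))/2 - E ]`
#' with `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`.
#'
#' @param true_labels,pred_labels equal-length label vectors (n >= 2).
#' @return ARI in `[-1, 1]`.
#' @export
ari <- function(true_labels, pred_labels) {
  ct <- contingency_table(true_labels, pred_labels)
  if (ct$n < 2) stop("ARI needs at least 2 observations", call. = FALSE)
  sum_ij <- sum(choose(ct$counts, 2))
  sum_a <- sum(choose(ct$row_sums, 2))
  sum_b <- sum(choose(ct$col_sums, 2))
  expected <- sum_a * sum_b / choose(ct$n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (abs(maxi - expected) < .Machine$double.eps * maxi ||
      maxi == expected) {
    # degenerate: both partitions trivial; identical partitions score 1
    return(if (sum_ij == maxi) 1 else 0)
  }
  (sum_ij - expected) / (maxi - expected)
}

#' Evaluate a clustering against ground truth
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @return List with `acc`, `nmi`, `ari`.
#' @export
evaluate_clustering <- function(true_labels, pred_labels) {
  list(acc = clustering_accuracy(true_labels, pred_labels),
       nmi = nmi(true_labels, pred_labels),
       ari = ari(true_labels, pred_labels))
}
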