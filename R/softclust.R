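# Fuzzy membership machinery: Student-t soft assignments q, closed-form fuzzy
# c-means memberships gamma, and cluster-center handling.

pairwise_sqdist <- function(a, b) {
  d2 <- outer(rowSums(a * a), rowSums(b * b), "+") - 2 * (a %*% t(b))
  pmax(d2, 0)
}

# graph version used during joint training: q from h (node) and centers (node)
student_t_graph <- function(tape, h_id, centers_id) {
  d2 <- ag_pairwise_sqdist(tape, h_id, centers_id)
  w <- ag_recip(tape, ag_affine(tape, d2, add = 1))
  ag_sumnorm_rows(tape, w)
}

#' Student-t soft assignments
#'
#' `q_ij = (1 + ||h_i - mu_j||^2)^{-1}`, row-normalized — the kernel of a
#' Student t distribution with one degree of freedom, the standard choice in
#' the deep-embedded-clustering family.
#'
#' @param h n x d embedding matrix.
#' @param centers k x d cluster centers.
#' @return n x k row-stochastic assignment matrix.
#' @export
student_t_assignment <- function(h, centers) {
  h <- as.matrix(h); centers <- as.matrix(centers)
  stopifnot(ncol(h) == ncol(centers))
  tape <- ag_tape()
  q <- student_t_graph(tape, ag_const(tape, h), ag_const(tape, centers))
  ag_value(tape, q)
}

#' Closed-form fuzzy c-means memberships
#'
#' The minimizer of `sum_j gamma_ij^m ||z_i - mu_j||^2` subject to
#' `sum_j gamma_ij = 1`:
#' `gamma_ij = [ sum_l (||z_i - mu_j|| / ||z_i - mu_l||)^{2/(m-1)} ]^{-1}`.
#' A point coinciding with one or more centers gets its whole membership
#' split uniformly over the coinciding centers.
#'
#' @param z n x d point matrix.
#' @param centers k x d cluster centers.
#' @param fuzzifier m > 1; larger m gives softer memberships.
#' @return n x k row-stochastic membership matrix.
#' @export
fuzzy_memberships <- function(z, centers, fuzzifier = 1.5) {
  if (fuzzifier <= 1) stop("fuzzifier m must be > 1", call. = FALSE)
  z <- as.matrix(z); centers <- as.matrix(centers)
  stopifnot(ncol(z) == ncol(centers))
  d2 <- pairwise_sqdist(z, centers)
  k <- ncol(d2)
  gamma <- matrix(0, nrow(d2), k)
  expo <- 1 / (fuzzifier - 1)
  for (i in seq_len(nrow(d2))) {
    di <- d2[i, ]
    zero <- di < 1e-24
    if (any(zero)) {
      gamma[i, zero] <- 1 / sum(zero)
    } else {
      # gamma_ij = (1/d_ij)^{1/(m-1)} / sum_l (1/d_il)^{1/(m-1)}, computed on
      # the log scale for stability
      lw <- -expo * log(di)
      w <- exp(lw - max(lw))
      gamma[i, ] <- w / sum(w)
    }
  }
  gamma
}

#' Fuzzy c-means objective value
#'
#' `sum_i sum_j gamma_ij^m ||z_i - mu_j||^2` — the quantity the closed-form
#' memberships minimize row-wise.
#'
#' @inheritParams fuzzy_memberships
#' @param gamma n x k membership matrix.
#' @return Scalar objective.
#' @export
fcm_objective <- function(z, centers, gamma, fuzzifier = 1.5) {
  d2 <- pairwise_sqdist(as.matrix(z), as.matrix(centers))
  sum(gamma^fuzzifier * d2)
}

#' Fuzzy c-means center update
#'
#' `mu_j = sum_i gamma_ij^m z_i / sum_i gamma_ij^m` — the stationarity
#' condition of the fuzzy objective in the centers. Used for
#' initialization-time FCM iterations and the `center_update = "fcm"` option;
#' during default joint training the centers are free gradient parameters.
#' A cluster whose effective mass falls below 1e-12 is re-seeded to the point
#' with the lowest maximum membership (logged via message).
#'
#' @param z n x d point matrix.
#' @param gamma n x k row-stochastic membership matrix.
#' @param fuzzifier m > 1.
#' @return k x d center matrix.
#' @export
update_centers <- function(z, gamma, fuzzifier = 1.5) {
  z <- as.matrix(z); gamma <- as.matrix(gamma)
  check_row_stochastic(gamma, "gamma")
  gm <- gamma^fuzzifier
  mass <- colSums(gm)
  centers <- matrix(0, ncol(gamma), ncol(z))
  for (j in seq_len(ncol(gamma))) {
    if (mass[j] < 1e-12) {
      i0 <- which.min(apply(gamma, 1L, max))
      message(sprintf("cluster %d empty; re-seeded to point %d", j, i0))
      centers[j, ] <- z[i0, ]
    } else {
      centers[j, ] <- colSums(gm[, j] * z) / mass[j]
    }
  }
  centers
}

#' Initialize cluster centers by k-means
#'
#' Runs seeded k-means with multiple restarts on the (pretrained) consensus
#' representation and returns the centroids.
#'
#' @param h n x d embedding matrix.
#' @param k number of clusters (must not exceed n).
#' @param seed RNG seed.
#' @param nstart k-means restarts (default 10).
#' @return k x d center matrix.
#' @export
initialize_centers <- function(h, k, seed = 0, nstart = 10) {
  h <- as.matrix(h)
  if (nrow(h) < k) {
    stop(sprintf("need at least k = %d points, got %d", k, nrow(h)),
         call. = FALSE)
  }
  set.seed(seed)
  if (k == 1L) return(matrix(colMeans(h), 1L, ncol(h)))
  km <- stats::kmeans(h, centers = k, nstart = nstart, iter.max = 100)
  km$centers
}

#' Write soft memberships and hard labels to disk
#'
#' @param gamma n x k membership matrix.
#' @param dir output directory.
#' @param cell_ids optional cell identifiers.
#' @return `dir`, invisibly.
#' @export
write_memberships <- function(gamma, dir, cell_ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gamma <- round(as.matrix(gamma), 6)
  df <- as.data.frame(gamma)
  colnames(df) <- sprintf("cluster_%d", seq_len(ncol(gamma)) - 1L)
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%d", seq_len(nrow(gamma)))
  utils::write.csv(cbind(cell_id = cell_ids, df),
                   file.path(dir, "memberships.csv"), row.names = FALSE)
  writeLines(as.character(max.col(gamma, ties.method = "first") - 1L),
             file.path(dir, "soft_labels.txt"))
  invisible(dir)
}
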