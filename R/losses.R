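# Training objectives: reconstruction, structure-guided contrastive, and the
# soft-clustering divergence, plus their weighted total.
#
# Each loss has a graph builder (used by the trainer, differentiable through
# the tape) and an exported numeric wrapper that validates its inputs and
# evaluates the same graph, so tests exercise one code path.

.sg_state <- new.env(parent = emptyenv())

sg_warn_once <- function(key, msg) {
  if (is.null(.sg_state[[key]])) {
    .sg_state[[key]] <- TRUE
    warning(msg, call. = FALSE)
  }
}

#' Reset per-run warning latches (called by the CLI at run start)
#' @return invisible NULL
#' @export
reset_run_state <- function() {
  rm(list = ls(.sg_state), envir = .sg_state)
  invisible(NULL)
}

#' Loss weights
#'
#' @param alpha weight of the contrastive loss (default 1).
#' @param beta weight of the soft-clustering loss (default 1).
#' @param temperature contrastive temperature T > 0 (default 0.5).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(alpha = 1, beta = 1, temperature = 0.5) {
  stopifnot(alpha >= 0, beta >= 0, temperature > 0)
  structure(list(alpha = alpha, beta = beta, temperature = temperature),
            class = "loss_weights")
}

# ---- reconstruction -------------------------------------------------------

loss_reconstruction_graph <- function(tape, x1, x2, x1_hat, x2_hat) {
  l1 <- ag_sum(tape, ag_square(tape, ag_sub(tape, x1, x1_hat)))
  l2 <- ag_sum(tape, ag_square(tape, ag_sub(tape, x2, x2_hat)))
  ag_add(tape, l1, l2)
}

#' Reconstruction loss
#'
#' Sum over cells of squared Euclidean distances between inputs and
#' reconstructions, summed over both modalities. Zero iff the reconstructions
#' equal the targets.
#'
#' @param x1,x2 input matrices.
#' @param x1_hat,x2_hat reconstructions with matching shapes.
#' @return Non-negative scalar.
#' @export
reconstruction_loss <- function(x1, x2, x1_hat, x2_hat) {
  x1 <- as.matrix(x1); x2 <- as.matrix(x2)
  x1_hat <- as.matrix(x1_hat); x2_hat <- as.matrix(x2_hat)
  if (!all(dim(x1) == dim(x1_hat))) {
    stop(sprintf("modality 1: input is %d x %d, reconstruction %d x %d",
                 nrow(x1), ncol(x1), nrow(x1_hat), ncol(x1_hat)), call. = FALSE)
  }
  if (!all(dim(x2) == dim(x2_hat))) {
    stop(sprintf("modality 2: input is %d x %d, reconstruction %d x %d",
                 nrow(x2), ncol(x2), nrow(x2_hat), ncol(x2_hat)), call. = FALSE)
  }
  tape <- ag_tape()
  id <- loss_reconstruction_graph(tape, ag_const(tape, x1), ag_const(tape, x2),
                                  ag_const(tape, x1_hat), ag_const(tape, x2_hat))
  ag_value(tape, id)[1L, 1L]
}

# ---- cosine similarity ----------------------------------------------------

#' Cosine similarity between two vectors
#'
#' Norms are floored at 1e-12 (a zero vector triggers a once-per-run warning),
#' so the value is always defined and lies in `[-1, 1]`.
#'
#' @param u,v numeric vectors of equal length.
#' @return Scalar cosine similarity.
#' @export
cosine_similarity <- function(u, v) {
  u <- as.numeric(u); v <- as.numeric(v)
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu < 1e-12 || nv < 1e-12) {
    sg_warn_once("zero_norm", "zero-norm vector in cosine similarity; norm floored at 1e-12")
  }
  sum(u * v) / (max(nu, 1e-12) * max(nv, 1e-12))
}

# ---- structure-guided contrastive -----------------------------------------

# One modality's contribution: sum_i [ log den_i - D_ii / T ], where
# den_i = sum_j exp((1 - S_ij) D_ij / T) - exp(1/T)        (as_printed)
# den_i = sum_{j != i} exp((1 - S_ij) D_ij / T)            (drop_self)
contrastive_modality_graph <- function(tape, h_hat_n, hm, s_id, temperature,
                                       denominator) {
  v <- ag_l2norm_rows(tape, hm)
  C <- ag_matmul(tape, h_hat_n, v, tb = TRUE)
  one_minus_s <- ag_affine(tape, s_id, mult = -1, add = 1)
  E <- ag_exp(tape, ag_affine(tape, ag_emul(tape, one_minus_s, C),
                              mult = 1 / temperature))
  rs <- ag_rowsums(tape, E)
  den <- if (denominator == "as_printed") {
    ag_affine(tape, rs, add = -exp(1 / temperature))
  } else {
    ag_sub(tape, rs, ag_diagpart(tape, E))
  }
  den <- ag_clamp_min(tape, den, 1e-8)
  pos <- ag_affine(tape, ag_diagpart(tape, C), mult = 1 / temperature)
  ag_sum(tape, ag_sub(tape, ag_log(tape, den), pos))
}

loss_contrastive_graph <- function(tape, h_hat, h1, h2, s_id, temperature,
                                   denominator = "as_printed") {
  n <- nrow(ag_value(tape, h_hat))
  u <- ag_l2norm_rows(tape, h_hat)
  t1 <- contrastive_modality_graph(tape, u, h1, s_id, temperature, denominator)
  t2 <- contrastive_modality_graph(tape, u, h2, s_id, temperature, denominator)
  ag_affine(tape, ag_add(tape, t1, t2), mult = 1 / (2 * n))
}

check_row_stochastic <- function(m, what, tol = 1e-6) {
  if (any(m < -tol) || any(abs(rowSums(m) - 1) > tol)) {
    stop(sprintf("%s must be row-stochastic (non-negative rows summing to 1)",
                 what), call. = FALSE)
  }
}

#' Structure-guided contrastive loss
#'
#' For each cell i and each modality m, the consensus row H-hat_i and the
#' modality row H^m_i form the positive pair; every other cell j is a
#' negative whose similarity is down-weighted by `(1 - S_ij)`, so cells that
#' the structural matrix already deems close are softer negatives:
#' `-(1/2n) sum_i sum_m log[ exp(D(H-hat_i, H^m_i)/T) / den_i ]` with
#' `den_i = sum_j exp((1 - S_ij) D(H-hat_i, H^m_j)/T) - exp(1/T)`.
#'
#' The subtracted `exp(1/T)` can make the denominator non-positive (already
#' for n = 1 with perfectly aligned pairs), so it is clamped below at 1e-8
#' and the clamp count is reported via `attr(, "clamp_count")`. The
#' `"drop_self"` variant instead removes the j = i term from the sum.
#'
#' @param h_hat n x d consensus representation.
#' @param h1,h2 n x d modality representations.
#' @param s n x n row-stochastic structural matrix.
#' @param temperature temperature T > 0.
#' @param denominator `"as_printed"` (default) or `"drop_self"`.
#' @return Scalar loss with attribute `clamp_count`.
#' @export
contrastive_loss <- function(h_hat, h1, h2, s, temperature = 0.5,
                             denominator = c("as_printed", "drop_self")) {
  denominator <- match.arg(denominator)
  h_hat <- as.matrix(h_hat); h1 <- as.matrix(h1); h2 <- as.matrix(h2)
  s <- as.matrix(s)
  stopifnot(temperature > 0,
            nrow(h_hat) == nrow(h1), nrow(h_hat) == nrow(h2),
            ncol(h_hat) == ncol(h1), ncol(h_hat) == ncol(h2),
            nrow(s) == nrow(h_hat), ncol(s) == nrow(h_hat))
  check_row_stochastic(s, "structural matrix S")
  tape <- ag_tape()
  id <- loss_contrastive_graph(tape, ag_const(tape, h_hat),
                               ag_const(tape, h1), ag_const(tape, h2),
                               ag_const(tape, s), temperature, denominator)
  structure(ag_value(tape, id)[1L, 1L], clamp_count = tape$clamp_count)
}

# ---- soft-clustering divergence -------------------------------------------

# gamma is a constant target (no gradient); q_id is a tape node.
loss_soft_graph <- function(tape, gamma, q_id) {
  const_term <- sum(ifelse(gamma > 0, gamma * log(gamma), 0))
  qc <- ag_clamp_min(tape, q_id, 1e-12)
  cross <- ag_sum(tape, ag_emul(tape, ag_const(tape, gamma),
                                ag_log(tape, qc)))
  ag_affine(tape, cross, mult = -1, add = const_term)
}

#' Soft-clustering divergence
#'
#' Row-wise Kullback-Leibler divergence `sum_i KL(gamma_i || q_i)` between
#' the fuzzy memberships gamma (the target, treated as a constant — no
#' gradient flows through it during training) and the Student-t assignments
#' q. Non-negative; zero iff gamma equals q row-wise.
#'
#' @param gamma n x k row-stochastic fuzzy membership matrix.
#' @param q n x k row-stochastic soft assignment matrix (entries floored at
#'   1e-12).
#' @return Non-negative scalar.
#' @export
soft_clustering_loss <- function(gamma, q) {
  gamma <- as.matrix(gamma); q <- as.matrix(q)
  stopifnot(all(dim(gamma) == dim(q)))
  check_row_stochastic(gamma, "gamma")
  check_row_stochastic(q, "q")
  tape <- ag_tape()
  id <- loss_soft_graph(tape, gamma, ag_const(tape, q))
  max(ag_value(tape, id)[1L, 1L], 0)
}

#' Weighted total loss
#'
#' `L = L_r + alpha * L_c + beta * L_s`; with `alpha = beta = 0` this is the
#' pure reconstruction objective (the autoencoder ablation).
#'
#' @param lr,lc,ls the three loss components.
#' @param weights a [loss_weights()].
#' @return Scalar total.
#' @export
total_loss <- function(lr, lc, ls, weights) {
  stopifnot(inherits(weights, "loss_weights"),
            is.finite(lr), is.finite(lc), is.finite(ls))
  as.numeric(lr) + weights$alpha * as.numeric(lc) + weights$beta * as.numeric(ls)
}
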