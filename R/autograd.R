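# Minimal reverse-mode automatic differentiation over dense matrices.
#
# The network is trained full-batch, so the computation graph per epoch is a
# few dozen dense-matrix nodes; a simple tape (nodes stored in creation order,
# which is a valid topological order) is all that is needed. Every value is a
# base-R numeric matrix; a scalar is a 1x1 matrix.

#' Create a fresh autodiff tape
#'
#' A tape records the forward computation graph so that [ag_backward()] can
#' accumulate gradients in reverse creation order. Tapes also count how often
#' the contrastive-loss denominator clamp fires (see [contrastive_loss()]).
#'
#' @return An environment holding the node list and a clamp counter.
#' @keywords internal
ag_tape <- function() {
  tape <- new.env(parent = emptyenv())
  tape$nodes <- vector("list", 256L)
  tape$n <- 0L
  tape$clamp_count <- 0L
  tape
}

ag_push <- function(tape, value, parents = integer(0), backward = NULL) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- list(value = value, parents = parents, backward = backward)
  tape$n <- n
  n
}

#' @keywords internal
ag_value <- function(tape, id) {
  # force id before touching tape$nodes: evaluating a lazily passed op call
  # pushes its node onto the tape, and the list must be read after that
  force(id)
  tape$nodes[[id]]$value
}

#' Wrap a constant (or parameter) matrix as a tape node
#' @keywords internal
ag_const <- function(tape, x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  ag_push(tape, x)
}

# ---- elementary ops -------------------------------------------------------

#' Matrix product with optional transposes, recorded on the tape
#' @keywords internal
ag_matmul <- function(tape, a, b, ta = FALSE, tb = FALSE) {
  A <- ag_value(tape, a); B <- ag_value(tape, b)
  Ae <- if (ta) t(A) else A
  Be <- if (tb) t(B) else B
  val <- Ae %*% Be
  bw <- function(g) {
    gA <- g %*% t(Be)
    gB <- t(Ae) %*% g
    list(if (ta) t(gA) else gA, if (tb) t(gB) else gB)
  }
  ag_push(tape, val, c(a, b), bw)
}

#' @keywords internal
ag_add <- function(tape, a, b) {
  val <- ag_value(tape, a) + ag_value(tape, b)
  ag_push(tape, val, c(a, b), function(g) list(g, g))
}

#' @keywords internal
ag_sub <- function(tape, a, b) {
  val <- ag_value(tape, a) - ag_value(tape, b)
  ag_push(tape, val, c(a, b), function(g) list(g, -g))
}

#' Add a 1 x d bias row to every row of an n x d matrix
#' @keywords internal
ag_addbias <- function(tape, a, bias) {
  A <- ag_value(tape, a); bv <- ag_value(tape, bias)
  val <- sweep(A, 2L, as.vector(bv), "+")
  bw <- function(g) list(g, matrix(colSums(g), 1L))
  ag_push(tape, val, c(a, bias), bw)
}

#' Elementwise product of two same-shape nodes
#' @keywords internal
ag_emul <- function(tape, a, b) {
  A <- ag_value(tape, a); B <- ag_value(tape, b)
  ag_push(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

#' y = mult * x + add, with scalar constants
#' @keywords internal
ag_affine <- function(tape, a, mult = 1, add = 0) {
  val <- mult * ag_value(tape, a) + add
  ag_push(tape, val, a, function(g) list(mult * g))
}

#' @keywords internal
ag_elu <- function(tape, a) {
  X <- ag_value(tape, a)
  val <- ifelse(X > 0, X, expm1(X))
  bw <- function(g) list(g * ifelse(X > 0, 1, exp(X)))
  ag_push(tape, val, a, bw)
}

#' @keywords internal
ag_exp <- function(tape, a) {
  val <- exp(ag_value(tape, a))
  ag_push(tape, val, a, function(g) list(g * val))
}

#' @keywords internal
ag_log <- function(tape, a) {
  X <- ag_value(tape, a)
  ag_push(tape, log(X), a, function(g) list(g / X))
}

#' @keywords internal
ag_square <- function(tape, a) {
  X <- ag_value(tape, a)
  ag_push(tape, X * X, a, function(g) list(2 * g * X))
}

#' @keywords internal
ag_recip <- function(tape, a) {
  X <- ag_value(tape, a)
  val <- 1 / X
  ag_push(tape, val, a, function(g) list(-g * val * val))
}

#' Clamp from below; clamped entries get zero gradient and are counted
#' @keywords internal
ag_clamp_min <- function(tape, a, lo) {
  X <- ag_value(tape, a)
  mask <- X > lo
  tape$clamp_count <- tape$clamp_count + sum(!mask)
  ag_push(tape, pmax(X, lo), a, function(g) list(g * mask))
}

#' Sum of all entries as a 1 x 1 node
#' @keywords internal
ag_sum <- function(tape, a) {
  X <- ag_value(tape, a)
  bw <- function(g) list(matrix(g[1L, 1L], nrow(X), ncol(X)))
  ag_push(tape, matrix(sum(X), 1L, 1L), a, bw)
}

#' Row sums as an n x 1 node
#' @keywords internal
ag_rowsums <- function(tape, a) {
  X <- ag_value(tape, a)
  bw <- function(g) list(matrix(as.vector(g), nrow(X), ncol(X)))
  ag_push(tape, matrix(rowSums(X), ncol = 1L), a, bw)
}

#' Diagonal of a square matrix as an n x 1 node
#' @keywords internal
ag_diagpart <- function(tape, a) {
  X <- ag_value(tape, a)
  n <- nrow(X)
  bw <- function(g) {
    G <- matrix(0, n, n)
    diag(G) <- as.vector(g)
    list(G)
  }
  ag_push(tape, matrix(diag(X), ncol = 1L), a, bw)
}

#' Row-wise softmax
#' @keywords internal
ag_softmax_rows <- function(tape, a) {
  X <- ag_value(tape, a)
  E <- exp(X - apply(X, 1L, max))
  Y <- E / rowSums(E)
  bw <- function(g) list(Y * (g - rowSums(g * Y)))
  ag_push(tape, Y, a, bw)
}

#' Row-wise L2 normalization (norms floored at 1e-12)
#' @keywords internal
ag_l2norm_rows <- function(tape, a) {
  X <- ag_value(tape, a)
  nrm <- pmax(sqrt(rowSums(X * X)), 1e-12)
  Y <- X / nrm
  bw <- function(g) list((g - Y * rowSums(g * Y)) / nrm)
  ag_push(tape, Y, a, bw)
}

#' Row-wise normalization to unit sum
#' @keywords internal
ag_sumnorm_rows <- function(tape, a) {
  X <- ag_value(tape, a)
  s <- rowSums(X)
  Y <- X / s
  bw <- function(g) list((g - rowSums(g * Y)) / s)
  ag_push(tape, Y, a, bw)
}

#' Column-bind two nodes
#' @keywords internal
ag_concat_cols <- function(tape, a, b) {
  A <- ag_value(tape, a); B <- ag_value(tape, b)
  ka <- ncol(A)
  bw <- function(g) list(g[, seq_len(ka), drop = FALSE],
                         g[, -seq_len(ka), drop = FALSE])
  ag_push(tape, cbind(A, B), c(a, b), bw)
}

#' Pairwise squared Euclidean distances between rows of a (n x d) and b (k x d)
#' @keywords internal
ag_pairwise_sqdist <- function(tape, a, b) {
  A <- ag_value(tape, a); B <- ag_value(tape, b)
  ra <- rowSums(A * A); rb <- rowSums(B * B)
  val <- outer(ra, rb, "+") - 2 * (A %*% t(B))
  val[val < 0] <- 0  # numerical floor
  bw <- function(g) {
    gA <- 2 * (A * rowSums(g) - g %*% B)
    gB <- 2 * (B * colSums(g) - t(g) %*% A)
    list(gA, gB)
  }
  ag_push(tape, val, c(a, b), bw)
}

# ---- backward pass --------------------------------------------------------

#' Run the backward pass from a scalar node
#'
#' @param tape the tape.
#' @param loss_id id of a 1 x 1 node.
#' @return A list of gradients indexed by node id (`NULL` where a node does
#'   not influence the loss).
#' @keywords internal
ag_backward <- function(tape, loss_id) {
  grads <- vector("list", tape$n)
  grads[[loss_id]] <- matrix(1, 1L, 1L)
  for (id in seq.int(loss_id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (is.null(node$backward)) next
    pg <- node$backward(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[[k]]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
  }
  grads
}
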