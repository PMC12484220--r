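# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, pair counting, scalar
# loops, and a generic constrained optimizer.

# all permutations of 1..k (k <= 7)
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

# clustering accuracy by exhaustive search over injective label mappings
acc_bruteforce <- function(true_labels, pred_labels) {
  ct <- table(true_labels, pred_labels)
  k <- max(dim(ct))
  padded <- matrix(0, k, k)
  padded[seq_len(nrow(ct)), seq_len(ncol(ct))] <- ct
  best <- 0
  for (p in all_permutations(k)) {
    best <- max(best, sum(padded[cbind(seq_len(k), p)]))
  }
  best / length(true_labels)
}

# adjusted Rand index by explicit pair counting over all n(n-1)/2 pairs
ari_paircount <- function(true_labels, pred_labels) {
  n <- length(true_labels)
  st <- outer(true_labels, true_labels, "==")
  sp <- outer(pred_labels, pred_labels, "==")
  up <- upper.tri(st)
  a <- sum(st[up] & sp[up])    # together in both
  b <- sum(st[up] & !sp[up])   # together in truth only
  c_ <- sum(!st[up] & sp[up])  # together in prediction only
  d <- sum(!st[up] & !sp[up])  # apart in both
  expected <- (a + b) * (a + c_) / (a + b + c_ + d)
  maxi <- ((a + b) + (a + c_)) / 2
  if (maxi == expected) return(if (b + c_ == 0) 1 else 0)
  (a - expected) / (maxi - expected)
}

# numerical simplex-constrained minimizer of sum_j g_j^m d2_j (one row of the
# fuzzy objective), via softmax parameterization with two starts and a
# Nelder-Mead polish
fcm_row_oracle <- function(d2row, m) {
  k <- length(d2row)
  obj <- function(u) {
    g <- exp(u - max(u)); g <- g / sum(g)
    sum(g^m * d2row)
  }
  best <- NULL
  for (start in list(rep(0, k), -log(d2row + 1e-12) / (m - 1))) {
    o <- stats::optim(start, obj, method = "BFGS",
                      control = list(reltol = 1e-16, maxit = 5000))
    o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-16, maxit = 20000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  g <- exp(best$par - max(best$par))
  g / sum(g)
}

rand_labels <- function(n, k) sample.int(k, n, replace = TRUE) - 1L

# random row-stochastic matrix
rand_stochastic <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}

# autodiff gradient of a loss with respect to one named input matrix;
# `build` receives (tape, ids) and returns the loss node id
ag_input_gradient <- function(build, inputs, wrt) {
  tape <- sgsdc:::ag_tape()
  ids <- lapply(inputs, function(x) sgsdc:::ag_const(tape, x))
  loss <- build(tape, ids)
  grads <- sgsdc:::ag_backward(tape, loss)
  grads[[ids[[wrt]]]]
}

# central finite-difference gradient of f at inputs[[wrt]], entrywise
fd_input_gradient <- function(f, inputs, wrt, eps = 1e-6) {
  x <- inputs[[wrt]]
  g <- x * 0
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      up <- inputs; up[[wrt]][i, j] <- x[i, j] + eps
      dn <- inputs; dn[[wrt]][i, j] <- x[i, j] - eps
      g[i, j] <- (f(up) - f(dn)) / (2 * eps)
    }
  }
  g
}

max_rel_err <- function(a, b) {
  max(abs(a - b) / pmax(abs(a), abs(b), 1e-6))
}

# small preprocessed synthetic dataset for trainer tests
tiny_dataset <- function(n = 150, k = 3, d_rna = 60, d_atac = 20, seed = 1,
                         separation = 8, frac_transitional = 0) {
  gen <- generate_dataset(synthetic_spec(
    n_cells = n, n_clusters = k, d_rna = d_rna, d_atac = d_atac,
    separation = separation, noise_sd = 0.5,
    frac_transitional = frac_transitional, seed = seed))
  gen$dataset <- preprocess(gen$dataset)
  gen
}

fast_config <- function(...) {
  args <- list(pretrain_epochs = 10, train_epochs = 8, hidden = 32,
               bottleneck = 8, fused_dim = 16, seed = 0)
  override <- list(...)
  args[names(override)] <- override
  do.call(training_config, args)
}
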