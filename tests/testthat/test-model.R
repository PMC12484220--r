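make_ds <- function(n, d1, d2, seed = 1) {
  set.seed(seed)
  multimodal_dataset(matrix(abs(rnorm(n * d1)), n, d1),
                     matrix(abs(rnorm(n * d2)), n, d2))
}

test_that("encode obeys the shape contract and rejects mismatched inputs", {
  ds <- make_ds(10, 30, 20)
  net <- sg_network(network_shapes(30, 20, hidden = 16, bottleneck = 64,
                                   fused_dim = 32))
  z <- encode(net, ds)
  expect_identical(dim(z$z1), c(10L, 64L))
  expect_identical(dim(z$z2), c(10L, 64L))
  expect_true(all(is.finite(z$z1)) && all(is.finite(z$z2)))
  bad <- make_ds(10, 29, 20)
  expect_error(encode(net, bad), "29 columns.*expects 30")
})

test_that("constant input maps to identical rows (bias image)", {
  ds <- multimodal_dataset(matrix(0, 10, 8), matrix(0, 10, 6))
  net <- sg_network(network_shapes(8, 6, hidden = 5, bottleneck = 3,
                                   fused_dim = 4), seed = 2)
  z <- encode(net, ds)
  expect_equal(z$z1, matrix(z$z1[1, ], 10, 3, byrow = TRUE))
  expect_equal(z$z2, matrix(z$z2[1, ], 10, 3, byrow = TRUE))
})

test_that("inference is deterministic across repeated calls", {
  ds <- make_ds(7, 12, 9, seed = 3)
  net <- sg_network(network_shapes(12, 9, hidden = 6, bottleneck = 4,
                                   fused_dim = 5), seed = 5)
  f1 <- sg_forward(net, ds)
  f2 <- sg_forward(net, ds)
  for (nm in names(f1)) expect_identical(f1[[nm]], f2[[nm]])
  d1 <- decode(net, f1$z1, f1$z2)
  d2 <- decode(net, f1$z1, f1$z2)
  expect_identical(d1, d2)
})

test_that("structural matrix is row-stochastic; n = 1 gives [[1]]", {
  net <- sg_network(network_shapes(5, 5, hidden = 4, bottleneck = 3,
                                   fused_dim = 4), seed = 1)
  s1 <- structural_matrix(net, matrix(rnorm(6), 1, 6))
  expect_equal(s1, matrix(1, 1, 1))
  set.seed(9)
  s <- structural_matrix(net, matrix(rnorm(8 * 6), 8, 6))
  expect_equal(rowSums(s), rep(1, 8), tolerance = 1e-6)
  expect_true(all(s > 0))
})

test_that("structural matrix matches the closed-form 2 x 2 softmax", {
  # identity query/key maps on two orthogonal unit rows: the Gram matrix is
  # I2, so logits are I2/sqrt(d) and each row is softmax([1/sqrt(d), 0])
  bn <- 2L
  net <- sg_network(network_shapes(4, 4, hidden = 3, bottleneck = bn,
                                   fused_dim = 4, attn_dim = 2 * bn), seed = 1)
  net$params$attn_Wq <- diag(2 * bn)
  net$params$attn_Wk <- diag(2 * bn)
  z <- rbind(c(1, 0, 0, 0), c(0, 1, 0, 0))
  s <- structural_matrix(net, z)
  a <- exp(1 / sqrt(4)); b <- exp(0)
  expected <- rbind(c(a, b), c(b, a)) / (a + b)
  expect_equal(s, expected, tolerance = 1e-12)
})

test_that("fuse reduces to the projected residual when attention adds nothing", {
  bn <- 2L
  net <- sg_network(network_shapes(4, 4, hidden = 3, bottleneck = bn,
                                   fused_dim = 2 * bn), seed = 4)
  net$params$W_R <- matrix(0, 2 * bn, 2 * bn)   # R = 0
  net$params$W3 <- diag(2 * bn)                 # identity projection
  net$params$b3 <- matrix(0, 1, 2 * bn)
  z <- matrix(rnorm(5 * 2 * bn), 5, 2 * bn)
  expect_equal(fuse(net, z, diag(5)), z)
})

test_that("uniform attention makes the fusion summand identical across cells", {
  net <- sg_network(network_shapes(4, 4, hidden = 3, bottleneck = 2,
                                   fused_dim = 6), seed = 6)
  z <- matrix(rnorm(8 * 4), 8, 4)
  s <- matrix(1 / 8, 8, 8)
  h <- fuse(net, z, s)
  # subtract the residual path: what remains is (S R) W3 + b3, constant rows
  resid <- z %*% net$params$W3
  summand <- h - resid
  expect_equal(summand, matrix(summand[1, ], 8, ncol(h), byrow = TRUE),
               tolerance = 1e-10)
})

test_that("structural_matrix + fuse equal an explicit per-cell loop", {
  set.seed(10)
  for (n in c(3, 5, 10)) {
    net <- sg_network(network_shapes(6, 6, hidden = 4, bottleneck = 3,
                                     fused_dim = 7), seed = n)
    z <- matrix(rnorm(n * 6), n, 6)
    s <- structural_matrix(net, z)

    # loop oracle for S
    q <- z %*% net$params$attn_Wq
    k <- z %*% net$params$attn_Wk
    s_loop <- matrix(0, n, n)
    for (i in seq_len(n)) {
      logit <- numeric(n)
      for (j in seq_len(n)) logit[j] <- sum(q[i, ] * k[j, ]) / sqrt(6)
      e <- exp(logit - max(logit))
      s_loop[i, ] <- e / sum(e)
    }
    expect_equal(s, s_loop, tolerance = 1e-5)

    # loop oracle for the fusion: h_i = (z_i + sum_j S_ij R_j) W3 + b3
    r <- z %*% net$params$W_R
    h_loop <- matrix(0, n, 7)
    for (i in seq_len(n)) {
      acc <- z[i, ]
      for (j in seq_len(n)) acc <- acc + s[i, j] * r[j, ]
      h_loop[i, ] <- acc %*% net$params$W3 + as.vector(net$params$b3)
    }
    expect_equal(fuse(net, z, s), h_loop, tolerance = 1e-5)
  }
})

test_that("modality heads are affine: identity init and bias image", {
  bn <- 4L
  net <- sg_network(network_shapes(5, 5, hidden = 3, bottleneck = bn,
                                   fused_dim = bn), seed = 2)
  net$params$head1_W <- diag(bn)
  net$params$head1_b <- matrix(0, 1, bn)
  z1 <- matrix(rnorm(6 * bn), 6, bn)
  z2 <- matrix(0, 6, bn)
  h <- modality_heads(net, z1, z2)
  expect_equal(h$h1, z1)
  expect_equal(h$h2, matrix(net$params$head2_b, 6, bn, byrow = TRUE))
})

test_that("contrastive gradients reach the head parameters", {
  set.seed(8)
  n <- 5
  net <- sg_network(network_shapes(6, 4, hidden = 4, bottleneck = 3,
                                   fused_dim = 4), seed = 8)
  ds <- make_ds(n, 6, 4, seed = 8)
  tape <- sgsdc:::ag_tape()
  pids <- sgsdc:::wrap_params(tape, net$params)
  g <- sgsdc:::sg_graph(tape, pids, sgsdc:::ag_const(tape, ds$x_rna),
                        sgsdc:::ag_const(tape, ds$x_atac), net)
  lc <- sgsdc:::loss_contrastive_graph(tape, g$h_hat, g$h1, g$h2, g$s, 0.5)
  grads <- sgsdc:::ag_backward(tape, lc)
  gh <- grads[[pids$head1_W]]
  expect_false(is.null(gh))
  expect_gt(max(abs(gh)), 0)
})

test_that("decode restores input dimensions", {
  net <- sg_network(network_shapes(11, 7, hidden = 5, bottleneck = 3,
                                   fused_dim = 4), seed = 3)
  out <- decode(net, matrix(rnorm(9 * 3), 9, 3), matrix(rnorm(9 * 3), 9, 3))
  expect_identical(dim(out$x1_hat), c(9L, 11L))
  expect_identical(dim(out$x2_hat), c(9L, 7L))
})

test_that("the pipeline runs end to end with attention disabled", {
  ds <- make_ds(12, 10, 6, seed = 4)
  net <- sg_network(network_shapes(10, 6, hidden = 5, bottleneck = 3,
                                   fused_dim = 4), seed = 4,
                    use_attention = FALSE)
  f <- sg_forward(net, ds)
  expect_equal(f$s, matrix(1 / 12, 12, 12))
  expect_true(all(vapply(f, function(m) all(is.finite(m)), logical(1))))
})

test_that("checkpoints round-trip parameters and config", {
  net <- sg_network(network_shapes(6, 5, hidden = 4, bottleneck = 2,
                                   fused_dim = 3), seed = 12)
  path <- withr::local_tempfile(fileext = ".rds")
  cfg <- training_config(seed = 12)
  save_checkpoint(net, path, config = cfg)
  ck <- load_checkpoint(path)
  expect_identical(ck$net$params, net$params)
  expect_identical(ck$config$seed, 12L)
})
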