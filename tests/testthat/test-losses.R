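test_that("reconstruction loss: closed forms and loop oracle", {
  x <- matrix(rnorm(12), 4, 3)
  expect_equal(reconstruction_loss(x, x, x, x), 0)

  z <- matrix(0, 4, 3); o <- matrix(1, 4, 3)
  expect_equal(reconstruction_loss(z, z, o, o), 2 * 4 * 3)

  set.seed(1)
  x1 <- matrix(rnorm(6), 3, 2); x2 <- matrix(rnorm(6), 3, 2)
  h1 <- matrix(rnorm(6), 3, 2); h2 <- matrix(rnorm(6), 3, 2)
  loop <- 0
  for (i in 1:3) for (j in 1:2) {
    loop <- loop + (x1[i, j] - h1[i, j])^2 + (x2[i, j] - h2[i, j])^2
  }
  expect_equal(reconstruction_loss(x1, x2, h1, h2), loop)
  expect_error(reconstruction_loss(x1, x2, h1[, 1, drop = FALSE], h2),
               "3 x 2.*3 x 1")
})

test_that("cosine similarity: unit cases and scale invariance", {
  expect_equal(cosine_similarity(c(1, 2, 3), c(1, 2, 3)), 1.0)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0.0)
  v <- c(0.3, -1.2, 2)
  expect_equal(cosine_similarity(v, 3 * v), 1.0)
  sgsdc::reset_run_state()
  expect_warning(cosine_similarity(c(0, 0), c(1, 1)), "zero-norm")
  # second call in the same run does not warn again
  expect_no_warning(cosine_similarity(c(0, 0), c(1, 1)))
})

test_that("contrastive loss: n = 1 takes the clamped branch and stays finite", {
  h <- matrix(c(1, 2, 2), 1, 3)
  l <- contrastive_loss(h, h, h, matrix(1, 1, 1), temperature = 0.5)
  expect_true(is.finite(l))
  expect_identical(attr(l, "clamp_count"), 2L)  # once per modality
})

test_that("contrastive loss matches a hand-evaluated two-cell expression", {
  # orthonormal consensus rows; both modality matrices identical to it, so
  # D(i,i) = 1 and D(i,j) = 0; uniform S = 1/2; T = 2 keeps denominators
  # positive:  den = e^{(1-1/2)*1/2} + e^0 - e^{1/2}
  h <- diag(2)
  s <- matrix(0.5, 2, 2)
  T <- 2
  den <- exp(0.5 * 1 / T) + 1 - exp(1 / T)
  hand <- -(1 / 4) * 4 * log(exp(1 / T) / den)
  l <- contrastive_loss(h, h, h, s, temperature = T)
  expect_equal(as.numeric(l), hand, tolerance = 1e-12)
  expect_identical(attr(l, "clamp_count"), 0L)
})

test_that("with all similarities zero the loss varies only via the e^{1/T} term", {
  # consensus rows orthogonal to every modality row: D identically 0, so
  # loss = log(n - e^{1/T}) exactly
  h_hat <- cbind(diag(2), matrix(0, 2, 2))
  h_m <- cbind(matrix(0, 2, 2), diag(2))
  s <- matrix(0.5, 2, 2)
  for (T in c(2, 4)) {
    l <- contrastive_loss(h_hat, h_m, h_m, s, temperature = T)
    expect_equal(as.numeric(l), log(2 - exp(1 / T)), tolerance = 1e-12)
  }
})

test_that("contrastive loss is invariant to common positive rescaling", {
  set.seed(3)
  n <- 8; d <- 5
  h_hat <- matrix(rnorm(n * d), n, d)
  h1 <- matrix(rnorm(n * d), n, d)
  h2 <- matrix(rnorm(n * d), n, d)
  s <- rand_stochastic(n, n)
  base <- as.numeric(contrastive_loss(h_hat, h1, h2, s))
  for (c in c(0.01, 3, 250)) {
    scaled <- as.numeric(contrastive_loss(c * h_hat, c * h1, c * h2, s))
    expect_equal(scaled, base, tolerance = 1e-6)
  }
  expect_error(contrastive_loss(h_hat, h1, h2, s * 2), "row-stochastic")
})

test_that("the drop-self variant removes the diagonal term instead", {
  set.seed(4)
  n <- 4; d <- 3
  h_hat <- matrix(rnorm(n * d), n, d)
  h1 <- matrix(rnorm(n * d), n, d)
  h2 <- matrix(rnorm(n * d), n, d)
  s <- rand_stochastic(n, n)
  # scalar re-derivation
  T <- 0.5
  nrm <- function(m) m / sqrt(rowSums(m^2))
  u <- nrm(h_hat)
  manual <- 0
  for (hm in list(h1, h2)) {
    C <- u %*% t(nrm(hm))
    for (i in 1:n) {
      den <- sum(exp((1 - s[i, -i]) * C[i, -i] / T))
      manual <- manual - log(exp(C[i, i] / T) / den)
    }
  }
  manual <- manual / (2 * n)
  l <- contrastive_loss(h_hat, h1, h2, s, temperature = T,
                        denominator = "drop_self")
  expect_equal(as.numeric(l), manual, tolerance = 1e-10)
})

test_that("soft clustering loss: KL identities and loop oracle", {
  g <- rand_stochastic(4, 3)
  expect_equal(soft_clustering_loss(g, g), 0)

  g1 <- matrix(c(1, 0), 1, 2)
  q1 <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(soft_clustering_loss(g1, q1), log(2))

  set.seed(5)
  gam <- rand_stochastic(5, 3)
  q <- rand_stochastic(5, 3)
  loop <- 0
  for (i in 1:5) for (j in 1:3) {
    loop <- loop + gam[i, j] * log(gam[i, j] / q[i, j])
  }
  expect_equal(soft_clustering_loss(gam, q), loop, tolerance = 1e-12)
  expect_error(soft_clustering_loss(gam * 2, q), "row-stochastic")
})

test_that("reconstruction and soft losses are non-negative on random inputs", {
  set.seed(6)
  for (rep in 1:200) {
    n <- sample(2:6, 1); d <- sample(2:4, 1); k <- sample(2:4, 1)
    lr <- reconstruction_loss(matrix(rnorm(n * d), n, d),
                              matrix(rnorm(n * d), n, d),
                              matrix(rnorm(n * d), n, d),
                              matrix(rnorm(n * d), n, d))
    ls <- soft_clustering_loss(rand_stochastic(n, k), rand_stochastic(n, k))
    expect_gte(lr, 0)
    expect_gte(ls, -1e-12)
  }
})

test_that("total loss combines components with the configured weights", {
  w <- loss_weights(alpha = 0.1, beta = 1)
  expect_equal(total_loss(1, 2, 3, w), 4.2)
  expect_equal(total_loss(1.7, 99, 99, loss_weights(alpha = 0, beta = 0)), 1.7)
  grid <- expand.grid(a = c(0.01, 0.1, 1, 10), b = c(0.01, 0.1, 1, 10))
  totals <- mapply(function(a, b) {
    total_loss(1, 2, 3, loss_weights(alpha = a, beta = b))
  }, grid$a, grid$b)
  expect_identical(length(unique(totals)), 16L)
})

test_that("autodiff loss gradients match central finite differences", {
  set.seed(7)
  n <- 6; d <- 4; k <- 3
  for (pt in 1:20) {
    inputs <- list(
      x = matrix(rnorm(n * d), n, d),
      x_hat = matrix(rnorm(n * d), n, d),
      h_hat = matrix(rnorm(n * d), n, d),
      h1 = matrix(rnorm(n * d), n, d),
      h2 = matrix(rnorm(n * d), n, d),
      centers = matrix(rnorm(k * d), k, d))
    s <- rand_stochastic(n, n)
    gamma <- rand_stochastic(n, k)

    # reconstruction, w.r.t. the reconstruction matrix
    ad <- ag_input_gradient(function(tape, ids) {
      sgsdc:::loss_reconstruction_graph(tape, ids$x, ids$x, ids$x_hat, ids$x_hat)
    }, inputs, "x_hat")
    fd <- fd_input_gradient(function(inp) {
      reconstruction_loss(inp$x, inp$x, inp$x_hat, inp$x_hat)
    }, inputs, "x_hat")
    expect_lt(max_rel_err(ad, fd), 1e-3)

    # contrastive, w.r.t. the consensus representation
    ad <- ag_input_gradient(function(tape, ids) {
      sgsdc:::loss_contrastive_graph(tape, ids$h_hat, ids$h1, ids$h2,
                                     sgsdc:::ag_const(tape, s), 0.5)
    }, inputs, "h_hat")
    fd <- fd_input_gradient(function(inp) {
      as.numeric(contrastive_loss(inp$h_hat, inp$h1, inp$h2, s))
    }, inputs, "h_hat")
    expect_lt(max_rel_err(ad, fd), 1e-3)

    # soft clustering through the Student-t assignment, w.r.t. embedding
    # and centers (gamma is a constant target)
    soft_builder <- function(wrt) {
      list(
        ad = ag_input_gradient(function(tape, ids) {
          q <- sgsdc:::student_t_graph(tape, ids$h_hat, ids$centers)
          sgsdc:::loss_soft_graph(tape, gamma, q)
        }, inputs, wrt),
        fd = fd_input_gradient(function(inp) {
          soft_clustering_loss(gamma,
                               student_t_assignment(inp$h_hat, inp$centers))
        }, inputs, wrt))
    }
    for (wrt in c("h_hat", "centers")) {
      g <- soft_builder(wrt)
      expect_lt(max_rel_err(g$ad, g$fd), 1e-3)
    }
  }
})
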