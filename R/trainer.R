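# End-to-end optimization: reconstruction pretraining, joint training of the
# weighted total loss with early stopping, final k-means on the consensus
# representation, plus ablation and hyperparameter-sweep drivers.

#' Training configuration
#'
#' Defaults follow the published training recipe: bottleneck 64, fused width
#' 128, fuzzifier m = 1.5, 200 pretraining epochs, 50 joint epochs with
#' early-stopping patience 20, learning rate 5e-4, temperature 0.5, and unit
#' weights for the contrastive and soft-clustering terms.
#'
#' @param alpha,beta weights of the contrastive and soft-clustering losses.
#' @param temperature contrastive temperature T.
#' @param fuzzifier fuzzy c-means exponent m > 1.
#' @param hidden encoder hidden widths.
#' @param bottleneck latent width per modality.
#' @param fused_dim consensus representation width.
#' @param pretrain_epochs,train_epochs epochs of the two phases.
#' @param patience early stopping: halt after this many joint epochs without
#'   total-loss improvement of at least 1e-6.
#' @param learning_rate Adam step size.
#' @param seed seed for every source of randomness in a run.
#' @param n_clusters number of clusters k (falls back to the dataset's).
#' @param use_contrastive,use_soft,use_attention ablation switches. With
#'   `use_soft = FALSE` the soft-clustering divergence is replaced by the
#'   classical self-sharpening KL target of deep embedded clustering.
#' @param attention_scale `"sqrt_d"` or `"d"` logit scaling.
#' @param contrastive_denominator `"as_printed"` or `"drop_self"` (see
#'   [contrastive_loss()]).
#' @param soft_space embedding the memberships live in: `"fused"` (the
#'   consensus H-hat, default) or `"concat"` (the concatenated latent Z).
#' @param center_update `"gradient"` (centers are free parameters receiving
#'   gradients from the soft loss) or `"fcm"` (closed-form update each epoch).
#' @param debug verify membership row-stochasticity every epoch.
#' @return An object of class `training_config`.
#' @export
training_config <- function(alpha = 1, beta = 1, temperature = 0.5,
                            fuzzifier = 1.5, hidden = 256, bottleneck = 64,
                            fused_dim = 128, pretrain_epochs = 200,
                            train_epochs = 50, patience = 20,
                            learning_rate = 5e-4, seed = 0,
                            n_clusters = NULL,
                            use_contrastive = TRUE, use_soft = TRUE,
                            use_attention = TRUE,
                            attention_scale = c("sqrt_d", "d"),
                            contrastive_denominator = c("as_printed", "drop_self"),
                            soft_space = c("fused", "concat"),
                            center_update = c("gradient", "fcm"),
                            debug = FALSE) {
  stopifnot(alpha >= 0, beta >= 0, temperature > 0, fuzzifier > 1,
            pretrain_epochs >= 0, train_epochs >= 0, patience >= 1,
            learning_rate >= 0)
  structure(list(
    alpha = alpha, beta = beta, temperature = temperature,
    fuzzifier = fuzzifier, hidden = as.integer(hidden),
    bottleneck = as.integer(bottleneck), fused_dim = as.integer(fused_dim),
    pretrain_epochs = as.integer(pretrain_epochs),
    train_epochs = as.integer(train_epochs), patience = as.integer(patience),
    learning_rate = learning_rate, seed = as.integer(seed),
    n_clusters = if (is.null(n_clusters)) NULL else as.integer(n_clusters),
    use_contrastive = isTRUE(use_contrastive),
    use_soft = isTRUE(use_soft), use_attention = isTRUE(use_attention),
    attention_scale = match.arg(attention_scale),
    contrastive_denominator = match.arg(contrastive_denominator),
    soft_space = match.arg(soft_space),
    center_update = match.arg(center_update),
    debug = isTRUE(debug)
  ), class = "training_config")
}

# ---- Adam -----------------------------------------------------------------

adam_state <- function(params) {
  list(m = lapply(params, function(w) w * 0),
       v = lapply(params, function(w) w * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, names,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

param_grads <- function(tape, pids, grads) {
  out <- list()
  for (nm in names(pids)) out[[nm]] <- grads[[pids[[nm]]]]
  out
}

abort_nonfinite <- function(epoch, phase, components, grads = NULL) {
  maxg <- if (is.null(grads)) NA_real_ else {
    max(vapply(grads[!vapply(grads, is.null, TRUE)],
               function(g) max(abs(g)), numeric(1)))
  }
  stop(sprintf(
    "non-finite loss at %s epoch %d (components: %s; max |grad| = %s)",
    phase, epoch, paste(sprintf("%s=%g", names(components),
                                unlist(components)), collapse = ", "),
    format(maxg)), call. = FALSE)
}

# ---- pretraining ----------------------------------------------------------

run_pretrain_loop <- function(net, x1, x2, config) {
  trainable <- grep("^(enc|dec)", names(net$params), value = TRUE)
  opt <- adam_state(net$params)
  history <- vector("list", config$pretrain_epochs)
  for (epoch in seq_len(config$pretrain_epochs)) {
    tape <- ag_tape()
    pids <- wrap_params(tape, net$params)
    g <- sg_graph(tape, pids, ag_const(tape, x1), ag_const(tape, x2), net,
                  stage = "pretrain")
    lr_id <- loss_reconstruction_graph(tape, ag_const(tape, x1),
                                       ag_const(tape, x2), g$x1_hat, g$x2_hat)
    lr_val <- ag_value(tape, lr_id)[1L, 1L]
    if (!is.finite(lr_val)) {
      abort_nonfinite(epoch, "pretrain", list(loss_r = lr_val))
    }
    grads <- param_grads(tape, pids, ag_backward(tape, lr_id))
    step <- adam_step(net$params, grads, opt, config$learning_rate, trainable)
    net$params <- step$params; opt <- step$state
    history[[epoch]] <- data.frame(phase = "pretrain", epoch = epoch,
                                   loss_r = lr_val, loss_c = NA_real_,
                                   loss_s = NA_real_, total = lr_val,
                                   clamp_count = 0L)
  }
  list(net = net, history = do.call(rbind, history))
}

#' Pretrain the autoencoders on reconstruction loss alone
#'
#' Builds a seeded network and optimizes only the encoder/decoder parameters
#' for `pretrain_epochs` full-batch Adam steps. With `pretrain_epochs = 0`
#' the returned parameters equal the seeded initialization.
#'
#' @param ds a preprocessed [multimodal_dataset()].
#' @param config a [training_config()].
#' @return List with `net` (the [sg_network()]) and `history` (per-epoch
#'   loss data frame).
#' @export
sg_pretrain <- function(ds, config = training_config()) {
  stopifnot(inherits(ds, "multimodal_dataset"),
            inherits(config, "training_config"))
  shapes <- network_shapes(ncol(ds$x_rna), ncol(ds$x_atac),
                           hidden = config$hidden,
                           bottleneck = config$bottleneck,
                           fused_dim = config$fused_dim)
  net <- sg_network(shapes, seed = config$seed,
                    use_attention = config$use_attention,
                    attention_scale = config$attention_scale)
  run_pretrain_loop(net, ds$x_rna, ds$x_atac, config)
}

# ---- joint training -------------------------------------------------------

# DEC self-sharpening target: p_ij = (q_ij^2 / f_j) / sum_j' (q_ij'^2 / f_j')
dec_target <- function(q) {
  w <- q^2 / colSums(q)
  w / rowSums(w)
}

row_entropy_ <- function(gamma) {
  apply(gamma, 1L, function(p) {
    p <- p[p > 0]
    -sum(p * log(p))
  })
}

#' Shannon entropy of each membership row (nats)
#'
#' High entropy means a cell's membership mass is spread over clusters —
#' the signature of a transitional cell.
#'
#' @param gamma n x k row-stochastic membership matrix.
#' @return Numeric vector of length n.
#' @export
membership_entropy <- function(gamma) {
  row_entropy_(as.matrix(gamma))
}

#' Fit the full model to a paired dataset
#'
#' Implements the training schedule end to end: reconstruction pretraining,
#' k-means initialization of the cluster centers on the consensus
#' representation, then joint full-batch epochs in which the fuzzy
#' memberships gamma are recomputed in closed form (and detached), the three
#' losses are evaluated, and all parameters (including the centers, by
#' default) take an Adam step on the weighted total. Training stops early
#' after `patience` epochs without total-loss improvement. Final hard labels
#' come from k-means on the final consensus representation; the fuzzy
#' memberships and their argmax are returned alongside.
#'
#' @param ds a preprocessed [multimodal_dataset()].
#' @param config a [training_config()].
#' @return An object of class `clustering_result`: `soft_memberships`,
#'   `hard_labels` (k-means, 0-based), `soft_labels` (membership argmax),
#'   `h_hat_final`, `centers`, `history`, `metrics` (when the dataset has
#'   labels), `net`, `config`.
#' @export
sg_fit <- function(ds, config = training_config()) {
  stopifnot(inherits(ds, "multimodal_dataset"),
            inherits(config, "training_config"))
  n <- nrow(ds$x_rna)
  k <- if (!is.null(config$n_clusters)) config$n_clusters else ds$n_clusters
  if (is.null(k) || is.na(k)) {
    stop("n_clusters must be set in the config or the dataset", call. = FALSE)
  }
  if (k > n) stop(sprintf("k = %d exceeds the %d cells", k, n), call. = FALSE)

  pre <- sg_pretrain(ds, config)
  net <- pre$net
  history <- list(pre$history)
  x1 <- ds$x_rna; x2 <- ds$x_atac
  soft_node <- function(g) if (config$soft_space == "fused") g$h_hat else g$zcat

  # center initialization on the pretrained consensus representation
  tape0 <- ag_tape()
  pids0 <- wrap_params(tape0, net$params)
  g0 <- sg_graph(tape0, pids0, ag_const(tape0, x1), ag_const(tape0, x2), net)
  z0 <- ag_value(tape0, soft_node(g0))
  net$params$centers <- initialize_centers(z0, k, seed = config$seed)

  trainable <- names(net$params)
  if (config$center_update == "fcm") trainable <- setdiff(trainable, "centers")
  opt <- adam_state(net$params)
  weights <- loss_weights(config$alpha, config$beta, config$temperature)
  best <- Inf; wait <- 0L

  for (epoch in seq_len(config$train_epochs)) {
    tape <- ag_tape()
    pids <- wrap_params(tape, net$params)
    g <- sg_graph(tape, pids, ag_const(tape, x1), ag_const(tape, x2), net)
    z_id <- soft_node(g)
    z_val <- ag_value(tape, z_id)

    gamma <- fuzzy_memberships(z_val, net$params$centers, config$fuzzifier)
    q_id <- student_t_graph(tape, z_id, pids$centers)
    if (config$debug) {
      check_row_stochastic(gamma, "gamma")
      check_row_stochastic(ag_value(tape, q_id), "q")
    }
    target <- if (config$use_soft) gamma else dec_target(ag_value(tape, q_id))

    lr_id <- loss_reconstruction_graph(tape, ag_const(tape, x1),
                                       ag_const(tape, x2), g$x1_hat, g$x2_hat)
    ls_id <- loss_soft_graph(tape, target, q_id)
    total_id <- ag_add(tape, lr_id,
                       ag_affine(tape, ls_id, mult = config$beta))
    lc_val <- NA_real_
    if (config$use_contrastive) {
      lc_id <- loss_contrastive_graph(tape, g$h_hat, g$h1, g$h2, g$s,
                                      config$temperature,
                                      config$contrastive_denominator)
      lc_val <- ag_value(tape, lc_id)[1L, 1L]
      total_id <- ag_add(tape, total_id,
                         ag_affine(tape, lc_id, mult = config$alpha))
    }
    lr_val <- ag_value(tape, lr_id)[1L, 1L]
    ls_val <- ag_value(tape, ls_id)[1L, 1L]
    total_val <- ag_value(tape, total_id)[1L, 1L]
    if (!is.finite(total_val)) {
      abort_nonfinite(epoch, "joint",
                      list(loss_r = lr_val, loss_c = lc_val, loss_s = ls_val))
    }
    history[[length(history) + 1L]] <- data.frame(
      phase = "train", epoch = epoch, loss_r = lr_val, loss_c = lc_val,
      loss_s = ls_val, total = total_val, clamp_count = tape$clamp_count)

    if (total_val < best - 1e-6) {
      best <- total_val
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }

    grads <- param_grads(tape, pids, ag_backward(tape, total_id))
    step <- adam_step(net$params, grads, opt, config$learning_rate, trainable)
    net$params <- step$params; opt <- step$state
    if (config$center_update == "fcm") {
      net$params$centers <- update_centers(z_val, gamma, config$fuzzifier)
    }
  }

  # final pass and Algorithm-style k-means readout
  tapef <- ag_tape()
  pidsf <- wrap_params(tapef, net$params)
  gf <- sg_graph(tapef, pidsf, ag_const(tapef, x1), ag_const(tapef, x2), net)
  h_final <- ag_value(tapef, gf$h_hat)
  z_final <- ag_value(tapef, soft_node(gf))
  gamma_final <- fuzzy_memberships(z_final, net$params$centers,
                                   config$fuzzifier)
  set.seed(config$seed + 1L)
  km <- stats::kmeans(h_final, centers = k, nstart = 10, iter.max = 100)
  hard_labels <- km$cluster - 1L
  soft_labels <- max.col(gamma_final, ties.method = "first") - 1L

  metrics <- if (!is.null(ds$labels)) {
    evaluate_clustering(ds$labels, hard_labels)
  }
  structure(list(
    soft_memberships = gamma_final, hard_labels = hard_labels,
    soft_labels = soft_labels, h_hat_final = h_final,
    centers = net$params$centers, history = do.call(rbind, history),
    metrics = metrics, net = net, config = config
  ), class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  k <- ncol(x$soft_memberships)
  cat(sprintf("clustering_result: %d cells, %d clusters\n",
              length(x$hard_labels), k))
  if (!is.null(x$metrics)) {
    cat(sprintf("  ACC %.4f  NMI %.4f  ARI %.4f\n",
                x$metrics$acc, x$metrics$nmi, x$metrics$ari))
  }
  cat(sprintf("  epochs: %d pretrain + %d joint\n",
              sum(x$history$phase == "pretrain"),
              sum(x$history$phase == "train")))
  invisible(x)
}

config_with <- function(config, ...) {
  mods <- list(...)
  for (nm in names(mods)) config[[nm]] <- mods[[nm]]
  config
}

#' Run the standard ablation battery
#'
#' Fits the full model and the three single-module ablations (no contrastive
#' loss; no soft clustering, i.e. the classical self-sharpening KL target in
#' place of the fuzzy divergence; no attention, i.e. uniform S) with a shared
#' seed, and tabulates their scores against the dataset's labels.
#'
#' @param ds a preprocessed, labeled [multimodal_dataset()].
#' @param config a [training_config()].
#' @return List with `results` (named list of [sg_fit()] outputs) and
#'   `table` (data frame: variant, acc, nmi, ari).
#' @export
run_ablation <- function(ds, config = training_config()) {
  if (is.null(ds$labels)) {
    stop("ablation scoring needs ground-truth labels", call. = FALSE)
  }
  variants <- list(
    full = config,
    no_contrastive = config_with(config, use_contrastive = FALSE),
    no_soft = config_with(config, use_soft = FALSE),
    no_attention = config_with(config, use_attention = FALSE)
  )
  results <- lapply(variants, function(cf) sg_fit(ds, cf))
  tab <- do.call(rbind, lapply(names(results), function(nm) {
    m <- results[[nm]]$metrics
    data.frame(variant = nm, acc = m$acc, nmi = m$nmi, ari = m$ari)
  }))
  list(results = results, table = tab)
}

#' Hyperparameter grid sweep
#'
#' Runs the Cartesian product of the supplied alpha, beta and temperature
#' grids (duplicate tuples removed) with a shared seed and reports ACC, NMI
#' and ARI per combination.
#'
#' @param ds a preprocessed, labeled [multimodal_dataset()].
#' @param config base [training_config()].
#' @param alpha,beta,temperature value grids; defaults are the single values
#'   in `config`.
#' @return Long-format data frame: alpha, beta, temperature, acc, nmi, ari.
#' @export
run_sweep <- function(ds, config = training_config(),
                      alpha = config$alpha, beta = config$beta,
                      temperature = config$temperature) {
  if (is.null(ds$labels)) {
    stop("sweep scoring needs ground-truth labels", call. = FALSE)
  }
  grid <- unique(expand.grid(alpha = alpha, beta = beta,
                             temperature = temperature,
                             KEEP.OUT.ATTRS = FALSE))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cf <- config_with(config, alpha = grid$alpha[i], beta = grid$beta[i],
                      temperature = grid$temperature[i])
    m <- sg_fit(ds, cf)$metrics
    data.frame(alpha = grid$alpha[i], beta = grid$beta[i],
               temperature = grid$temperature[i],
               acc = m$acc, nmi = m$nmi, ari = m$ari)
  })
  do.call(rbind, rows)
}
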