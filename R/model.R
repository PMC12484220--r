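# The network: two modality autoencoders, a global-attention fusion block
# producing the consensus representation H-hat, and affine modality heads
# H1/H2 used by the contrastive loss.

#' Network shape configuration
#'
#' @param d1,d2 input feature counts of the scRNA and scATAC modalities.
#' @param hidden hidden widths of each encoder (mirror-image decoder).
#' @param bottleneck latent width per modality (default 64).
#' @param fused_dim width of the consensus representation and of each
#'   modality head (default 128).
#' @param attn_dim projection width of the attention query/key maps; defaults
#'   to `2 * bottleneck`, the width of the concatenated latent.
#' @return An object of class `network_shapes`.
#' @export
network_shapes <- function(d1, d2, hidden = 256, bottleneck = 64,
                           fused_dim = 128, attn_dim = 2 * bottleneck) {
  stopifnot(d1 >= 1, d2 >= 1, length(hidden) >= 1, all(hidden >= 1),
            bottleneck >= 1, fused_dim >= 1, attn_dim >= 1)
  structure(list(d1 = as.integer(d1), d2 = as.integer(d2),
                 hidden = as.integer(hidden),
                 bottleneck = as.integer(bottleneck),
                 fused_dim = as.integer(fused_dim),
                 attn_dim = as.integer(attn_dim)),
            class = "network_shapes")
}

glorot <- function(fin, fout) {
  lim <- sqrt(6 / (fin + fout))
  matrix(stats::runif(fin * fout, -lim, lim), fin, fout)
}

init_mlp <- function(params, prefix, widths) {
  for (l in seq_len(length(widths) - 1L)) {
    params[[sprintf("%s_W%d", prefix, l)]] <- glorot(widths[l], widths[l + 1L])
    params[[sprintf("%s_b%d", prefix, l)]] <- matrix(0, 1L, widths[l + 1L])
  }
  params
}

#' Build a network with seeded parameter initialization
#'
#' @param shapes a [network_shapes()].
#' @param seed RNG seed for Glorot-uniform initialization.
#' @param use_attention when `FALSE` the structural matrix is forced uniform
#'   (1/n everywhere) — the "no attention" ablation.
#' @param attention_scale `"sqrt_d"` (default) scales attention logits by
#'   1/sqrt(attn_dim); `"d"` scales by 1/attn_dim.
#' @return An object of class `sg_network` holding the parameter list.
#' @export
sg_network <- function(shapes, seed = 0,
                       use_attention = TRUE,
                       attention_scale = c("sqrt_d", "d")) {
  stopifnot(inherits(shapes, "network_shapes"))
  attention_scale <- match.arg(attention_scale)
  set.seed(seed)
  bn <- shapes$bottleneck; fd <- shapes$fused_dim
  zc <- 2L * bn
  p <- list()
  p <- init_mlp(p, "enc1", c(shapes$d1, shapes$hidden, bn))
  p <- init_mlp(p, "enc2", c(shapes$d2, shapes$hidden, bn))
  p <- init_mlp(p, "dec1", c(bn, rev(shapes$hidden), shapes$d1))
  p <- init_mlp(p, "dec2", c(bn, rev(shapes$hidden), shapes$d2))
  p$W_R <- glorot(zc, zc)
  p$attn_Wq <- glorot(zc, shapes$attn_dim)
  p$attn_Wk <- glorot(zc, shapes$attn_dim)
  p$W3 <- glorot(zc, fd)
  p$b3 <- matrix(0, 1L, fd)
  p$head1_W <- glorot(bn, fd)
  p$head1_b <- matrix(0, 1L, fd)
  p$head2_W <- glorot(bn, fd)
  p$head2_b <- matrix(0, 1L, fd)
  structure(list(params = p, shapes = shapes,
                 use_attention = use_attention,
                 attention_scale = attention_scale),
            class = "sg_network")
}

#' @export
print.sg_network <- function(x, ...) {
  s <- x$shapes
  cat(sprintf(paste0("sg_network: d1=%d, d2=%d, hidden=[%s], bottleneck=%d, ",
                     "fused_dim=%d, attention=%s (%s scaling)\n"),
              s$d1, s$d2, paste(s$hidden, collapse = ","), s$bottleneck,
              s$fused_dim, x$use_attention, x$attention_scale))
  invisible(x)
}

# wrap every parameter as a tape node; returns named list of ids
wrap_params <- function(tape, params) {
  lapply(params, function(w) ag_const(tape, w))
}

mlp_graph <- function(tape, pids, prefix, x_id, n_layers, final_linear = TRUE) {
  h <- x_id
  for (l in seq_len(n_layers)) {
    h <- ag_addbias(tape,
                    ag_matmul(tape, h, pids[[sprintf("%s_W%d", prefix, l)]]),
                    pids[[sprintf("%s_b%d", prefix, l)]])
    if (l < n_layers || !final_linear) h <- ag_elu(tape, h)
  }
  h
}

# Full forward graph. Returns node ids for every intermediate. `stage`
# "pretrain" skips fusion/heads (reconstruction only); "joint" builds all.
sg_graph <- function(tape, pids, x1_id, x2_id, net, stage = "joint") {
  nl <- length(net$shapes$hidden) + 1L
  z1 <- mlp_graph(tape, pids, "enc1", x1_id, nl)
  z2 <- mlp_graph(tape, pids, "enc2", x2_id, nl)
  x1_hat <- mlp_graph(tape, pids, "dec1", z1, nl)
  x2_hat <- mlp_graph(tape, pids, "dec2", z2, nl)
  out <- list(z1 = z1, z2 = z2, x1_hat = x1_hat, x2_hat = x2_hat)
  if (stage == "pretrain") return(out)

  zcat <- ag_concat_cols(tape, z1, z2)
  n <- nrow(ag_value(tape, zcat))
  if (net$use_attention) {
    q <- ag_matmul(tape, zcat, pids$attn_Wq)
    k <- ag_matmul(tape, zcat, pids$attn_Wk)
    scale <- if (net$attention_scale == "sqrt_d") sqrt(net$shapes$attn_dim)
             else net$shapes$attn_dim
    logits <- ag_affine(tape, ag_matmul(tape, q, k, tb = TRUE), mult = 1 / scale)
    s <- ag_softmax_rows(tape, logits)
  } else {
    s <- ag_const(tape, matrix(1 / n, n, n))
  }
  r <- ag_matmul(tape, zcat, pids$W_R)
  fused_in <- ag_add(tape, zcat, ag_matmul(tape, s, r))
  h_hat <- ag_addbias(tape, ag_matmul(tape, fused_in, pids$W3), pids$b3)
  h1 <- ag_addbias(tape, ag_matmul(tape, z1, pids$head1_W), pids$head1_b)
  h2 <- ag_addbias(tape, ag_matmul(tape, z2, pids$head2_W), pids$head2_b)
  c(out, list(zcat = zcat, s = s, r = r, h_hat = h_hat, h1 = h1, h2 = h2))
}

as_modality_matrices <- function(x, net, what = "input") {
  if (inherits(x, "multimodal_dataset")) list(x1 = x$x_rna, x2 = x$x_atac)
  else stop(sprintf("%s must be a multimodal_dataset", what), call. = FALSE)
}

check_dims <- function(x, d, what) {
  if (ncol(x) != d) {
    stop(sprintf("%s has %d columns but the network expects %d",
                 what, ncol(x), d), call. = FALSE)
  }
}

#' Encode both modalities to their latent representations
#'
#' @param net an [sg_network()].
#' @param ds a [multimodal_dataset()] whose feature counts match the network.
#' @return List with `z1`, `z2` (n x bottleneck matrices).
#' @export
encode <- function(net, ds) {
  m <- as_modality_matrices(ds, net)
  check_dims(m$x1, net$shapes$d1, "scRNA matrix")
  check_dims(m$x2, net$shapes$d2, "scATAC matrix")
  tape <- ag_tape()
  pids <- wrap_params(tape, net$params)
  g <- sg_graph(tape, pids, ag_const(tape, m$x1), ag_const(tape, m$x2),
                net, stage = "pretrain")
  list(z1 = ag_value(tape, g$z1), z2 = ag_value(tape, g$z2))
}

#' Compute the global structural (attention) matrix S
#'
#' S = row-softmax of (Z Wq)(Z Wk)' scaled by the configured attention scale;
#' every row is a probability distribution over cells.
#'
#' @param net an [sg_network()].
#' @param z_cat n x (2 * bottleneck) concatenated latent matrix.
#' @return n x n row-stochastic matrix.
#' @export
structural_matrix <- function(net, z_cat) {
  z_cat <- as.matrix(z_cat)
  n <- nrow(z_cat)
  if (!net$use_attention) return(matrix(1 / n, n, n))
  tape <- ag_tape()
  q <- z_cat %*% net$params$attn_Wq
  k <- z_cat %*% net$params$attn_Wk
  scale <- if (net$attention_scale == "sqrt_d") sqrt(net$shapes$attn_dim)
           else net$shapes$attn_dim
  logits <- (q %*% t(k)) / scale
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

#' Fuse the concatenated latent with attention-weighted features
#'
#' H-hat = (Z + S R) W3 + b3 with R = Z W_R. The residual Z term keeps the
#' fusion informative even when S is uniform.
#'
#' @param net an [sg_network()].
#' @param z_cat n x (2 * bottleneck) concatenated latent matrix.
#' @param s n x n row-stochastic structural matrix.
#' @return n x fused_dim consensus representation.
#' @export
fuse <- function(net, z_cat, s) {
  z_cat <- as.matrix(z_cat); s <- as.matrix(s)
  if (nrow(s) != nrow(z_cat) || ncol(s) != nrow(z_cat)) {
    stop(sprintf("S is %d x %d but Z has %d rows",
                 nrow(s), ncol(s), nrow(z_cat)), call. = FALSE)
  }
  r <- z_cat %*% net$params$W_R
  sweep((z_cat + s %*% r) %*% net$params$W3, 2L,
        as.vector(net$params$b3), "+")
}

#' Project modality latents to the fused width
#'
#' Affine heads mapping Z1 and Z2 into the fused dimension so cosine
#' similarity with the consensus H-hat is well defined.
#'
#' @param net an [sg_network()].
#' @param z1,z2 n x bottleneck latent matrices.
#' @return List with `h1`, `h2` (n x fused_dim).
#' @export
modality_heads <- function(net, z1, z2) {
  list(h1 = sweep(as.matrix(z1) %*% net$params$head1_W, 2L,
                  as.vector(net$params$head1_b), "+"),
       h2 = sweep(as.matrix(z2) %*% net$params$head2_W, 2L,
                  as.vector(net$params$head2_b), "+"))
}

#' Decode latents back to the input feature spaces
#'
#' @param net an [sg_network()].
#' @param z1,z2 n x bottleneck latent matrices.
#' @return List with `x1_hat` (n x d1), `x2_hat` (n x d2).
#' @export
decode <- function(net, z1, z2) {
  tape <- ag_tape()
  pids <- wrap_params(tape, net$params)
  nl <- length(net$shapes$hidden) + 1L
  x1 <- mlp_graph(tape, pids, "dec1", ag_const(tape, as.matrix(z1)), nl)
  x2 <- mlp_graph(tape, pids, "dec2", ag_const(tape, as.matrix(z2)), nl)
  list(x1_hat = ag_value(tape, x1), x2_hat = ag_value(tape, x2))
}

#' Run the full forward pass
#'
#' @param net an [sg_network()].
#' @param ds a preprocessed [multimodal_dataset()].
#' @return A `fusion_state` list: `z1`, `z2`, `zcat`, `s`, `r`, `h_hat`,
#'   `h1`, `h2`, `x1_hat`, `x2_hat`.
#' @export
sg_forward <- function(net, ds) {
  m <- as_modality_matrices(ds, net)
  check_dims(m$x1, net$shapes$d1, "scRNA matrix")
  check_dims(m$x2, net$shapes$d2, "scATAC matrix")
  tape <- ag_tape()
  pids <- wrap_params(tape, net$params)
  g <- sg_graph(tape, pids, ag_const(tape, m$x1), ag_const(tape, m$x2), net)
  out <- lapply(g, function(id) ag_value(tape, id))
  class(out) <- "fusion_state"
  out
}

#' Save a network checkpoint (parameters + the config that produced it)
#'
#' @param net an [sg_network()].
#' @param path output `.rds` path.
#' @param config optional [training_config()] stored alongside.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path, config = NULL) {
  saveRDS(list(params = net$params, shapes = unclass(net$shapes),
               use_attention = net$use_attention,
               attention_scale = net$attention_scale,
               config = config), path)
  invisible(path)
}

#' Load a network checkpoint written by [save_checkpoint()]
#' @param path checkpoint path.
#' @return List with `net` (an [sg_network()]) and `config`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  shapes <- structure(ck$shapes, class = "network_shapes")
  net <- structure(list(params = ck$params, shapes = shapes,
                        use_attention = ck$use_attention,
                        attention_scale = ck$attention_scale),
                   class = "sg_network")
  list(net = net, config = ck$config)
}
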