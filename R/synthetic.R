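# Paired bimodal count simulator with known (possibly soft) cluster structure.

#' Specify a synthetic paired bimodal dataset
#'
#' Defaults emulate a small paired scRNA/scATAC benchmark: 1,728 cells, 5
#' clusters, 1,000 RNA features and 25 ATAC features. Cells live in a latent
#' space where each cluster is an archetype; `separation` is the expected
#' between-archetype distance in latent units and `noise_sd` the per-cell
#' Gaussian jitter. A fraction of cells are "transitional": convex mixtures of
#' two archetypes with weight drawn from Uniform(0.3, 0.7), mimicking cells
#' moving between identities.
#'
#' @param n_cells number of cells.
#' @param n_clusters number of latent clusters k.
#' @param d_rna,d_atac feature counts of the two modalities.
#' @param separation expected distance between cluster archetypes (latent units).
#' @param noise_sd standard deviation of per-cell latent noise.
#' @param frac_transitional fraction in `[0, 1)` of mixed-identity cells.
#' @param latent_dim dimension of the shared latent space.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_cells = 1728, n_clusters = 5, d_rna = 1000,
                           d_atac = 25, separation = 8, noise_sd = 0.5,
                           frac_transitional = 0, latent_dim = 10, seed = 0) {
  stopifnot(n_cells >= 1, n_clusters >= 1, d_rna >= 1, d_atac >= 1,
            separation > 0, noise_sd > 0, latent_dim >= 1,
            frac_transitional >= 0, frac_transitional < 1)
  structure(list(n_cells = as.integer(n_cells),
                 n_clusters = as.integer(n_clusters),
                 d_rna = as.integer(d_rna), d_atac = as.integer(d_atac),
                 separation = separation, noise_sd = noise_sd,
                 frac_transitional = frac_transitional,
                 latent_dim = as.integer(latent_dim),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a paired bimodal dataset with known soft memberships
#'
#' Draws k latent archetypes with expected pairwise distance `separation`;
#' each pure cell is its archetype plus Gaussian noise, each transitional cell
#' a convex mixture of two archetypes (weight ~ Uniform(0.3, 0.7)). Latent
#' coordinates are pushed through a fixed random linear map per modality,
#' a softplus link, and Poisson sampling, so both count matrices share the
#' latent cluster geometry. Hard labels are the argmax of the true soft
#' memberships.
#'
#' @param spec a [synthetic_spec()].
#' @return A list with elements `dataset` (a [multimodal_dataset()] of raw
#'   counts), `memberships` (n x k true soft memberships, rows sum to 1),
#'   `latent` (noisy latent coordinates) and `latent_mean` (noiseless
#'   archetype mixtures).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_cells; k <- spec$n_clusters; L <- spec$latent_dim

  # archetypes: iid Gaussian with sd chosen so E||a - b||^2 = separation^2
  arch <- matrix(stats::rnorm(k * L, sd = spec$separation / sqrt(2 * L)), k, L)

  n_trans <- round(spec$frac_transitional * n)
  memberships <- matrix(0, n, k)
  primary <- sample.int(k, n, replace = TRUE)
  is_trans <- rep(FALSE, n)
  if (n_trans > 0) is_trans[sample.int(n, n_trans)] <- TRUE
  for (i in seq_len(n)) {
    if (is_trans[i] && k >= 2) {
      other <- sample(setdiff(seq_len(k), primary[i]), 1L)
      w <- stats::runif(1, 0.3, 0.7)
      memberships[i, primary[i]] <- w
      memberships[i, other] <- 1 - w
    } else {
      memberships[i, primary[i]] <- 1
    }
  }
  latent_mean <- memberships %*% arch
  latent <- latent_mean + matrix(stats::rnorm(n * L, sd = spec$noise_sd), n, L)

  sample_modality <- function(d) {
    A <- matrix(stats::rnorm(L * d, sd = 1 / sqrt(L)), L, d)
    rate <- log1p(exp(latent %*% A))  # softplus link, non-negative rates
    matrix(stats::rpois(n * d, lambda = rate), n, d)
  }
  x_rna <- sample_modality(spec$d_rna)
  x_atac <- sample_modality(spec$d_atac)
  colnames(x_rna) <- sprintf("gene_%d", seq_len(spec$d_rna))
  colnames(x_atac) <- sprintf("peak_%d", seq_len(spec$d_atac))

  labels <- max.col(memberships, ties.method = "first") - 1L
  ds <- multimodal_dataset(x_rna, x_atac, labels = labels,
                           cell_ids = sprintf("cell_%d", seq_len(n)),
                           n_clusters = k)
  list(dataset = ds, memberships = memberships,
       latent = latent, latent_mean = latent_mean,
       transitional = is_trans)
}

#' Write a generated dataset plus truth files to disk
#'
#' Emits the modality files [load_dataset()] reads, `labels.txt`, and
#' `memberships.csv` (true soft memberships).
#'
#' @param gen result of [generate_dataset()].
#' @param dir output directory.
#' @param format `"csv"` or `"mtx"`.
#' @return `dir`, invisibly.
#' @export
write_synthetic <- function(gen, dir, format = c("csv", "mtx")) {
  format <- match.arg(format)
  write_dataset(gen$dataset, dir, format = format)
  mem <- as.data.frame(gen$memberships)
  colnames(mem) <- sprintf("cluster_%d", seq_len(ncol(mem)) - 1L)
  utils::write.csv(cbind(cell_id = gen$dataset$cell_ids, mem),
                   file.path(dir, "memberships.csv"), row.names = FALSE)
  invisible(dir)
}
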