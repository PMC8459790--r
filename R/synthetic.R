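#' Specification for a synthetic expression dataset
#'
#' The generator emulates the structure of the microarray classification
#' problems this package targets: thousands of genes, tens of samples,
#' optional class imbalance, a small planted set of differentially expressed
#' genes (some carrying the negated signal, i.e. negatively co-expressed with
#' the rest of their block), correlated signal blocks, and Gaussian noise
#' genes.
#'
#' @param n_per_class integer vector of per-class sample counts (imbalance
#'   allowed).
#' @param n_genes total number of genes V.
#' @param n_informative number of planted informative genes (<= V).
#' @param effect_size class-mean shift between adjacent classes, in units of
#'   `noise_sd`.
#' @param anti_correlated_fraction fraction of informative genes carrying the
#'   negated signal.
#' @param block_correlation pairwise correlation (via a shared per-sample
#'   latent factor) among informative genes of the block, in `[0, 1)`.
#' @param noise_sd standard deviation of the Gaussian noise.
#' @param seed integer seed; generation is fully reproducible.
#' @param class_labels optional label strings (default `class1..classN`).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = c(40L, 20L), n_genes = 1000L,
                           n_informative = 20L, effect_size = 3,
                           anti_correlated_fraction = 0.5,
                           block_correlation = 0.7, noise_sd = 1,
                           seed = 1L, class_labels = NULL) {
  n_per_class <- as.integer(n_per_class)
  if (any(n_per_class < 1L) || length(n_per_class) < 2L)
    stop("need >= 2 classes with >= 1 sample each")
  if (n_informative > n_genes) stop("n_informative exceeds n_genes")
  if (anti_correlated_fraction < 0 || anti_correlated_fraction > 1)
    stop("anti_correlated_fraction must be in [0, 1]")
  if (block_correlation < 0 || block_correlation >= 1)
    stop("block_correlation must be in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  class_labels <- class_labels %||%
    paste0("class", seq_along(n_per_class))
  structure(list(n_per_class = n_per_class, n_genes = as.integer(n_genes),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size,
                 anti_correlated_fraction = anti_correlated_fraction,
                 block_correlation = block_correlation, noise_sd = noise_sd,
                 seed = as.integer(seed), class_labels = class_labels),
            class = "synthetic_spec")
}

#' Generate a synthetic expression dataset with known ground truth
#'
#' Noise genes are `Normal(0, noise_sd)`. An informative gene g of a sample
#' in class c is
#' `sign_g * (delta * mu_c + sqrt(rho) * f_s) * noise_sd + sqrt(1 - rho) * e`,
#' where `mu_c` are equally spaced class offsets (0, 1, ...), `f_s` is a
#' standard-normal latent factor shared by all informative genes of the
#' sample (giving pairwise correlation `rho` within the block, negative
#' between opposite-sign genes) and `e ~ Normal(0, noise_sd)`. Marginal
#' variance is `noise_sd^2` for every gene.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (an [expression_dataset()]) and `truth`
#'   (informative gene indices/ids, per-gene signal sign, class mean matrix).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  U <- sum(spec$n_per_class)
  V <- spec$n_genes
  N <- length(spec$n_per_class)
  classes <- rep(spec$class_labels, spec$n_per_class)
  cls_i <- rep(seq_len(N), spec$n_per_class)
  with_seed(spec$seed, {
    X <- matrix(rnorm(U * V, 0, spec$noise_sd), U, V)
    info <- sort(sample.int(V, spec$n_informative))
    n_neg <- round(spec$anti_correlated_fraction * spec$n_informative)
    sign_g <- rep(1, spec$n_informative)
    if (n_neg > 0)
      sign_g[sample.int(spec$n_informative, n_neg)] <- -1
    mu_c <- seq_len(N) - 1                     # class offsets in SD units
    f <- rnorm(U)                              # shared latent factor
    rho <- spec$block_correlation
    for (q in seq_along(info)) {
      e <- rnorm(U, 0, spec$noise_sd)
      X[, info[q]] <- sign_g[q] * (spec$effect_size * mu_c[cls_i] +
                                     sqrt(rho) * f) * spec$noise_sd +
        sqrt(1 - rho) * e
    }
    ds <- expression_dataset(
      X, classes,
      gene_ids = sprintf("g%0*d", nchar(V), seq_len(V)),
      sample_ids = sprintf("s%0*d", nchar(U), seq_len(U)))
    class_means <- outer(sign_g, spec$effect_size * mu_c * spec$noise_sd)
    dimnames(class_means) <- list(ds$gene_ids[info], spec$class_labels)
    list(dataset = ds,
         truth = list(informative = info,
                      informative_ids = ds$gene_ids[info],
                      sign = sign_g, class_means = class_means))
  })
}

#' The frozen reference fixture
#'
#' The dataset used across the test suites and the acceptance run: 60
#' samples (40/20 imbalanced, two classes), 1000 genes of which 20 are
#' informative (half anti-correlated), effect size 3 SD, block correlation
#' 0.7, unit noise, fixed seed. Identical across calls.
#'
#' @return as [generate_expression()].
#' @export
default_fixture <- function() {
  generate_expression(synthetic_spec(
    n_per_class = c(40L, 20L), n_genes = 1000L, n_informative = 20L,
    effect_size = 3, anti_correlated_fraction = 0.5,
    block_correlation = 0.7, noise_sd = 1, seed = 19L,
    class_labels = c("tumor", "normal")))
}
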