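#' Configuration for a simulated maturation time-course count matrix
#'
#' Emulates the structure of a targeted-sequencing count matrix recorded over
#' a neuronal maturation time course: genes x (time points x replicates),
#' negative-binomial counts with a shared dispersion, and a planted fraction
#' of differentially expressed genes whose log2 fold change versus the first
#' time point is drawn from `effect_log2fc_range` (random sign). Defaults are
#' desk-scale: 2000 genes, 7 time points, 3 replicate differentiations.
#'
#' @param n_genes Number of genes.
#' @param n_timepoints Number of time points (first = baseline).
#' @param n_replicates Replicates per time point.
#' @param library_size_mean Mean sequencing depth per sample (reads); actual
#'   depths vary log-normally by ~10%.
#' @param dispersion Shared negative-binomial dispersion (> 0); variance is
#'   `mu + dispersion * mu^2`.
#' @param deg_fraction Fraction of genes with a planted effect, in \[0, 1\].
#' @param effect_log2fc_range Length-2 vector `(lo, hi)` with `lo <= hi`;
#'   planted |log2FC| is uniform on this range, sign random.
#' @param effect_profile `"step"` (full effect at every non-baseline time
#'   point) or `"ramp"` (effect grows linearly with time-point index,
#'   emulating progressive maturation).
#' @param geneset_definitions Optional named list mapping set names to gene
#'   ids (used downstream for scoring); members must be valid gene ids.
#' @param seed Integer seed.
#' @return A `sim_counts_config` list.
#' @export
sim_counts_config <- function(n_genes = 2000, n_timepoints = 7,
                              n_replicates = 3, library_size_mean = 2e6,
                              dispersion = 0.05, deg_fraction = 0.1,
                              effect_log2fc_range = c(1, 3),
                              effect_profile = c("step", "ramp"),
                              geneset_definitions = NULL, seed = 1L) {
  effect_profile <- match.arg(effect_profile)
  if (dispersion <= 0) stop("'dispersion' must be > 0", call. = FALSE)
  if (deg_fraction < 0 || deg_fraction > 1) {
    stop("'deg_fraction' must lie in [0, 1]", call. = FALSE)
  }
  if (length(effect_log2fc_range) != 2L ||
      effect_log2fc_range[1L] > effect_log2fc_range[2L]) {
    stop("'effect_log2fc_range' must be (lo, hi) with lo <= hi", call. = FALSE)
  }
  if (n_genes < 1 || n_timepoints < 2 || n_replicates < 1) {
    stop("need >= 1 gene, >= 2 time points, >= 1 replicate", call. = FALSE)
  }
  gene_ids <- sprintf("gene_%04d", seq_len(n_genes))
  if (!is.null(geneset_definitions)) {
    bad <- setdiff(unlist(geneset_definitions), gene_ids)
    if (length(bad)) {
      stop("gene-set members not in the simulated gene universe: ",
           paste(utils::head(bad, 3), collapse = ", "), call. = FALSE)
    }
  }
  structure(list(n_genes = n_genes, n_timepoints = n_timepoints,
                 n_replicates = n_replicates,
                 library_size_mean = library_size_mean,
                 dispersion = dispersion, deg_fraction = deg_fraction,
                 effect_log2fc_range = effect_log2fc_range,
                 effect_profile = effect_profile,
                 geneset_definitions = geneset_definitions,
                 gene_ids = gene_ids, seed = seed),
            class = "sim_counts_config")
}

#' Simulate a time-course count matrix with planted effects
#'
#' @param cfg A [sim_counts_config()].
#' @return A list of class `sim_counts` with elements `counts` (integer
#'   matrix genes x samples, sample names `T<k>_R<j>`), `sample_info` (data
#'   frame: sample, time_point, replicate), and `truth` (data frame of
#'   planted effects: gene, log2fc; empty when `deg_fraction = 0`).
#' @examples
#' sim <- simulate_counts(sim_counts_config(n_genes = 50, seed = 3))
#' dim(sim$counts)
#' head(sim$truth)
#' @export
simulate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_counts_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes; TT <- cfg$n_timepoints; R <- cfg$n_replicates
  # relative gene abundances, log-normal across genes
  rel <- exp(stats::rnorm(G, 0, 1.5))
  rel <- rel / sum(rel)
  n_deg <- round(cfg$deg_fraction * G)
  deg_idx <- if (n_deg > 0) sort(sample.int(G, n_deg)) else integer(0)
  lfc <- numeric(G)
  if (n_deg > 0) {
    lo <- cfg$effect_log2fc_range[1L]; hi <- cfg$effect_log2fc_range[2L]
    lfc[deg_idx] <- stats::runif(n_deg, lo, hi) *
      sample(c(-1, 1), n_deg, replace = TRUE)
  }
  tp_scale <- switch(cfg$effect_profile,
                     step = c(0, rep(1, TT - 1)),
                     ramp = (seq_len(TT) - 1) / (TT - 1))
  samples <- expand.grid(replicate = seq_len(R), time_point = seq_len(TT))
  sample_ids <- sprintf("T%d_R%d", samples$time_point, samples$replicate)
  lib <- cfg$library_size_mean * exp(stats::rnorm(nrow(samples), 0, 0.1))
  counts <- matrix(0L, G, nrow(samples),
                   dimnames = list(cfg$gene_ids, sample_ids))
  size <- 1 / cfg$dispersion
  for (s in seq_len(nrow(samples))) {
    f <- 2^(lfc * tp_scale[samples$time_point[s]])
    mu <- rel * f
    mu <- mu / sum(mu) * lib[s]
    counts[, s] <- stats::rnbinom(G, mu = mu, size = size)
  }
  truth <- data.frame(gene = cfg$gene_ids[deg_idx], log2fc = lfc[deg_idx])
  sample_info <- data.frame(sample = sample_ids,
                            time_point = samples$time_point,
                            replicate = samples$replicate)
  structure(list(counts = counts, sample_info = sample_info, truth = truth,
                 cfg = cfg),
            class = "sim_counts")
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf("<sim_counts> %d genes x %d samples (%d time points x %d reps), %d planted DEGs\n",
              nrow(x$counts), ncol(x$counts), x$cfg$n_timepoints,
              x$cfg$n_replicates, nrow(x$truth)))
  invisible(x)
}
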