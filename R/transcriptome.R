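#' Counts per million reads (CPM)
#'
#' `cpm = count / sample_total * 1e6`; every column of the result sums to
#' 1e6.
#'
#' @param counts Non-negative matrix, genes x samples.
#' @return Matrix of the same shape.
#' @export
compute_cpm <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  tot <- colSums(counts)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total counts: ",
         paste(colnames(counts)[tot <= 0], collapse = ", "), call. = FALSE)
  }
  sweep(counts, 2L, tot, "/") * 1e6
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up false-discovery-rate adjustment with monotonicity
#' enforcement (delegates to [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must be finite and lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' Differentially-expressed-gene predicate
#'
#' A gene is a DEG iff its BH-adjusted p-value is below `alpha` and its
#' linear fold change is at least `fc_threshold` in either direction
#' (`|log2FC| >= log2(fc_threshold)`).
#'
#' @param log2fc,p_adjusted Numeric vectors.
#' @param alpha Significance level (default 0.05).
#' @param fc_threshold Linear fold-change cutoff (default 2).
#' @return Logical vector.
#' @export
deg_call <- function(log2fc, p_adjusted, alpha = 0.05, fc_threshold = 2) {
  p_adjusted < alpha & abs(log2fc) >= log2(fc_threshold)
}

# pooled-variance two-sample t-test per row; returns two-sided p-values
row_t_test <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, stats::var); v2 <- apply(y, 1L, stats::var)
  df <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  p <- 2 * stats::pt(-abs(tt), df)
  # zero pooled variance: identical groups -> p = 1; separated -> p = 0
  zero <- se == 0
  p[zero & m1 == m2] <- 1
  p[zero & m1 != m2] <- 0
  p
}

#' Per-time-point differential expression versus baseline
#'
#' Simplified differential-expression stand-in operating on CPM: for each
#' non-baseline time point, per gene, the log2 fold change of mean CPM
#' (pseudocount added) versus the baseline time point and a pooled two-sample
#' t-test on `log2(CPM + pseudocount)`; p-values are BH-adjusted across genes
#' within each time point and the DEG filter (adjusted p < `alpha`, fold
#' change >= `fc_threshold`) is applied. Externally computed p-values can be
#' supplied to bypass the built-in test.
#'
#' @param counts Matrix, genes x samples.
#' @param sample_info Data frame with columns `sample`, `time_point`
#'   matching the columns of `counts`.
#' @param baseline Baseline time point; default the smallest.
#' @param pseudocount Added to CPM before log transform (default 1).
#' @param alpha,fc_threshold DEG filter parameters (see [deg_call()]).
#' @param p_values Optional matrix (genes x non-baseline time points) of
#'   precomputed raw p-values to use instead of the built-in test.
#' @return Long data frame: `gene`, `time_point`, `mean_cpm`,
#'   `baseline_cpm`, `log2fc`, `p_value`, `p_adjusted`, `is_deg`.
#' @export
differential_expression <- function(counts, sample_info, baseline = NULL,
                                    pseudocount = 1, alpha = 0.05,
                                    fc_threshold = 2, p_values = NULL) {
  if (!all(c("sample", "time_point") %in% names(sample_info))) {
    stop("'sample_info' needs 'sample' and 'time_point' columns",
         call. = FALSE)
  }
  if (!all(colnames(counts) %in% sample_info$sample)) {
    stop("count matrix columns missing from 'sample_info'", call. = FALSE)
  }
  tp_of <- sample_info$time_point[match(colnames(counts), sample_info$sample)]
  tps <- sort(unique(tp_of))
  if (is.null(baseline)) baseline <- tps[1L]
  if (!baseline %in% tps) stop("baseline time point not present", call. = FALSE)
  cpm <- compute_cpm(counts)
  lcpm <- log2(cpm + pseudocount)
  base_cols <- tp_of == baseline
  if (sum(base_cols) < 2L) {
    stop("need >= 2 replicates at the baseline time point", call. = FALSE)
  }
  base_mean <- rowMeans(cpm[, base_cols, drop = FALSE])
  out <- list()
  for (tp in setdiff(tps, baseline)) {
    cols <- tp_of == tp
    if (sum(cols) < 2L) {
      stop(sprintf("need >= 2 replicates at time point %s", tp),
           call. = FALSE)
    }
    m <- rowMeans(cpm[, cols, drop = FALSE])
    log2fc <- log2((m + pseudocount) / (base_mean + pseudocount))
    p <- if (!is.null(p_values)) {
      p_values[, as.character(tp)]
    } else {
      row_t_test(lcpm[, cols, drop = FALSE], lcpm[, base_cols, drop = FALSE])
    }
    padj <- bh_adjust(p)
    out[[as.character(tp)]] <- data.frame(
      gene = rownames(counts), time_point = tp, mean_cpm = m,
      baseline_cpm = base_mean, log2fc = log2fc, p_value = p,
      p_adjusted = padj,
      is_deg = deg_call(log2fc, padj, alpha, fc_threshold))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hypergeometric over-representation test for one gene set
#'
#' One-sided tail probability of observing at least the realised overlap
#' between the DEG list and a gene set, given the measured gene universe.
#'
#' @param deg_genes Character vector of DEG ids (subset of `universe`).
#' @param set_genes Character vector of gene-set member ids (subset of
#'   `universe`).
#' @param universe Character vector of all measured gene ids.
#' @return List with `overlap`, `n_deg`, `n_set`, `n_universe`, `p_value`.
#' @export
over_representation <- function(deg_genes, set_genes, universe) {
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  universe <- unique(universe)
  deg_genes <- unique(deg_genes); set_genes <- unique(set_genes)
  if (!all(deg_genes %in% universe) || !all(set_genes %in% universe)) {
    stop("DEG list and gene set must be subsets of the universe",
         call. = FALSE)
  }
  k <- length(intersect(deg_genes, set_genes))
  m <- length(set_genes); K <- length(deg_genes); N <- length(universe)
  p <- stats::phyper(k - 1, m, N - m, K, lower.tail = FALSE)
  list(overlap = k, n_deg = K, n_set = m, n_universe = N,
       p_value = min(p, 1))
}

#' Identify over-represented gene sets (oGOs) among the DEGs
#'
#' Tests every gene set against the DEG list (members restricted to the
#' measured universe), BH-adjusts across sets, and flags sets with adjusted
#' p below `alpha` as over-represented. Optionally keeps only the `top_n`
#' sets with the smallest p-values.
#'
#' @param deg_genes Character vector of DEG ids.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]); members outside the universe are dropped with a warning.
#' @param universe Character vector of measured gene ids.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param top_n Optional cap on the number of over-represented sets,
#'   ranked by p-value (default 50; `NULL` = no cap).
#' @return Data frame: `set`, `n_set_measured`, `overlap`, `p_value`,
#'   `p_adjusted`, `over_represented`.
#' @export
find_ogo <- function(deg_genes, gene_sets, universe, alpha = 0.05,
                     top_n = 50) {
  deg_genes <- intersect(deg_genes, universe)
  measured <- lapply(gene_sets, intersect, universe)
  dropped <- sum(lengths(gene_sets) - lengths(measured))
  if (dropped > 0) {
    warning(sprintf("%d gene-set members not measured; scoring on the %s",
                    dropped, "measured subset"), call. = FALSE)
  }
  nonempty <- lengths(measured) > 0L
  measured <- measured[nonempty]
  res <- lapply(names(measured), function(s) {
    h <- over_representation(deg_genes, measured[[s]], universe)
    data.frame(set = s, n_set_measured = h$n_set, overlap = h$overlap,
               p_value = h$p_value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p_value)
  out$over_represented <- out$p_adjusted < alpha
  if (!is.null(top_n)) {
    ord <- order(out$p_value)
    keep_rank <- seq_len(nrow(out)) %in% ord[seq_len(min(top_n, nrow(out)))]
    out$over_represented <- out$over_represented & keep_rank
  }
  out[order(out$p_value), ]
}

#' Activation score of one gene set at one time point
#'
#' The score multiplies the percentage of measured set members that are
#' significantly regulated (DEGs) with the average fold change of those
#' regulations. By default the average fold change is the mean |log2FC| over
#' the DEG members (symmetric in up-/down-regulation); linear and signed
#' variants are available. The score is 0 when no member is a DEG.
#'
#' @param set_genes Character vector of gene-set member ids.
#' @param stats_tp Data frame for a single time point with columns `gene`,
#'   `log2fc`, `is_deg` (one row per measured gene).
#' @param fc_type `"abs_log2"` (default), `"linear"` (mean of `2^|log2FC|`)
#'   or `"signed_log2"`.
#' @return List with `score`, `pct_significant`, `mean_fold_change`,
#'   `n_measured`, `n_deg`.
#' @examples
#' st <- data.frame(gene = letters[1:10],
#'                  log2fc = c(1, 2, 3, 2, rep(0, 6)),
#'                  is_deg = c(rep(TRUE, 4), rep(FALSE, 6)))
#' activation_score(letters[1:10], st)$score   # 40% x 2.0 = 80
#' @export
activation_score <- function(set_genes, stats_tp,
                             fc_type = c("abs_log2", "linear", "signed_log2")) {
  fc_type <- match.arg(fc_type)
  idx <- stats_tp$gene %in% set_genes
  n_measured <- sum(idx)
  if (n_measured == 0L) {
    stop("no gene-set member measured at this time point", call. = FALSE)
  }
  sub <- stats_tp[idx, , drop = FALSE]
  degs <- sub[sub$is_deg, , drop = FALSE]
  n_deg <- nrow(degs)
  pct <- 100 * n_deg / n_measured
  mfc <- if (n_deg == 0L) 0 else switch(fc_type,
    abs_log2 = mean(abs(degs$log2fc)),
    linear = mean(2^abs(degs$log2fc)),
    signed_log2 = mean(degs$log2fc))
  list(score = pct * mfc, pct_significant = pct, mean_fold_change = mfc,
       n_measured = n_measured, n_deg = n_deg)
}

#' Activation-score matrix (gene sets x time points)
#'
#' @param gene_sets Named list of member-id vectors.
#' @param stats Long differential-expression table from
#'   [differential_expression()].
#' @param fc_type Passed to [activation_score()].
#' @return Numeric matrix, sets x time points (baseline excluded).
#' @export
score_matrix <- function(gene_sets, stats, fc_type = "abs_log2") {
  tps <- sort(unique(stats$time_point))
  out <- matrix(NA_real_, length(gene_sets), length(tps),
                dimnames = list(names(gene_sets), as.character(tps)))
  for (tp in tps) {
    st <- stats[stats$time_point == tp, , drop = FALSE]
    for (s in names(gene_sets)) {
      out[s, as.character(tp)] <-
        activation_score(gene_sets[[s]], st, fc_type = fc_type)$score
    }
  }
  out
}

#' Superordinate-group activation-score trajectories
#'
#' Averages the activation scores of all over-represented gene sets assigned
#' to the same superordinate group (e.g. "Synapse signaling",
#' "Neurotransmitter") per time point, with SEM across member sets, and
#' tests each time point against a reference time point by a paired t-test
#' over member sets (pairing by set id).
#'
#' @param scores Matrix, sets x time points (from [score_matrix()]).
#' @param groups Named character vector mapping set id -> group.
#' @param reference_tp Reference time point (column name of `scores`).
#' @return Data frame: `group`, `time_point`, `n_sets`, `mean`, `sem`,
#'   `p_value` (NA at the reference itself; SEM NA for single-set groups).
#' @export
group_trajectories <- function(scores, groups, reference_tp) {
  reference_tp <- as.character(reference_tp)
  if (!reference_tp %in% colnames(scores)) {
    stop("reference time point not in the score matrix", call. = FALSE)
  }
  groups <- groups[names(groups) %in% rownames(scores)]
  out <- list()
  for (g in unique(groups)) {
    members <- names(groups)[groups == g]
    sub <- scores[members, , drop = FALSE]
    ref <- sub[, reference_tp]
    for (tp in colnames(scores)) {
      v <- sub[, tp]
      sem <- if (length(v) >= 2L) stats::sd(v) / sqrt(length(v)) else NA_real_
      p <- if (tp == reference_tp || length(v) < 2L) NA_real_ else {
        d <- v - ref
        if (stats::sd(d) == 0) {
          if (all(d == 0)) 1 else 0
        } else {
          stats::t.test(v, ref, paired = TRUE)$p.value
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        group = g, time_point = tp, n_sets = length(v), mean = mean(v),
        sem = sem, p_value = p)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' PCA of the most variable genes
#'
#' Selects the `n` genes with the highest variance of `log2(CPM + 1)` across
#' samples, centres them, and returns the sample coordinates on the first
#' two principal components together with the explained-variance fractions.
#'
#' @param cpm CPM matrix, genes x samples (>= 3 samples).
#' @param n Number of top-variance genes (clamped to the gene count with a
#'   warning).
#' @return List with `coords` (data frame: sample, PC1, PC2),
#'   `explained_variance` (fractions for PC1 and PC2) and `genes_used`.
#' @export
top_variable_pca <- function(cpm, n = 500) {
  if (ncol(cpm) < 3L) stop("need >= 3 samples for a PCA", call. = FALSE)
  if (n > nrow(cpm)) {
    warning(sprintf("only %d genes available; using all", nrow(cpm)),
            call. = FALSE)
    n <- nrow(cpm)
  }
  l <- log2(cpm + 1)
  v <- apply(l, 1L, stats::var)
  top <- names(sort(v, decreasing = TRUE))[seq_len(n)]
  pc <- stats::prcomp(t(l[top, , drop = FALSE]), center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  list(coords = data.frame(sample = colnames(cpm),
                           PC1 = pc$x[, 1L], PC2 = pc$x[, 2L]),
       explained_variance = ev[1:2], genes_used = top)
}
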