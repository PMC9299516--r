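test_that("CPM is counts per million with exact column sums", {
  counts <- matrix(c(10, 999990, 500, 500), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  cpm <- compute_cpm(counts)
  expect_equal(cpm["g1", "s1"], 10)     # 10 reads in a 1e6-read sample
  expect_equal(unname(colSums(cpm)), c(1e6, 1e6))
  zero_gene <- rbind(counts, g3 = c(0, 0))
  expect_true(all(compute_cpm(zero_gene)["g3", ] == 0))
  bad <- cbind(counts, s3 = c(0, 0))
  expect_error(compute_cpm(bad), "zero total")
})

test_that("BH adjustment matches the worked example and its properties", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(2)
  p <- runif(30)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))  # order-preserving
})

test_that("BH adjustment agrees with the exhaustive step-up oracle", {
  for (s in 1:200) {
    set.seed(s)
    p <- runif(sample(1:20, 1))
    expect_equal(bh_adjust(p), bh_step_up(p), tolerance = 1e-12)
  }
})

test_that("hypergeometric enrichment matches exact enumeration", {
  # all 5 DEGs inside a 5-gene set from a 20-gene universe: p = 1 / C(20,5)
  uni <- sprintf("g%02d", 1:20)
  res <- over_representation(uni[1:5], uni[1:5], uni)
  expect_equal(res$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  # degenerate: DEG set = gene set = universe -> p = 1, no error
  expect_equal(over_representation(uni, uni, uni)$p_value, 1)
  # overlap at exactly its expectation is unremarkable (p >= 0.5)
  uni30 <- sprintf("g%02d", 1:20)
  res_e <- over_representation(uni30[1:10], uni30[c(1:5, 11:15)], uni30)
  expect_equal(res_e$overlap, 5)  # E[overlap] = 10 * 10 / 20 = 5
  expect_gte(res_e$p_value, 0.5)
  # random small instances vs the enumeration oracle
  for (s in 1:50) {
    set.seed(s)
    N <- sample(10:30, 1)
    uni <- sprintf("g%02d", seq_len(N))
    deg <- sample(uni, sample(0:N, 1))
    gs <- sample(uni, sample(1:N, 1))
    got <- over_representation(deg, gs, uni)
    k <- length(intersect(deg, gs))
    expect_equal(got$p_value,
                 if (k == 0) 1 else hyper_tail(k, length(gs), N, length(deg)),
                 tolerance = 1e-12)
  }
})

test_that("the DEG filter keeps exactly the genes with fold change >= 2", {
  fc <- c(1.2, 1.5, 1.9, 2.0, 3.0)
  is_deg <- deg_call(log2(fc), p_adjusted = rep(0.001, 5))
  expect_identical(is_deg, fc >= 2)
  # down-regulation passes symmetrically; the filter is a pure predicate
  expect_true(deg_call(-1.5, 0.01))
  expect_false(deg_call(1.5, 0.06))
  expect_identical(deg_call(log2(fc), rep(0.001, 5)), is_deg)
})

test_that("differential expression is null on identical groups", {
  set.seed(5)
  base <- matrix(rnbinom(200 * 3, mu = 50, size = 20), 200, 3)
  counts <- cbind(base, base)
  rownames(counts) <- sprintf("g%03d", 1:200)
  colnames(counts) <- sprintf("T%d_R%d", rep(1:2, each = 3), rep(1:3, 2))
  si <- data.frame(sample = colnames(counts),
                   time_point = rep(1:2, each = 3))
  st <- differential_expression(counts, si)
  expect_true(all(abs(st$log2fc) < 1e-12))
  expect_true(all(st$p_value > 0.99))
  expect_false(any(st$is_deg))
})

test_that("planted DEGs are recovered with high sensitivity and low FDR", {
  cfg <- sim_counts_config(n_genes = 2000, n_timepoints = 2,
                           n_replicates = 3, dispersion = 0.02,
                           deg_fraction = 0.05,
                           effect_log2fc_range = c(1.5, 3), seed = 21)
  sim <- simulate_counts(cfg)
  st <- differential_expression(sim$counts, sim$sample_info)
  called <- st$gene[st$is_deg]
  truth <- sim$truth$gene
  sensitivity <- length(intersect(called, truth)) / length(truth)
  fdr <- if (length(called)) length(setdiff(called, truth)) / length(called)
         else 0
  expect_gte(sensitivity, 0.8)
  expect_lte(fdr, 0.1)
})

test_that("the activation score is the product of its two factors", {
  st <- data.frame(gene = sprintf("g%02d", 1:10),
                   log2fc = c(1, 2, 3, 2, rep(0.1, 6)),
                   is_deg = c(rep(TRUE, 4), rep(FALSE, 6)))
  sc <- activation_score(st$gene, st)
  expect_equal(sc$pct_significant, 40)
  expect_equal(sc$mean_fold_change, 2)
  expect_equal(sc$score, 80)
  # no DEG members -> score 0
  st0 <- st; st0$is_deg <- FALSE
  expect_equal(activation_score(st0$gene, st0)$score, 0)
  # all members DEGs at |log2FC| = 1 -> 100 x 1
  st1 <- data.frame(gene = st$gene, log2fc = c(rep(1, 5), rep(-1, 5)),
                    is_deg = TRUE)
  expect_equal(activation_score(st1$gene, st1)$score, 100)
  # membership restricted to measured genes; none measured is an error
  expect_error(activation_score(c("absent1", "absent2"), st), "measured")
  # independent recomputation of the product
  sub <- st[st$gene %in% st$gene[1:10], ]
  expect_equal(sc$score,
               100 * sum(sub$is_deg) / nrow(sub) *
                 mean(abs(sub$log2fc[sub$is_deg])))
})

test_that("group trajectories report means, SEM and paired tests vs reference", {
  scores <- rbind(set_a = c(10, 10, 30), set_b = c(20, 20, 41))
  colnames(scores) <- c("2", "3", "4")
  groups <- c(set_a = "Synapse signaling", set_b = "Synapse signaling")
  tr <- group_trajectories(scores, groups, reference_tp = "2")
  at2 <- tr[tr$time_point == "2", ]
  expect_equal(at2$mean, 15)
  expect_equal(at2$sem, 5)
  expect_true(is.na(at2$p_value))       # the reference itself
  at3 <- tr[tr$time_point == "3", ]
  expect_equal(at3$p_value, 1)          # identical to reference
  at4 <- tr[tr$time_point == "4", ]
  expect_lt(at4$p_value, 0.05)          # consistent planted increase
})

test_that("monotone planted score increases become significant vs reference", {
  set.seed(8)
  tps <- as.character(2:6)
  n_sets <- 6
  scores <- t(vapply(seq_len(n_sets), function(i) {
    10 + 8 * (seq_along(tps) - 1) + rnorm(length(tps), 0, 1)
  }, numeric(length(tps))))
  dimnames(scores) <- list(sprintf("set_%d", seq_len(n_sets)), tps)
  groups <- setNames(rep("Neurotransmitter", n_sets), rownames(scores))
  tr <- group_trajectories(scores, groups, reference_tp = "2")
  late <- tr[tr$time_point %in% c("5", "6"), "p_value"]
  expect_true(all(late < 0.05))
})

test_that("PCA of top-variance genes reflects a maturation gradient", {
  cfg <- sim_counts_config(n_genes = 600, n_timepoints = 5, n_replicates = 3,
                           deg_fraction = 0.2, effect_profile = "ramp",
                           dispersion = 0.02, seed = 13)
  sim <- simulate_counts(cfg)
  cpm <- compute_cpm(sim$counts)
  pca <- top_variable_pca(cpm, n = 500)
  tp <- sim$sample_info$time_point[match(pca$coords$sample,
                                         sim$sample_info$sample)]
  expect_gte(abs(cor(pca$coords$PC1, tp)), 0.9)
  expect_lte(sum(pca$explained_variance), 1)
  # duplicated samples get identical coordinates
  cpm2 <- cbind(cpm, dup = cpm[, 1])
  colnames(cpm2) <- c(colnames(cpm), "dup")
  pca2 <- top_variable_pca(cpm2, n = 500)
  expect_equal(unname(unlist(pca2$coords[pca2$coords$sample == "dup",
                                         c("PC1", "PC2")])),
               unname(unlist(pca2$coords[1, c("PC1", "PC2")])))
  # n larger than the gene count clamps with a warning
  expect_warning(top_variable_pca(cpm[1:50, ], n = 500), "available")
})

test_that("over-represented sets are found and capped by rank", {
  uni <- sprintf("g%03d", 1:200)
  deg <- uni[1:20]
  sets <- list(hit = uni[1:15],                 # strongly enriched
               miss = uni[101:120],             # disjoint from DEGs
               partial = uni[c(1:3, 150:160)])
  res <- suppressWarnings(find_ogo(deg, sets, uni))
  expect_true(res$over_represented[res$set == "hit"])
  expect_false(res$over_represented[res$set == "miss"])
  res_top <- find_ogo(deg, sets, uni, top_n = 1)
  expect_equal(sum(res_top$over_represented), 1)
})
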