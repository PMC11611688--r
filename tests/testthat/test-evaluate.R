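test_that("mixing score formula hits its analytic endpoints", {
  expect_equal(mixing_score_from_counts(500, 500), 1)
  expect_equal(mixing_score_from_counts(1000, 0), 0.5)
  expect_equal(mixing_score_from_counts(0, 1000), 0.5)
  expect_equal(mixing_score_from_counts(750, 250), 0.75)
})

test_that("the kNN mixing score reflects the neighbourhood composition and
          stays in [0.5, 1]", {
  # probe cell alone in its own type; its 100 neighbours split 50/50
  set.seed(2)
  base <- rnorm(5)
  nbrs <- matrix(rep(base, each = 100), 100, 5) +
    matrix(rnorm(500, sd = 1e-3), 100, 5)
  emb <- rbind(base, nbrs)
  modality <- c("RNA", rep(c("RNA", "ATAC"), 50))
  types <- c("probe", rep("bulk", 100))
  sc <- modality_mixing_score(emb, modality, types, n_neighbors = 100,
                              n_draws = 5, seed = 3)
  expect_equal(sc$score[sc$cell_type == "probe"], 1)
  # all-one-modality neighbourhood scores 0.5
  modality2 <- c("RNA", rep("ATAC", 100))
  sc2 <- modality_mixing_score(emb, modality2, types, n_neighbors = 100,
                               n_draws = 5, seed = 3)
  expect_equal(sc2$score[sc2$cell_type == "probe"], 0.5)
  # random embedding: every score within the admissible range
  emb_r <- matrix(rnorm(400), 80, 5)
  sc3 <- modality_mixing_score(emb_r, rep(c("RNA", "ATAC"), 40),
                               rep(c("a", "b"), each = 40),
                               n_neighbors = 20, n_draws = 10, seed = 4)
  expect_true(all(sc3$score >= 0.5 & sc3$score <= 1))
  # small populations fall back with a warning
  expect_warning(
    modality_mixing_score(emb_r, rep(c("RNA", "ATAC"), 40),
                          rep("a", 80), n_neighbors = 500, n_draws = 2,
                          seed = 1),
    "fewer than")
})

test_that("global homogeneity: separated identical clusters score silhouette
          1, label-identical clusterings score ARI/AMI 1, random labels score
          near 0", {
  emb <- rbind(matrix(rep(c(1, 0, 0), each = 10), 10, 3),
               matrix(rep(c(0, 1, 0), each = 10), 10, 3))
  labels <- rep(c("a", "b"), each = 10)
  h <- global_homogeneity(emb, labels,
                          cluster_fun = function(x, k) {
                            as.integer(factor(labels))
                          })
  expect_equal(h$silhouette, 1)
  expect_equal(h$ari, 1)
  expect_equal(h$ami, 1)
  expect_error(global_homogeneity(emb, rep("a", 20)), "single label")

  # ARI near zero for independent random labelings (Monte-Carlo check)
  set.seed(5)
  aris <- replicate(30, {
    scxlate:::adjusted_rand_index(sample(1:3, 60, TRUE),
                                  sample(1:3, 60, TRUE))
  })
  expect_lt(abs(mean(aris)), 0.05)
  # agreement with the mclust implementation on random partitions
  skip_if_not_installed("mclust")
  for (i in 1:5) {
    a <- sample(1:4, 40, TRUE)
    b <- sample(1:3, 40, TRUE)
    expect_equal(scxlate:::adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  # AMI of a labeling with itself is 1; of independent labelings ~ 0
  a <- sample(1:3, 50, TRUE)
  expect_equal(scxlate:::adjusted_mutual_information(a, a), 1,
               tolerance = 1e-10)
  amis <- replicate(30, {
    scxlate:::adjusted_mutual_information(sample(1:3, 60, TRUE),
                                          sample(1:3, 60, TRUE))
  })
  expect_lt(abs(mean(amis)), 0.05)
})

test_that("pairwise cosine distances: zeros for identical cells, one for
          orthogonal pairs, subsampling agrees with the exhaustive
          computation", {
  emb_same <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  emb_orth <- rbind(diag(3), diag(3))[, 1:3]
  labels <- rep("t", 6)
  res <- pairwise_cosine_test(emb_same, emb_orth + rnorm(18, sd = 1e-9),
                              labels)
  d_a <- res$distances$distance[res$distances$method == "a"]
  expect_equal(d_a, rep(0, length(d_a)), tolerance = 1e-12)
  # orthogonal unit vectors have cosine distance exactly 1
  d_orth <- scxlate:::cosine_distance(diag(3))
  expect_equal(d_orth[upper.tri(d_orth)], rep(1, 3))

  set.seed(6)
  emb1 <- matrix(rnorm(50 * 4), 50, 4)
  emb2 <- emb1 + rnorm(200, sd = 0.5)
  lab <- rep("x", 50)
  exact <- pairwise_cosine_test(emb1, emb2, lab, max_pairs = 1e6)
  sub <- pairwise_cosine_test(emb1, emb2, lab, max_pairs = 200, seed = 8)
  se <- sd(exact$distances$distance[exact$distances$method == "a"]) /
    sqrt(200)
  expect_lt(abs(sub$tests$mean_a - exact$tests$mean_a), 3 * se)
  expect_true(all(c("t_p_value", "f_p_value") %in% names(sub$tests)))
})

test_that("translation AUROC matches its analytic endpoints, a null
          simulation, the pROC oracle, and is rank-invariant", {
  set.seed(7)
  truth <- matrix(rbinom(200, 1, 0.4), 10, 20)
  expect_equal(translation_auroc(truth, truth)$auroc[1], 1)
  expect_equal(translation_auroc(1 - truth, truth)$auroc[1], 0)
  # random scores on random truth: 0.5 within Monte-Carlo tolerance
  big_truth <- matrix(rbinom(10000, 1, 0.5), 100, 100)
  big_p <- matrix(runif(10000), 100, 100)
  expect_lt(abs(translation_auroc(big_p, big_truth)$auroc[1] - 0.5), 0.02)
  # strictly monotone transforms leave the AUROC unchanged
  p <- matrix(runif(200), 10, 20)
  a1 <- translation_auroc(p, truth)$auroc[1]
  expect_equal(translation_auroc(plogis(5 * p - 2), truth)$auroc[1], a1)
  skip_if_not_installed("pROC")
  a_oracle <- as.numeric(pROC::auc(as.numeric(truth), as.numeric(p),
                                   direction = "<", quiet = TRUE))
  expect_equal(a1, a_oracle, tolerance = 1e-12)
  # degenerate truth reported as NA; per-type rows present
  expect_true(is.na(translation_auroc(p, matrix(1, 10, 20))$auroc[1]))
  by_type <- translation_auroc(p, truth, group_labels = rep(c("a", "b"), 5))
  expect_equal(nrow(by_type), 3)
})

test_that("translation R-squared is 1 for exact and affine predictions and
          matches the textbook formula", {
  set.seed(8)
  truth <- matrix(rpois(300, 4), 15, 20)
  expect_equal(translation_r2(truth, truth)$r_squared[1], 1)
  expect_equal(translation_r2(3 * truth + 2, truth)$r_squared[1], 1)
  pred <- truth + matrix(rnorm(300), 15, 20)
  r2 <- translation_r2(pred, truth)$r_squared[1]
  mx <- colMeans(pred); my <- colMeans(truth)
  oracle <- (sum((mx - mean(mx)) * (my - mean(my))) /
               sqrt(sum((mx - mean(mx))^2) * sum((my - mean(my))^2)))^2
  expect_equal(r2, oracle, tolerance = 1e-12)
  expect_true(is.na(translation_r2(matrix(1, 15, 20), truth)$r_squared[1]))
  ct <- translation_r2(pred, truth, group_labels = rep(c("a", "b", "c"), 5),
                       level = "celltype")
  expect_equal(nrow(ct), 4)
})

test_that("motif activation scores are windowed, strand-aware, weighted
          means of accessibility", {
  # 4 peaks on chr1 at midpoints ~1250, 301250, 701250, 801250
  ann <- data.frame(chrom = "chr1",
                    start = c(1000, 301000, 701000, 801000),
                    end = c(1500, 301500, 701500, 801500))
  v <- matrix(c(1, 1, 1, 1,
                0, 1, 1, 0), 2, 4, byrow = TRUE)
  atac <- omics_matrix(v, "ATAC", feature_ids = format_peak_names(ann),
                       cell_meta = data.frame(cell_id = c("c1", "c2"),
                                              cell_type = c("x", "y")))
  tss <- data.frame(gene = "g1", chrom = "chr1", pos = 760000, strand = "+")
  out <- motif_activation_score(atac, tss, window_bp = 750000)
  # window [10000, 760000] upstream of + strand: peaks 2 and 3 only
  expect_equal(out$n_peaks_in_window, c(2L, 2L))
  expect_equal(out$score[out$cell_type == "x"], 1)     # both accessible
  expect_equal(out$score[out$cell_type == "y"], 1)     # cell 2: both open
  # a peak 800k upstream is excluded
  tss2 <- data.frame(gene = "g2", chrom = "chr1", pos = 801500,
                     strand = "+")
  out2 <- motif_activation_score(atac, tss2, window_bp = 750000)
  expect_false(any(out2$n_peaks_in_window > 3))
  # mixed accessibility: 0 and 1 average to 0.5
  v3 <- matrix(c(0, 0, 1, 0), 1, 4)
  atac3 <- omics_matrix(v3, "ATAC", feature_ids = format_peak_names(ann),
                        cell_meta = data.frame(cell_id = "c1"))
  out3 <- motif_activation_score(atac3, tss, window_bp = 750000)
  expect_equal(out3$score, 0.5)
  # minus strand looks downstream in coordinates; empty window warns -> NA
  tss_m <- data.frame(gene = "g3", chrom = "chr1", pos = 900000,
                      strand = "-")
  expect_warning(out_m <- motif_activation_score(atac3, tss_m,
                                                 window_bp = 50000),
                 "no peaks")
  expect_true(is.na(out_m$score[1]))
  # unstranded genes fall back to a symmetric window
  tss_u <- data.frame(gene = "g4", chrom = "chr1", pos = 760000)
  expect_message(out_u <- motif_activation_score(atac3, tss_u,
                                                 window_bp = 750000),
                 "symmetric")
  # symmetric window [10000, 1510000]: the 1250-midpoint peak stays outside
  expect_equal(out_u$n_peaks_in_window[1], 3L)
})

test_that("peak-to-gene linkage recovers a planted pseudo-bulk relation and
          rejects degenerate inputs", {
  set.seed(9)
  n_groups <- 7
  cells_per <- 30
  n <- n_groups * cells_per
  groups <- rep(sprintf("g%d", 1:n_groups), each = cells_per)
  # group-level driver: accessibility of peak 1 and expression of the gene
  # rise together across groups
  driver <- seq(0.15, 0.85, length.out = n_groups)
  acc <- cbind(rbinom(n, 1, driver[as.integer(factor(groups))]),
               matrix(rbinom(n * 3, 1, 0.4), n, 3))
  ann <- data.frame(chrom = "chr1",
                    start = c(5000, 20000, 40000, 900000),
                    end = c(5500, 20500, 40500, 900500))
  atac <- omics_matrix(acc, "ATAC", feature_ids = format_peak_names(ann),
                       cell_meta = data.frame(cell_id = sprintf("a%03d", 1:n),
                                              cell_type = groups))
  expr <- matrix(rpois(n, 5 + 20 * driver[as.integer(factor(groups))]),
                 n, 1)
  rna <- omics_matrix(expr, "RNA", feature_ids = "geneX",
                      cell_meta = data.frame(cell_id = sprintf("r%03d", 1:n),
                                             cell_type = groups))
  links <- peak_gene_linkage(atac, rna, "geneX",
                             gene_pos = list(chrom = "chr1", pos = 10000),
                             span_bp = 100000)
  expect_equal(nrow(links), 3)            # the 900kb peak is out of span
  planted <- links[links$peak_index == 1, ]
  expect_gt(planted$correlation, 0)
  expect_true(planted$significant)
  # constant accessibility gives a null correlation
  acc2 <- acc; acc2[, 2] <- 1
  atac2 <- omics_matrix(acc2, "ATAC", feature_ids = format_peak_names(ann),
                        cell_meta = atac$cell_meta)
  links2 <- peak_gene_linkage(atac2, rna, "geneX",
                              gene_pos = list(chrom = "chr1", pos = 10000))
  expect_true(is.na(links2$correlation[links2$peak_index == 2]))
  # a perfectly proportional pseudo-bulk relation gives r = 1
  pb_acc <- matrix(rep(driver[as.integer(factor(groups))], 2), n, 2)
  atac3 <- omics_matrix(pb_acc, "ATAC",
                        feature_ids = format_peak_names(ann[1:2, ]),
                        cell_meta = atac$cell_meta)
  rna3 <- omics_matrix(matrix(2 * driver[as.integer(factor(groups))] + 1),
                       "RNA", feature_ids = "geneX",
                       cell_meta = rna$cell_meta)
  links3 <- peak_gene_linkage(atac3, rna3, "geneX",
                              gene_pos = list(chrom = "chr1", pos = 10000))
  expect_equal(links3$correlation, rep(1, 2), tolerance = 1e-10)
  # fewer than 3 groups is an error
  two <- atac[groups %in% c("g1", "g2"), ]
  rna_two <- rna[groups %in% c("g1", "g2"), ]
  expect_error(peak_gene_linkage(two, rna_two, "geneX",
                                 gene_pos = list(chrom = "chr1", pos = 1e4)),
               ">= 3")
})
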