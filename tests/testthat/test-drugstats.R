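null_means <- function(conds = c("DMSO", "c1", "c2", "c3"),
                       conc = c(0, 1, 3, 10)) {
  tibble::tibble(condition = conds, concentration = conc,
                 n_nb = 20, total_spikes = 100)
}

test_that("parameter tables assemble, order, and flag missing cells", {
  gm <- null_means()
  tb <- gen_param_samples(gm, n_per_group = 6, sd = 2, seed = 1)
  expect_identical(nrow(tb), 24L)
  expect_identical(setdiff(names(tb), c("sample_id", "condition",
                                        "concentration")),
                   burst_metric_names())
  expect_true(!is.unsorted(tb$condition))

  m <- compute_metrics(
    tibble::tibble(electrode_id = 1L, time_s = 0.5, amplitude_uV = -50),
    detect_network_bursts(
      tibble::tibble(electrode_id = 1L, time_s = 0.5,
                     amplitude_uV = -50)), 10)
  bt <- build_param_table(list(m, m), sample_id = c("a", "b"),
                          condition = "DMSO")
  expect_true(is.na(bt$cv_imfi[1]))   # NaN-flagged metric became NA
  expect_error(build_param_table(list(m, m), sample_id = "a",
                                 condition = "DMSO"), "duplicate")
})

test_that("Dunnett comparisons detect planted shifts and are adjusted", {
  gm <- null_means()
  gm$n_nb <- c(20, 20, 24, 30)
  tb <- gen_param_samples(gm, n_per_group = 8, sd = 2, seed = 7)
  hd <- anova_dunnett(tb, "n_nb", "DMSO")
  expect_identical(nrow(hd), 3L)
  top <- hd[hd$condition == "c3", ]
  expect_lt(top$p_adj, 0.01)
  expect_identical(top$tier, "**")
  expect_identical(top$direction, 1)

  # adjustment monotonicity: adjusted p >= unadjusted p for the same
  # model-based comparisons
  d <- data.frame(y = tb$n_nb,
                  g = factor(tb$condition,
                             levels = c("DMSO", "c1", "c2", "c3")))
  gl <- multcomp::glht(aov(y ~ g, data = d),
                       linfct = multcomp::mcp(g = "Dunnett"))
  p_raw <- summary(gl, test = multcomp::adjusted("none"))$test$pvalues
  expect_true(all(hd$p_adj + 1e-6 >= unname(p_raw)))

  # identical data in every group: F = 0, all p = 1
  tb0 <- tb
  for (m in burst_metric_names()) tb0[[m]] <- rep(1:8, 4)
  hd0 <- anova_dunnett(tb0, "n_nb", "DMSO")
  expect_true(all(hd0$p_adj > 0.9))
  tbc <- tb; tbc$n_nb <- 5
  hdc <- anova_dunnett(tbc, "n_nb", "DMSO")
  expect_true(all(hdc$p_adj == 1))
  expect_identical(attr(hdc, "f_value"), 0)

  expect_error(anova_dunnett(tb, "n_nb", "vehicle"), "control")
  expect_error(anova_dunnett(tb, "nope", "DMSO"), "unknown parameter")
})

test_that("a planted shift is flagged in nearly all replicates", {
  hits <- 0L
  for (r in 1:100) {
    gm <- null_means()
    gm$n_nb <- c(0, 0, 0, 3)       # one group shifted by 3 SD
    tb <- gen_param_samples(gm, n_per_group = 8, sd = 1, seed = 5000 + r)
    hd <- anova_dunnett(tb, "n_nb", "DMSO")
    if (hd$p_adj[hd$condition == "c3"] < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("the heat map stacks one row per parameter and condition", {
  tb <- gen_param_samples(null_means(), n_per_group = 6, sd = 1, seed = 3)
  hm <- dunnett_heatmap(tb, "DMSO")
  expect_identical(nrow(hm), 10L * 3L)
  expect_true(all(hm$p_adj > 0 & hm$p_adj <= 1))
  expect_true(all(hm$tier[hm$p_adj >= 0.05] == ""))
  p <- plot_dunnett_heatmap(hm)
  expect_s3_class(p, "ggplot")
})

test_that("PCA matches the SVD oracle and its invariances", {
  tb <- gen_param_samples(null_means(), n_per_group = 8, sd = 1, seed = 13)
  pc <- pca5(tb)

  # orthonormal loadings
  expect_equal(crossprod(pc$loadings), diag(5), tolerance = 1e-10,
               ignore_attr = TRUE)
  # explained variance non-increasing, sums to 1
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_equal(sum(pc$explained), 1)

  # SVD oracle: identical scores up to the fixed sign convention
  X <- as.matrix(tb[, rownames(pc$loadings)])
  Z <- scale(X)
  sv <- svd(Z)
  or <- Z %*% sv$v
  expect_equal(abs(unname(pc$all_scores)), abs(or), tolerance = 1e-10)

  # row permutation leaves scores attached to their rows
  perm <- sample(nrow(tb))
  pc2 <- pca5(tb[perm, ])
  expect_equal(pc2$scores$PC1[order(pc2$scores$sample_id)],
               pc$scores$PC1[order(pc$scores$sample_id)])

  # affine rescaling of a column changes nothing (z-scoring)
  tb3 <- tb
  tb3$total_spikes <- tb3$total_spikes * 1000 + 5
  pc3 <- pca5(tb3)
  expect_equal(pc3$scores$PC1, pc$scores$PC1, tolerance = 1e-9)

  # rank-1 data: PC1 explains everything
  tbl1 <- tb
  base <- seq_len(nrow(tb))
  tbl1$total_spikes <- base; tbl1$mean_nb_duration_s <- 2 * base
  tbl1$mean_imfi_s <- -base; tbl1$cv_nb_duration <- 0.5 * base
  tbl1$cv_spikes_per_nb <- 3 * base
  pcl <- pca5(tbl1)
  expect_equal(pcl$explained[1], 1, tolerance = 1e-10)

  # zero-variance column dropped with a warning
  tb0 <- tb; tb0$cv_nb_duration <- 1
  expect_warning(pc0 <- pca5(tb0), "zero-variance")
  expect_identical(pc0$dropped_columns, "cv_nb_duration")

  expect_s3_class(autoplot(pc), "ggplot")
  expect_identical(nrow(tidy(pc)), 25L)
})

test_that("pairwise MANOVA separates shifted groups and is symmetric", {
  set.seed(19)
  sc <- tibble::tibble(
    condition = rep(c("a", "b", "c"), each = 20),
    PC1 = rnorm(60) + rep(c(0, 5, 0), each = 20),
    PC2 = rnorm(60) + rep(c(0, 0, 5), each = 20))
  mp <- manova_pairwise(sc)
  expect_equal(mp$p_matrix, t(mp$p_matrix))
  expect_true(all(is.na(diag(mp$p_matrix))))
  expect_lt(mp$p_matrix["a", "b"], 0.01)
  expect_lt(mp$p_matrix["b", "c"], 0.01)

  # same-distribution groups are usually not separated
  nulls <- vapply(1:100, function(r) {
    set.seed(900 + r)
    d <- tibble::tibble(condition = rep(c("x", "y"), each = 50),
                        PC1 = rnorm(100), PC2 = rnorm(100))
    manova_pairwise(d)$p_matrix["x", "y"]
  }, numeric(1))
  expect_gte(mean(nulls > 0.05), 0.90)

  expect_error(manova_pairwise(sc[sc$condition == "a", ]), "2 conditions")
  expect_error(
    manova_pairwise(tibble::tibble(condition = c("a", "a", "b", "b"),
                                   PC1 = rnorm(4), PC2 = rnorm(4))),
    "n >= 3")
})

test_that("the paired t-test matches the difference formula", {
  pre <- c(1.2, 2.1, 0.8, 1.9, 1.5)
  post <- c(1.9, 2.6, 1.1, 2.8, 1.7)
  got <- paired_t(pre, post)
  d <- post - pre
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(got$t, t_hand)
  expect_equal(got$p_value, 2 * pt(-abs(t_hand), 4))
  expect_equal(got$mean_diff, mean(d))

  same <- paired_t(pre, pre)
  expect_identical(same$p_value, 1)
  expect_identical(same$mean_diff, 0)
  shift <- paired_t(pre, pre + 2)
  expect_identical(shift$p_value, 0)
  expect_error(paired_t(pre, post[1:4]), "length")
})
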