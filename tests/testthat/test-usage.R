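two_gene_sample <- function(c11, c12, c21 = 0) {
  # clonotypes on TRBV2/TRBV9 x TRBJ1-1/TRBJ1-2 with given read counts
  keys <- c("CASA", "CASB", "CASC")
  counts <- c(c11, c12, c21)
  keep <- counts > 0
  repdx:::aggregate_records(data.frame(
    v_gene = c("TRBV2", "TRBV2", "TRBV9")[keep],
    j_gene = c("TRBJ1-1", "TRBJ1-2", "TRBJ1-1")[keep],
    cdr3_nt = paste0("nt", keys)[keep], cdr3_aa = keys[keep],
    count = as.integer(counts[keep])))
}

test_that("usage matrices live on the full grid and are row-stochastic", {
  set <- make_set(list(S1 = two_gene_sample(6, 4), S2 = two_gene_sample(10, 0)),
                  rbind(meta_row("S1", "P1"), meta_row("S2", "P2")))
  vj <- usage_matrix(set, "VJ")
  expect_equal(dim(vj), c(2, 624))
  expect_equal(unname(rowSums(vj)), c(1, 1))
  expect_equal(vj["S1", "TRBV2_TRBJ1-1"], 0.6)
  expect_equal(vj["S1", "TRBV2_TRBJ1-2"], 0.4)
  expect_equal(sum(vj["S2", ] > 0), 1) # single pairing carries everything
  expect_equal(vj["S2", "TRBV2_TRBJ1-1"], 1)

  v <- usage_matrix(set, "V")
  j <- usage_matrix(set, "J")
  expect_equal(dim(v), c(2, 48))
  expect_equal(dim(j), c(2, 13))
  expect_equal(v["S1", "TRBV2"], 1)
  expect_equal(j["S1", "TRBJ1-1"], 0.6)
  expect_equal(j["S1", "TRBJ1-2"], 0.4)
})

test_that("V and J usage are the marginals of VJ usage", {
  sim <- simulate_tissue_cohort(sim_config(n_patients = 2,
                                           clonotypes_per_sample = 200,
                                           reads_per_sample = 4000,
                                           seed = 31))
  vj <- usage_matrix(sim$set, "VJ")
  v <- usage_matrix(sim$set, "V")
  j <- usage_matrix(sim$set, "J")
  expect_lt(usage_marginal_gap(vj, v, j), 1e-12)
  expect_true(all(abs(rowSums(vj) - 1) < 1e-9))
})

test_that("records outside the universe are ignored, empty samples dropped", {
  s <- two_gene_sample(6, 4)
  s$v_gene[1] <- "TRBV99"
  bad <- repdx:::aggregate_records(
    data.frame(v_gene = "TRBV98", j_gene = "TRBJ9-9", cdr3_nt = "nt",
               cdr3_aa = "CASX", count = 5L))
  set <- make_set(list(S1 = s, S2 = bad),
                  rbind(meta_row("S1", "P1"), meta_row("S2", "P2")))
  expect_warning(m <- usage_matrix(set, "VJ"), "zero usable")
  expect_equal(rownames(m), "S1")
  expect_equal(m["S1", "TRBV2_TRBJ1-2"], 1) # only in-universe record left
})

test_that("group_usage_test finds planted shifts and flags constants", {
  set.seed(32)
  n <- 8
  mat <- matrix(runif(3 * n * 4, 0.1, 0.2), ncol = 4,
                dimnames = list(NULL, c("f_shift", "f_null", "f_const",
                                        "f_noise")))
  groups <- rep(c("T", "N", "B"), each = n)
  mat[groups == "B", "f_shift"] <- mat[groups == "B", "f_shift"] + 0.5
  mat[, "f_const"] <- 0.25
  rownames(mat) <- paste0("S", seq_len(3 * n))
  res <- group_usage_test(mat, groups)
  omni <- setNames(res$omnibus$p, res$omnibus$feature)
  expect_lt(omni["f_shift"], 0.01)
  expect_gt(omni["f_null"], 0.05)
  expect_true(is.na(omni["f_const"]))
  pw <- res$pairwise
  expect_equal(nrow(pw), 3 * 4)
  expect_equal(pw$p_adjusted[!is.na(pw$p)],
               pmin(1, pw$p[!is.na(pw$p)] * 3))
  shift_tb <- pw[pw$feature == "f_shift" & pw$group1 == "B", ]
  expect_true(all(shift_tb$p_adjusted < 0.05))
})

test_that("pairwise usage tests at tiny n equal exact enumeration", {
  set.seed(33)
  v <- sample(seq_len(30), 8)
  mat <- matrix(v, ncol = 1, dimnames = list(paste0("S", 1:8), "f"))
  res <- group_usage_test(mat, rep(c("A", "B"), each = 4))
  expect_equal(res$pairwise$p, oracle_wilcoxon_exact(v[1:4], v[5:8]),
               tolerance = 1e-12)
})

test_that("paired usage testing restricts to complete subjects", {
  set.seed(34)
  pat <- rep(paste0("P", 1:6), 2)
  groups <- rep(c("T", "B"), each = 6)
  base <- runif(6, 0.1, 0.2)
  shift <- c(0.11, 0.14, 0.12, 0.15, 0.13, 0.16) # tie-free differences
  mat <- matrix(c(base, base + shift), ncol = 1,
                dimnames = list(paste0("S", 1:12), "f"))
  res <- group_usage_test(mat, groups, paired_by = pat)
  # all six differences positive: exact signed-rank two-sided p = 2/2^6
  expect_equal(res$pairwise$p, 2 / 64, tolerance = 1e-12)
  # an incomplete subject is excluded from the paired comparison
  res2 <- group_usage_test(mat[-1, , drop = FALSE], groups[-1],
                           paired_by = pat[-1])
  expect_equal(res2$pairwise$p, 2 / 32, tolerance = 1e-12)
})

test_that("dominant_vj needs both abundance and significance", {
  set.seed(35)
  n <- 10
  mk <- function(mean_a, shift) {
    c(rnorm(n, mean_a, 0.001), rnorm(n, mean_a + shift, 0.001),
      rnorm(n, mean_a, 0.001))
  }
  mat <- cbind(
    dom_shift = mk(0.05, 0.02),   # abundant and shifted -> selected
    dom_flat = mk(0.05, 0),       # abundant, not shifted
    rare_shift = mk(0.002, 0.004) # shifted but < 1% mean
  )
  rownames(mat) <- paste0("S", seq_len(3 * n))
  groups <- rep(c("T", "N", "B"), each = n)
  expect_equal(dominant_vj(mat, groups), "dom_shift")
  # strict > on the mean-abundance threshold
  mat2 <- cbind(at_boundary = rep(0.01, 3 * n))
  rownames(mat2) <- rownames(mat)
  expect_equal(dominant_vj(mat2, groups), character(0))
  expect_equal(dominant_vj(mat * 0 + 1e-4, groups), character(0))
})

test_that("pca_usage is deterministic, sign-fixed and variance-complete", {
  set.seed(36)
  mat <- matrix(rnorm(20 * 6, 0.1, 0.02), nrow = 20,
                dimnames = list(paste0("S", 1:20), paste0("f", 1:6)))
  mat[1:10, "f1"] <- mat[1:10, "f1"] + 0.3
  pc <- pca_usage(mat)
  expect_equal(sum(pc$explained), 1, tolerance = 1e-12)
  expect_true(all(pc$explained >= 0))
  # largest loading of each component is positive
  for (k in seq_len(ncol(pc$loadings))) {
    expect_gt(pc$loadings[which.max(abs(pc$loadings[, k])), k], 0)
  }
  # duplicated sample -> identical coordinates
  mat2 <- rbind(mat, dup = mat["S1", ])
  pc2 <- pca_usage(mat2)
  expect_equal(pc2$scores[pc2$scores$sample_id == "dup", c("PC1", "PC2")],
               pc2$scores[pc2$scores$sample_id == "S1", c("PC1", "PC2")],
               ignore_attr = TRUE)

  mat3 <- cbind(mat, zv = 0.5)
  expect_warning(pc3 <- pca_usage(mat3), "zero-variance")
  expect_equal(pc3$dropped, "zv")
  expect_error(pca_usage(mat[1:2, ]), "at least 3")
})

test_that("separated synthetic cohorts split along PC1", {
  cfg <- sim_config(n_case = 12, n_control = 12, effect_size = 8,
                    n_diff_features = 20, clonotypes_per_sample = 300,
                    reads_per_sample = 6000, seed = 37)
  sim <- simulate_cohorts(cfg)
  mat <- usage_matrix(sim$set, "VJ")
  pc <- suppressWarnings(pca_usage(mat))
  lab <- sim$set$meta$cohort[match(pc$scores$sample_id,
                                   sim$set$meta$sample_id)]
  x <- pc$scores$PC1
  pooled_sd <- sqrt((stats::var(x[lab == "case"]) +
                       stats::var(x[lab == "control"])) / 2)
  expect_gt(abs(mean(x[lab == "case"]) - mean(x[lab == "control"])),
            2 * pooled_sd)
})
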