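test_that("pairwise sharing matches hand-computed fractions", {
  x <- rec_table(c("a", "b"), c(6, 4))
  y <- rec_table(c("b", "c"), c(1, 9))
  ps <- pairwise_shared(x, y, scheme = "aa")
  expect_equal(ps$f_x, 0.4)
  expect_equal(ps$f_y, 0.1)
  expect_equal(ps$c_x, 0.5)
  expect_equal(ps$c_y, 0.5)
  expect_equal(ps$shared_keys, "b")

  same <- pairwise_shared(x, x, scheme = "aa")
  expect_equal(unlist(same[c("f_x", "f_y", "c_x", "c_y")]),
               c(f_x = 1, f_y = 1, c_x = 1, c_y = 1))

  z <- rec_table(c("q", "r"), c(2, 2))
  none <- pairwise_shared(x, z, scheme = "aa")
  expect_equal(unlist(none[c("f_x", "f_y", "c_x", "c_y")]),
               c(f_x = 0, f_y = 0, c_x = 0, c_y = 0))

  empty <- rec_table(character(0), integer(0))
  expect_error(pairwise_shared(x, empty), "empty sample")
})

test_that("sharing is key-symmetric but focal-asymmetric", {
  set.seed(11)
  x <- random_rec_table(40)
  y <- random_rec_table(40)
  a <- pairwise_shared(x, y, scheme = "aa")
  b <- pairwise_shared(y, x, scheme = "aa")
  expect_setequal(a$shared_keys, b$shared_keys)
  expect_equal(a$f_x, b$f_y)
  expect_equal(a$c_x, b$c_y)
})

test_that("adding a non-shared clonotype strictly dilutes sharing", {
  x <- rec_table(c("a", "b", "c"), c(5, 3, 2))
  y <- rec_table(c("a", "b"), c(1, 1))
  before <- pairwise_shared(x, y, scheme = "aa")
  x2 <- rec_table(c("a", "b", "c", "zzz"), c(5, 3, 2, 4))
  after <- pairwise_shared(x2, y, scheme = "aa")
  expect_lt(after$f_x, before$f_x)
  expect_lt(after$c_x, before$c_x)
})

test_that("three-way sharing covers subset, empty and single-key cases", {
  tt <- rec_table(c("a", "b", "c", "d"), c(1, 1, 1, 1))
  nn <- rec_table(c("a", "b", "c"), c(1, 1, 1))
  bb <- rec_table(c("a", "b"), c(1, 1))
  tw <- threeway_shared(tt, nn, bb, scheme = "aa")
  expect_equal(tw$f_tnb_b, 1) # B subset of N subset of T
  expect_equal(tw$f_tnb_t, 0.5)
  expect_equal(tw$c_tnb_n, 2 / 3)

  disjoint <- threeway_shared(tt, rec_table("x", 1), bb, scheme = "aa")
  expect_equal(disjoint$f_tnb_t, 0)
  expect_length(disjoint$shared_keys, 0)
  expect_error(expansion_degree(disjoint), "undefined")

  t1 <- rec_table(c("s", "t1", "t2"), c(2, 6, 2))
  n1 <- rec_table(c("s", "n1"), c(3, 7))
  b1 <- rec_table(c("s", "b1", "b2", "b3"), c(1, 3, 3, 3))
  tw1 <- threeway_shared(t1, n1, b1, scheme = "aa")
  expect_equal(tw1$f_tnb_t, 0.2)
  expect_equal(tw1$f_tnb_n, 0.3)
  expect_equal(tw1$f_tnb_b, 0.1)
  expect_equal(tw1$c_tnb_t, 1 / 3)
})

test_that("expansion degree is a frequency ratio", {
  ov <- list(f_tnb_t = 0.135, f_tnb_n = 0.266, f_tnb_b = 3.68e-3)
  ed <- expansion_degree(ov)
  expect_equal(ed$E_T, 0.135 / 0.00368, tolerance = 1e-12) # ~36.68
  expect_equal(ed$E_T, 36.6847826086957, tolerance = 1e-10)
  expect_equal(expansion_degree(list(f_tnb_t = 0.1, f_tnb_n = 0.2,
                                     f_tnb_b = 0.1))$E_T, 1)
  # scaling all B counts leaves the ratio unchanged
  tt <- rec_table(c("s", "t"), c(2, 8))
  nn <- rec_table(c("s", "n"), c(3, 7))
  bb <- rec_table(c("s", "b"), c(1, 9))
  bb10 <- rec_table(c("s", "b"), c(10, 90))
  e1 <- expansion_degree(threeway_shared(tt, nn, bb, scheme = "aa"))
  e2 <- expansion_degree(threeway_shared(tt, nn, bb10, scheme = "aa"))
  expect_equal(e1$E_T, e2$E_T)
})

test_that("overlap fractions equal brute-force set intersections", {
  set.seed(12)
  for (i in 1:12) {
    nx <- sample(50:1000, 1)
    ny <- sample(50:1000, 1)
    keys_x <- paste0("K", sample.int(1500, nx))
    keys_y <- paste0("K", sample.int(1500, ny))
    cx <- sample.int(30, nx, replace = TRUE)
    cy <- sample.int(30, ny, replace = TRUE)
    ps <- pairwise_shared(rec_table(keys_x, cx), rec_table(keys_y, cy),
                          scheme = "aa")
    or <- oracle_shared(keys_x, cx, keys_y, cy)
    expect_equal(ps$f_x, or$f_x, tolerance = 1e-12)
    expect_equal(ps$f_y, or$f_y, tolerance = 1e-12)
    expect_equal(ps$c_x, or$c_x, tolerance = 1e-12)
    expect_equal(ps$c_y, or$c_y, tolerance = 1e-12)
    expect_setequal(ps$shared_keys, or$shared)
  }
})

test_that("patient_overlap assembles per-patient rows and skips gaps", {
  samples <- list(
    P1_T = rec_table(c("s", "t"), c(5, 5)),
    P1_N = rec_table(c("s", "n"), c(5, 5)),
    P1_B = rec_table(c("s", "b"), c(1, 9)),
    P2_T = rec_table(c("x", "y"), c(5, 5)),
    P2_B = rec_table(c("x"), 10)
  )
  meta <- rbind(meta_row("P1_T", "P1", "T"), meta_row("P1_N", "P1", "N"),
                meta_row("P1_B", "P1", "B"), meta_row("P2_T", "P2", "T"),
                meta_row("P2_B", "P2", "B"))
  ov <- patient_overlap(make_set(samples, meta), scheme = "aa")
  expect_equal(nrow(ov), 2)
  p1 <- ov[ov$patient_id == "P1", ]
  expect_equal(p1$f_tnb_t, 0.5)
  expect_equal(p1$E_T, 0.5 / 0.1)
  p2 <- ov[ov$patient_id == "P2", ]
  expect_true(is.na(p2$f_tn_t)) # no N sample
  expect_equal(p2$f_tb_t, 0.5)
  expect_true(is.na(p2$E_T))
  # three-way set is a subset of every pairwise set
  expect_lte(p1$f_tnb_t, p1$f_tn_t)
  expect_lte(p1$f_tnb_b, p1$f_nb_b)
})

test_that("expansion_summary reports both aggregation conventions", {
  ov <- data.frame(patient_id = c("P1", "P2"),
                   f_tnb_t = c(0.2, 0.1), f_tnb_n = c(0.3, 0.2),
                   f_tnb_b = c(0.01, 0.05),
                   E_T = c(20, 2), E_N = c(30, 4))
  es <- expansion_summary(ov)
  expect_equal(unname(es$mean_of_ratios["E_T"]), 11)
  expect_equal(unname(es$ratio_of_means["E_T"]), 0.15 / 0.03)
  expect_equal(es$n_patients, 2)
})

test_that("within-patient sharing separates from between-patient sharing", {
  one <- make_set(
    list(P1_T = rec_table(c("s", "t"), c(5, 5)),
         P1_N = rec_table(c("s", "n"), c(5, 5)),
         P1_B = rec_table(c("s", "b"), c(5, 5))),
    rbind(meta_row("P1_T", "P1", "T"), meta_row("P1_N", "P1", "N"),
          meta_row("P1_B", "P1", "B")))
  ip <- suppressWarnings(interpatient_sharing(one, scheme = "aa"))
  expect_equal(sum(ip$pairs$relation == "within"), 3)
  expect_equal(sum(ip$pairs$relation == "between"), 0)

  # identical repertoire filed under two patients is flagged as full sharing
  dup <- make_set(
    list(P1_B = rec_table(c("a", "b"), c(5, 5)),
         P2_B = rec_table(c("a", "b"), c(5, 5)),
         P1_T = rec_table(c("z"), 10)),
    rbind(meta_row("P1_B", "P1", "B"), meta_row("P2_B", "P2", "B"),
          meta_row("P1_T", "P1", "T")))
  ip2 <- interpatient_sharing(dup, scheme = "aa")
  expect_true(any(ip2$between == 1))

  sim <- simulate_tissue_cohort(sim_config(n_patients = 3,
                                           clonotypes_per_sample = 200,
                                           reads_per_sample = 4000,
                                           seed = 21))
  ip3 <- interpatient_sharing(sim$set)
  expect_gt(mean(ip3$within), mean(ip3$between))
  expect_lt(ip3$p, 0.05)
})

test_that("public clonotype detection ranks injected publics first", {
  sim <- simulate_tissue_cohort(sim_config(n_patients = 3, n_public = 3,
                                           clonotypes_per_sample = 200,
                                           reads_per_sample = 4000,
                                           seed = 22))
  blood_ids <- sim$set$meta$sample_id[sim$set$meta$tissue == "B"]
  blood <- make_set(sim$set$samples[blood_ids],
                    sim$set$meta[sim$set$meta$tissue == "B", ])
  pub <- public_clonotypes(blood)
  expect_true(all(sim$truth$public %in% pub$key))
  expect_true(all(pub$prevalence == length(blood_ids)))

  all_keys <- public_clonotypes(blood, min_prevalence = 1)
  expect_equal(nrow(all_keys),
               length(unique(unlist(lapply(blood$samples, clonotype_key,
                                           scheme = "v_aa_j")))))
  none <- public_clonotypes(blood, min_prevalence = length(blood_ids) + 1)
  expect_equal(nrow(none), 0)
})

test_that("chi-square association matches the hand formula", {
  perfect <- clinical_association(rep(c(TRUE, FALSE), each = 10),
                                  rep(c("yes", "no"), each = 10))
  expect_lt(perfect$p, 1e-4)

  flat <- clinical_association(rep(c(TRUE, FALSE), 10),
                               rep(c("yes", "no"), each = 10))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  presence <- rep(c(TRUE, FALSE), c(10, 10))
  covariate <- c(rep("pos", 8), rep("neg", 2), rep("pos", 3), rep("neg", 7))
  res <- clinical_association(presence, covariate)
  expect_equal(res$statistic, oracle_chisq(res$table), tolerance = 1e-12)

  expect_error(clinical_association(rep(TRUE, 5), rep(c("a", "b"), c(2, 3))),
               "empty margin")
})

test_that("the clinical screen honors the prevalence window", {
  set.seed(13)
  samples <- list()
  meta <- list()
  for (i in 1:10) {
    # "COMMON" in all samples, "MID" in 6/10, "RARE" in 1
    keys <- c("COMMON", if (i <= 6) "MID", if (i == 1) "RARE",
              paste0("pvt", i))
    sid <- paste0("S", i)
    samples[[sid]] <- rec_table(keys, rep(5, length(keys)))
    meta[[sid]] <- cbind(meta_row(sid, paste0("P", i)),
                         mvi = ifelse(i <= 5, "yes", "no"))
  }
  set <- make_set(samples, do.call(rbind, meta))
  out <- clinical_association_screen(set, fields = "mvi",
                                     prevalence_range = c(0.47, 0.8),
                                     scheme = "aa")
  expect_equal(unique(out$key), "MID") # 60% prevalence; others outside window
})
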