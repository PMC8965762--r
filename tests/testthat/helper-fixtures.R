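# Hand-built clonotype tables and independent oracles used across the suite.

# A record table from cdr3_aa "keys" and counts; single V/J by default so the
# aa and v_aa_j schemes agree on identity structure.
rec_table <- function(keys, counts, v = "TRBV9", j = "TRBJ2-1") {
  repdx:::aggregate_records(data.frame(
    v_gene = rep_len(v, length(keys)), j_gene = rep_len(j, length(keys)),
    cdr3_nt = if (length(keys)) paste0("nt", tolower(keys)) else character(0),
    cdr3_aa = keys,
    count = as.integer(counts),
    stringsAsFactors = FALSE
  ))
}

make_set <- function(samples, meta) {
  repdx:::new_repertoire_set(samples, meta)
}

meta_row <- function(sample_id, patient_id, tissue = "B", cohort = "case") {
  data.frame(sample_id = sample_id, patient_id = patient_id,
             tissue = tissue, cohort = cohort, stringsAsFactors = FALSE)
}

# random record table over arbitrary key strings
random_rec_table <- function(n_keys, max_count = 50) {
  keys <- paste0("K", sample.int(10 * n_keys, n_keys))
  rec_table(keys, sample.int(max_count, n_keys, replace = TRUE))
}

## ---- independent oracles -------------------------------------------------

# direct summation, term by term
oracle_entropy <- function(p, base = exp(1)) {
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi, base = base)
  h
}

# brute-force sharing fractions from two key->count maps
oracle_shared <- function(keys_x, counts_x, keys_y, counts_y) {
  shared <- character(0)
  for (k in unique(keys_x)) if (k %in% keys_y) shared <- c(shared, k)
  f <- function(keys, counts) {
    tot <- sum(counts)
    s <- 0
    for (i in seq_along(keys)) if (keys[i] %in% shared) s <- s + counts[i]
    s / tot
  }
  list(f_x = f(keys_x, counts_x), f_y = f(keys_y, counts_y),
       c_x = length(shared) / length(unique(keys_x)),
       c_y = length(shared) / length(unique(keys_y)),
       shared = sort(shared))
}

# exhaustive pairwise win/tie counting
oracle_auc <- function(case, control) {
  w <- 0
  for (a in case) {
    for (b in control) {
      w <- w + (a > b) + 0.5 * (a == b)
    }
  }
  w / (length(case) * length(control))
}

# exact two-sided rank-sum p by enumerating all group assignments (no ties)
oracle_wilcoxon_exact <- function(x, y) {
  v <- c(x, y)
  stopifnot(!anyDuplicated(v))
  n1 <- length(x)
  r <- rank(v)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  picks <- utils::combn(length(v), n1)
  w_all <- apply(picks, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
  min(1, p)
}

oracle_chisq <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}
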