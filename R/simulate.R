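# Synthetic repertoire generator.
#
# Emulates the statistical structure the downstream analyses consume, not
# receptor biology: blood repertoires drawn from a shallow power law (high
# Shannon entropy), tumor (T) and adjacent non-tumor (N) repertoires built
# from a smaller clonotype pool with a planted T/N-shared subset whose
# expanded members are boosted multiplicatively, a small fraction of tissue
# clonotypes recirculating in blood, public clonotypes injected into every
# blood sample, and (for two-cohort blood panels) per-sample VJ-pairing usage
# drawn from a Dirichlet around a cohort base with a planted shift on a known
# feature subset. Ground truth is recorded alongside every table.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulation configuration
#'
#' Builds and validates the configuration consumed by [simulate_patient()],
#' [simulate_tissue_cohort()] and [simulate_cohorts()]. Defaults describe a
#' desk-scale cohort: 20 patients with all three tissues, ~30k reads and
#' 1,500 blood clonotypes per sample, strong clonal expansion in tissues,
#' half of tumor clonotypes shared with adjacent non-tumor tissue, 15% of
#' tissue clonotypes recirculating in blood, 3 public blood clonotypes at
#' 0.5% frequency, and for two-cohort panels 43 cases vs 439 controls with a
#' planted 8-fold usage shift on 20 of the 624 VJ pairings.
#'
#' @param n_patients patients in the multi-tissue cohort.
#' @param tissues tissues generated per patient, subset of `c("T","N","B")`.
#' @param clonotypes_per_sample blood clonotype richness; tissue richness is
#'   40% of this.
#' @param reads_per_sample sequencing reads per sample.
#' @param clone_size_exponent power-law exponent of blood clone sizes
#'   (smaller = flatter = more diverse).
#' @param expansion_factor multiplicative abundance boost of the expanded
#'   clone subset in adjacent non-tumor tissue; tumor uses half this boost.
#' @param frac_shared_TN fraction of tumor clonotypes also present in N.
#' @param frac_shared_blood fraction of tissue clonotypes recirculating in B.
#' @param n_public number of public clonotypes present in every blood sample.
#' @param public_freq per-sample frequency of each public clonotype.
#' @param n_case,n_control blood cohort sizes for [simulate_cohorts()].
#' @param n_diff_features number of VJ pairings with a planted cohort shift.
#' @param effect_size fold-change of the planted shift (>0; 1 = null).
#' @param dirichlet_concentration total concentration of the per-sample
#'   Dirichlet draw around the cohort base (larger = less sample noise).
#' @param mean_clone_reads target reads per clonotype when expanding VJ
#'   counts into clonotype tables in [simulate_cohorts()].
#' @param seed integer seed; the single source of randomness for a run.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20,
                       tissues = c("T", "N", "B"),
                       clonotypes_per_sample = 1500,
                       reads_per_sample = 30000,
                       clone_size_exponent = 0.55,
                       expansion_factor = 30,
                       frac_shared_TN = 0.5,
                       frac_shared_blood = 0.15,
                       n_public = 3,
                       public_freq = 0.005,
                       n_case = 43,
                       n_control = 439,
                       n_diff_features = 20,
                       effect_size = 8,
                       dirichlet_concentration = 750,
                       mean_clone_reads = 40,
                       seed = 1) {
  cfg <- list(n_patients = n_patients, tissues = tissues,
              clonotypes_per_sample = clonotypes_per_sample,
              reads_per_sample = reads_per_sample,
              clone_size_exponent = clone_size_exponent,
              expansion_factor = expansion_factor,
              frac_shared_TN = frac_shared_TN,
              frac_shared_blood = frac_shared_blood,
              n_public = n_public, public_freq = public_freq,
              n_case = n_case, n_control = n_control,
              n_diff_features = n_diff_features, effect_size = effect_size,
              dirichlet_concentration = dirichlet_concentration,
              mean_clone_reads = mean_clone_reads, seed = seed)
  counts <- c("n_patients", "clonotypes_per_sample", "reads_per_sample",
              "n_public", "n_case", "n_control", "n_diff_features",
              "mean_clone_reads")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0 ||
        cfg[[f]] != floor(cfg[[f]])) {
      stop("sim_config: '", f, "' must be a non-negative integer")
    }
  }
  for (f in c("frac_shared_TN", "frac_shared_blood")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop("sim_config: '", f, "' must lie in [0, 1]")
    }
  }
  if (cfg$effect_size <= 0) stop("sim_config: effect_size must be > 0")
  if (cfg$expansion_factor <= 0) {
    stop("sim_config: expansion_factor must be > 0")
  }
  if (!all(tissues %in% c("T", "N", "B")) || length(tissues) == 0) {
    stop("sim_config: tissues must be a non-empty subset of T, N, B")
  }
  n_vj <- length(trb_gene_universe()$vj_pairings)
  if (cfg$n_diff_features > n_vj) {
    stop("sim_config: n_diff_features exceeds the ", n_vj, " VJ pairings")
  }
  if (cfg$n_public * cfg$public_freq >= 0.5) {
    stop("sim_config: public clonotypes would occupy >= 50% of blood reads")
  }
  structure(cfg, class = "sim_config")
}

# Deterministic 31-bit substream seed for patient/sample `counter`.
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 48271 + counter * 104729) %% 2147483587) + 1L
}

# Vectorized random fixed-alphabet strings: draw a max-length character
# matrix in one call, paste columns, truncate to per-string lengths.
random_strings <- function(lens, alphabet) {
  n <- length(lens)
  if (n == 0) return(character(0))
  maxlen <- max(lens)
  m <- matrix(sample(alphabet, n * maxlen, replace = TRUE), nrow = n)
  full <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
  substring(full, 1L, lens)
}

# Unique random CDR3 amino-acid strings, lengths 8-20 peaked near 14.
random_cdr3 <- function(n) {
  lens <- 8:20
  w <- stats::dnorm(lens, mean = 14, sd = 2.5)
  out <- random_strings(sample(lens, n, replace = TRUE, prob = w),
                        AA_ALPHABET)
  while (anyDuplicated(out)) {
    dup <- which(duplicated(out))
    out[dup] <- random_strings(sample(lens, length(dup), replace = TRUE,
                                      prob = w), AA_ALPHABET)
  }
  out
}

# Random nucleotide CDR3 of length 3 * nchar(aa); not a real back-translation,
# only a distinct nt-level identity.
random_nt <- function(aa) {
  random_strings(nchar(aa) * 3L, c("a", "c", "g", "t"))
}

# Pool of clonotype identities with uniform-ish V/J assignment drawn from the
# frozen gene universe with mildly skewed gene weights.
make_clonotype_pool <- function(n, universe = trb_gene_universe()) {
  nv <- length(universe$v_genes)
  nj <- length(universe$j_genes)
  wv <- (seq_len(nv))^-0.5
  wj <- (seq_len(nj))^-0.5
  aa <- random_cdr3(n)
  data.frame(
    v_gene = sample(universe$v_genes, n, replace = TRUE, prob = wv),
    j_gene = sample(universe$j_genes, n, replace = TRUE, prob = wj),
    cdr3_nt = random_nt(aa),
    cdr3_aa = aa,
    stringsAsFactors = FALSE
  )
}

# Multinomial read draw over a clonotype pool; drops zero-count clonotypes
# and returns an aggregated record table.
draw_sample <- function(pool, probs, reads) {
  counts <- as.integer(stats::rmultinom(1, reads, probs))
  keep <- counts > 0
  rec <- pool[keep, , drop = FALSE]
  rec$count <- counts[keep]
  aggregate_records(rec)
}

#' Simulate one patient's multi-tissue repertoires
#'
#' Blood clone sizes follow `rank^-clone_size_exponent` (shallow: high
#' entropy); tumor and adjacent non-tumor tissues draw from a 2.5x smaller
#' clonotype pool with a steeper law, share `frac_shared_TN` of the tumor
#' pool, and carry an expanded subset (20% of the shared pool) boosted by
#' `expansion_factor` in N and half that in T. `frac_shared_blood` of the
#' tissue pool, biased toward expanded clones, recirculates in blood at
#' power-law tail frequencies; public clonotypes (passed in by the cohort
#' wrapper) occupy fixed slots of the blood simplex.
#'
#' @param config a [sim_config()].
#' @param patient_id label used in sample ids.
#' @param seed integer seed for this patient (derive from the run seed).
#' @param public optional data.frame of public clonotype identities
#'   (columns as a clonotype pool) injected into blood.
#' @return list with `samples` (named list of record tables, one per
#'   requested tissue) and `truth` (realized shared-key sets `shared_TN`,
#'   `shared_TB`, `shared_NB`, `shared_TNB` and the planted `expanded` keys,
#'   all under the `v_aa_j` scheme).
#' @export
simulate_patient <- function(config, patient_id, seed = config$seed,
                             public = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  tissues <- config$tissues
  n_b <- config$clonotypes_per_sample
  n_t <- max(2L, round(0.4 * n_b))
  n_shared <- round(config$frac_shared_TN * n_t)
  reads <- config$reads_per_sample

  pool <- make_clonotype_pool(n_shared + 2L * (n_t - n_shared) + n_b)
  idx_shared <- seq_len(n_shared)
  idx_t_only <- n_shared + seq_len(n_t - n_shared)
  idx_n_only <- n_shared + (n_t - n_shared) + seq_len(n_t - n_shared)
  idx_tissue <- c(idx_shared, idx_t_only, idx_n_only)
  idx_blood_own <- setdiff(seq_len(nrow(pool)), idx_tissue)

  # expanded subset: 20% of the T/N-shared pool, boosted in both tissues
  n_exp <- max(1L, round(0.2 * max(n_shared, 1L)))
  idx_exp <- if (n_shared > 0) sample(idx_shared, min(n_exp, n_shared)) else
    integer(0)

  # tissue clonotypes recirculating in blood, biased toward expanded clones
  n_blood_shared <- round(config$frac_shared_blood * length(idx_tissue))
  w <- ifelse(idx_tissue %in% idx_exp, 5, 1)
  idx_recirc <- if (n_blood_shared > 0) {
    sample(idx_tissue, min(n_blood_shared, length(idx_tissue)), prob = w)
  } else integer(0)

  # one intrinsic clone-size weight per tissue clonotype, shared between T
  # and N (clone sizes of shared clones are correlated across adjacent
  # tissues); only the expansion boost differs by tissue
  base_w <- numeric(nrow(pool))
  base_w[idx_tissue] <- sample(length(idx_tissue))^(-1)
  tissue_probs <- function(idx_own, boost) {
    p <- numeric(nrow(pool))
    p[idx_own] <- base_w[idx_own]
    boosted <- intersect(idx_own, idx_exp)
    p[boosted] <- p[boosted] * boost
    p / sum(p)
  }

  samples <- list()
  if ("T" %in% tissues) {
    pT <- tissue_probs(c(idx_shared, idx_t_only), config$expansion_factor / 2)
    samples$T <- draw_sample(pool, pT, reads)
  }
  if ("N" %in% tissues) {
    pN <- tissue_probs(c(idx_shared, idx_n_only), config$expansion_factor)
    samples$N <- draw_sample(pool, pN, reads)
  }
  if ("B" %in% tissues) {
    idx_b <- unique(c(idx_blood_own, idx_recirc))
    bpool <- pool[idx_b, , drop = FALSE]
    ranks <- sample(nrow(bpool))
    p <- ranks^(-config$clone_size_exponent)
    p <- p / sum(p)
    if (!is.null(public) && nrow(public) > 0) {
      p <- p * (1 - nrow(public) * config$public_freq)
      bpool <- rbind(bpool, public)
      p <- c(p, rep(config$public_freq, nrow(public)))
    }
    samples$B <- draw_sample(bpool, p, reads)
  }

  keys <- lapply(samples, clonotype_key, scheme = "v_aa_j")
  truth <- list(
    shared_TN = if (all(c("T", "N") %in% names(keys)))
      intersect(keys$T, keys$N) else character(0),
    shared_TB = if (all(c("T", "B") %in% names(keys)))
      intersect(keys$T, keys$B) else character(0),
    shared_NB = if (all(c("N", "B") %in% names(keys)))
      intersect(keys$N, keys$B) else character(0),
    shared_TNB = if (all(c("T", "N", "B") %in% names(keys)))
      Reduce(intersect, keys[c("T", "N", "B")]) else character(0),
    expanded = clonotype_key(pool[idx_exp, , drop = FALSE], "v_aa_j")
  )
  list(samples = samples, truth = truth)
}

#' Simulate a multi-tissue patient cohort
#'
#' Runs [simulate_patient()] for `n_patients` patients on deterministic
#' per-patient substreams of the run seed and assembles a `repertoire_set`
#' plus recorded truth. Public clonotype identities are generated once and
#' injected into every blood sample.
#'
#' @param config a [sim_config()].
#' @return list with `set` (a `repertoire_set`, cohort `"case"`) and
#'   `truth` (per-patient shared-key sets, `public` keys, config echo).
#' @export
simulate_tissue_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 0L))
  public <- if (config$n_public > 0) make_clonotype_pool(config$n_public)
    else NULL
  samples <- list()
  meta_rows <- list()
  patient_truth <- list()
  for (i in seq_len(config$n_patients)) {
    pid <- sprintf("P%03d", i)
    sim <- simulate_patient(config, pid, seed = derive_seed(config$seed, i),
                            public = public)
    for (tis in names(sim$samples)) {
      sid <- paste0(pid, "_", tis)
      samples[[sid]] <- sim$samples[[tis]]
      meta_rows[[sid]] <- data.frame(sample_id = sid, patient_id = pid,
                                     tissue = tis, cohort = "case",
                                     stringsAsFactors = FALSE)
    }
    patient_truth[[pid]] <- sim$truth
  }
  set <- new_repertoire_set(samples, do.call(rbind, meta_rows))
  truth <- list(
    patients = patient_truth,
    public = if (is.null(public)) character(0) else
      clonotype_key(public, "v_aa_j"),
    seed = config$seed
  )
  list(set = set, truth = truth)
}

rdirichlet <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

#' Simulate two-cohort blood panels with planted VJ usage shifts
#'
#' Per-sample VJ-pairing usage is drawn from a Dirichlet around a
#' cohort-specific base. The case base differs from the control base on
#' exactly `n_diff_features` pairings: the first half is multiplied by
#' `effect_size` (up in cases), the rest divided by it (down in cases);
#' `effect_size = 1` plants nothing. VJ read counts are multinomial and are
#' expanded into clonotype tables with ~`mean_clone_reads` reads per clone
#' and random CDR3 strings (8-20 aa).
#'
#' @param config a [sim_config()] with `n_case`, `n_control` > 0.
#' @return list with `set` (a blood-only `repertoire_set` with cohorts
#'   `"case"`/`"control"`) and `truth` (`diff_features` data.frame with
#'   feature, direction and fold change; cohort base usage vectors).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_case < 1 || config$n_control < 1) {
    stop("simulate_cohorts needs n_case and n_control >= 1")
  }
  set.seed(derive_seed(config$seed, 424243L))
  universe <- trb_gene_universe()
  vj <- universe$vj_pairings
  n_vj <- length(vj)

  base_control <- sample(seq_len(n_vj))^(-0.8)
  base_control <- base_control / sum(base_control)
  base_case <- base_control
  planted <- character(0)
  direction <- character(0)
  if (config$effect_size != 1 && config$n_diff_features > 0) {
    # plant shifts only on pairings with a workable baseline (0.05%-0.5%
    # usage, the range of reported discriminative VJ pairings); a shift on
    # an effectively-absent pairing is undetectable by construction
    eligible <- vj[base_control >= 5e-4 & base_control <= 5e-3]
    if (length(eligible) < config$n_diff_features) eligible <- vj
    planted <- sample(eligible, config$n_diff_features)
    n_up <- ceiling(length(planted) / 2)
    up <- planted[seq_len(n_up)]
    down <- setdiff(planted, up)
    i_up <- match(up, vj)
    i_down <- match(down, vj)
    base_case[i_up] <- base_case[i_up] * config$effect_size
    base_case[i_down] <- base_case[i_down] / config$effect_size
    base_case <- base_case / sum(base_case)
    direction <- c(rep("up_in_case", length(up)),
                   rep("up_in_control", length(down)))
    planted <- c(up, down)
  }

  vj_split <- strsplit(vj, "_", fixed = TRUE)
  vj_v <- vapply(vj_split, `[`, "", 1L)
  vj_j <- vapply(vj_split, `[`, "", 2L)

  one_sample <- function(base, sid) {
    p <- rdirichlet(1, config$dirichlet_concentration * base)[1, ]
    counts <- as.integer(stats::rmultinom(1, config$reads_per_sample, p))
    nz <- which(counts > 0)
    cnt <- counts[nz]
    n_clones <- pmax(1L, as.integer(round(cnt / config$mean_clone_reads)))
    sizes_by_cell <- vector("list", length(nz))
    for (k in seq_along(nz)) {
      sizes_by_cell[[k]] <- if (n_clones[k] == 1L) cnt[k] else
        as.integer(stats::rmultinom(1, cnt[k],
                                    rep.int(1, n_clones[k])))
    }
    vj_idx <- rep.int(nz, n_clones)
    sizes <- unlist(sizes_by_cell, use.names = FALSE)
    keep <- sizes > 0
    vj_idx <- vj_idx[keep]
    aa <- random_cdr3(sum(keep))
    rec <- data.frame(v_gene = vj_v[vj_idx], j_gene = vj_j[vj_idx],
                      cdr3_nt = random_nt(aa), cdr3_aa = aa,
                      count = sizes[keep], stringsAsFactors = FALSE)
    aggregate_records(rec)
  }

  samples <- list()
  meta_rows <- list()
  for (i in seq_len(config$n_case)) {
    sid <- sprintf("HCC%03d", i)
    samples[[sid]] <- one_sample(base_case, sid)
    meta_rows[[sid]] <- data.frame(sample_id = sid, patient_id = sid,
                                   tissue = "B", cohort = "case",
                                   stringsAsFactors = FALSE)
  }
  for (i in seq_len(config$n_control)) {
    sid <- sprintf("CTR%03d", i)
    samples[[sid]] <- one_sample(base_control, sid)
    meta_rows[[sid]] <- data.frame(sample_id = sid, patient_id = sid,
                                   tissue = "B", cohort = "control",
                                   stringsAsFactors = FALSE)
  }
  set <- new_repertoire_set(samples, do.call(rbind, meta_rows))
  truth <- list(
    diff_features = data.frame(feature = planted, direction = direction,
                               effect_size = rep(config$effect_size,
                                                 length(planted)),
                               stringsAsFactors = FALSE),
    base_case = stats::setNames(base_case, vj),
    base_control = stats::setNames(base_control, vj),
    seed = config$seed
  )
  list(set = set, truth = truth)
}

#' Write a simulated fixture to disk
#'
#' Emits one AIRR-style TSV per sample (`<sample_id>.airr.tsv` with columns
#' `v_call`, `j_call`, `junction`, `junction_aa`, `duplicate_count`), a
#' `metadata.tsv`, and a `truth.json`, readable back with [read_airr()].
#'
#' @param set a `repertoire_set`.
#' @param truth truth list from the simulator (serialized as JSON).
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_fixture <- function(set, truth, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sid in names(set$samples)) {
    s <- set$samples[[sid]]
    out <- data.frame(v_call = s$v_gene, j_call = s$j_gene,
                      junction = s$cdr3_nt, junction_aa = s$cdr3_aa,
                      duplicate_count = s$count)
    p <- file.path(out_dir, paste0(sid, ".airr.tsv"))
    utils::write.table(out, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  mp <- file.path(out_dir, "metadata.tsv")
  utils::write.table(set$meta, mp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tp <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, tp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp, tp))
}
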