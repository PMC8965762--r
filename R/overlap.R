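# Cross-tissue clonotype sharing, clonal-expansion ratios, public-clonotype
# detection and clonotype-clinical association.
#
# Two complementary sharing statistics are always computed together:
#   f ("shared clones")     abundance-weighted: reads of shared clonotypes in
#                           the focal sample / total reads of that sample
#   c ("shared clonotypes") richness: number of shared clonotypes / number of
#                           distinct clonotypes of the focal sample

#' Pairwise clonotype sharing between two samples
#'
#' The shared set is the exact intersection of clonotype keys under
#' `scheme`. Fractions are reported from both focal sides: the key set is
#' symmetric but the abundance a shared set occupies generally is not.
#'
#' @param sample_x,sample_y clonotype record tables.
#' @param scheme clonotype key scheme (default `"v_aa_j"`).
#' @return list with `f_x`, `f_y` (abundance fractions), `c_x`, `c_y`
#'   (richness fractions) and `shared_keys`.
#' @export
pairwise_shared <- function(sample_x, sample_y, scheme = "v_aa_j") {
  fx <- key_freq(sample_x, scheme)
  fy <- key_freq(sample_y, scheme)
  if (length(fx) == 0 || length(fy) == 0) {
    stop("shared fractions undefined for an empty sample")
  }
  shared <- intersect(names(fx), names(fy))
  list(
    f_x = sum(fx[shared]), f_y = sum(fy[shared]),
    c_x = length(shared) / length(fx), c_y = length(shared) / length(fy),
    shared_keys = shared
  )
}

#' Three-way sharing among a patient's T, N and B samples
#'
#' The TNB set is the intersection of clonotype keys across all three
#' tissues; per-tissue abundance (`f_tnb_*`) and richness (`c_tnb_*`)
#' fractions of that set are returned.
#'
#' @param t_sample,n_sample,b_sample clonotype record tables for tumor,
#'   adjacent non-tumor tissue and blood.
#' @param scheme clonotype key scheme.
#' @return list with `f_tnb_t`, `f_tnb_n`, `f_tnb_b`, `c_tnb_t`, `c_tnb_n`,
#'   `c_tnb_b` and `shared_keys`.
#' @export
threeway_shared <- function(t_sample, n_sample, b_sample,
                            scheme = "v_aa_j") {
  ft <- key_freq(t_sample, scheme)
  fn <- key_freq(n_sample, scheme)
  fb <- key_freq(b_sample, scheme)
  if (!length(ft) || !length(fn) || !length(fb)) {
    stop("shared fractions undefined for an empty sample")
  }
  shared <- Reduce(intersect, list(names(ft), names(fn), names(fb)))
  list(
    f_tnb_t = sum(ft[shared]), f_tnb_n = sum(fn[shared]),
    f_tnb_b = sum(fb[shared]),
    c_tnb_t = length(shared) / length(ft),
    c_tnb_n = length(shared) / length(fn),
    c_tnb_b = length(shared) / length(fb),
    shared_keys = shared
  )
}

#' Clonal-expansion degree of the TNB shared set
#'
#' `E_T = f_TNB|T / f_TNB|B` and `E_N = f_TNB|N / f_TNB|B`: how many-fold
#' more abundant the clones common to all three tissues are in tumor /
#' adjacent tissue than in blood. Undefined (error) when the TNB set
#' occupies zero abundance in blood.
#'
#' @param overlap result of [threeway_shared()].
#' @return list with `E_T` and `E_N`.
#' @export
expansion_degree <- function(overlap) {
  if (!is.finite(overlap$f_tnb_b) || overlap$f_tnb_b <= 0) {
    stop("expansion degree undefined: f_TNB|B is zero")
  }
  list(E_T = overlap$f_tnb_t / overlap$f_tnb_b,
       E_N = overlap$f_tnb_n / overlap$f_tnb_b)
}

#' Per-patient overlap and expansion table
#'
#' For every patient, computes all available pairwise fractions (TN, TB, NB,
#' both focal sides) and, for patients with all three tissues, the TNB
#' fractions and expansion degrees. Patients missing a tissue contribute NA
#' for the statistics needing it; patients whose TNB set is empty in blood
#' get NA expansion and are counted in `attr(., "n_expansion_undefined")`.
#'
#' @param set a `repertoire_set`.
#' @param scheme clonotype key scheme.
#' @return data.frame, one row per patient.
#' @export
patient_overlap <- function(set, scheme = "v_aa_j") {
  patients <- unique(set$meta$patient_id)
  n_undef <- 0L
  rows <- lapply(patients, function(pid) {
    sids <- set$meta$sample_id[set$meta$patient_id == pid]
    tis <- set$meta$tissue[match(sids, set$meta$sample_id)]
    have <- stats::setNames(as.list(sids), tis)
    row <- list(patient_id = pid,
                f_tn_t = NA_real_, f_tn_n = NA_real_, c_tn_t = NA_real_,
                c_tn_n = NA_real_,
                f_tb_t = NA_real_, f_tb_b = NA_real_, c_tb_t = NA_real_,
                c_tb_b = NA_real_,
                f_nb_n = NA_real_, f_nb_b = NA_real_, c_nb_n = NA_real_,
                c_nb_b = NA_real_,
                f_tnb_t = NA_real_, f_tnb_n = NA_real_, f_tnb_b = NA_real_,
                c_tnb_t = NA_real_, c_tnb_n = NA_real_, c_tnb_b = NA_real_,
                E_T = NA_real_, E_N = NA_real_)
    g <- function(t) set$samples[[have[[t]]]]
    if (all(c("T", "N") %in% tis)) {
      ps <- pairwise_shared(g("T"), g("N"), scheme)
      row[c("f_tn_t", "f_tn_n", "c_tn_t", "c_tn_n")] <-
        ps[c("f_x", "f_y", "c_x", "c_y")]
    }
    if (all(c("T", "B") %in% tis)) {
      ps <- pairwise_shared(g("T"), g("B"), scheme)
      row[c("f_tb_t", "f_tb_b", "c_tb_t", "c_tb_b")] <-
        ps[c("f_x", "f_y", "c_x", "c_y")]
    }
    if (all(c("N", "B") %in% tis)) {
      ps <- pairwise_shared(g("N"), g("B"), scheme)
      row[c("f_nb_n", "f_nb_b", "c_nb_n", "c_nb_b")] <-
        ps[c("f_x", "f_y", "c_x", "c_y")]
    }
    if (all(c("T", "N", "B") %in% tis)) {
      tw <- threeway_shared(g("T"), g("N"), g("B"), scheme)
      row[c("f_tnb_t", "f_tnb_n", "f_tnb_b",
            "c_tnb_t", "c_tnb_n", "c_tnb_b")] <-
        tw[c("f_tnb_t", "f_tnb_n", "f_tnb_b",
             "c_tnb_t", "c_tnb_n", "c_tnb_b")]
      if (tw$f_tnb_b > 0) {
        ed <- expansion_degree(tw)
        row$E_T <- ed$E_T
        row$E_N <- ed$E_N
      } else {
        n_undef <<- n_undef + 1L
      }
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_expansion_undefined") <- n_undef
  out
}

#' Cohort summary of clonal expansion
#'
#' Reports both aggregation conventions for the expansion degree: the mean
#' of per-patient ratios and the ratio of cohort means of the TNB
#' fractions, together with a paired Wilcoxon test of E_T vs E_N across
#' patients.
#'
#' @param overlap data.frame from [patient_overlap()].
#' @return list with `mean_of_ratios` (E_T, E_N), `ratio_of_means`
#'   (E_T, E_N), `n_patients`, and `p_paired_wilcoxon`.
#' @export
expansion_summary <- function(overlap) {
  ok <- stats::complete.cases(overlap[, c("E_T", "E_N")])
  ov <- overlap[ok, , drop = FALSE]
  if (nrow(ov) == 0) stop("no patient with a defined expansion degree")
  p <- if (nrow(ov) >= 2)
    suppressWarnings(stats::wilcox.test(ov$E_T, ov$E_N,
                                        paired = TRUE)$p.value)
    else NA_real_
  list(
    mean_of_ratios = c(E_T = mean(ov$E_T), E_N = mean(ov$E_N)),
    ratio_of_means = c(E_T = mean(ov$f_tnb_t) / mean(ov$f_tnb_b),
                       E_N = mean(ov$f_tnb_n) / mean(ov$f_tnb_b)),
    n_patients = nrow(ov),
    p_paired_wilcoxon = p
  )
}

#' Within- vs between-patient sharing
#'
#' Labels every unordered sample pair as within-patient or between-patient
#' and collects both focal abundance fractions of each pair as the sharing
#' observations, then compares the two distributions with an unpaired
#' Wilcoxon rank-sum test.
#'
#' @param set a `repertoire_set` with at least 2 patients.
#' @param scheme clonotype key scheme.
#' @return list with `pairs` (data.frame: sample_1, sample_2, relation,
#'   f_1, f_2), `within`, `between` (numeric vectors of fractions) and `p`.
#' @export
interpatient_sharing <- function(set, scheme = "v_aa_j") {
  sids <- names(set$samples)
  if (length(unique(set$meta$patient_id)) < 2) {
    warning("single patient: no between-patient pairs")
  }
  pat <- set$meta$patient_id[match(sids, set$meta$sample_id)]
  freqs <- lapply(set$samples, key_freq, scheme = scheme)
  combos <- utils::combn(seq_along(sids), 2)
  rows <- vector("list", ncol(combos))
  for (k in seq_len(ncol(combos))) {
    i <- combos[1, k]
    j <- combos[2, k]
    shared <- intersect(names(freqs[[i]]), names(freqs[[j]]))
    rows[[k]] <- data.frame(
      sample_1 = sids[i], sample_2 = sids[j],
      relation = if (pat[i] == pat[j]) "within" else "between",
      f_1 = sum(freqs[[i]][shared]), f_2 = sum(freqs[[j]][shared]),
      stringsAsFactors = FALSE
    )
  }
  pairs <- do.call(rbind, rows)
  within <- c(pairs$f_1[pairs$relation == "within"],
              pairs$f_2[pairs$relation == "within"])
  between <- c(pairs$f_1[pairs$relation == "between"],
               pairs$f_2[pairs$relation == "between"])
  p <- if (length(within) && length(between))
    suppressWarnings(stats::wilcox.test(within, between)$p.value)
    else NA_real_
  list(pairs = pairs, within = within, between = between, p = p)
}

#' Public clonotypes across blood samples
#'
#' Finds clonotype keys present in at least `min_prevalence` of the given
#' samples, with their prevalence and mean frequency over the samples that
#' carry them, sorted by prevalence then mean frequency (both descending).
#'
#' @param set a `repertoire_set` (typically restricted to blood samples).
#' @param min_prevalence minimum number of samples carrying the key;
#'   defaults to all samples (fully public).
#' @param scheme clonotype key scheme.
#' @return data.frame with key, prevalence, mean_fraction.
#' @export
public_clonotypes <- function(set, min_prevalence = length(set$samples),
                              scheme = "v_aa_j") {
  if (length(set$samples) < 2) stop("need at least 2 samples")
  freqs <- lapply(set$samples, key_freq, scheme = scheme)
  keys <- unlist(lapply(freqs, names), use.names = FALSE)
  prev <- table(keys)
  hit <- names(prev)[prev >= min_prevalence]
  if (length(hit) == 0) {
    return(data.frame(key = character(0), prevalence = integer(0),
                      mean_fraction = numeric(0)))
  }
  mean_frac <- vapply(hit, function(k) {
    v <- vapply(freqs, function(f) if (k %in% names(f)) f[[k]] else
      NA_real_, numeric(1))
    mean(v, na.rm = TRUE)
  }, numeric(1))
  out <- data.frame(key = hit, prevalence = as.integer(prev[hit]),
                    mean_fraction = unname(mean_frac),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$prevalence, -out$mean_fraction, out$key), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Association of clonotype presence with a clinical covariate
#'
#' Chi-square test of independence (no continuity correction, i.e. the
#' plain `sum((O-E)^2 / E)` statistic) on the presence/absence x category
#' contingency table of one clonotype against one clinical column.
#'
#' @param presence logical (or 0/1) vector: does the sample carry the
#'   clonotype.
#' @param covariate categorical clinical value per sample.
#' @return list with `statistic`, `p`, `table`.
#' @export
clinical_association <- function(presence, covariate) {
  tab <- table(factor(presence, levels = c(FALSE, TRUE),
                      labels = c("without", "with")),
               as.character(covariate))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate contingency table: empty margin")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p = ct$p.value, table = tab)
}

#' Screen recurrent blood clonotypes for clinical association
#'
#' Selects clonotypes present in a prevalence window of the blood samples
#' (default 47%-80%, so the "without" group keeps a workable size) and
#' tests each against each requested clinical column.
#'
#' @param set blood `repertoire_set` whose metadata carries the clinical
#'   columns.
#' @param fields clinical column names in `set$meta`.
#' @param prevalence_range numeric length-2 fraction window (inclusive).
#' @param scheme clonotype key scheme.
#' @return data.frame with key, prevalence, field, statistic, p.
#' @export
clinical_association_screen <- function(set, fields,
                                        prevalence_range = c(0.47, 0.80),
                                        scheme = "v_aa_j") {
  n <- length(set$samples)
  freqs <- lapply(set$samples, key_freq, scheme = scheme)
  keys <- unlist(lapply(freqs, names), use.names = FALSE)
  prev <- table(keys)
  lo <- ceiling(prevalence_range[1] * n)
  hi <- floor(prevalence_range[2] * n)
  cand <- names(prev)[prev >= lo & prev <= hi]
  rows <- list()
  for (k in cand) {
    presence <- vapply(freqs, function(f) k %in% names(f), logical(1))
    for (f in fields) {
      cov <- set$meta[[f]][match(names(set$samples), set$meta$sample_id)]
      res <- tryCatch(clinical_association(presence, cov),
                      error = function(e) NULL)
      if (!is.null(res)) {
        rows[[length(rows) + 1]] <- data.frame(
          key = k, prevalence = as.integer(prev[[k]]), field = f,
          statistic = res$statistic, p = res$p, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(key = character(0), prevalence = integer(0),
                      field = character(0), statistic = numeric(0),
                      p = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$p), , drop = FALSE]
}
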