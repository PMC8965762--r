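# Per-sample clonotype diversity: richness, Shannon entropy, top-k clonality,
# the entropy-vs-clonality correlation, and grouped tissue comparisons with
# Bonferroni-adjusted pairwise follow-ups.

#' Shannon entropy of a clonotype frequency distribution
#'
#' `H = -sum(p * log(p))` with the `0 * log(0) = 0` convention. Natural log
#' (nats) by default; pass `base = 2` for bits.
#'
#' @param frequencies non-negative frequencies summing to 1 (tolerance 1e-9).
#' @param base logarithm base.
#' @return entropy (scalar).
#' @examples
#' shannon_entropy(rep(0.25, 4)) # log(4)
#' @export
shannon_entropy <- function(frequencies, base = exp(1)) {
  if (any(is.na(frequencies)) || any(frequencies < 0)) {
    stop("frequencies must be non-negative")
  }
  if (abs(sum(frequencies) - 1) > 1e-9) {
    stop("frequencies must sum to 1 (got ", format(sum(frequencies)), ")")
  }
  p <- frequencies[frequencies > 0]
  -sum(p * log(p, base = base))
}

#' Summed abundance of the k most-abundant clonotypes
#'
#' Clonotypes are aggregated at the requested identity level before ranking;
#' ties at the cut are broken by key lexicographic order so the statistic is
#' deterministic. Returns 1 when the sample has at most `k` clonotypes.
#'
#' @param sample a clonotype record table (one element of
#'   `repertoire_set$samples`).
#' @param k number of top clonotypes (default 100).
#' @param level identity level, `"aa"`, `"nt"` or `"v_aa_j"`.
#' @return fraction in \[0, 1\].
#' @export
top_k_abundance <- function(sample, k = 100, level = "aa") {
  stopifnot(k >= 1)
  f <- key_freq(sample, level)
  if (length(f) == 0) stop("sample has no records usable at level ", level)
  f <- f[order(-f, names(f))]
  sum(f[seq_len(min(k, length(f)))])
}

#' Per-sample diversity table
#'
#' Computes, for every sample, clonotype richness, Shannon entropy and top-k
#' abundance at the requested CDR3 identity level, joined with sample
#' metadata.
#'
#' @param set a `repertoire_set`.
#' @param level `"aa"` (default), `"nt"` or `"v_aa_j"`.
#' @param k top-k cut (default 100).
#' @param base entropy log base (default natural).
#' @return data.frame with columns sample_id, patient_id, tissue, cohort,
#'   level, n_clonotypes, entropy, top_k_abundance.
#' @export
diversity_table <- function(set, level = c("aa", "nt", "v_aa_j"), k = 100,
                            base = exp(1)) {
  level <- match.arg(level)
  rows <- lapply(names(set$samples), function(sid) {
    f <- key_freq(set$samples[[sid]], level)
    data.frame(
      sample_id = sid,
      level = level,
      n_clonotypes = length(f),
      entropy = shannon_entropy(f, base = base),
      top_k_abundance = top_k_abundance(set$samples[[sid]], k, level),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  merge(set$meta[, c("sample_id", "patient_id", "tissue", "cohort")], out,
        by = "sample_id", sort = FALSE)
}

#' Correlation between diversity and clonality
#'
#' Pearson correlation (with the usual t-test on the correlation
#' coefficient) between per-sample Shannon entropy and top-k abundance; in a
#' repertoire dominated by expanded clones the two move in opposite
#' directions, so r is expected to be strongly negative.
#'
#' @param div a data.frame from [diversity_table()] (needs columns `entropy`
#'   and `top_k_abundance`).
#' @return list with `r`, `p`, `n`.
#' @export
entropy_clonality_correlation <- function(div) {
  if (nrow(div) < 3) stop("need at least 3 samples")
  if (stats::sd(div$entropy) == 0 || stats::sd(div$top_k_abundance) == 0) {
    stop("correlation undefined: zero variance")
  }
  ct <- stats::cor.test(div$entropy, div$top_k_abundance, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = nrow(div))
}

#' Compare a per-sample statistic across tissue groups
#'
#' Runs the omnibus and all pairwise two-group tests on a per-sample value
#' (entropy, richness, an overlap fraction, ...) grouped by tissue or any
#' other label. Paired variants (`paired_t`, paired `wilcoxon`) restrict
#' each pairwise comparison to patients contributing both groups and pair
#' by `patient_id`. Pairwise p-values are Bonferroni-adjusted by the number
#' of pairwise comparisons (capped at 1).
#'
#' @param values numeric vector of the statistic.
#' @param group group label per value.
#' @param patient patient id per value (required for paired tests).
#' @param test `"paired_t"`, `"kruskal_wallis"` or `"wilcoxon"`; the omnibus
#'   is always Kruskal-Wallis except under `paired_t`, where it is omitted.
#' @param paired for `test = "wilcoxon"`: use the signed-rank (paired)
#'   variant instead of rank-sum.
#' @return list with `omnibus_p` (NA when not computed) and `pairwise`, a
#'   data.frame with group1, group2, n, p, p_adjusted.
#' @export
compare_groups <- function(values, group,
                           patient = NULL,
                           test = c("kruskal_wallis", "paired_t", "wilcoxon"),
                           paired = FALSE) {
  test <- match.arg(test)
  group <- as.character(group)
  groups <- sort(unique(group))
  if (length(groups) < 2) stop("need at least 2 groups")
  needs_pairing <- test == "paired_t" || (test == "wilcoxon" && paired)
  if (needs_pairing && is.null(patient)) {
    stop("paired comparisons require 'patient'")
  }

  omnibus_p <- if (test == "paired_t") NA_real_ else
    stats::kruskal.test(values, factor(group))$p.value

  pairs <- utils::combn(groups, 2, simplify = FALSE)
  n_comp <- length(pairs)
  rows <- lapply(pairs, function(pr) {
    i <- group == pr[1]
    j <- group == pr[2]
    if (needs_pairing) {
      common <- intersect(patient[i], patient[j])
      if (length(common) < 2) {
        stop("fewer than 2 complete pairs for ", pr[1], " vs ", pr[2])
      }
      x <- values[i][match(common, patient[i])]
      y <- values[j][match(common, patient[j])]
      p <- if (test == "paired_t") stats::t.test(x, y, paired = TRUE)$p.value
        else suppressWarnings(
          stats::wilcox.test(x, y, paired = TRUE)$p.value)
      n <- length(common)
    } else {
      x <- values[i]
      y <- values[j]
      p <- suppressWarnings(stats::wilcox.test(x, y)$p.value)
      n <- length(x) + length(y)
    }
    data.frame(group1 = pr[1], group2 = pr[2], n = n, p = p,
               p_adjusted = min(1, p * n_comp), stringsAsFactors = FALSE)
  })
  list(omnibus_p = omnibus_p, pairwise = do.call(rbind, rows),
       test = test, n_comparisons = n_comp)
}
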