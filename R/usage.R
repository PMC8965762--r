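# Gene-usage matrices (V, J, VJ) over the frozen TRB grid, cross-group
# differential-usage testing, dominant-pairing selection, and PCA on scaled
# VJ usage.

#' Gene-usage matrix
#'
#' Samples x features matrix of relative abundances over the full gene grid
#' of the universe (48 V, 13 J or 624 VJ columns); features never observed
#' in a sample are explicit zeros and every row sums to 1. Records whose V
#' or J call is outside the universe are ignored; samples with zero usable
#' reads are dropped with a warning.
#'
#' @param set a `repertoire_set`.
#' @param level `"VJ"` (default), `"V"` or `"J"`.
#' @param universe a `gene_universe`.
#' @return numeric matrix with sample ids as rownames and feature names
#'   (`"<V>_<J>"` at VJ level) as colnames.
#' @export
usage_matrix <- function(set, level = c("VJ", "V", "J"),
                         universe = trb_gene_universe()) {
  level <- match.arg(level)
  features <- switch(level, V = universe$v_genes, J = universe$j_genes,
                     VJ = universe$vj_pairings)
  rows <- lapply(names(set$samples), function(sid) {
    s <- set$samples[[sid]]
    ok <- s$v_gene %in% universe$v_genes & s$j_gene %in% universe$j_genes
    s <- s[ok, , drop = FALSE]
    if (nrow(s) == 0 || sum(s$count) == 0) return(NULL)
    feat <- switch(level, V = s$v_gene, J = s$j_gene,
                   VJ = paste(s$v_gene, s$j_gene, sep = "_"))
    agg <- rowsum(s$count, feat)
    v <- stats::setNames(numeric(length(features)), features)
    v[rownames(agg)] <- agg[, 1] / sum(agg[, 1])
    v
  })
  names(rows) <- names(set$samples)
  dropped <- names(rows)[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    warning("sample(s) with zero usable reads dropped: ",
            paste(dropped, collapse = ", "))
    rows <- rows[!names(rows) %in% dropped]
  }
  do.call(rbind, rows)
}

#' Differential usage testing across groups
#'
#' Per feature: a Kruskal-Wallis omnibus test across the groups, then all
#' pairwise Wilcoxon follow-ups, Bonferroni-adjusted by the number of
#' pairwise comparisons. When `paired_by` is given, pairwise follow-ups use
#' the signed-rank test on subjects contributing both groups; the omnibus
#' is Kruskal-Wallis restricted to subjects contributing every group
#' (see the package vignette for why "paired" omnibus testing is
#' approximated this way). Features constant across all samples are
#' reported with NA p-values.
#'
#' @param matrix a [usage_matrix()].
#' @param groups group label per row of `matrix`.
#' @param paired_by optional subject (patient) id per row.
#' @return list with `omnibus` (data.frame feature, p) and `pairwise`
#'   (data.frame feature, group1, group2, p, p_adjusted).
#' @export
group_usage_test <- function(matrix, groups, paired_by = NULL) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(matrix))
  glev <- sort(unique(groups))
  if (length(glev) < 2) stop("need at least 2 groups")
  if (any(table(groups) < 2)) stop("each group needs at least 2 samples")
  pairs <- utils::combn(glev, 2, simplify = FALSE)
  n_comp <- length(pairs)

  complete <- rep(TRUE, nrow(matrix))
  if (!is.null(paired_by)) {
    tab <- table(paired_by, groups)
    full <- rownames(tab)[apply(tab > 0, 1, all)]
    complete <- paired_by %in% full
  }

  omni <- vapply(colnames(matrix), function(f) {
    x <- matrix[complete, f]
    if (stats::sd(matrix[, f]) == 0) return(NA_real_)
    if (length(unique(groups[complete])) < 2) return(NA_real_)
    stats::kruskal.test(x, factor(groups[complete]))$p.value
  }, numeric(1))

  pw <- list()
  for (pr in pairs) {
    i <- groups == pr[1]
    j <- groups == pr[2]
    for (f in colnames(matrix)) {
      if (stats::sd(matrix[, f]) == 0) {
        p <- NA_real_
      } else if (!is.null(paired_by)) {
        common <- intersect(paired_by[i], paired_by[j])
        if (length(common) < 2) {
          p <- NA_real_
        } else {
          x <- matrix[i, f][match(common, paired_by[i])]
          y <- matrix[j, f][match(common, paired_by[j])]
          p <- if (all(x == y)) 1 else
            suppressWarnings(stats::wilcox.test(x, y,
                                                paired = TRUE)$p.value)
        }
      } else {
        p <- suppressWarnings(
          stats::wilcox.test(matrix[i, f], matrix[j, f])$p.value)
      }
      pw[[length(pw) + 1]] <- data.frame(
        feature = f, group1 = pr[1], group2 = pr[2], p = p,
        p_adjusted = if (is.na(p)) NA_real_ else min(1, p * n_comp),
        stringsAsFactors = FALSE)
    }
  }
  list(omnibus = data.frame(feature = colnames(matrix), p = unname(omni),
                            stringsAsFactors = FALSE),
       pairwise = do.call(rbind, pw))
}

#' Dominant differentially-used VJ pairings
#'
#' Features with mean abundance across all samples strictly above
#' `mean_min` (default 1%) and Kruskal-Wallis p below `p_max` (default
#' 0.01) across the groups.
#'
#' @param matrix a VJ-level [usage_matrix()].
#' @param groups group label per row.
#' @param mean_min mean-abundance threshold (strict `>`).
#' @param p_max omnibus p-value threshold (strict `<`).
#' @param paired_by optional subject id per row (see [group_usage_test()]).
#' @return character vector of feature names, ordered by decreasing mean
#'   abundance.
#' @export
dominant_vj <- function(matrix, groups, mean_min = 0.01, p_max = 0.01,
                        paired_by = NULL) {
  m <- colMeans(matrix)
  cand <- names(m)[m > mean_min]
  if (!length(cand)) return(character(0))
  gt <- group_usage_test(matrix[, cand, drop = FALSE], groups,
                         paired_by = paired_by)
  keep <- gt$omnibus$feature[!is.na(gt$omnibus$p) & gt$omnibus$p < p_max]
  keep[order(-m[keep])]
}

#' PCA of scaled gene usage
#'
#' Principal component analysis of the usage matrix after per-feature
#' centering and (by default) unit-variance scaling; zero-variance features
#' are dropped with a warning beforehand. Component signs are fixed so the
#' largest-magnitude loading of each component is positive, making scores
#' reproducible across platforms.
#'
#' @param matrix a [usage_matrix()] (>= 3 rows).
#' @param scale z-score features before decomposition (default TRUE).
#' @return list with `scores` (data.frame sample_id, PC1, PC2),
#'   `explained` (variance fraction of every component), `loadings`
#'   (feature x component matrix) and `dropped` (zero-variance features).
#' @export
pca_usage <- function(matrix, scale = TRUE) {
  if (nrow(matrix) < 3) stop("PCA needs at least 3 samples")
  sds <- apply(matrix, 2, stats::sd)
  dropped <- colnames(matrix)[sds == 0]
  if (length(dropped)) {
    warning(length(dropped), " zero-variance feature(s) dropped before PCA")
  }
  m <- matrix[, sds > 0, drop = FALSE]
  pc <- stats::prcomp(m, center = TRUE, scale. = scale)
  # sign convention: largest-|loading| of each PC is positive
  for (k in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, k]))
    if (pc$rotation[i, k] < 0) {
      pc$rotation[, k] <- -pc$rotation[, k]
      pc$x[, k] <- -pc$x[, k]
    }
  }
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  list(
    scores = data.frame(sample_id = rownames(m), PC1 = pc$x[, 1],
                        PC2 = pc$x[, 2], stringsAsFactors = FALSE,
                        row.names = NULL),
    explained = explained,
    loadings = pc$rotation,
    dropped = dropped
  )
}

#' Check V/J marginals of a VJ usage matrix
#'
#' The V-level abundance of a gene must equal the sum of its VJ-level
#' abundances over all J (and symmetrically for J). Used as an internal
#' conservation check; returns the maximum absolute discrepancy.
#'
#' @param vj_matrix VJ-level usage matrix.
#' @param v_matrix,j_matrix V- and J-level usage matrices on the same
#'   samples.
#' @return largest absolute difference between marginalized VJ usage and
#'   the direct V/J matrices.
#' @export
usage_marginal_gap <- function(vj_matrix, v_matrix, j_matrix) {
  split_vj <- strsplit(colnames(vj_matrix), "_", fixed = TRUE)
  v_of <- vapply(split_vj, `[`, "", 1L)
  j_of <- vapply(split_vj, `[`, "", 2L)
  gap <- 0
  for (v in colnames(v_matrix)) {
    gap <- max(gap, max(abs(rowSums(vj_matrix[, v_of == v, drop = FALSE]) -
                              v_matrix[, v])))
  }
  for (j in colnames(j_matrix)) {
    gap <- max(gap, max(abs(rowSums(vj_matrix[, j_of == j, drop = FALSE]) -
                              j_matrix[, j])))
  }
  gap
}
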