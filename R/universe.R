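# Frozen TRB gene grid: 48 functional V segments x 13 functional J segments.
# Kept as a packaged text file so the 624-pairing feature space is
# reproducible offline and identical across runs.

.universe_cache <- new.env(parent = emptyenv())

#' TRB gene universe
#'
#' Returns the bundled, frozen universe of human TRB gene segments at gene
#' (allele-collapsed) level: 48 TRBV genes, 13 TRBJ genes, and the full grid
#' of 48 x 13 = 624 V-J pairings. All usage matrices and VJ-level analyses
#' are indexed against this grid so that unobserved genes appear as explicit
#' zeros and feature spaces are comparable across cohorts.
#'
#' @return A list of class `gene_universe` with components:
#'   \describe{
#'     \item{v_genes}{character vector of 48 TRBV gene names}
#'     \item{j_genes}{character vector of 13 TRBJ gene names}
#'     \item{vj_pairings}{character vector of 624 names `"<V>_<J>"`,
#'       V-major order}
#'   }
#' @examples
#' u <- trb_gene_universe()
#' length(u$vj_pairings) # 624
#' @export
trb_gene_universe <- function() {
  if (!is.null(.universe_cache$u)) {
    return(.universe_cache$u)
  }
  path <- system.file("extdata", "trb_genes.tsv", package = "repdx",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  v <- tab$gene[tab$segment == "V"]
  j <- tab$gene[tab$segment == "J"]
  u <- structure(
    list(
      v_genes = v,
      j_genes = j,
      vj_pairings = as.vector(t(outer(v, j, paste, sep = "_")))
    ),
    class = "gene_universe"
  )
  .universe_cache$u <- u
  u
}

#' @export
print.gene_universe <- function(x, ...) {
  cat(sprintf(
    "TRB gene universe: %d V genes x %d J genes = %d VJ pairings\n",
    length(x$v_genes), length(x$j_genes), length(x$vj_pairings)
  ))
  invisible(x)
}
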