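# Clonotype table I/O: AIRR Rearrangement-style TSVs plus a sample-metadata
# table, normalised into a `repertoire_set`.
#
# A repertoire_set is the package's central container:
#   $samples  named list (by sample_id) of clonotype data.frames with columns
#             v_gene, j_gene, cdr3_nt, cdr3_aa, count, freq
#   $meta     data.frame with sample_id, patient_id, tissue, cohort and any
#             further clinical columns
# Records are aggregated by full clonotype identity (v, j, nt, aa); counts are
# read counts and freq = count / total reads of the sample.

AIRR_COLUMNS <- c(v_call = "v_call", j_call = "j_call",
                  junction = "junction", junction_aa = "junction_aa",
                  duplicate_count = "duplicate_count")

#' Strip IMGT allele suffixes from gene calls
#'
#' Truncates gene names at the first `"*"` (e.g. `"TRBV20-1*01"` becomes
#' `"TRBV20-1"`). Idempotent; names without an allele suffix pass through
#' unchanged.
#'
#' @param x character vector of gene calls.
#' @return character vector of gene-level names.
#' @export
strip_allele <- function(x) {
  sub("\\*.*$", "", x)
}

#' Build clonotype key strings
#'
#' Clonotype identity is configurable: `"aa"` keys on the CDR3 amino-acid
#' string alone, `"nt"` on the CDR3 nucleotide string, and `"v_aa_j"`
#' (the default throughout the package) on `"<v_gene>_<cdr3_aa>_<j_gene>"`,
#' the convention in which public blood clonotypes are usually reported.
#'
#' @param records data.frame with columns `v_gene`, `j_gene`, `cdr3_nt`,
#'   `cdr3_aa` (only those required by the scheme need be non-empty).
#' @param scheme one of `"v_aa_j"`, `"aa"`, `"nt"`.
#' @return character vector of keys, one per record.
#' @examples
#' r <- data.frame(v_gene = "TRBV20-1", j_gene = "TRBJ2-5",
#'                 cdr3_nt = "tgt", cdr3_aa = "CSAGSQGKQETQYF")
#' clonotype_key(r, "v_aa_j")
#' @export
clonotype_key <- function(records, scheme = c("v_aa_j", "aa", "nt")) {
  scheme <- match.arg(scheme)
  need <- switch(scheme,
    aa = "cdr3_aa",
    nt = "cdr3_nt",
    v_aa_j = c("v_gene", "cdr3_aa", "j_gene")
  )
  for (col in need) {
    vals <- records[[col]]
    if (is.null(vals) || any(is.na(vals)) || any(!nzchar(vals))) {
      stop("clonotype key scheme '", scheme, "' requires non-empty '", col, "'")
    }
  }
  switch(scheme,
    aa = records$cdr3_aa,
    nt = records$cdr3_nt,
    v_aa_j = paste(records$v_gene, records$cdr3_aa, records$j_gene, sep = "_")
  )
}

# Merge duplicate clonotypes (same v, j, nt, aa) by summing counts and
# recompute per-sample frequencies. Idempotent.
aggregate_records <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) {
    records$freq <- numeric(0)
    return(records)
  }
  id <- paste(records$v_gene, records$j_gene, records$cdr3_nt,
              records$cdr3_aa, sep = "\r")
  if (anyDuplicated(id)) {
    count <- rowsum(records$count, id, reorder = FALSE)
    first <- !duplicated(id)
    records <- records[first, , drop = FALSE]
    records$count <- as.integer(count[match(id[first], rownames(count)), 1L])
  }
  records <- records[order(-records$count,
                           records$v_gene, records$cdr3_aa, records$j_gene), ,
                     drop = FALSE]
  rownames(records) <- NULL
  records$freq <- records$count / sum(records$count)
  records
}

new_repertoire_set <- function(samples, meta) {
  stopifnot(is.list(samples), is.data.frame(meta))
  if (!all(names(samples) %in% meta$sample_id)) {
    missing <- setdiff(names(samples), meta$sample_id)
    stop("samples without metadata: ", paste(missing, collapse = ", "))
  }
  meta <- meta[match(names(samples), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  structure(list(samples = samples, meta = meta), class = "repertoire_set")
}

#' @export
print.repertoire_set <- function(x, ...) {
  cat(sprintf("repertoire_set: %d samples, %d patients\n",
              length(x$samples), length(unique(x$meta$patient_id))))
  if (length(x$samples)) {
    cat(sprintf("  tissues: %s\n",
                paste(sort(unique(x$meta$tissue)), collapse = " ")))
    cat(sprintf("  clonotypes/sample: median %d\n",
                as.integer(stats::median(vapply(x$samples, nrow, 0L)))))
  }
  invisible(x)
}

#' Total reads per sample
#' @param set a `repertoire_set`.
#' @return named integer vector of per-sample read totals.
#' @export
total_reads <- function(set) {
  vapply(set$samples, function(s) sum(s$count), numeric(1))
}

#' Read sample metadata
#'
#' @param path TSV with header `sample_id`, `patient_id`, `tissue`, `cohort`
#'   followed by free-form clinical columns. Tissue codes are restricted to
#'   `T` (tumor), `N` (adjacent non-tumor) and `B` (peripheral blood);
#'   cohort to `case` / `control`.
#' @return data.frame of metadata.
#' @export
read_metadata <- function(path) {
  meta <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
  required <- c("sample_id", "patient_id", "tissue", "cohort")
  absent <- setdiff(required, names(meta))
  if (length(absent)) {
    stop("metadata is missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  bad <- setdiff(unique(meta$tissue), c("T", "N", "B"))
  if (length(bad)) {
    stop("unknown tissue code(s): ", paste(bad, collapse = ", "),
         " (expected T, N or B)")
  }
  bad <- setdiff(unique(meta$cohort), c("case", "control"))
  if (length(bad)) {
    stop("unknown cohort label(s): ", paste(bad, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata")
  }
  dup <- duplicated(meta[, c("patient_id", "tissue")])
  if (any(dup)) {
    stop("duplicate (patient_id, tissue) combination in metadata: ",
         paste(meta$sample_id[dup], collapse = ", "))
  }
  meta
}

read_one_airr <- function(path, sample_id) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  absent <- setdiff(unname(AIRR_COLUMNS), names(tab))
  # junction (nt) is tolerated as missing; the rest are required
  absent <- setdiff(absent, "junction")
  if (length(absent)) {
    stop("AIRR file '", basename(path), "' is missing required column(s): ",
         paste(absent, collapse = ", "))
  }
  count <- suppressWarnings(as.numeric(tab$duplicate_count))
  if (nrow(tab) && (any(is.na(count)) || any(count != floor(count)))) {
    stop("non-integer duplicate_count in '", basename(path), "'")
  }
  records <- data.frame(
    v_gene = strip_allele(tab$v_call),
    j_gene = strip_allele(tab$j_call),
    cdr3_nt = if ("junction" %in% names(tab)) tab$junction else
      character(nrow(tab)),
    cdr3_aa = tab$junction_aa,
    count = as.integer(count),
    stringsAsFactors = FALSE
  )
  aggregate_records(records)
}

#' Read AIRR-style clonotype tables into a repertoire set
#'
#' `path` may be a directory of per-sample TSVs named `<sample_id>.tsv` (or
#' `<sample_id>.airr.tsv`), or a single combined TSV carrying a `sample_id`
#' column. Each table must have columns `v_call`, `j_call`, `junction_aa`
#' and `duplicate_count` (`junction`, the nucleotide string, is optional;
#' extra columns are ignored). Gene calls are collapsed to gene level and
#' rows with identical clonotype identity are merged by summing counts.
#'
#' @param path directory or file of clonotype tables.
#' @param metadata_path sample metadata TSV (see [read_metadata()]).
#' @return a `repertoire_set`.
#' @export
read_airr <- function(path, metadata_path) {
  meta <- read_metadata(metadata_path)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
    files <- files[basename(files) != basename(metadata_path)]
    ids <- sub("\\.airr\\.tsv$|\\.tsv$", "", basename(files))
    samples <- lapply(seq_along(files),
                      function(i) read_one_airr(files[i], ids[i]))
    names(samples) <- ids
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    if (!"sample_id" %in% names(tab)) {
      stop("combined AIRR file is missing required column(s): sample_id")
    }
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp), add = TRUE)
    samples <- lapply(split(tab, tab$sample_id), function(sub) {
      utils::write.table(sub, tmp, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      read_one_airr(tmp, sub$sample_id[1])
    })
  }
  empty <- vapply(samples, nrow, 0L) == 0
  if (any(empty)) {
    warning("empty clonotype table(s) dropped: ",
            paste(names(samples)[empty], collapse = ", "))
    samples <- samples[!empty]
  }
  if (length(samples) == 0) {
    warning("no clonotype records found under '", path, "'")
  }
  absent <- setdiff(names(samples), meta$sample_id)
  if (length(absent)) {
    stop("sample(s) without metadata: ", paste(absent, collapse = ", "))
  }
  new_repertoire_set(samples, meta)
}

#' Validate a repertoire set against the bundled gene universe
#'
#' Checks every record's V and J call against the frozen TRB gene lists and
#' its count for positivity. Under `policy = "strict"` the first violation
#' raises an error; under `"quarantine"` offending records are dropped and
#' reported.
#'
#' @param set a `repertoire_set`.
#' @param policy `"strict"` or `"quarantine"`.
#' @param universe a `gene_universe`; defaults to the bundled one.
#' @return a list of class `validation_report`: `set` (the possibly cleaned
#'   set), `summary` (per-sample record and rejection counts) and
#'   `rejected` (data.frame of dropped records with reasons).
#' @export
validate_samples <- function(set, policy = c("quarantine", "strict"),
                             universe = trb_gene_universe()) {
  policy <- match.arg(policy)
  rejected <- list()
  summary <- data.frame(sample_id = names(set$samples),
                        n_records = NA_integer_, n_rejected = NA_integer_,
                        stringsAsFactors = FALSE)
  for (i in seq_along(set$samples)) {
    s <- set$samples[[i]]
    reason <- rep(NA_character_, nrow(s))
    reason[!(s$j_gene %in% universe$j_genes)] <- "unknown gene"
    reason[!(s$v_gene %in% universe$v_genes)] <- "unknown gene"
    reason[s$count < 1] <- "nonpositive count"
    bad <- !is.na(reason)
    if (any(bad) && policy == "strict") {
      k <- which(bad)[1]
      stop("sample '", names(set$samples)[i], "': ", reason[k],
           " (", s$v_gene[k], "/", s$j_gene[k], ", count=", s$count[k], ")")
    }
    if (any(bad)) {
      rej <- s[bad, , drop = FALSE]
      rej$sample_id <- names(set$samples)[i]
      rej$reason <- reason[bad]
      rejected[[length(rejected) + 1]] <- rej
      s <- aggregate_records(s[!bad, , drop = FALSE])
      set$samples[[i]] <- s
    }
    summary$n_records[i] <- nrow(s)
    summary$n_rejected[i] <- sum(bad)
  }
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame(sample_id = character(0), reason = character(0))
  structure(list(set = set, summary = summary, rejected = rejected,
                 policy = policy),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("validation (%s): %d samples, %d rejected records\n",
              x$policy, nrow(x$summary), sum(x$summary$n_rejected)))
  if (nrow(x$rejected)) {
    print(table(x$rejected$reason))
  }
  invisible(x)
}

#' Write a normalized clonotype table
#'
#' One row per clonotype per sample with columns `sample_id`, `v_gene`,
#' `j_gene`, `cdr3_nt`, `cdr3_aa`, `count`, `frequency`.
#'
#' @param set a `repertoire_set`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(set, path) {
  rows <- lapply(names(set$samples), function(id) {
    s <- set$samples[[id]]
    cbind(data.frame(sample_id = rep(id, nrow(s))), s[,
      c("v_gene", "j_gene", "cdr3_nt", "cdr3_aa", "count")],
      frequency = s$freq)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Per-sample named frequency vector keyed by clonotype, aggregated under the
# given scheme. Records lacking a field the scheme needs are dropped.
key_freq <- function(sample, scheme = "v_aa_j") {
  ok <- switch(scheme,
    aa = nzchar(sample$cdr3_aa) & !is.na(sample$cdr3_aa),
    nt = nzchar(sample$cdr3_nt) & !is.na(sample$cdr3_nt),
    v_aa_j = nzchar(sample$cdr3_aa) & !is.na(sample$cdr3_aa) &
      nzchar(sample$v_gene) & nzchar(sample$j_gene)
  )
  s <- sample[ok, , drop = FALSE]
  if (nrow(s) == 0) return(stats::setNames(numeric(0), character(0)))
  keys <- clonotype_key(s, scheme)
  agg <- rowsum(s$count, keys, reorder = TRUE)
  stats::setNames(agg[, 1] / sum(agg[, 1]), rownames(agg))
}
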