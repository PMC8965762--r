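# Pipeline orchestration: one validated config drives
# simulate -> validate -> diversity -> overlap -> usage/pca -> markers ->
# classify, with every stage output written to disk and a manifest
# sufficient to re-run bit-identically.

RUN_CONFIG_KEYS <- c("input", "simulate", "key_scheme", "level", "top_k",
                     "entropy_base", "lfc_min", "auc_min", "train_fraction",
                     "n_folds", "n_repeats", "threshold", "seed", "out_dir",
                     "stages")

#' Build and validate a pipeline run configuration
#'
#' A run either reads clonotype tables (`input = list(airr = ...,
#' metadata = ...)`) or simulates them (`simulate = list(...)` of
#' [sim_config()] arguments, plus `what = "tissue"` and/or `"cohorts"`).
#' Unknown keys and out-of-range thresholds are rejected before any
#' computation. `config` may also be the path to a YAML file with the same
#' structure.
#'
#' @param config named list or YAML file path.
#' @return validated list of class `run_config`.
#' @export
run_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  defaults <- list(key_scheme = "v_aa_j", level = "aa", top_k = 100,
                   entropy_base = exp(1), lfc_min = 0.25, auc_min = 0.7,
                   train_fraction = 0.8, n_folds = 10, n_repeats = 100,
                   threshold = 0.5, seed = 1, out_dir = "repdx_out",
                   stages = c("validate", "diversity", "overlap", "usage",
                              "pca", "markers", "classify"))
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$key_scheme %in% c("v_aa_j", "aa", "nt")) {
    stop("key_scheme must be one of v_aa_j, aa, nt")
  }
  if (!cfg$level %in% c("aa", "nt")) stop("level must be aa or nt")
  in_01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!in_01(cfg$auc_min)) stop("auc_min must lie in [0, 1]")
  if (!in_01(cfg$threshold)) stop("threshold must lie in [0, 1]")
  if (!in_01(cfg$train_fraction)) stop("train_fraction must lie in [0, 1]")
  if (cfg$lfc_min < 0) stop("lfc_min must be >= 0")
  if (cfg$top_k < 1) stop("top_k must be >= 1")
  if (is.null(config$input) && is.null(config$simulate)) {
    stop("config needs either 'input' or 'simulate'")
  }
  structure(cfg, class = "run_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the requested stages on read or simulated repertoires, writes
#' every stage output under `out_dir`, and returns (and writes) a manifest
#' recording the configuration, seeds, package version and the md5 digest
#' of every output file. Marker screening and classification run only when
#' both cohorts are present. Identical config and seed give identical
#' outputs and manifest.
#'
#' @param config a [run_config()] (or list / YAML path coercible to one).
#' @param quiet suppress per-stage log lines.
#' @return the manifest list, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[repdx] ", sprintf(...))
  outputs <- character(0)
  truth <- NULL

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    what <- sim_args$what %||% "tissue"
    sim_args$what <- NULL
    sim_args$seed <- sim_args$seed %||% cfg$seed
    sc <- do.call(sim_config, sim_args)
    say("simulate: %s cohort, seed %d", what, sc$seed)
    sim <- if (identical(what, "cohorts")) simulate_cohorts(sc) else
      simulate_tissue_cohort(sc)
    set <- sim$set
    truth <- sim$truth
    fx_dir <- file.path(cfg$out_dir, "fixture")
    outputs <- c(outputs, write_fixture(set, truth, fx_dir))
  } else {
    say("read: %s", cfg$input$airr)
    set <- read_airr(cfg$input$airr, cfg$input$metadata)
  }

  if ("validate" %in% cfg$stages) {
    rep <- validate_samples(set, policy = "quarantine")
    set <- rep$set
    p <- write_tsv(rep$summary, file.path(cfg$out_dir, "validation.tsv"))
    outputs <- c(outputs, p)
    say("validate: %d samples, %d rejected records", nrow(rep$summary),
        sum(rep$summary$n_rejected))
  }

  if ("diversity" %in% cfg$stages) {
    div <- diversity_table(set, level = cfg$level, k = cfg$top_k,
                           base = cfg$entropy_base)
    outputs <- c(outputs, write_tsv(div, file.path(cfg$out_dir,
                                                   "diversity.tsv")))
    say("diversity: %d samples at %s level", nrow(div), cfg$level)
  }

  if ("overlap" %in% cfg$stages &&
      length(unique(set$meta$tissue)) > 1) {
    ov <- patient_overlap(set, scheme = cfg$key_scheme)
    outputs <- c(outputs, write_tsv(ov, file.path(cfg$out_dir,
                                                  "overlap.tsv")))
    if (any(stats::complete.cases(ov[, c("E_T", "E_N")]))) {
      es <- expansion_summary(ov)
      p <- file.path(cfg$out_dir, "expansion.json")
      jsonlite::write_json(es, p, auto_unbox = TRUE, digits = NA)
      outputs <- c(outputs, p)
    }
    say("overlap: %d patients", nrow(ov))
  }

  mat <- NULL
  if (any(c("usage", "pca", "markers", "classify") %in% cfg$stages)) {
    for (lev in c("V", "J", "VJ")) {
      m <- usage_matrix(set, level = lev)
      if (lev == "VJ") mat <- m
      p <- write_tsv(data.frame(sample_id = rownames(m), m,
                                check.names = FALSE),
                     file.path(cfg$out_dir, paste0("usage_", lev, ".tsv")))
      outputs <- c(outputs, p)
    }
    say("usage: %d samples x %d VJ features", nrow(mat), ncol(mat))
  }

  if ("pca" %in% cfg$stages && nrow(mat) >= 3) {
    pc <- suppressWarnings(pca_usage(mat))
    outputs <- c(outputs, write_tsv(pc$scores,
                                    file.path(cfg$out_dir, "pca.tsv")))
    say("pca: PC1 %.1f%%, PC2 %.1f%% of variance",
        100 * pc$explained[1], 100 * pc$explained[2])
  }

  cohorts <- set$meta$cohort[match(rownames(mat), set$meta$sample_id)]
  two_cohorts <- !is.null(mat) && length(unique(cohorts)) == 2

  if ("markers" %in% cfg$stages && two_cohorts) {
    mk <- roc_marker_test(mat, cohorts, lfc_min = cfg$lfc_min,
                          auc_min = cfg$auc_min)
    outputs <- c(outputs, write_tsv(mk, file.path(cfg$out_dir,
                                                  "markers.tsv")))
    say("markers: %d discriminative VJ pairings", nrow(mk))
  }

  if ("classify" %in% cfg$stages && two_cohorts) {
    report <- repeated_evaluation(mat, cohorts, n_repeats = cfg$n_repeats,
                                  train_fraction = cfg$train_fraction,
                                  n_folds = cfg$n_folds,
                                  threshold = cfg$threshold,
                                  base_seed = cfg$seed)
    p <- file.path(cfg$out_dir, "classifier_report.json")
    jsonlite::write_json(
      list(repeats = report$repeats, aggregate = report$aggregate,
           feature_frequency = as.list(report$feature_frequency),
           failures = report$failures, seeds = report$seeds),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    outputs <- c(outputs, p)
    say("classify: mean AUC %.4f over %d repeats",
        report$aggregate$mean[report$aggregate$metric == "auc"],
        report$n_completed)
  }

  manifest <- list(
    package = "repdx",
    version = as.character(utils::packageVersion("repdx")),
    seed = cfg$seed,
    config = unclass(cfg),
    outputs = lapply(sort(outputs), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    })
  )
  mp <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Minimal CLI shim around [run_pipeline()]:
#' `repdx <all|simulate|validate|diversity|overlap|usage|pca|markers|classify>
#' --config run.yaml [--out DIR] [--seed N] [--quiet]`.
#' Installed as `inst/cli/repdx` (run with `Rscript`).
#'
#' @param args command-line arguments (default `commandArgs(TRUE)`).
#' @return exit status, invisibly.
#' @export
repdx_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  stages_all <- c("validate", "diversity", "overlap", "usage", "pca",
                  "markers", "classify")
  if (length(args) == 0 || args[1] %in% c("-h", "--help")) {
    cat("usage: repdx <all|simulate|", paste(stages_all, collapse = "|"),
        "> --config run.yaml [--out DIR] [--seed N] [--quiet]\n", sep = "")
    return(invisible(0L))
  }
  cmd <- args[1]
  opt <- list(quiet = FALSE)
  i <- 2
  while (i <= length(args)) {
    a <- args[i]
    if (a == "--quiet") {
      opt$quiet <- TRUE
      i <- i + 1
    } else if (a %in% c("--config", "--out", "--seed")) {
      if (i == length(args)) stop("missing value for ", a)
      opt[[sub("^--", "", a)]] <- args[i + 1]
      i <- i + 2
    } else {
      stop("unknown argument: ", a)
    }
  }
  if (is.null(opt$config)) stop("--config is required")
  cfg <- yaml::read_yaml(opt$config)
  if (!is.null(opt$out)) cfg$out_dir <- opt$out
  if (!is.null(opt$seed)) cfg$seed <- as.integer(opt$seed)
  if (cmd == "simulate") {
    cfg$stages <- character(0)
  } else if (cmd != "all") {
    if (!cmd %in% stages_all) stop("unknown command: ", cmd)
    cfg$stages <- cmd
  }
  run_pipeline(run_config(cfg), quiet = opt$quiet)
  invisible(0L)
}
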