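# End-to-end protocol driver: build matrix families from blocks, pick
# entropy analogs, split a benchmark by fold, tune gap penalties on the
# training half, evaluate on the test half, and compare matrices with the
# Bayesian bootstrap.

#' Split domains into train and test sets by fold
#'
#' Folds — not sequences — are partitioned at random, and every sequence
#' follows its fold, so no fold (and hence no superfamily) spans the two
#' sides.  This is what makes test-set coverage a remote-homology measure:
#' gap penalties tuned on the training folds have never seen a test fold.
#'
#' @param domains Domain data frame (see [read_scop_fasta()]).
#' @param train_fraction Fraction of folds assigned to training.
#' @param seed Integer seed.
#' @return List with `train`, `test` (domain data frames) and `report`
#'   (fold/superfamily/sequence counts for each side).
#' @export
split_by_fold <- function(domains, train_fraction = 0.5, seed = 1L) {
  folds <- sort(unique(domains$fold_id), method = "radix")
  if (length(folds) < 2L) stop("need at least 2 folds to split")
  n_train <- round(train_fraction * length(folds))
  n_train <- min(max(n_train, 1L), length(folds) - 1L)
  train_folds <- with_seed(seed, sample(folds, n_train))
  in_train <- domains$fold_id %in% train_folds
  tally <- function(d) {
    list(folds = length(unique(d$fold_id)),
         superfamilies = length(unique(d$superfamily_id)),
         sequences = nrow(d))
  }
  train <- domains[in_train, , drop = FALSE]
  test <- domains[!in_train, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  list(train = train, test = test,
       report = list(train = tally(train), test = tally(test)))
}

#' Tune gap penalties on a training set
#'
#' Exhaustive grid search: for every (gap_open, gap_extend) cell, run the
#' all-against-all search on the training domains, normalize, and record
#' coverage at the EPQ limit.  Ties break toward the lower gap_open, then
#' the lower gap_extend.
#'
#' @param domains Training domain data frame.
#' @param matrix Score matrix.
#' @param gap_open,gap_extend Integer vectors defining the grid (defaults
#'   11:16 and 1:2, the conventional search ranges).
#' @param mode Normalization mode (see [normalize_hits()]).
#' @param epq_limit EPQ cutoff.
#' @return List with `best` (named vector `gap_open`, `gap_extend`),
#'   `coverage` (the best cell's coverage) and `table` (the full grid:
#'   `gap_open`, `gap_extend`, `coverage`).
#' @export
tune_gaps <- function(domains, matrix, gap_open = 11:16, gap_extend = 1:2,
                      mode = "raw", epq_limit = 0.01) {
  if (length(gap_open) == 0L || length(gap_extend) == 0L) {
    stop("empty gap-penalty grid")
  }
  grid <- expand.grid(gap_open = as.integer(gap_open),
                      gap_extend = as.integer(gap_extend))
  grid <- grid[order(grid$gap_open, grid$gap_extend), , drop = FALSE]
  rownames(grid) <- NULL
  grid$coverage <- vapply(seq_len(nrow(grid)), function(i) {
    hits <- run_search(domains, domains, matrix,
                       grid$gap_open[i], grid$gap_extend[i])
    hits <- label_hits(hits, domains)
    hits <- normalize_hits(hits, mode)
    coverage_at_epq(cve_curve(hits), epq_limit)
  }, 0)
  best <- grid[order(-grid$coverage, grid$gap_open, grid$gap_extend), ][1L, ]
  list(best = c(gap_open = best$gap_open, gap_extend = best$gap_extend),
       coverage = best$coverage,
       table = grid)
}

#' Study configuration
#'
#' Collects everything [run_study()] needs.  Defaults mirror the standard
#' protocol: a 45..70 threshold sweep, an 11..16 x 1..2 gap grid, coverage
#' read off at 0.01 errors per query, and a fold-disjoint half/half split.
#'
#' @param blocks List of blocks the matrices are built from.
#' @param benchmark Domain data frame used for evaluation.
#' @param variants Clustering variants to build (first acts as reference
#'   unless `reference_variant` says otherwise).
#' @param reference_variant,reference_threshold The reference matrix is
#'   built at this variant/threshold; its entropy is the analog target for
#'   the other variants' sweeps.
#' @param thresholds Sweep thresholds for analog selection.
#' @param gap_open,gap_extend Gap-penalty grids for tuning.
#' @param epq_limit Coverage operating point.
#' @param normalization `"raw"`, `"linear"` or `"quadratic"`.
#' @param bootstrap_B Bootstrap replicates per pairwise comparison.
#' @param train_fraction Fraction of folds used for gap tuning.
#' @param include_control Add a shuffled-cell control matrix (the reference
#'   matrix with its cells permuted) to the evaluation.
#' @param seed Top-level seed; split, bootstrap and control-shuffle seeds
#'   are derived from it and recorded in the report.
#' @return An object of class `study_config`.
#' @export
study_config <- function(blocks, benchmark,
                         variants = c("legacy_blosum", "rblosum", "corblosum"),
                         reference_variant = variants[1L],
                         reference_threshold = 62L,
                         thresholds = 45:70,
                         gap_open = 11:16, gap_extend = 1:2,
                         epq_limit = 0.01,
                         normalization = "raw",
                         bootstrap_B = 200L,
                         train_fraction = 0.5,
                         include_control = TRUE,
                         seed = 1L) {
  variants <- vapply(variants, .check_variant, "")
  stopifnot(reference_variant %in% variants,
            length(thresholds) >= 1L, epq_limit > 0,
            bootstrap_B >= 1L)
  structure(
    list(blocks = blocks, benchmark = benchmark, variants = unname(variants),
         reference_variant = reference_variant,
         reference_threshold = as.integer(reference_threshold),
         thresholds = as.integer(thresholds),
         gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
         epq_limit = epq_limit, normalization = normalization,
         bootstrap_B = as.integer(bootstrap_B),
         train_fraction = train_fraction,
         include_control = isTRUE(include_control),
         seed = as.integer(seed)),
    class = "study_config")
}

#' Run the full study protocol
#'
#' Stages, each logged and aborting with its name on error:
#' 1. build the reference matrix and take its entropy as the analog target;
#' 2. sweep the remaining variants over the thresholds and select analogs;
#' 3. optionally add a shuffled-cell control of the reference matrix;
#' 4. split the benchmark by fold;
#' 5. per matrix, tune gap penalties on the training folds, then evaluate
#'    the test folds at the tuned penalties (search, normalize, CVE);
#' 6. pairwise Bayesian-bootstrap comparisons of the test-set searches.
#'
#' The run is deterministic given the config (all stage seeds derive from
#' `config$seed` and are recorded in the report).
#'
#' @param config A [study_config()].
#' @param verbose Log stage progress with `message()`.
#' @return An object of class `study_report`: `target_entropy`, `matrices`
#'   (named score holders), `sweeps`, `analogs`, `split` report, `tuning`
#'   per matrix, `test` (per-matrix coverage and `cve_curve`), `bootstrap`
#'   (named pairwise comparisons), `seeds`, and the `config`.
#' @export
run_study <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  say <- function(...) if (verbose) message("[study] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("study stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  seeds <- derive_seeds(config$seed, 3L)
  names(seeds) <- c("split", "bootstrap", "control")

  say("building reference ", config$reference_variant, " at L=",
      config$reference_threshold)
  reference <- stage("reference_build",
    build_matrix(config$blocks, config$reference_threshold,
                 config$reference_variant))
  target_H <- reference$entropy

  matrices <- list()
  ref_name <- sprintf("%s%d", config$reference_variant,
                      config$reference_threshold)
  matrices[[ref_name]] <- reference
  sweeps <- list()
  analogs <- list()
  for (v in setdiff(config$variants, config$reference_variant)) {
    say("sweeping ", v, " over ", length(config$thresholds), " thresholds")
    sw <- stage(paste0("sweep_", v),
                entropy_sweep(config$blocks, v, config$thresholds))
    an <- stage(paste0("analog_", v), select_analog(sw, target_H))
    sweeps[[v]] <- sw
    analogs[[v]] <- an[c("threshold", "entropy", "delta")]
    matrices[[sprintf("%s%d", v, an$threshold)]] <- an$model
  }
  if (config$include_control) {
    matrices[["shuffled_control"]] <-
      shuffle_matrix_cells(reference, seeds[["control"]])
  }

  say("splitting benchmark by fold")
  split <- stage("split",
    split_by_fold(config$benchmark, config$train_fraction, seeds[["split"]]))

  tuning <- list()
  test_eval <- list()
  for (nm in names(matrices)) {
    say("tuning gaps for ", nm)
    tu <- stage(paste0("tune_", nm),
      tune_gaps(split$train, matrices[[nm]],
                config$gap_open, config$gap_extend,
                mode = config$normalization, epq_limit = config$epq_limit))
    tuning[[nm]] <- tu
    say("evaluating ", nm, " on test folds at gaps ",
        tu$best[["gap_open"]], "/", tu$best[["gap_extend"]])
    hits <- stage(paste0("test_search_", nm), {
      h <- run_search(split$test, split$test, matrices[[nm]],
                      tu$best[["gap_open"]], tu$best[["gap_extend"]])
      h <- label_hits(h, split$test)
      normalize_hits(h, config$normalization)
    })
    curve <- stage(paste0("test_cve_", nm), cve_curve(hits))
    test_eval[[nm]] <- list(
      gaps = tu$best,
      hits = hits,
      curve = curve,
      coverage = coverage_at_epq(curve, config$epq_limit))
  }

  comparisons <- list()
  nms <- names(matrices)
  if (length(nms) >= 2L) {
    for (i in seq_len(length(nms) - 1L)) {
      for (j in (i + 1L):length(nms)) {
        key <- paste(nms[i], "vs", nms[j])
        say("bootstrap ", key)
        comparisons[[key]] <- stage(paste0("bootstrap_", key),
          bayesian_bootstrap_compare(
            test_eval[[nms[i]]]$hits, test_eval[[nms[j]]]$hits,
            B = config$bootstrap_B, seed = seeds[["bootstrap"]],
            epq_limit = config$epq_limit))
      }
    }
  }

  structure(
    list(target_entropy = target_H,
         matrices = matrices,
         sweeps = sweeps,
         analogs = analogs,
         split = split$report,
         tuning = tuning,
         test = test_eval,
         bootstrap = comparisons,
         seeds = seeds,
         config = config),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> target entropy ", sprintf("%.4f", x$target_entropy),
      " bits\n", sep = "")
  for (nm in names(x$test)) {
    cat(sprintf("  %-22s gaps %d/%d  test coverage %.4f\n", nm,
                x$test[[nm]]$gaps[["gap_open"]],
                x$test[[nm]]$gaps[["gap_extend"]],
                x$test[[nm]]$coverage))
  }
  invisible(x)
}
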