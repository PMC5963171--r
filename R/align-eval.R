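# Smith-Waterman search, score normalization, SCOP-style truth labels,
# coverage-versus-errors-per-query curves, and the Bayesian-bootstrap
# paired comparison of two matrices.

.encode_sequence <- function(seq, alphabet) {
  chars <- .split_residues(seq)
  code <- match(chars, alphabet)
  if (anyNA(code)) {
    stop("residue '", chars[is.na(code)][1L], "' not in matrix alphabet")
  }
  code
}

#' Smith-Waterman local alignment score
#'
#' Maximum local-alignment score under an affine gap model in which a gap of
#' length `l` costs `gap_open + l * gap_extend` (open-plus-extend
#' convention; note that some tools quote penalties in an open-includes-
#' first-extension convention instead, so their "12/1" is this package's
#' `gap_open = 11, gap_extend = 1`... conventions differ and this one is
#' fixed here: the first gapped position already pays both terms).
#' The score is never negative (the empty alignment scores 0) and is
#' symmetric in its sequence arguments.
#'
#' @param query,target Amino-acid strings over the matrix alphabet.
#' @param matrix Score matrix (a [build_matrix()] model, [read_matrix()]
#'   file, or bare symmetric integer matrix with residue dimnames).
#' @param gap_open,gap_extend Positive integer gap penalties,
#'   `gap_open >= gap_extend >= 1`.
#' @return Non-negative integer score.
#' @export
smith_waterman <- function(query, target, matrix, gap_open, gap_extend) {
  S <- .score_matrix(matrix)
  if (gap_extend < 1 || gap_open < gap_extend) {
    stop("gap penalties must satisfy gap_open >= gap_extend >= 1")
  }
  ab <- rownames(S)
  sw_score_cpp(.encode_sequence(query, ab), .encode_sequence(target, ab),
               S, as.integer(gap_open), as.integer(gap_extend))
}

#' All-against-all homology search
#'
#' Scores every (query, target) pair with [smith_waterman()], excluding
#' self-pairs (same id).  Deterministic: hit order and scores do not depend
#' on the database order.
#'
#' @param queries,database Domain data frames (as from [read_scop_fasta()]
#'   or [generate_benchmark()]) with `sid` and `sequence` columns, or named
#'   character vectors of sequences.
#' @param matrix Score matrix (see [smith_waterman()]).
#' @param gap_open,gap_extend Gap penalties.
#' @return Data frame of hits: `query_id`, `target_id`, `raw_score`,
#'   `query_len`, `target_len`, sorted by query id then target id.
#' @export
run_search <- function(queries, database, matrix, gap_open, gap_extend) {
  as_named <- function(x) {
    if (is.data.frame(x)) setNames(x$sequence, x$sid)
    else if (!is.null(names(x))) x
    else stop("sequences must be a domain data frame or a named vector")
  }
  q <- as_named(queries)
  db <- as_named(database)
  S <- .score_matrix(matrix)
  ab <- rownames(S)
  pool_ids <- union(names(q), names(db))
  pool_seq <- c(q, db)[pool_ids]
  enc <- lapply(pool_seq, .encode_sequence, alphabet = ab)
  pairs <- expand.grid(target_id = names(db), query_id = names(q),
                       stringsAsFactors = FALSE)[, c("query_id", "target_id")]
  pairs <- pairs[pairs$query_id != pairs$target_id, , drop = FALSE]
  pairs <- pairs[order(pairs$query_id, pairs$target_id, method = "radix"), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  qi <- match(pairs$query_id, pool_ids)
  ti <- match(pairs$target_id, pool_ids)
  pairs$raw_score <- sw_search_cpp(enc, qi, ti, S,
                                   as.integer(gap_open), as.integer(gap_extend))
  pairs$query_len <- nchar(pool_seq)[qi]
  pairs$target_len <- nchar(pool_seq)[ti]
  pairs
}

#' Length-normalize search scores for ranking
#'
#' Adds a `rank_stat` column (orientation: larger = better).  `raw` keeps
#' the raw score.  `linear` removes a fitted linear trend in `ln(m * n)`
#' (`m`, `n` the query and target lengths): `rank_stat = raw - a * ln(mn)`
#' with `a` fitted by least squares of score on `ln(mn)` over the fitting
#' pairs.  `quadratic` also removes a `(ln(mn))^2` term.  These regression
#' forms are this package's stand-ins for pairwise-comparison evaluation
#' normalizations whose exact published formulas vary between tools; the
#' fitted coefficients are attached as the `"normalization"` attribute.
#'
#' Fitting should use presumed-unrelated pairs: by default, hits labelled
#' `non_homolog` when a `label` column is present (see [label_hits()]),
#' otherwise all hits.
#'
#' @param hits A [run_search()] data frame.
#' @param mode `"raw"`, `"linear"` or `"quadratic"`.
#' @param fit_on Optional logical vector selecting the fitting pairs.
#' @return `hits` with a `rank_stat` column and a `"normalization"`
#'   attribute (`mode` and fitted coefficients).
#' @export
normalize_hits <- function(hits, mode = c("raw", "linear", "quadratic"),
                           fit_on = NULL) {
  mode <- match.arg(mode)
  if (mode == "raw") {
    hits$rank_stat <- as.numeric(hits$raw_score)
    attr(hits, "normalization") <- list(mode = "raw", coefficients = NULL)
    return(hits)
  }
  lnmn <- log(hits$query_len * hits$target_len)
  if (is.null(fit_on)) {
    fit_on <- if ("label" %in% names(hits)) hits$label == "non_homolog"
              else rep(TRUE, nrow(hits))
  }
  if (sum(fit_on) < 10L) {
    stop("need at least 10 fitting pairs for length normalization, have ",
         sum(fit_on))
  }
  df <- data.frame(score = hits$raw_score[fit_on], x = lnmn[fit_on])
  if (mode == "linear") {
    cf <- coef(lm(score ~ x, data = df))
    a <- if (is.na(cf[["x"]])) 0 else cf[["x"]]
    hits$rank_stat <- hits$raw_score - a * lnmn
    coefs <- c(a = a)
  } else {
    cf <- coef(lm(score ~ x + I(x^2), data = df))
    a <- if (is.na(cf[["x"]])) 0 else cf[["x"]]
    b <- if (is.na(cf[["I(x^2)"]])) 0 else cf[["I(x^2)"]]
    hits$rank_stat <- hits$raw_score - a * lnmn - b * lnmn^2
    coefs <- c(a = a, b = b)
  }
  attr(hits, "normalization") <- list(mode = mode, coefficients = coefs)
  hits
}

#' Homology truth label for a pair of SCOP-style classifications
#'
#' The standard SCOP benchmark convention: same superfamily = homolog;
#' different fold = non-homolog; same fold but different superfamily is
#' ambiguous (possible distant homology) and excluded from both error and
#' coverage counts.
#'
#' @param sccs_a,sccs_b Classification strings
#'   (`class.fold.superfamily.family`); vectorized.
#' @return Character vector over `homolog` / `non_homolog` / `ambiguous`.
#' @export
#' @examples
#' truth_label("a.1.1.1", "a.1.1.2")  # homolog
#' truth_label("a.1.1.1", "a.1.2.1")  # ambiguous
truth_label <- function(sccs_a, sccs_b) {
  lvl <- function(x, k) {
    vapply(strsplit(x, ".", fixed = TRUE),
           function(p) paste(p[seq_len(k)], collapse = "."), "")
  }
  sf_a <- lvl(sccs_a, 3L); sf_b <- lvl(sccs_b, 3L)
  fo_a <- lvl(sccs_a, 2L); fo_b <- lvl(sccs_b, 2L)
  ifelse(sf_a == sf_b, "homolog",
         ifelse(fo_a != fo_b, "non_homolog", "ambiguous"))
}

#' Attach truth labels to search hits
#'
#' @param hits A [run_search()] data frame.
#' @param domains Domain data frame with `sid` and `sccs` columns.
#' @return `hits` with a `label` column from [truth_label()].
#' @export
label_hits <- function(hits, domains) {
  sccs <- setNames(domains$sccs, domains$sid)
  qa <- sccs[hits$query_id]
  ta <- sccs[hits$target_id]
  if (anyNA(qa) || anyNA(ta)) stop("hit references a sid absent from domains")
  hits$label <- truth_label(unname(qa), unname(ta))
  hits
}

# Precompute the sorted structures shared by cve_curve() and the bootstrap:
# hits ordered best-first (rank_stat desc, ties stable by query then target
# id), with ambiguous hits dropped, plus per-hit query indices into the
# query universe.
.prepare_cve <- function(hits) {
  if (!"label" %in% names(hits)) stop("hits must carry a 'label' column")
  stat <- if ("rank_stat" %in% names(hits)) hits$rank_stat else hits$raw_score
  queries <- sort(unique(hits$query_id), method = "radix")
  keep <- hits$label != "ambiguous"
  h <- hits[keep, , drop = FALSE]
  stat <- stat[keep]
  ord <- order(-stat, h$query_id, h$target_id, method = "radix")
  h <- h[ord, , drop = FALSE]
  is_hom <- h$label == "homolog"
  if (!any(is_hom)) stop("no true homolog pairs in the hit list")
  list(queries = queries,
       qidx = match(h$query_id, queries),
       is_hom = is_hom,
       is_err = h$label == "non_homolog")
}

# Curve points for one weight assignment (one weight per query).
.cve_points <- function(prep, w) {
  wq <- w[prep$qidx]
  total_q <- sum(w)
  total_true <- sum(wq[prep$is_hom])
  data.frame(
    errors_per_query = cumsum(wq * prep$is_err) / total_q,
    coverage = cumsum(wq * prep$is_hom) / total_true)
}

#' Coverage-versus-errors-per-query curve
#'
#' Sorts hits best-first by `rank_stat` (ties broken stably by query id then
#' target id) and sweeps a score threshold down the list.  At each prefix,
#' errors per query (EPQ) is the weight of queries of non-homolog hits in
#' the prefix divided by the total query weight, and coverage is the weight
#' of queries of homolog hits in the prefix divided by the total weight over
#' all true homolog pairs in the list.  Ambiguous hits (same fold,
#' different superfamily) are excluded throughout.  Weights default to 1
#' per query; the Bayesian bootstrap supplies Dirichlet weights instead.
#'
#' @param hits Labelled hits (see [label_hits()]), with a `rank_stat`
#'   column if normalization has been applied (falls back to `raw_score`).
#' @param query_weights Optional positive weights named by query id.
#' @return An object of class `cve_curve`: list with `points` (data frame
#'   `errors_per_query`, `coverage`, one row per prefix), `n_queries`,
#'   `n_true_pairs`.
#' @export
cve_curve <- function(hits, query_weights = NULL) {
  prep <- .prepare_cve(hits)
  w <- rep(1, length(prep$queries))
  names(w) <- prep$queries
  if (!is.null(query_weights)) {
    if (is.null(names(query_weights))) {
      stop("query_weights must be named by query id")
    }
    miss <- setdiff(prep$queries, names(query_weights))
    if (length(miss)) stop("missing weights for queries: ", miss[1L], " ...")
    w <- query_weights[prep$queries]
  }
  structure(
    list(points = .cve_points(prep, w),
         n_queries = length(prep$queries),
         n_true_pairs = sum(prep$is_hom)),
    class = "cve_curve")
}

#' @export
print.cve_curve <- function(x, ...) {
  cat("<cve_curve> ", nrow(x$points), " points, ", x$n_queries,
      " queries, ", x$n_true_pairs, " true pairs; coverage at 0.01 EPQ = ",
      sprintf("%.4f", coverage_at_epq(x, 0.01)), "\n", sep = "")
  invisible(x)
}

#' Coverage at an errors-per-query limit
#'
#' @param curve A [cve_curve()] object.
#' @param epq_limit EPQ cutoff (default 0.01, the conventional operating
#'   point for remote-homology benchmarks).
#' @return Maximum coverage among curve points with EPQ at or below the
#'   limit; 0 if no point qualifies.
#' @export
coverage_at_epq <- function(curve, epq_limit = 0.01) {
  stopifnot(inherits(curve, "cve_curve"))
  ok <- curve$points$errors_per_query <= epq_limit
  if (!any(ok)) return(0)
  max(curve$points$coverage[ok])
}

#' Bayesian-bootstrap paired comparison of two matrices' searches
#'
#' Replicates reweight queries with flat-Dirichlet draws (independent
#' standard-exponential deviates normalized to mean 1) instead of discrete
#' resampling.  The same weight vector is applied to both hit lists in each
#' replicate (paired design), and the difference in weighted coverage at
#' the EPQ limit is recorded.
#'
#' @param hits_a,hits_b Labelled (and optionally normalized) hit lists over
#'   the same query set.
#' @param B Number of replicates (>= 1).
#' @param seed Integer seed; the caller's RNG state is left untouched.
#' @param epq_limit EPQ cutoff (default 0.01).
#' @return An object of class `bootstrap_comparison`: `B`, `seed`,
#'   `coverage_a`, `coverage_b` (per replicate), `delta` (a - b), and
#'   `delta_summary` (mean, 95% percentile interval, fraction of replicates
#'   with delta <= 0).
#' @export
bayesian_bootstrap_compare <- function(hits_a, hits_b, B, seed,
                                       epq_limit = 0.01) {
  if (B < 1) stop("need at least one bootstrap replicate")
  prep_a <- .prepare_cve(hits_a)
  prep_b <- .prepare_cve(hits_b)
  if (!identical(prep_a$queries, prep_b$queries)) {
    stop("the two hit lists must cover the same query set")
  }
  nq <- length(prep_a$queries)
  cov_w <- function(prep, w) {
    pts <- .cve_points(prep, w)
    ok <- pts$errors_per_query <= epq_limit
    if (!any(ok)) 0 else max(pts$coverage[ok])
  }
  cov_a <- cov_b <- numeric(B)
  with_seed(seed, {
    for (b in seq_len(B)) {
      w <- rexp(nq)
      w <- w / mean(w)
      cov_a[b] <- cov_w(prep_a, w)
      cov_b[b] <- cov_w(prep_b, w)
    }
  })
  delta <- cov_a - cov_b
  structure(
    list(B = as.integer(B), seed = as.integer(seed),
         epq_limit = epq_limit,
         coverage_a = cov_a, coverage_b = cov_b, delta = delta,
         delta_summary = list(
           mean = mean(delta),
           ci95 = unname(quantile(delta, c(0.025, 0.975), type = 7)),
           frac_nonpositive = mean(delta <= 0))),
    class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  s <- x$delta_summary
  cat("<bootstrap_comparison> B=", x$B, " seed=", x$seed,
      sprintf("\n  mean delta = %.4f  95%% CI [%.4f, %.4f]  P(delta <= 0) = %.3f\n",
              s$mean, s$ci95[1], s$ci95[2], s$frac_nonpositive), sep = "")
  invisible(x)
}

#' Shuffled-cell control matrix
#'
#' Randomly permutes the 210 unordered cells of a score matrix (symmetry is
#' preserved).  The control keeps the score distribution but destroys the
#' residue-specific information, giving a null reference for discrimination
#' checks.
#'
#' @param matrix Score matrix (model, matrix file, or bare matrix).
#' @param seed Integer seed.
#' @return A symmetric integer matrix with the same dimnames.
#' @export
shuffle_matrix_cells <- function(matrix, seed) {
  S <- .score_matrix(matrix)
  ut <- upper.tri(S, diag = TRUE)
  vals <- S[ut]
  perm <- with_seed(seed, sample(vals))
  out <- S
  out[ut] <- perm
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}
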