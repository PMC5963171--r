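# From clustered blocks to a substitution matrix: weighted pair counts,
# target/background frequencies, log-odds in bits, relative entropy,
# bit-fraction scaling and rounding, plus matrix differencing.
#
# Conventions: pair-count and frequency tables are stored as full symmetric
# 20 x 20 matrices in the classic residue order, where cell [i, j] holds the
# *unordered* pair quantity f_ij (so the table has 210 free entries).  Sums
# over unordered pairs are therefore (sum(M) + sum(diag(M))) / 2.

.empty_pair_table <- function() {
  matrix(0, 20L, 20L, dimnames = list(AA_ALPHABET, AA_ALPHABET))
}

.unordered_sum <- function(m) (sum(m) + sum(diag(m))) / 2

#' Weighted between-cluster pair counts for one block
#'
#' For every column and every unordered pair of rows lying in *different*
#' clusters, adds `weight_u * weight_v` to the count cell of the two
#' residues.  Pairs within a cluster contribute nothing (that is the whole
#' point of the clustering: near-duplicate rows are collapsed), and pairs
#' where either residue is outside the 20-letter alphabet are dropped.
#'
#' @param block A [new_block()] object.
#' @param partition The [cluster_block()] partition of the same block.
#' @return A `pair_counts` object: symmetric 20 x 20 numeric matrix of
#'   unordered pair counts with attribute `total` (the sum T over unordered
#'   pairs).
#' @export
count_block <- function(block, partition) {
  stopifnot(inherits(block, "block"), inherits(partition, "cluster_partition"))
  if (!identical(names(block$rows), names(partition$assignment)) ||
      !identical(block$block_id, partition$block_id)) {
    stop("partition does not belong to block ", block$block_id)
  }
  f <- .empty_pair_table()
  d <- length(block$rows)
  if (d >= 2L) {
    idx <- which(upper.tri(matrix(0L, d, d)), arr.ind = TRUE)
    keep <- partition$assignment[idx[, 1L]] != partition$assignment[idx[, 2L]]
    idx <- idx[keep, , drop = FALSE]
    if (nrow(idx) > 0L) {
      chm <- .block_char_matrix(block)
      wprod <- partition$weights[idx[, 1L]] * partition$weights[idx[, 2L]]
      a <- match(chm[idx[, 1L], , drop = FALSE], AA_ALPHABET)
      b <- match(chm[idx[, 2L], , drop = FALSE], AA_ALPHABET)
      wv <- rep(wprod, times = block$width)
      ok <- !is.na(a) & !is.na(b)
      if (any(ok)) {
        lo <- pmin(a[ok], b[ok])
        hi <- pmax(a[ok], b[ok])
        acc <- rowsum(wv[ok], group = (lo - 1L) * 20L + hi)
        half <- matrix(0, 20L, 20L)
        half[as.integer(rownames(acc))] <- acc[, 1L]
        f <- half + t(half)
        diag(f) <- diag(half)
        dimnames(f) <- list(AA_ALPHABET, AA_ALPHABET)
      }
    }
  }
  structure(f, total = .unordered_sum(f), class = c("pair_counts", "matrix"))
}

#' Sum pair-count tables across blocks
#'
#' @param tables List of `pair_counts` tables.
#' @return A single `pair_counts` table (entrywise sum; totals add).
#' @export
aggregate_counts <- function(tables) {
  if (length(tables) == 0L) {
    f <- .empty_pair_table()
    return(structure(f, total = 0, class = c("pair_counts", "matrix")))
  }
  f <- Reduce(`+`, lapply(tables, unclass))
  attributes(f)$total <- NULL
  structure(f, total = .unordered_sum(f), class = c("pair_counts", "matrix"))
}

#' Derive the frequency model and log-odds from pair counts
#'
#' Implements the standard log-odds construction.  With `T` the total of
#' the unordered pair counts `f`:
#' target frequencies `q_ij = f_ij / T`; background frequencies
#' `p_i = q_ii + sum_{j != i} q_ij / 2`; expected frequencies
#' `e_ii = p_i^2`, `e_ij = 2 p_i p_j`; real-valued log-odds
#' `s_ij = log2(q_ij / e_ij)` (bits); relative entropy
#' `H = sum_{i <= j} q_ij s_ij` (bits, non-negative, zero iff q = e).
#'
#' The model is restricted to the *observed* alphabet (residues with any
#' nonzero count).  Pair cells with zero counts get `q_ij = 0`, a log-odds
#' of `-Inf`, and contribute nothing to the entropy sum; they are recorded
#' in the model's `zero_pairs` field.  Such cells cannot be rounded to an
#' integer score, so [finalize_model()] raises a zero-cell error naming the
#' pair rather than silently smoothing: under realistic block volumes empty
#' cells indicate broken input.  For small-data experimentation,
#' `pseudocount = TRUE` explicitly adds 1 to every unordered pair cell of
#' the full 20-letter table before normalising; the flag is recorded in the
#' model's provenance.
#'
#' @param counts A `pair_counts` table.
#' @param pseudocount Add a uniform pseudo-count of 1 per pair cell.
#' @return An object of class `subst_model` with `q`, `p`, `e`, `s_real`
#'   (over the observed alphabet), `entropy` (bits), `total_T`, and empty
#'   scaling slots (`bit_denominator`, `scores`) to be filled by
#'   [finalize_model()].
#' @export
derive_model <- function(counts, pseudocount = FALSE) {
  f <- unclass(counts)
  attributes(f)$total <- NULL
  if (isTRUE(pseudocount)) {
    f <- f + 1
  }
  total <- .unordered_sum(f)
  if (total <= 0) stop("no counts: T = 0, cannot derive frequencies")
  obs <- which(rowSums(f) > 0)
  f <- f[obs, obs, drop = FALSE]
  zero <- which(f == 0 & upper.tri(f, diag = TRUE), arr.ind = TRUE)
  ab <- rownames(f)
  zero_pairs <- if (nrow(zero) > 0L) {
    paste0(ab[zero[, 1L]], ab[zero[, 2L]])
  } else character()
  q <- f / total
  p <- (rowSums(q) + diag(q)) / 2
  e <- 2 * outer(p, p)
  diag(e) <- p^2
  s <- log2(q / e)          # -Inf on zero-count cells
  qs <- q * s
  qs[q == 0] <- 0           # 0 * log(0) := 0 in the entropy sum
  H <- .unordered_sum(qs)
  structure(
    list(q = q, p = p, e = e, s_real = s,
         entropy = H, total_T = total, zero_pairs = zero_pairs,
         bit_denominator = NULL, scores = NULL,
         provenance = list(variant = NA_character_, threshold = NA_real_,
                           source = NULL, pseudocount = isTRUE(pseudocount))),
    class = "subst_model")
}

#' Pick the bit-fraction denominator for a given entropy
#'
#' Published matrices of this family are printed in 1/n-bit units, with n
#' growing as the matrix's relative entropy falls (low-information matrices
#' need a finer grid to keep distinct scores distinct).  This piecewise rule
#' is calibrated against the published entropy/bit-unit pairings across
#' BLOCKS releases: n = 2 for H >= 0.6; 3 for H in \[0.3, 0.6); 4 for
#' \[0.2, 0.3); 5 for \[0.145, 0.2); 6 below.  The 5/6 boundary is only
#' constrained by the published pairs to lie between 0.1198 and 0.1477; an
#' explicit `scale` override in [build_matrix()] is always available.
#'
#' @param entropy_H Relative entropy in bits, > 0.
#' @return Integer denominator n.
#' @export
#' @examples
#' auto_scale(0.6979)  # 2
#' auto_scale(0.2360)  # 4
auto_scale <- function(entropy_H) {
  if (!is.finite(entropy_H) || entropy_H <= 0) {
    stop("entropy must be positive to pick a scale")
  }
  if (entropy_H >= 0.6) 2L
  else if (entropy_H >= 0.3) 3L
  else if (entropy_H >= 0.2) 4L
  else if (entropy_H >= 0.145) 5L
  else 6L
}

#' Scale real log-odds to integer scores
#'
#' `score_ij = round(n * s_ij)` with ties rounded half away from zero (the
#' convention of the classic matrix programs, not banker's rounding).
#'
#' @param s_real Symmetric matrix of real log-odds in bits.
#' @param n Bit-fraction denominator (scores are in 1/n bit units).
#' @return Symmetric integer matrix.
#' @export
scale_and_round <- function(s_real, n) {
  if (n < 1) stop("bit denominator must be >= 1")
  x <- n * s_real
  sc <- sign(x) * floor(abs(x) + 0.5)
  storage.mode(sc) <- "integer"
  sc
}

#' Finalize a model: choose units and round scores
#'
#' @param model A [derive_model()] result.
#' @param scale `"auto"` (use [auto_scale()]) or an explicit integer n.
#' @return The model with `bit_denominator` and integer `scores` filled in.
#' @export
finalize_model <- function(model, scale = "auto") {
  stopifnot(inherits(model, "subst_model"))
  if (length(model$zero_pairs) > 0L) {
    stop("zero count for observed residue pair (", model$zero_pairs[1L],
         "): cannot round -Inf log-odds to an integer score; supply more ",
         "data or set pseudocount = TRUE")
  }
  n <- if (identical(scale, "auto")) auto_scale(model$entropy) else as.integer(scale)
  model$bit_denominator <- n
  model$scores <- scale_and_round(model$s_real, n)
  model
}

#' Build a substitution matrix from blocks
#'
#' The full derivation chain for one clustering threshold: cluster every
#' block at `L` under `variant`, accumulate weighted between-cluster pair
#' counts, derive frequencies/log-odds/entropy, pick bit units and round.
#'
#' @param blocks List of [new_block()] objects.
#' @param threshold Percent-identity clustering threshold L.
#' @param variant Clustering variant (see [threshold_met()]).
#' @param scale `"auto"` or an explicit bit denominator.
#' @param pseudocount See [derive_model()].
#' @param source Free-text provenance note recorded in the model.
#' @return A finalized `subst_model`.
#' @export
build_matrix <- function(blocks, threshold, variant, scale = "auto",
                         pseudocount = FALSE, source = NULL) {
  variant <- .check_variant(variant)
  if (length(blocks) == 0L) stop("no blocks supplied")
  tabs <- lapply(blocks, function(blk) {
    count_block(blk, cluster_block(blk, threshold, variant))
  })
  model <- derive_model(aggregate_counts(tabs), pseudocount = pseudocount)
  model <- finalize_model(model, scale = scale)
  model$provenance$variant <- variant
  model$provenance$threshold <- threshold
  model$provenance$source <- source %||%
    sprintf("%d blocks", length(blocks))
  model
}

#' @export
print.subst_model <- function(x, ...) {
  cat("<subst_model> variant=", x$provenance$variant,
      " L=", x$provenance$threshold,
      sprintf(" H=%.4f bits", x$entropy), sep = "")
  if (!is.null(x$bit_denominator)) {
    cat(" units=1/", x$bit_denominator, sep = "")
  }
  cat(" alphabet=", nrow(x$q), " residues\n", sep = "")
  invisible(x)
}

#' Difference two substitution matrices cell by cell
#'
#' @param a,b Score matrices (models, matrix files, or bare matrices) over
#'   the same residue alphabet.
#' @return An object of class `matrix_diff`: list with `delta`
#'   (`a - b`, antisymmetric under argument swap), `n_differing` (count of
#'   unordered cells that differ) and `max_abs` (largest absolute
#'   difference).
#' @export
diff_matrices <- function(a, b) {
  ma <- .score_matrix(a)
  mb <- .score_matrix(b)
  if (!identical(rownames(ma), rownames(mb))) {
    stop("matrices have different residue alphabets")
  }
  delta <- ma - mb
  ut <- upper.tri(delta, diag = TRUE)
  structure(
    list(delta = delta,
         n_differing = sum(delta[ut] != 0),
         max_abs = if (all(delta == 0)) 0L else max(abs(delta))),
    class = "matrix_diff")
}

#' @export
print.matrix_diff <- function(x, ...) {
  cat("<matrix_diff> differing cells=", x$n_differing,
      " max|delta|=", x$max_abs, "\n", sep = "")
  invisible(x)
}
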