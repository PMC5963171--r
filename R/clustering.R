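# Percent-identity clustering of block rows under the three variant rules,
# and the 1/cluster-size sequence weights used for pair counting.

CLUSTER_VARIANTS <- c("legacy_blosum", "rblosum", "corblosum")

.check_variant <- function(variant) {
  match.arg(variant, CLUSTER_VARIANTS)
}

#' Count identical positions between two block rows
#'
#' The number of columns at which the two rows carry the same letter.
#' Positions where either letter lies outside the 20-residue alphabet
#' (ambiguity codes B/Z/X, unknown placeholders) never count as identities.
#' The identity *fraction* used by clustering is `k / w` with `w` the full
#' block width: blocks are ungapped and fixed-width, so the denominator is
#' not reduced for ambiguous positions.
#'
#' @param row_a,row_b Residue strings of equal length.
#' @return Non-negative integer count.
#' @export
#' @examples
#' identity_count("AAAA", "AAAT")  # 3
identity_count <- function(row_a, row_b) {
  a <- .split_residues(row_a)
  b <- .split_residues(row_b)
  if (length(a) != length(b)) {
    stop("rows have different lengths (", length(a), " vs ", length(b), ")")
  }
  valid <- a %in% AA_ALPHABET & b %in% AA_ALPHABET
  sum(a == b & valid)
}

#' Does an identity count meet a clustering threshold?
#'
#' The legacy BLOSUM code converts the percentage threshold `L` into a
#' residue count by *integer truncation*, `floor(L * w / 100)`, before
#' comparing; a pair meets the threshold iff `k >= floor(L * w / 100)`.
#' Because of the truncation, pairs whose true identity fraction lies just
#' below L% can still be clustered — e.g. k = 4 of w = 7 (57.1%) meets an
#' L = 62 integer threshold since `floor(62 * 7 / 100) = 4`.  Both
#' `legacy_blosum` and `rblosum` use this integer rule.
#'
#' The `corblosum` variant compares the exact fraction instead:
#' `100 * k >= L * w`, evaluated in integer arithmetic so no floating-point
#' rounding is introduced.  The two rules agree whenever `L * w` is
#' divisible by 100 and differ exactly on pairs with
#' `floor(L * w / 100) <= k < L * w / 100`.
#'
#' @param k Identity count, `0 <= k <= w`.
#' @param w Block width.
#' @param L Percentage threshold in `[1, 100]`.
#' @param variant One of `"legacy_blosum"`, `"rblosum"`, `"corblosum"`.
#' @return Logical.
#' @export
#' @examples
#' threshold_met(4, 7, 62, "rblosum")    # TRUE: floor(4.34) = 4
#' threshold_met(4, 7, 62, "corblosum")  # FALSE: 400 < 434
threshold_met <- function(k, w, L, variant) {
  variant <- .check_variant(variant)
  if (any(k < 0) || any(k > w)) stop("identity count k must lie in [0, w]")
  if (L < 1 || L > 100) stop("threshold L must lie in [1, 100]")
  if (variant == "corblosum") {
    100 * k >= L * w
  } else {
    k >= (L * w) %/% 100
  }
}

#' Cluster a block's rows at an identity threshold
#'
#' Rows whose pairwise identity meets the threshold (see [threshold_met()])
#' are merged by single-linkage transitive closure: two rows share a cluster
#' iff they are connected by a chain of above-threshold pairs.  Each row is
#' then weighted `1 / (its cluster's size)`, the Henikoff down-weighting
#' that stops families of near-duplicates from dominating the pair counts.
#'
#' `legacy_blosum` and `rblosum` share the integer threshold rule and, in
#' this implementation, the same transitive-closure merge; they are kept as
#' distinct variants so that a faithful port of the originally distributed
#' single-pass merge loop can be slotted in without touching the counting
#' code.  `corblosum` differs only in using the exact rational threshold.
#'
#' @param block A [new_block()] object.
#' @param L Percentage identity threshold in `[1, 100]`.
#' @param variant Clustering variant (see [threshold_met()]).
#' @return An object of class `cluster_partition`: list with `block_id`,
#'   `threshold_L`, `variant`, `assignment` (integer cluster index per row,
#'   named by sequence id), `weights` (named, `1/cluster size`), and
#'   `n_clusters`.
#' @export
cluster_block <- function(block, L, variant) {
  variant <- .check_variant(variant)
  stopifnot(inherits(block, "block"))
  d <- length(block$rows)
  parent <- seq_len(d)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (d > 1L) {
    chm <- .block_char_matrix(block)
    valid <- matrix(chm %in% AA_ALPHABET, nrow = d)
    w <- block$width
    for (u in seq_len(d - 1L)) {
      for (v in (u + 1L):d) {
        k <- sum(chm[u, ] == chm[v, ] & valid[u, ] & valid[v, ])
        if (threshold_met(k, w, L, variant)) {
          ru <- find(u); rv <- find(v)
          if (ru != rv) parent[rv] <- ru
        }
      }
    }
  }
  roots <- vapply(seq_len(d), find, 0L)
  assignment <- match(roots, unique(roots))
  sizes <- tabulate(assignment)
  weights <- 1 / sizes[assignment]
  names(assignment) <- names(weights) <- names(block$rows)
  structure(
    list(block_id = block$block_id, threshold_L = L, variant = variant,
         assignment = assignment, weights = weights,
         n_clusters = max(assignment)),
    class = "cluster_partition")
}

#' @export
print.cluster_partition <- function(x, ...) {
  cat("<cluster_partition> block=", x$block_id, " L=", x$threshold_L,
      " variant=", x$variant, " clusters=", x$n_clusters, "/",
      length(x$assignment), " rows\n", sep = "")
  invisible(x)
}
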