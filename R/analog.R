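# Threshold sweeps and entropy-matched analog selection.  Matrices from
# different construction pipelines are only comparable at matched relative
# entropy, so a family is swept across clustering thresholds and the member
# whose entropy is closest to a target is chosen as its analog.

#' Sweep clustering thresholds and record entropies
#'
#' Runs the full build (cluster, count, derive, scale) at every threshold
#' and records the resulting model and its relative entropy.  Partitions
#' are recomputed per threshold; nothing is reused across thresholds, so a
#' sweep is exactly equivalent to independent [build_matrix()] calls.
#'
#' @param blocks List of [new_block()] objects.
#' @param variant Clustering variant (see [threshold_met()]).
#' @param thresholds Strictly increasing integer thresholds (default 45:70,
#'   the conventional search range around the widely used matrices).
#' @param ... Passed to [build_matrix()] (`scale`, `pseudocount`, `source`).
#' @return An object of class `entropy_sweep`: list with `variant`, `table`
#'   (data frame: `threshold`, `entropy`, `bit_denominator`) and `models`
#'   (one finalized `subst_model` per threshold).
#' @export
entropy_sweep <- function(blocks, variant, thresholds = 45:70, ...) {
  variant <- .check_variant(variant)
  if (length(thresholds) == 0L) stop("empty threshold list")
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  models <- lapply(thresholds, function(L) {
    tryCatch(build_matrix(blocks, L, variant, ...),
             error = function(e) {
               stop("sweep failed at threshold ", L, ": ", conditionMessage(e))
             })
  })
  names(models) <- as.character(thresholds)
  structure(
    list(variant = variant,
         table = data.frame(
           threshold = as.integer(thresholds),
           entropy = vapply(models, function(m) m$entropy, 0),
           bit_denominator = vapply(models, function(m) m$bit_denominator, 0L),
           row.names = NULL),
         models = models),
    class = "entropy_sweep")
}

#' @export
print.entropy_sweep <- function(x, ...) {
  cat("<entropy_sweep> variant=", x$variant, ", ",
      nrow(x$table), " thresholds\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Select the entropy-matched analog from a sweep
#'
#' Returns the sweep member whose relative entropy is closest to the target
#' (`argmin |H(L) - target|`); ties break toward the lower threshold.
#'
#' @param sweep An [entropy_sweep()] result.
#' @param target_H Target relative entropy in bits (e.g. the entropy of the
#'   reference matrix the analog is being matched to).
#' @return List with `threshold`, `entropy`, `delta` (achieved
#'   `|H - target|`) and `model`.
#' @export
select_analog <- function(sweep, target_H) {
  stopifnot(inherits(sweep, "entropy_sweep"))
  if (nrow(sweep$table) == 0L) stop("empty sweep")
  if (!is.finite(target_H)) stop("target entropy must be finite")
  dist <- abs(sweep$table$entropy - target_H)
  i <- which.min(dist)  # first minimum = lowest threshold on ties
  list(threshold = sweep$table$threshold[i],
       entropy = sweep$table$entropy[i],
       delta = dist[i],
       model = sweep$models[[i]])
}
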