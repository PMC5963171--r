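# Seed handling: run code under a fixed seed without disturbing the caller's
# RNG state.  All stochastic entry points (generators, bootstrap, splits)
# funnel through here so a single integer seed reproduces a whole run.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive n per-stage seeds from one top-level seed (all below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Read either a file path or literal text (single string with newlines, or a
# character vector of lines) into a vector of lines.
.as_lines <- function(x) {
  if (length(x) == 1L && !grepl("\n", x, fixed = TRUE) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
}

# Extract a plain integer score matrix from any of the containers the
# package passes around (bare matrix, subst_model, matrix_file).
.score_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else if (inherits(x, "subst_model")) {
    if (is.null(x$scores)) stop("substitution model has no integer scores yet")
    m <- x$scores
  } else if (inherits(x, "matrix_file")) {
    m <- x$scores
  } else {
    stop("cannot interpret object of class '", paste(class(x), collapse = "/"),
         "' as a score matrix")
  }
  if (is.null(dimnames(m))) stop("score matrix must carry residue dimnames")
  m
}
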