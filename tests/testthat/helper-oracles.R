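# Independent oracles used to cross-check the implementation.  These are
# deliberately naive (explicit loops, exhaustive enumeration) and share no
# code with the package internals they verify.

# Position-by-position identity scan over two residue strings.
oracle_identity <- function(a, b) {
  aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
            "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  n <- nchar(a)
  stopifnot(nchar(b) == n)
  k <- 0L
  for (i in seq_len(n)) {
    ca <- substr(a, i, i)
    cb <- substr(b, i, i)
    if (ca == cb && ca %in% aa20 && cb %in% aa20) k <- k + 1L
  }
  k
}

# Breadth-first connected components over a logical adjacency matrix.
oracle_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue) > 0L) {
        u <- queue[1L]
        queue <- queue[-1L]
        nb <- which(adj[u, ] & is.na(comp))
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  comp
}

# Frequency model by explicit loops over unordered residue pairs.
# `counts` is a named numeric vector like c("A A" = 1, "A V" = 1).
oracle_model <- function(counts) {
  pairs <- strsplit(names(counts), " ", fixed = TRUE)
  letters_obs <- sort(unique(unlist(pairs)))
  total <- sum(counts)
  getf <- function(x, y) {
    v <- 0
    for (k in seq_along(pairs)) {
      p <- pairs[[k]]
      if ((p[1] == x && p[2] == y) || (p[1] == y && p[2] == x)) {
        v <- v + counts[[k]]
      }
    }
    v
  }
  q <- function(x, y) getf(x, y) / total
  p <- sapply(letters_obs, function(i) {
    v <- q(i, i)
    for (j in setdiff(letters_obs, i)) v <- v + q(i, j) / 2
    v
  })
  e <- function(x, y) if (x == y) p[[x]]^2 else 2 * p[[x]] * p[[y]]
  s <- function(x, y) log2(q(x, y) / e(x, y))
  H <- 0
  for (i in seq_along(letters_obs)) {
    for (j in i:length(letters_obs)) {
      x <- letters_obs[i]
      y <- letters_obs[j]
      if (q(x, y) > 0) H <- H + q(x, y) * s(x, y)
    }
  }
  list(letters = letters_obs, q = q, p = p, e = e, s = s, H = H)
}

# Exhaustive local-alignment enumerator.  Enumerates every increasing
# matching between positions of a and b; internal unmatched runs cost
# gap_open + len * gap_extend per run.  With strictly positive gap costs
# the optimal local alignment starts and ends with an aligned pair, so
# enumerating matchings covers all optima; the empty alignment scores 0.
oracle_sw <- function(a, b, S, gap_open, gap_extend) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  m <- length(A)
  n <- length(B)
  best <- 0
  extend <- function(lasti, lastj, score) {
    if (lasti >= m || lastj >= n) return(invisible())
    for (ii in (lasti + 1L):m) {
      for (jj in (lastj + 1L):n) {
        gi <- ii - lasti - 1L
        gj <- jj - lastj - 1L
        gap <- 0
        if (gi > 0L) gap <- gap + gap_open + gi * gap_extend
        if (gj > 0L) gap <- gap + gap_open + gj * gap_extend
        sc <- score + S[A[ii], B[jj]] - gap
        if (sc > best) best <<- sc
        extend(ii, jj, sc)
      }
    }
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      sc <- S[A[i], B[j]]
      if (sc > best) best <- sc
      extend(i, j, sc)
    }
  }
  best
}

# Prefix-by-prefix CVE enumeration with explicit loops.
# df: data.frame(query, target, stat, label); weights named by query.
oracle_cve <- function(df, weights = NULL) {
  df <- df[df$label != "ambiguous", , drop = FALSE]
  ord <- order(-df$stat, df$query, df$target, method = "radix")
  df <- df[ord, , drop = FALSE]
  queries <- sort(unique(df$query))
  if (is.null(weights)) weights <- setNames(rep(1, length(queries)), queries)
  total_q <- sum(weights[queries])
  total_true <- 0
  for (r in seq_len(nrow(df))) {
    if (df$label[r] == "homolog") total_true <- total_true + weights[[df$query[r]]]
  }
  epq <- cov <- numeric(nrow(df))
  err_sum <- hom_sum <- 0
  for (r in seq_len(nrow(df))) {
    w <- weights[[df$query[r]]]
    if (df$label[r] == "non_homolog") err_sum <- err_sum + w
    if (df$label[r] == "homolog") hom_sum <- hom_sum + w
    epq[r] <- err_sum / total_q
    cov[r] <- hom_sum / total_true
  }
  data.frame(errors_per_query = epq, coverage = cov)
}

# Toy score matrix over the 20-letter alphabet: +match / -mismatch.
toy_matrix <- function(match = 2L, mismatch = -1L) {
  ab <- aa_alphabet()
  S <- matrix(mismatch, 20L, 20L, dimnames = list(ab, ab))
  diag(S) <- match
  storage.mode(S) <- "integer"
  S
}

# Random uniform-letter residue string.
random_residues <- function(n, alphabet = aa_alphabet()) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
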