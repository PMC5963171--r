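# Pair counting, frequency/log-odds derivation, entropy, scaling, rounding,
# and matrix differencing.

test_that("count_block reproduces hand-enumerated weighted pair counts", {
  # width-2 block, two singleton rows "AA" and "AV":
  # column 1 gives (A,A), column 2 gives (A,V), each with weight 1*1
  blk <- new_block("C1", c(a = "AA", b = "AV"))
  part <- cluster_block(blk, 80L, "corblosum")  # 100*1 < 80*2: singletons
  expect_equal(part$n_clusters, 2L)
  f <- count_block(blk, part)
  expect_equal(f["A", "A"], 1)
  expect_equal(f["A", "V"], 1)
  expect_equal(f["V", "A"], 1)  # symmetric access
  expect_equal(attr(f, "total"), 2)

  # all rows in one cluster: nothing is counted
  blk2 <- new_block("C2", c(a = "AAAA", b = "AAAA"))
  part2 <- cluster_block(blk2, 50L, "rblosum")
  f2 <- count_block(blk2, part2)
  expect_true(all(f2 == 0))
  expect_equal(attr(f2, "total"), 0)

  # width-1 block, rows A,A clustered together (weight 1/2 each) plus
  # singleton V: f(A,V) = 2 * (1/2) * 1 = 1
  blk3 <- new_block("C3", c(a = "A", b = "A", v = "V"))
  part3 <- cluster_block(blk3, 100L, "rblosum")
  expect_equal(part3$n_clusters, 2L)
  f3 <- count_block(blk3, part3)
  expect_equal(f3["A", "V"], 1)
  expect_equal(f3["A", "A"], 0)
  expect_equal(attr(f3, "total"), 1)

  # ambiguity letters contribute nothing
  blk4 <- new_block("C4", c(a = "AB", b = "VX"))
  part4 <- cluster_block(blk4, 100L, "corblosum")
  f4 <- count_block(blk4, part4)
  expect_equal(f4["A", "V"], 1)
  expect_equal(attr(f4, "total"), 1)

  expect_error(count_block(blk, part3), "belong")
})

test_that("aggregate_counts is entrywise summation", {
  blk <- new_block("A1", c(a = "AVC", b = "AVR"))
  part <- cluster_block(blk, 100L, "corblosum")
  x <- count_block(blk, part)
  zero <- aggregate_counts(list())
  expect_equal(unclass(aggregate_counts(list(x, zero))), unclass(x),
               ignore_attr = TRUE)
  twice <- aggregate_counts(list(x, x))
  expect_equal(unclass(twice), 2 * unclass(x), ignore_attr = TRUE)
  expect_equal(attr(twice, "total"), 2 * attr(x, "total"))

  set.seed(3)
  tabs <- replicate(10, {
    rows <- setNames(c(random_residues(6), random_residues(6)), c("a", "b"))
    b <- new_block("R", rows)
    count_block(b, cluster_block(b, 100L, "corblosum"))
  }, simplify = FALSE)
  total <- aggregate_counts(tabs)
  brute <- Reduce(`+`, lapply(tabs, function(t) matrix(t, 20, 20)))
  expect_equal(matrix(total, 20, 20), brute)
})

test_that("derive_model matches the independent arithmetic oracle to 1e-12", {
  # two-row fixture: f(A,A) = 1, f(A,V) = 1
  blk <- new_block("D1", c(a = "AA", b = "AV"))
  m <- derive_model(count_block(blk, cluster_block(blk, 80L, "corblosum")))
  orac <- oracle_model(c("A A" = 1, "A V" = 1))
  expect_equal(m$q["A", "A"], 0.5, tolerance = 1e-12)
  expect_equal(m$q["A", "V"], 0.5, tolerance = 1e-12)
  expect_equal(unname(m$p["A"]), 0.75, tolerance = 1e-12)
  expect_equal(unname(m$p["V"]), 0.25, tolerance = 1e-12)
  expect_equal(m$s_real["A", "A"], orac$s("A", "A"), tolerance = 1e-12)
  expect_equal(m$s_real["A", "V"], orac$s("A", "V"), tolerance = 1e-12)
  expect_equal(m$s_real["A", "A"], log2(0.5 / 0.5625), tolerance = 1e-12)
  expect_equal(m$entropy, orac$H, tolerance = 1e-12)
  expect_equal(m$entropy, 0.5 * log2(0.5 / 0.5625) + 0.5 * log2(0.5 / 0.375),
               tolerance = 1e-12)

  # three-row fixture: f(A,V) = 1 only
  blk3 <- new_block("D2", c(a = "A", b = "A", v = "V"))
  m3 <- derive_model(count_block(blk3, cluster_block(blk3, 100L, "rblosum")))
  orac3 <- oracle_model(c("A V" = 1))
  expect_equal(m3$q["A", "V"], 1, tolerance = 1e-12)
  expect_equal(unname(m3$p), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(m3$entropy, orac3$H, tolerance = 1e-12)
  expect_equal(m3$entropy, 1, tolerance = 1e-12)  # log2(1/0.5) = 1 bit

  # degenerate single-letter alphabet: q = 1, p = 1, s = 0, H = 0
  blk1 <- new_block("D3", c(a = "AAAAA", b = "AAAAA"))
  part1 <- structure(list(block_id = "D3", threshold_L = 100, variant = "rblosum",
                          assignment = c(a = 1L, b = 2L),
                          weights = c(a = 1, b = 1), n_clusters = 2L),
                     class = "cluster_partition")
  m1 <- derive_model(count_block(blk1, part1))
  expect_equal(dim(m1$q), c(1L, 1L))
  expect_equal(m1$q[1, 1], 1)
  expect_equal(unname(m1$p), 1)
  expect_equal(m1$s_real[1, 1], 0)
  expect_equal(m1$entropy, 0)
})

test_that("derivation errors: no counts, and zero cells at finalization", {
  blk <- new_block("Z1", c(a = "AAAA", b = "AAAA"))
  part <- cluster_block(blk, 50L, "rblosum")  # single cluster, T = 0
  expect_error(derive_model(count_block(blk, part)), "T = 0")

  # observed alphabet {A, V} but f(V,V) = 0: entropy is fine, integer
  # scores are not
  blk2 <- new_block("Z2", c(a = "AA", b = "AV"))
  m <- derive_model(count_block(blk2, cluster_block(blk2, 80L, "corblosum")))
  expect_true("VV" %in% m$zero_pairs)
  expect_error(finalize_model(m), "VV")
  # explicit pseudo-counts clear the zeros and are recorded in provenance
  mp <- derive_model(count_block(blk2, cluster_block(blk2, 80L, "corblosum")),
                     pseudocount = TRUE)
  expect_length(mp$zero_pairs, 0L)
  expect_true(mp$provenance$pseudocount)
  expect_s3_class(finalize_model(mp), "subst_model")
})

test_that("frequencies conserve mass and entropy is non-negative (Gibbs)", {
  set.seed(21)
  for (rep in 1:15) {
    # random counts over a random sub-alphabet, all cells positive
    k <- sample(3:8, 1L)
    ab <- sample(aa_alphabet(), k)
    f <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
    for (i in seq_len(k)) {
      for (j in i:k) {
        v <- runif(1, 0.1, 5)
        f[ab[i], ab[j]] <- f[ab[j], ab[i]] <- v
      }
    }
    counts <- structure(f, total = (sum(f) + sum(diag(f))) / 2,
                        class = c("pair_counts", "matrix"))
    m <- derive_model(counts)
    us <- function(x) (sum(x) + sum(diag(x))) / 2
    expect_equal(us(m$q), 1, tolerance = 1e-12)
    expect_equal(sum(m$p), 1, tolerance = 1e-12)
    expect_equal(us(m$e), 1, tolerance = 1e-12)
    expect_gte(m$entropy, 0)
  }
  # equality iff q = e: a product-form q built from p has H = 0
  p <- c(0.5, 0.3, 0.2)
  ab <- c("A", "V", "L")
  f <- matrix(0, 20, 20, dimnames = list(aa_alphabet(), aa_alphabet()))
  for (i in 1:3) for (j in 1:3) {
    f[ab[i], ab[j]] <- if (i == j) p[i]^2 else 2 * p[i] * p[j] / 2
  }
  # store unordered values: off-diagonal cell (i,j) holds 2*p_i*p_j
  for (i in 1:2) for (j in (i + 1):3) {
    f[ab[i], ab[j]] <- f[ab[j], ab[i]] <- 2 * p[i] * p[j]
  }
  counts <- structure(f, total = 1, class = c("pair_counts", "matrix"))
  m <- derive_model(counts)
  expect_equal(m$entropy, 0, tolerance = 1e-12)
  expect_true(all(abs(m$s_real) < 1e-12))
})

test_that("auto_scale reproduces the published entropy/bit-unit pairings", {
  # (relative entropy, denominator n) pairs for the published BLOSUM and
  # corrected-clustering matrices across BLOCKS releases 5.0, 13+, 14.3
  published <- list(
    c(0.4808, 3), c(0.4918, 3), c(0.6979, 2), c(0.7003, 2),
    c(0.2430, 4), c(0.1922, 5), c(0.2410, 4), c(0.2411, 4),
    c(0.3672, 3), c(0.3173, 3), c(0.3601, 3),
    c(0.1509, 5), c(0.1198, 6), c(0.1477, 5), c(0.1537, 5),
    c(0.2685, 4), c(0.2360, 4), c(0.2662, 4), c(0.2773, 4))
  for (pr in published) {
    expect_equal(auto_scale(pr[1]), as.integer(pr[2]),
                 label = sprintf("auto_scale(%.4f)", pr[1]))
  }
  expect_error(auto_scale(0), "positive")
})

test_that("scale_and_round rounds half away from zero and bounds the error", {
  expect_equal(scale_and_round(matrix(0.4150), 3L)[1, 1], 1L)   # 1.245
  expect_equal(scale_and_round(matrix(-0.1699), 2L)[1, 1], 0L)  # -0.3398
  expect_equal(scale_and_round(matrix(0), 5L)[1, 1], 0L)
  # half-away-from-zero, not banker's rounding
  expect_equal(scale_and_round(matrix(0.5), 1L)[1, 1], 1L)
  expect_equal(scale_and_round(matrix(-0.5), 1L)[1, 1], -1L)
  expect_equal(scale_and_round(matrix(1.5), 1L)[1, 1], 2L)

  set.seed(8)
  s <- matrix(runif(25, -3, 3), 5, 5)
  s <- (s + t(s)) / 2
  for (n in 2:6) {
    sc <- scale_and_round(s, n)
    expect_true(all(abs(sc - n * s) <= 0.5 + 1e-12))
    expect_true(isSymmetric(sc))
  }
})

test_that("diff_matrices is antisymmetric with an exact summary", {
  x <- toy_matrix()
  expect_equal(diff_matrices(x, x)$n_differing, 0L)
  y <- x
  y["A", "C"] <- y["C", "A"] <- x["A", "C"] + 2L
  d <- diff_matrices(x, y)
  expect_equal(d$n_differing, 1L)  # one unordered cell
  expect_equal(d$max_abs, 2L)
  expect_equal(d$delta, -diff_matrices(y, x)$delta)
  bad <- x[1:19, 1:19]
  expect_error(diff_matrices(x, bad), "alphabet")
})

test_that("clustering removes near-duplicate contributions from the counts", {
  # a block with a planted pair of near-identical rows: clustering below
  # their identity zeroes their mutual pair counts
  set.seed(31)
  root <- random_residues(40L)
  near <- sub("^.", ifelse(substr(root, 1, 1) == "A", "C", "A"), root)
  blk <- new_block("ND", c(r1 = root, r2 = near, u = random_residues(40L)))
  unclustered <- structure(
    list(block_id = "ND", threshold_L = 101, variant = "rblosum",
         assignment = c(r1 = 1L, r2 = 2L, u = 3L),
         weights = c(r1 = 1, r2 = 1, u = 1), n_clusters = 3L),
    class = "cluster_partition")
  f_all <- count_block(blk, unclustered)
  part <- cluster_block(blk, 70L, "rblosum")  # r1/r2 at 97.5% merge
  expect_equal(unname(part$assignment[c("r1", "r2")]), c(1L, 1L))
  f_clu <- count_block(blk, part)
  expect_lt(attr(f_clu, "total"), attr(f_all, "total"))
  # the duplicates' strong diagonal contribution shrinks
  expect_lt(sum(diag(f_clu)), sum(diag(f_all)))
})
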