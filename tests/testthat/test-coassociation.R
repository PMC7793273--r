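test_that("windowed summit counting matches the worked example and edge rules", {
  a <- ps_from_summits(c(100, 400, 1000))
  b <- ps_from_summits(c(120, 700), factor = "B")
  oc <- count_overlap(a, b)
  expect_equal(oc$k, 1L)                       # only 100<->120; |400-700| > 150
  expect_equal(oc$share_a, 1 / 3)
  # self-overlap saturates at 100%
  oc_self <- count_overlap(a, a)
  expect_equal(oc_self$k, 3L)
  expect_equal(oc_self$share_a, 1.0)
  # other chromosome only: zero
  b2 <- ps_from_summits(c(100, 400), factor = "B", chrom = "chr9")
  expect_equal(count_overlap(a, b2)$k, 0L)
  # window bound is inclusive at exactly 150 bp
  expect_equal(count_overlap(ps_from_summits(1000),
                             ps_from_summits(1150, factor = "B"))$k, 1L)
  expect_equal(count_overlap(ps_from_summits(1000),
                             ps_from_summits(1151, factor = "B"))$k, 0L)
})

test_that("count_overlap equals O(n^2) brute force on random fixtures", {
  set.seed(101)
  for (i in 1:100) {
    na <- sample(5:2000, 1); nb <- sample(5:2000, 1)
    chroms <- sample(1:3, 1)
    a <- ps_from_summits(sample(1:3e5, na),
                         chrom = sample(sprintf("chr%d", 1:chroms), na, TRUE))
    b <- ps_from_summits(sample(1:3e5, nb), factor = "B",
                         chrom = sample(sprintf("chr%d", 1:chroms), nb, TRUE))
    oc <- count_overlap(a, b)
    expect_identical(oc$k, brute_count(a, b))
    expect_identical(oc$k_b, brute_count(b, a))
  }
})

test_that("poisson scores match direct tail summation to 1e-9 relative error", {
  cfg <- analysis_config()
  cases <- expand.grid(n_a = c(50, 100, 500), n_b = c(100, 1000),
                       k = c(0, 1, 5, 10, 40))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    k <- min(cs$k, cs$n_a)
    oc <- structure(list(factor_a = "a", factor_b = "b", n_a = cs$n_a,
                         n_b = cs$n_b, k = k, k_b = k,
                         share_a = k / cs$n_a, share_b = k / cs$n_b),
                    class = "OverlapCount")
    res <- poisson_score(oc, n_tests = 1, cfg = cfg)
    lambda <- cs$n_a * cs$n_b / cfg$accessible_regions_n
    oracle <- poisson_tail_oracle(k, lambda, upper = k >= lambda)
    expect_equal(res$p_raw, oracle, tolerance = 1e-9)
    expect_equal(sign(res$score), if (k >= lambda) 1 else -1)
  }
  # the documented example: n_a = n_b = 100, k = 10 vs lambda = 0.04
  oc <- structure(list(factor_a = "a", factor_b = "b", n_a = 100, n_b = 100,
                       k = 10L, k_b = 10L, share_a = .1, share_b = .1),
                  class = "OverlapCount")
  expect_equal(poisson_score(oc, 1)$score,
               -log10(poisson_tail_oracle(10, 0.04)), tolerance = 1e-9)
})

test_that("score is near zero at expectation, monotone in k, and Bonferroni-corrected", {
  mk <- function(k, n_a = 20000, n_b = 20000) {
    structure(list(factor_a = "a", factor_b = "b", n_a = n_a, n_b = n_b,
                   k = k, k_b = k, share_a = k / n_a, share_b = k / n_b),
              class = "OverlapCount")
  }
  lambda <- 20000 * 20000 / 250000   # 1600
  expect_lt(abs(poisson_score(mk(round(lambda)), 1)$score), 1)
  sc <- vapply(seq(1600, 3000, by = 100),
               function(k) poisson_score(mk(k), 1)$score, 1)
  expect_true(all(diff(sc) >= 0))
  # Bonferroni multiplies the p-value
  r1 <- poisson_score(mk(1800), 1)
  r2 <- poisson_score(mk(1800), 100)
  expect_equal(r2$p_bonf, min(1, r1$p_raw * 100))
})

test_that("underflowed p-values clamp at the subnormal floor giving score 323", {
  oc <- structure(list(factor_a = "a", factor_b = "a", n_a = 20000,
                       n_b = 20000, k = 20000L, k_b = 20000L,
                       share_a = 1, share_b = 1), class = "OverlapCount")
  res <- poisson_score(oc, n_tests = 1)
  expect_equal(floor(res$score), 323)
  expect_equal(res$score, -log10(2^-1074))
})

test_that("significance needs both the score and the anchor-share rule (strict)", {
  mk_res <- function(score) {
    structure(list(counts = NULL, lambda_exp = 1, p_raw = 1, p_bonf = 1,
                   score = score, degenerate = FALSE), class = "CoassocResult")
  }
  expect_true(significance_call(mk_res(323), 0.23))
  expect_false(significance_call(mk_res(150), 0.08))
  expect_false(significance_call(mk_res(99), 0.5))
  expect_false(significance_call(mk_res(100), 0.5))    # strict >
  expect_false(significance_call(mk_res(150), 0.10))   # strict >
})

test_that("anchored overlap restricts to the anchor neighborhood and rescales the null", {
  anchor <- ps_from_summits(seq(10000, 2e6, by = 10000), factor = "NF-YB")
  a <- ps_from_summits(seq(10000, 2e6, by = 10000) + 40, factor = "A")
  b <- ps_from_summits(seq(10000, 2e6, by = 10000) - 40, factor = "B")
  res <- anchored_overlap(a, b, anchor)
  expect_equal(res$counts$share_a, 1.0)
  expect_false(res$degenerate)
  expect_equal(res$lambda_exp,
               res$counts$n_a * res$counts$n_b / length(anchor))
  # disjoint from the anchor: degenerate zero result
  far <- ps_from_summits(seq(5000, 2e6, by = 10000), factor = "C")
  res2 <- anchored_overlap(a, far, anchor)
  expect_true(res2$degenerate)
  expect_equal(res2$counts$k, 0L)
  expect_equal(res2$score, 0)
  expect_error(anchored_overlap(a, b, ps_from_summits(integer(0))), "empty")
})

test_that("triple-overlap fractions planted on synthetic data are recovered in anchored mode", {
  g <- make_genome(2, 10e6, 9000, seed = 31)
  fac <- c("NF-YB", "A", "B")
  co <- matrix(0, 3, 3, dimnames = list(fac, fac))
  co["NF-YB", c("A", "B")] <- c(1.0, 0.5)
  co[c("A", "B"), "NF-YB"] <- c(1.0, 0.5)
  pp <- plant_peaksets(g, fac, 2000, coassoc = co, seed = 32)
  res <- anchored_overlap(pp$peaksets$B, pp$peaksets$A, pp$peaksets[["NF-YB"]])
  # B's anchor-restricted summits sit in NF-YB regions; A covers all of them
  expect_equal(res$counts$n_a, 1000L)
  expect_equal(res$counts$share_a, 1.0)
})

test_that("matrix clustering merges identical rows first and anti-correlated last", {
  m <- rbind(r1 = c(1, 2, 3, 4), r2 = c(1, 2, 3, 4) * 2 + 1,
             r3 = c(4, 3, 2, 1), r4 = c(0.9, 2.2, 3.1, 3.9))
  cl <- cluster_matrix(m)
  h <- cl$hclust
  first <- sort(h$labels[-h$merge[1, ]])
  expect_equal(first, c("r1", "r2"))            # correlation 1, distance 0
  expect_equal(h$height[1], 0, tolerance = 1e-12)
  # the anti-correlated row joins last, near the maximum distance of 2
  expect_true(-match("r3", h$labels) %in% h$merge[nrow(h$merge), ])
  expect_gt(max(h$height), 1.9)
  expect_match(cl$newick, "^\\(")
  # constant rows are dropped with a warning; all-constant errors
  m2 <- rbind(m, flat = c(1, 1, 1, 1))
  expect_warning(cluster_matrix(m2), "constant")
  expect_error(suppressWarnings(cluster_matrix(rbind(a = c(1, 1), b = c(2, 2)))),
               "constant|cluster")
})

test_that("a planted two-block score matrix is split at the top of the dendrogram", {
  set.seed(41)
  block <- function(members, n = 8) {
    base <- runif(n)
    t(vapply(members, function(m) base + rnorm(n, sd = 0.02), numeric(n)))
  }
  m <- rbind(block(c("a1", "a2", "a3")), -2 * block(c("b1", "b2", "b3")))
  rownames(m) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  cl <- cluster_matrix(m)
  groups <- stats::cutree(cl$hclust, k = 2)
  expect_length(unique(groups[c("a1", "a2", "a3")]), 1L)
  expect_length(unique(groups[c("b1", "b2", "b3")]), 1L)
  expect_false(groups[["a1"]] == groups[["b1"]])
})

test_that("coassoc_matrix reports ordered pairs, both shares, and the ceiling diagonal", {
  sets <- list(A = ps_from_summits(seq(1000, 3e6, by = 3000)),
               B = ps_from_summits(seq(1000, 3e6, by = 3000) + 50, factor = "B"),
               C = ps_from_summits(seq(1500, 3e6, by = 2911), factor = "C"))
  m <- coassoc_matrix(sets)
  expect_equal(dim(m$scores), c(3L, 3L))
  expect_equal(unname(diag(m$scores)), rep(-log10(2^-1074), 3))
  expect_equal(nrow(m$pairs), 6L)
  ab <- m$pairs[m$pairs$factor_a == "A" & m$pairs$factor_b == "B", ]
  expect_equal(ab$share_a, 1.0)
  expect_equal(m$n_tests, 6L)
})
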