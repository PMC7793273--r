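rand_genome_seq <- function(len = 2000, seed = 1) {
  set.seed(seed)
  c(chr1 = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""))
}

test_that("consensus scores exactly 1, anti-consensus 0, and strands are symmetric", {
  tf <- synthetic_tf_pwm("X", seed = 7)
  cons <- pwm_consensus(tf)
  seqs <- rand_genome_seq(seed = 3)
  substr(seqs["chr1"], 501, 500 + nchar(cons)) <- cons
  sc <- scan_windows(seqs, data.frame(chrom = "chr1", start = 450L, end = 600L), tf)
  expect_equal(sc$best_score, 1.0)
  expect_equal(sc$best_pos, 50L)
  expect_equal(sc$best_strand, "+")
  # anti-consensus: the minimizing base at every position scores exactly 0
  # after min-max normalization
  lo <- pwm_log_odds(tf)
  anti <- rownames(lo)[apply(lo, 2, which.min)]
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  anti_score <- sum(lo[cbind(match(anti, rownames(lo)), seq_len(ncol(lo)))])
  expect_equal((anti_score - smin) / (smax - smin), 0)
  # reverse-complementing the genome flips the strand, preserves the score
  seqs_rc <- c(chr1 = revcomp(seqs[["chr1"]]))
  sc3 <- scan_windows(seqs_rc, data.frame(chrom = "chr1", start = 1400L,
                                          end = 1550L), tf)
  expect_equal(sc3$best_score, 1.0)
  expect_equal(sc3$best_strand, "-")
  expect_equal(sc3$best_pos, 2000L - (450L + 50L + tf$length) - 1400L)
})

test_that("vectorized scanning equals a per-window exhaustive oracle", {
  tf <- synthetic_tf_pwm("X", seed = 9)
  seqs <- rand_genome_seq(len = 30000, seed = 13)
  wins <- data.frame(chrom = "chr1", start = seq(0L, 29000L, by = 1000L))
  wins$end <- wins$start + 150L
  got <- scan_windows(seqs, wins, tf)
  lo <- pwm_log_odds(tf)
  lo_rc <- nfyregulome:::.lo_revcomp(lo)
  smin <- sum(apply(lo, 2, min)); smax <- sum(apply(lo, 2, max))
  for (i in seq_len(nrow(wins))) {
    s <- substr(seqs["chr1"], wins$start[i] + 1, wins$end[i])
    ch <- strsplit(s, "")[[1]]
    best <- -Inf
    code <- match(ch, c("A", "C", "G", "T"))
    for (o in 1:(150 - tf$length + 1)) {
      for (m in list(lo, lo_rc)) {
        v <- sum(m[cbind(code[o:(o + tf$length - 1)], seq_len(tf$length))])
        if (v > best) best <- v
      }
    }
    expect_equal(got$best_score[i], (best - smin) / (smax - smin),
                 tolerance = 1e-12)
  }
})

test_that("global enrichment calls planted CCAAT and stays null-calibrated", {
  ccaat <- synthetic_ccaat_pwm()
  g <- make_genome(1, 500 * 1200, 500, seed = 51)
  g <- plant_sequences(g, ccaat, list(list(pwm = NULL, fraction = 1.0)),
                       seed = 52)
  gbg <- make_genome(1, 400 * 1200, 400, seed = 53)
  gbg <- plant_sequences(gbg, ccaat, list(), seed = 54)
  sc <- scan_windows(g$sequence, g$accessible_regions, ccaat)
  bg <- scan_windows(gbg$sequence, gbg$accessible_regions, ccaat)
  expect_lt(global_enrichment(sc, bg), 1e-10)
  # permutation route agrees on direction
  expect_lt(global_enrichment(sc, bg, method = "permutation", n_perm = 200),
            0.01)
  # regions drawn from the background itself: p is uniform over seeds
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    idx <- sample(400, 100)
    global_enrichment(bg$best_score[idx], bg$best_score[-idx])
  }, 1)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  expect_error(global_enrichment(c(1, 1), c(0.5, 0.5)), "variance")
})

test_that("local enrichment contrasts center against flanks", {
  ccaat <- synthetic_ccaat_pwm()
  n <- 200
  g <- make_genome(1, 3 * n * 1200, 3 * n, seed = 61)
  g <- plant_sequences(g, ccaat,
                       list(list(pwm = NULL, fraction = 1.0,
                                 regions = 1:n)), seed = 62)
  sc <- scan_windows(g$sequence, g$accessible_regions, ccaat)$best_score
  central <- sc[1:n]; f5 <- sc[n + 1:n]; f3 <- sc[2 * n + 1:n]
  expect_lt(local_enrichment(central, f5, f3), 1e-10)
  # planted everywhere equally: no local signal
  g2 <- make_genome(1, 3 * n * 1200, 3 * n, seed = 63)
  g2 <- plant_sequences(g2, ccaat, list(list(pwm = NULL, fraction = 0.5)),
                        seed = 64)
  sc2 <- scan_windows(g2$sequence, g2$accessible_regions, ccaat)$best_score
  expect_gt(local_enrichment(sc2[1:n], sc2[n + 1:n], sc2[2 * n + 1:n]), 1e-10)
  expect_error(local_enrichment(1:5, 1:4, 1:5), "equal length")
})

test_that("CCAAT classification applies the primary/secondary/local rules", {
  mk <- function(cc_g, cc_l, own_g) {
    data.frame(matrix_id = c("MA0060.1", "OWN"), global_p = c(cc_g, own_g),
               local_p = c(cc_l, NA))
  }
  expect_equal(classify_ccaat(mk(1e-50, 1e-60, 1e-3))$enrichment_class,
               "global_primary")
  expect_equal(classify_ccaat(mk(1e-30, 1e-40, 1e-80))$enrichment_class,
               "global_secondary")
  expect_equal(classify_ccaat(mk(1e-4, 1e-15, 1e-80))$enrichment_class,
               "local_only")
  expect_equal(classify_ccaat(mk(1e-4, 1e-8, 1e-80))$enrichment_class, "none")
  res <- classify_ccaat(mk(1e-50, 1e-60, 1e-3))
  expect_equal(res$rank_global, 1L)
  expect_error(classify_ccaat(data.frame(matrix_id = "OWN", global_p = 1,
                                         local_p = 1)), "not among")
  expect_true(is_ccaat_enriched("local_only"))
  expect_false(is_ccaat_enriched("local_only", global_only = TRUE))
  expect_false(is_ccaat_enriched("none"))
})

test_that("planted spacings are recovered exactly across non-overlapping offsets", {
  ccaat <- synthetic_ccaat_pwm()
  tf <- synthetic_tf_pwm("P", seed = 17)
  # offsets whose motif windows cannot collide with the CCAAT matrix window
  offsets <- c(-20:-8, 17:20)
  for (off in offsets) {
    g <- make_genome(1, 40 * 1200, 40, seed = 70 + off)
    g <- plant_sequences(g, ccaat,
                         list(list(pwm = tf, offset = off, orientation = "+",
                                   fraction = 1.0)), seed = 170 + off)
    pb <- positional_bias(g$accessible_regions, g$sequence, tf, ccaat)
    expect_equal(pb$mode_offset, off)
  }
})

test_that("positional bias detects the -11 arrangement, bimodality, and reverse plants", {
  ccaat <- synthetic_ccaat_pwm()
  tf <- synthetic_tf_pwm("P", seed = 3)
  g <- make_genome(1, 400 * 1200, 400, seed = 81)
  g <- plant_sequences(g, ccaat,
                       list(list(pwm = tf, offset = -11L, orientation = "+",
                                 fraction = 1.0)), seed = 82)
  pb <- positional_bias(g$accessible_regions, g$sequence, tf, ccaat)
  expect_equal(pb$mode_offset, -11L)
  expect_lt(pb$bias_p, 1e-10)
  expect_true(pb$biased)
  # equal halves at -10 and -12: bimodal histogram
  g2 <- make_genome(1, 400 * 1200, 400, seed = 83)
  g2 <- plant_sequences(g2, ccaat, list(
    list(pwm = tf, offset = -10L, orientation = "+", fraction = 1.0,
         regions = 1:200),
    list(pwm = tf, offset = -12L, orientation = "+", fraction = 1.0,
         regions = 201:400)), seed = 84)
  pb2 <- positional_bias(g2$accessible_regions, g2$sequence, tf, ccaat)
  top2 <- as.integer(names(sort(table(pb2$offsets), decreasing = TRUE)[1:2]))
  expect_setequal(top2, c(-10L, -12L))
  # reverse-orientation plant at +18 keeps the offset, flips the strand split
  g3 <- make_genome(1, 200 * 1200, 200, seed = 85)
  g3 <- plant_sequences(g3, ccaat,
                        list(list(pwm = tf, offset = 18L, orientation = "-",
                                  fraction = 1.0)), seed = 86)
  pb3 <- positional_bias(g3$accessible_regions, g3$sequence, tf, ccaat)
  expect_equal(pb3$mode_offset, 18L)
  expect_gt(pb3$orientation_split[["opposite"]],
            sum(pb3$orientation_split) * 0.9)
})

test_that("positional bias is calibrated under uniform placement", {
  ccaat <- synthetic_ccaat_pwm()
  tf <- synthetic_tf_pwm("P", seed = 3)
  support <- c(seq(-71L, -8L), seq(17L, 70L))
  pvals <- vapply(1:10, function(s) {
    g <- make_genome(1, 300 * 1200, 300, seed = 900 + s)
    set.seed(5000 + s)
    offs <- sample(support, 300, replace = TRUE)
    plants <- lapply(1:300, function(r) {
      list(pwm = tf, offset = offs[r],
           orientation = sample(c("+", "-"), 1), fraction = 1.0, regions = r)
    })
    g <- plant_sequences(g, ccaat, plants, seed = 6000 + s)
    positional_bias(g$accessible_regions, g$sequence, tf, ccaat)$bias_p
  }, 1)
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("regions without a confident CCAAT match are excluded and counted", {
  ccaat <- synthetic_ccaat_pwm()
  tf <- synthetic_tf_pwm("P", seed = 5)
  g <- make_genome(1, 100 * 1200, 100, seed = 91)
  g <- plant_sequences(g, ccaat,
                       list(list(pwm = tf, offset = -15L, orientation = "+",
                                 fraction = 1.0, regions = 1:60)), seed = 92)
  pb <- positional_bias(g$accessible_regions, g$sequence, tf, ccaat)
  expect_gte(pb$n_excluded, 30L)   # most unplanted regions lack a 0.8+ CCAAT
  expect_equal(pb$mode_offset, -15L)
})
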