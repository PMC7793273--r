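test_that("genome generation is reproducible, seed-sensitive and rejects infeasible packing", {
  g1 <- make_genome(1, 10e6, 1000, seed = 7)
  g2 <- make_genome(1, 10e6, 1000, seed = 7)
  expect_identical(g1$accessible_regions, g2$accessible_regions)
  expect_equal(nrow(g1$accessible_regions), 1000L)
  # disjoint and within bounds
  r <- g1$accessible_regions
  expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
  expect_true(all(r$end <= 10e6))
  expect_true(all(r$end - r$start == 150L))
  g3 <- make_genome(2, 5e6, 500, seed = 1)
  g4 <- make_genome(2, 5e6, 500, seed = 2)
  expect_false(identical(g3$accessible_regions, g4$accessible_regions))
  expect_error(make_genome(1, 1000, 100), "pack")
})

test_that("planted co-association fractions are recovered by the overlap counter", {
  g <- make_genome(2, 8e6, 10000, seed = 3)
  fac <- c("A", "B", "C", "D")
  co <- matrix(0, 4, 4, dimnames = list(fac, fac))
  co["A", "B"] <- co["B", "A"] <- 1.0
  co["A", "C"] <- co["C", "A"] <- 0.30
  pp <- plant_peaksets(g, fac, 2000, coassoc = co, seed = 4)
  ocB <- count_overlap(pp$peaksets$B, pp$peaksets$A)
  expect_equal(ocB$share_a, 1.0)          # full planted overlap
  ocC <- count_overlap(pp$peaksets$C, pp$peaksets$A)
  expect_equal(ocC$share_a, 0.30)         # exact by construction
  # planted-zero pair: no spurious co-association, share stays at or below
  # the chance expectation for uniform placement (within 3 binomial SD)
  ocAD <- count_overlap(pp$peaksets$D, pp$peaksets$A)
  p_chance <- 2000 / 10000
  expect_lt(ocAD$share_a,
            p_chance + 3 * sqrt(p_chance * (1 - p_chance) / 2000))
  # demands beyond the peak budget fail loudly
  co2 <- matrix(0.8, 4, 4, dimnames = list(fac, fac)); diag(co2) <- 0
  expect_error(plant_peaksets(g, fac, 2000, coassoc = co2, seed = 5),
               "shared summits|free regions")
})

test_that("summit jitter stays within the co-association window for planted pairs", {
  g <- make_genome(1, 4e6, 3000, seed = 9)
  co <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  pp <- plant_peaksets(g, c("A", "B"), 1500, coassoc = co, seed = 10)
  dists <- abs(pp$peaksets$A$peaks$summit[
    match(pp$truth$regions$B, pp$truth$regions$A)] -
      pp$peaksets$B$peaks$summit)
  expect_true(all(dists <= 100))
})

test_that("sequence planting writes the CCAAT box and partner motif where stated", {
  ccaat <- synthetic_ccaat_pwm()
  tf <- synthetic_tf_pwm("P", seed = 2)
  g <- make_genome(1, 60 * 1200, 60, seed = 12)
  g <- plant_sequences(g, ccaat,
                       list(list(pwm = tf, offset = -20L, orientation = "-",
                                 fraction = 1.0)), seed = 13)
  r <- g$accessible_regions[1, ]
  center <- r$start + 75L
  a_off <- ccaat_middle_a(ccaat)
  ccons <- pwm_consensus(ccaat)
  written <- substr(g$sequence[[r$chrom]], center - a_off + 1,
                    center - a_off + nchar(ccons))
  expect_equal(written, ccons)
  t_start <- center - 20L - (tf$length - 1L) %/% 2L
  expect_equal(substr(g$sequence[[r$chrom]], t_start + 1, t_start + tf$length),
               revcomp(pwm_consensus(tf)))
  # placement outside the region fails
  expect_error(plant_sequences(g, ccaat,
                               list(list(pwm = tf, offset = 200L,
                                         fraction = 1.0)), seed = 1),
               "outside region")
})

test_that("planted DEG tables have exact UP/DOWN counts and recoverable target overlaps", {
  d <- plant_deg_tables(1000, 0.2, 0.15, seed = 21)
  part <- partition_degs(d$deg)
  expect_length(part$up, 200L)
  expect_length(part$down, 150L)
  expect_length(part$neutral, 650L)
  # identical reruns under the same seed
  d2 <- plant_deg_tables(1000, 0.2, 0.15, seed = 21)
  expect_identical(d$deg, d2$deg)
  # planted target overlap
  ov <- matrix(c(0, 0.5, 0.5, 0), 2, 2, dimnames = list(c("X", "Y"), c("X", "Y")))
  d3 <- plant_deg_tables(2000, 0.2, 0.2, factors = c("X", "Y"),
                         target_size = 200, overlaps = ov, seed = 22)
  expect_length(intersect(d3$targets$X, d3$targets$Y), 100L)
  expect_error(plant_deg_tables(100, 0.7, 0.6), "exceed 1")
})
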