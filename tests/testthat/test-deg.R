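test_that("DEG partitioning applies strict thresholds on both axes", {
  deg <- data.frame(
    gene_id = sprintf("g%d", 1:6),
    log2FoldChange = c(1.5, 1.0, -1.5, -1.0, 3.0, 0.2),
    padj = c(0.005, 0.005, 0.005, 0.005, 0.01, 0.0001))
  part <- partition_degs(deg)
  expect_equal(part$up, "g1")              # g2 sits exactly at |lfc| = 1
  expect_equal(part$down, "g3")            # g5 sits exactly at fdr = 0.01
  expect_setequal(part$neutral, c("g2", "g4", "g5", "g6"))
  expect_setequal(c(part$up, part$down, part$neutral), deg$gene_id)
  # NA FDR is neutral
  deg$padj[1] <- NA
  expect_length(partition_degs(deg)$up, 0L)
})

test_that("fisher test matches the enumeration oracle and is symmetric", {
  # the canonical balanced 2x2: p = 1
  uni <- c("a", "b", "c", "d")
  r <- fisher_coreg(c("a", "b"), c("a", "c"), uni)
  expect_equal(unname(r$table[1, 1]), 1L)
  expect_equal(r$p, 1.0)
  # symmetry
  set.seed(31)
  uni2 <- sprintf("g%d", 1:120)
  a <- sample(uni2, 30); b <- sample(uni2, 45)
  expect_equal(fisher_coreg(a, b, uni2)$p, fisher_coreg(b, a, uni2)$p)
  # sweep against enumeration on universes up to 300
  for (i in 1:60) {
    N <- sample(10:300, 1)
    uni3 <- sprintf("h%d", 1:N)
    a <- sample(uni3, sample(1:N, 1)); b <- sample(uni3, sample(1:N, 1))
    r <- fisher_coreg(a, b, uni3)
    expect_equal(r$p, fisher_twosided_oracle(r$table), tolerance = 1e-9)
  }
})

test_that("identical target sets give the minimal attainable p with the clamp transform", {
  uni <- sprintf("g%d", 1:200)
  a <- uni[1:100]
  r <- fisher_coreg(a, a, uni)
  support <- 0:100
  dens <- dhyper(support, 100, 100, 100)
  expect_equal(r$p, sum(dens[dens <= dens[101] * (1 + 1e-7)]),
               tolerance = 1e-12)
  expect_equal(r$neg_log10_p, -log10(r$p))
  # the clamp keeps underflowed p finite
  expect_equal(neg_log10(0), -log10(2^-1074))
  expect_error(fisher_coreg(a, a, character(0)), "empty")
})

test_that("independent planted sets yield unremarkable p-values over seeds", {
  pvals <- vapply(1:100, function(s) {
    set.seed(s)
    uni <- sprintf("g%d", 1:400)
    fisher_coreg(sample(uni, 80), sample(uni, 80), uni)$p
  }, 1)
  expect_gt(stats::median(pvals), 0.1)
  expect_lte(mean(pvals < 0.05), 0.10)
})

test_that("an activator block planted in the DOWN state clusters in DOWN only", {
  set.seed(41)
  d <- plant_deg_tables(3000, 0.15, 0.15,
                        factors = sprintf("TF%d", 1:6), target_size = 250,
                        overlaps = local({
                          m <- matrix(0, 6, 6, dimnames = list(
                            sprintf("TF%d", 1:6), sprintf("TF%d", 1:6)))
                          m[1:3, 1:3] <- 0.45; diag(m) <- 0; m
                        }), seed = 42)
  part <- partition_degs(d$deg)
  tg_down <- lapply(d$targets, intersect, y = part$down)
  pairs_down <- fisher_coreg_all(tg_down, part$down, state = "DOWN")
  block <- pairs_down$factor_a %in% c("TF1", "TF2", "TF3") &
    pairs_down$factor_b %in% c("TF1", "TF2", "TF3")
  expect_gt(min(pairs_down$neg_log10_p[block]),
            max(pairs_down$neg_log10_p[!block]))
  hm <- coreg_heatmap(pairs_down)
  groups <- stats::cutree(hm$hclust, k = 2)
  expect_length(unique(groups[c("TF1", "TF2", "TF3")]), 1L)
  # factors with identical target sets pair up first in the dendrogram
  tg2 <- list(A = d$targets$TF1, B = d$targets$TF1, C = d$targets$TF4,
              D = d$targets$TF5)
  hm2 <- coreg_heatmap(fisher_coreg_all(lapply(tg2, intersect, y = part$down),
                                        part$down, "DOWN"))
  first <- sort(hm2$hclust$labels[-hm2$hclust$merge[1, ]])
  expect_equal(first, c("A", "B"))
})

test_that("expression shifts of the partner factors are extracted and flagged", {
  deg <- data.frame(gene_id = c("NFYB", "FOS", "SP1"),
                    log2FoldChange = c(-3, 0.2, 0.6),
                    padj = c(1e-30, 0.5, 0.01))
  rep <- expression_shift_report(deg, c("NFYB", "FOS", "SP1", "GONE"))
  expect_equal(rep$factor[which.min(rep$log2FoldChange)], "NFYB")
  expect_equal(rep$flagged, c(TRUE, FALSE, TRUE, FALSE))
  expect_true(rep$missing[rep$factor == "GONE"])
  # all modest shifts: nothing flagged
  deg2 <- data.frame(gene_id = c("A", "B"), log2FoldChange = c(0.3, -0.4),
                     padj = c(0.5, 0.5))
  expect_equal(sum(expression_shift_report(deg2, c("A", "B"))$flagged), 0L)
})
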