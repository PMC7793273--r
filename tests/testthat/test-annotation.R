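toy_segmentation <- function() {
  chromatin_segmentation(data.frame(
    chrom = "chr1",
    start = seq(0L, by = 200L, length.out = 6L),
    end = seq(200L, by = 200L, length.out = 6L),
    state = c("TssA", "Quies", "TssA", "EnhA1", "Quies", "EnhA1")))
}

test_that("summits map to half-open segmentation bins, boundaries to the right bin", {
  seg <- toy_segmentation()
  ps <- ps_from_summits(c(250, 400, 399, 1100, 5000))
  d <- state_distribution(ps, seg)
  # 250 -> Quies[200,400); 399 -> Quies; 400 -> TssA[400,600); 1100 -> EnhA1
  expect_equal(unname(d$counts["Quies"]), 2L)
  expect_equal(unname(d$counts["TssA"]), 1L)
  expect_equal(unname(d$counts["EnhA1"]), 1L)
  expect_equal(d$n_unannotated, 1L)
  expect_equal(sum(d$fractions), 1, tolerance = 1e-9)
})

test_that("state counts equal a per-summit linear-scan oracle and scope filtering shrinks them", {
  set.seed(5)
  seg_df <- data.frame(chrom = "chr1",
                       start = seq(0L, by = 200L, length.out = 300L))
  seg_df$end <- seg_df$start + 200L
  seg_df$state <- sample(c("S1", "S2", "S3"), 300, replace = TRUE)
  seg <- chromatin_segmentation(seg_df)
  # summits spaced beyond the 300 bp window so scope filtering is exact
  summits <- sample(seq(100L, by = 400L, length.out = 140L), 100)
  ps <- ps_from_summits(summits)
  d <- state_distribution(ps, seg)
  oracle <- table(vapply(sort(summits), function(s) {
    hit <- which(seg_df$start <= s & s < seg_df$end)
    if (length(hit)) seg_df$state[hit] else "un"
  }, ""))
  for (st in c("S1", "S2", "S3")) {
    expect_equal(unname(d$counts[st]),
                 as.integer(oracle[st] %||% 0L))
  }
  anchor <- ps_from_summits(sample(summits, 40), factor = "NF-YB")
  d2 <- state_distribution(ps, seg, scope_filter = anchor)
  expect_true(all(d2$counts <= d$counts))
  expect_equal(sum(d2$counts), 40L)
})

test_that("promoter windows are strand-oriented and inclusive", {
  ann <- data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                    tss = c(5000L, 5000L), strand = c("+", "-"),
                    stringsAsFactors = FALSE)
  hit <- function(summit, gene) {
    gene %in% promoter_targets(ps_from_summits(summit), ann)$genes
  }
  expect_true(hit(4200, "gp"))    # inside [4000, 5100]
  expect_true(hit(4000, "gp"))    # inclusive upstream bound
  expect_true(hit(5100, "gp"))    # inclusive downstream bound
  expect_false(hit(3900, "gp"))
  expect_false(hit(5101, "gp"))
  expect_true(hit(5800, "gm"))    # mirrored window [4900, 6000]
  expect_true(hit(4900, "gm"))
  expect_false(hit(4899, "gm"))
  # the proximal TFBS window is selectable
  t2 <- promoter_targets(ps_from_summits(4600), ann, window = c(-450L, 50L))
  expect_equal(t2$genes, "gp")
  t3 <- promoter_targets(ps_from_summits(4500), ann, window = c(-450L, 50L))
  expect_false("gm" %in% t3$genes)
})

test_that("hypergeometric ORA equals enumeration on all small tables", {
  universe <- sprintf("u%03d", 1:100)
  pw <- list(P1 = universe[1:10])
  targets <- universe[c(1:8, 50:61)]    # overlap 8 of 10, targets 20
  res <- pathway_ora(targets, pw, universe)
  expect_equal(res$p, hyper_tail_oracle(8, 10, 100, 20), tolerance = 1e-12)
  expect_equal(res$overlap, 8L)
  # sweep of small universes against the enumeration oracle
  set.seed(9)
  for (i in 1:50) {
    N <- sample(20:200, 1); m <- sample(1:(N %/% 2), 1)
    k <- sample(1:(N %/% 2), 1)
    uni <- sprintf("g%d", 1:N)
    pws <- list(X = sample(uni, m))
    tg <- sample(uni, k)
    q <- length(intersect(tg, pws$X))
    expect_equal(pathway_ora(tg, pws, uni)$p,
                 hyper_tail_oracle(q, m, N, k), tolerance = 1e-9)
  }
  # overlap at expectation is unremarkable; a nested pathway is maximal
  expect_gt(pathway_ora(universe[1:20], list(P = universe[seq(1, 100, by = 5)]),
                        universe)$p, 0.3)
  full <- pathway_ora(universe[1:20], list(P = universe[1:10]), universe)
  expect_equal(full$p, hyper_tail_oracle(10, 10, 100, 20), tolerance = 1e-12)
  expect_error(pathway_ora(targets, pw, character(0)), "empty")
})

test_that("pathway matrix filtering, merging and ordering follow the stated rules", {
  uni <- sprintf("g%03d", 1:300)
  shared_genes <- uni[1:30]
  pathways <- list(
    BIG = c(shared_genes, uni[200:290]),       # background 121 genes
    SMALL = shared_genes,                      # identical contributing set? no: full set differs
    HUGE = uni[1:250],                         # background 250 > 200: discarded
    WEAK = uni[100:150])                       # never significant
  # two pathways with literally identical gene sets merge to the larger id
  pathways$DUP_A <- shared_genes
  pathways$DUP_B <- shared_genes
  targets <- list(TF1 = uni[1:40], TF2 = uni[250:300])
  ora <- lapply(targets, pathway_ora, pathways = pathways, universe = uni)
  pm <- build_pathway_matrix(ora, pathways)
  expect_false("HUGE" %in% rownames(pm$p))     # size filter
  expect_false("WEAK" %in% rownames(pm$p))     # p filter
  # DUP_A and DUP_B share a gene set: exactly one representative survives
  expect_equal(sum(c("DUP_A", "DUP_B", "SMALL") %in% rownames(pm$p)), 1L)
  repr <- intersect(c("DUP_A", "DUP_B", "SMALL"), rownames(pm$p))
  expect_setequal(c(pm$merged_from[[repr]], repr), c("DUP_A", "DUP_B", "SMALL"))
  # permuting the input factors/rows leaves the matrix unchanged
  pm2 <- build_pathway_matrix(rev(ora), pathways)
  expect_equal(pm$p, pm2$p)
  expect_equal(pm$membership, pm2$membership)
})
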