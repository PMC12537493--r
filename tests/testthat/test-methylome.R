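# Site calling, segmentation, gene classification, mean mCG and population
# summaries.

test_that("call_site reproduces the canonical decision boundary cases", {
  expect_equal(call_site(4, 10, 0.01, 0.05), "partial")
  expect_equal(call_site(0, 50, 0.01, 0.05), "unmethylated")
  expect_equal(call_site(9, 10, 0.01, 0.05), "methylated")
  expect_equal(call_site(1, 2, 0.01, 0.05), "insufficient")
})

test_that("call_site validates inputs", {
  expect_error(call_site(5, 3, 0.01, 0.05), "reads_meth")
  expect_error(call_site(1, 10, 0.7, 0.05), "error_rate")
})

test_that("raising alpha never turns a methylated call unmethylated", {
  set.seed(1)
  n <- rpois(300, 20) + 1
  x <- rbinom(300, n, runif(300))
  rank_of <- c(insufficient = 0, unmethylated = 1, partial = 2,
               methylated = 3)
  s1 <- call_site(x, n, 0.01, 0.01)
  s2 <- call_site(x, n, 0.01, 0.10)
  # a looser alpha can only move calls away from "unmethylated" towards
  # significance, and from "insufficient" to called
  expect_true(all(!(s1 == "methylated" & s2 == "unmethylated")))
  expect_true(all(rank_of[s2] >= rank_of[s1] |
                    (s1 == "partial" & s2 == "partial")))
})

test_that("segmentation merges runs by gap and flags non-CG content", {
  s <- make_sites(c(100, 150, 250), rep("CG", 3), rep("methylated", 3))
  seg <- segment_gene(s, max_gap = 200)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$seg_class, "gbM-like")
  expect_equal(seg$n_cg_methylated, 3)

  s2 <- make_sites(c(100, 150, 200, 250), c("CG", "CHH", "CHH", "CG"),
                   rep("methylated", 4))
  seg2 <- segment_gene(s2, max_gap = 200)
  expect_equal(nrow(seg2), 1)
  expect_equal(seg2$seg_class, "teM-like")

  s3 <- make_sites(c(100, 200, 300, 400, 500),
                   rep("CG", 5),
                   c("methylated", "unmethylated", "unmethylated",
                     "unmethylated", "methylated"))
  seg3 <- segment_gene(s3, max_gap = 200)
  expect_equal(nrow(seg3), 2)

  expect_error(segment_gene(make_sites(c(5, 1), c("CG", "CG"),
                                       c("methylated", "methylated"))),
               "sorted")
})

test_that("gene classification applies the printed rules in order", {
  # gbM: >=3-CG segment with >=1 methylated, no teM
  segs <- data.frame(start = 0L, end = 300L, seg_class = "gbM-like",
                     n_cg_sites = 3L, n_cg_methylated = 1L)
  sites <- make_sites(c(10, 150, 290), rep("CG", 3),
                      c("methylated", "unmethylated", "unmethylated"))
  expect_equal(classify_gene(segs, sites)$state, "gbM")

  # teM segment at least 25% of the gbM segment length demotes to both
  segs2 <- rbind(segs,
                 data.frame(start = 400L, end = 520L,
                            seg_class = "teM-like", n_cg_sites = 3L,
                            n_cg_methylated = 2L))
  segs2$end[1] <- 400L  # gbM segment 400 bp, teM 120 bp (= 30%)
  expect_equal(classify_gene(segs2, sites)$state, "both")

  # UM: no segments, >=3 unmethylated calls
  um_sites <- make_sites(c(1, 2, 3), rep("CG", 3), rep("unmethylated", 3))
  expect_equal(classify_gene(segs[0, ], um_sites)$state, "UM")

  # short teM segment only, <3 unmethylated calls: indeterminate
  segs3 <- data.frame(start = 0L, end = 120L, seg_class = "teM-like",
                      n_cg_sites = 2L, n_cg_methylated = 1L)
  ind_sites <- make_sites(c(10, 100), c("CG", "CHH"),
                          c("methylated", "methylated"))
  expect_equal(classify_gene(segs3, ind_sites)$state, "indeterminate")
})

test_that("mean mCG uses only binomially called CG sites", {
  s <- make_sites(1:13, rep("CG", 13),
                  c(rep("methylated", 6), rep("unmethylated", 4),
                    rep("partial", 3)))
  expect_equal(gene_mean_mcg(s), 0.6)
  expect_equal(gene_mean_mcg(make_sites(1:10, "CG",
                                        rep("unmethylated", 10))), 0)
  s3 <- make_sites(1:7, rep("CG", 7),
                   c(rep("methylated", 5), rep("insufficient", 2)))
  expect_equal(gene_mean_mcg(s3), 1)
  expect_true(is.na(gene_mean_mcg(make_sites(1:2, "CG",
                                             rep("partial", 2)))))
  # invariant under permutation of site order
  set.seed(4)
  perm <- sample(nrow(s))
  expect_equal(gene_mean_mcg(s[perm, ]), gene_mean_mcg(s))
})

test_that("fast matrix classifier agrees with segment + classify", {
  set.seed(10)
  for (rep in 1:40) {
    n <- sample(4:20, 1)
    sites <- make_sites(
      sort(sample(1:2000, n)),
      sample(c("CG", "CHH", "CHG"), n, replace = TRUE, prob = c(.6, .2, .2)),
      sample(c("methylated", "unmethylated", "partial", "insufficient"),
             n, replace = TRUE))
    ref <- classify_gene(segment_gene(sites, 200), sites)
    fast <- epiqtl:::.classify_fast(sites$pos, sites$context, sites$status,
                                    200)
    expect_equal(fast$state, ref$state)
    if (!is.na(ref$mean_mcg)) expect_equal(fast$mean_mcg, ref$mean_mcg)
  }
})

test_that("conservation summary bins population frequencies", {
  st <- data.table::data.table(
    gene_id = rep(c("g1", "g2", "g3"), each = 400),
    accession = rep(sprintf("a%03d", 1:400), 3),
    state = c(rep(c("gbM", "UM"), c(100, 300)),
              rep("indeterminate", 400),
              rep("gbM", 400)))
  cs <- conservation_summary(st)
  expect_equal(cs[cs$gene_id == "g1", ]$gbm_freq, 0.25)
  expect_equal(cs[cs$gene_id == "g1", ]$gbm_bin, "[10,90)")
  expect_true(is.na(cs[cs$gene_id == "g2", ]$gbm_freq))
  expect_equal(cs[cs$gene_id == "g3", ]$gbm_bin, "100%")
  expect_true(cs[cs$gene_id == "g2", ]$low_call)
})

test_that("state counts correlate as the closed-form oracle dictates", {
  mk <- function(gbm, tem) {
    acc <- sprintf("a%d", seq_along(gbm))
    rows <- list()
    for (i in seq_along(acc)) {
      rows[[i]] <- data.table::data.table(
        gene_id = sprintf("g%03d", seq_len(gbm[i] + tem[i])),
        accession = acc[i],
        state = c(rep("gbM", gbm[i]), rep("teM", tem[i])))
    }
    data.table::rbindlist(rows)
  }
  out <- state_count_correlation(mk(c(10, 20, 30, 40), c(5, 4, 9, 8)))
  # independent closed-form Pearson oracle
  x <- c(10, 20, 30, 40); y <- c(5, 4, 9, 8)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_oracle, tolerance = 1e-12)

  perfect <- state_count_correlation(mk(c(5, 10, 15), c(5, 10, 15)))
  expect_equal(perfect$r, 1, tolerance = 1e-12)
  flat <- state_count_correlation(mk(c(10, 10, 10), c(5, 6, 7)))
  expect_true(is.na(flat$r) && flat$constant)
})

test_that("state calls partition each gene-accession pair", {
  set.seed(3)
  truth <- matrix(sample(c("gbM", "teM", "UM"), 40, replace = TRUE),
                  10, 4, dimnames = list(sprintf("g%02d", 1:10),
                                         sprintf("a%02d", 1:4)))
  meth <- simulate_gene_methylomes(truth, seed = 5)
  reads <- simulate_reads(meth$sites, read_sim_config(seed = 6))
  reads$gene_id <- meth$sites$gene_id
  calls <- call_epistate_matrix(reads)
  expect_equal(nrow(calls), 40)
  expect_equal(anyDuplicated(calls[, c("gene_id", "accession")]), 0)
  expect_true(all(calls$state %in%
                    c("UM", "gbM", "teM", "both", "indeterminate")))
})

test_that("sites are assigned to half-open gene spans", {
  genes <- data.frame(gene_id = c("g1", "g2"), chrom = "Chr1",
                      start = c(0L, 100L), end = c(100L, 200L))
  allc <- data.frame(chrom = "Chr1", pos = c(0L, 99L, 100L, 199L, 200L),
                     x = 1:5)
  res <- assign_sites_to_genes(allc, genes)
  expect_equal(res$gene_id[res$pos == 99], "g1")
  expect_equal(res$gene_id[res$pos == 100], "g2")
  expect_false(200L %in% res$pos)
})
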