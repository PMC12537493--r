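# Genetic-confound accounting: cis scans, nested populations, haplogroups,
# SV-invariant subpopulations, LD statistics, trans-QTL variance.

test_that("cis scan flags a perfectly collinear SNP and skips monomorphic windows", {
  set.seed(1)
  G <- matrix(rbinom(200 * 20, 1, 0.4), 200, 20,
              dimnames = list(NULL, sprintf("s%02d", 1:20)))
  expr <- as.numeric(G[, 7])
  sc <- cis_scan(expr, G)
  expect_true("s07" %in% sc$significant)
  expect_lt(sc$stats$p_value[7], 1e-20)

  mono <- cis_scan(rnorm(200), matrix(1, 200, 5))
  expect_true(mono$monomorphic)
  expect_length(mono$significant, 0)
})

test_that("null cis scans control the family-wise error at the scan level", {
  set.seed(2)
  n_hit <- 0
  for (i in 1:100) {
    G <- matrix(rbinom(300 * 100, 1, 0.3), 300, 100)
    sc <- cis_scan(rnorm(300), G)
    if (length(sc$significant) > 0) n_hit <- n_hit + 1
  }
  # Bonferroni: P(any hit) <= 0.05 per scan; allow binomial slack at 100 scans
  expect_lte(n_hit, 12)
})

test_that("nested populations retain genuine methylation effects and drop collinear ones", {
  set.seed(3)
  n <- 600
  snp <- rbinom(n, 1, 0.5)
  # mCG collinear with the split SNP: no variance within classes
  coll <- nested_population_test(snp * 0.8, rnorm(n) + snp, snp)
  expect_false(coll$verdict == "retained")

  # genuinely epigenetic effect, independent of the SNP
  ok <- 0
  for (i in 1:20) {
    mcg <- runif(n)
    expr <- sqrt(0.1) * scale(mcg)[, 1] + sqrt(0.9) * rnorm(n) +
      0.5 * snp
    if (nested_population_test(mcg, expr, snp)$verdict == "retained")
      ok <- ok + 1
  }
  expect_gte(ok, 19)

  # one class below min_n: decision rests on the other
  snp2 <- c(rep(0, 10), rep(1, 90))
  mcg2 <- runif(100); expr2 <- 2 * mcg2 + rnorm(100, sd = 0.1)
  res <- nested_population_test(mcg2, expr2, snp2, min_n = 15)
  expect_false(res$per_class$valid[res$per_class$allele == 0])
  expect_equal(res$verdict, "retained")
})

test_that("haplogroups are genotype equivalence classes with a size floor", {
  G <- rbind(matrix(rep(c(0, 1, 0), 15), 15, 3, byrow = TRUE),
             matrix(rep(c(1, 1, 0), 14), 14, 3, byrow = TRUE),
             matrix(rep(c(1, 1, 1), 20), 20, 3, byrow = TRUE))
  rownames(G) <- sprintf("a%02d", 1:49)
  hg <- define_haplogroups(G, min_size = 15)
  sizes <- sort(vapply(hg, function(h) length(h$members), 0L))
  expect_equal(sizes, c(15L, 20L))               # 15 kept, 14 discarded
  disc <- attr(hg, "discarded")
  expect_equal(length(disc), 1)
  expect_equal(length(disc[[1]]$members), 14)
  # union of kept + discarded = all accessions with complete genotypes
  all_mem <- c(unlist(lapply(hg, `[[`, "members")),
               unlist(lapply(disc, `[[`, "members")))
  expect_setequal(all_mem, rownames(G))
  # a single differing SNP separates signatures
  expect_equal(length(unique(vapply(c(hg, disc), `[[`, "",
                                    "signature"))), 3)
  # missing window genotypes exclude the accession
  G[1, 2] <- NA
  hg2 <- define_haplogroups(G, min_size = 15)
  expect_false("a01" %in% unlist(lapply(c(hg2, attr(hg2, "discarded")),
                                        `[[`, "members")))
})

test_that("within-haplogroup tests detect shifts and skip one-class groups", {
  set.seed(4)
  acc <- sprintf("a%03d", 1:60)
  hg <- list(list(members = acc, signature = "x"))
  meth <- setNames(rep(c(0, 1), each = 30), acc)

  # identical trait values in both epiallelic classes: no effect
  same <- within_haplogroup_association(hg, meth,
                                        setNames(rep(rnorm(30), 2), acc))
  expect_gt(same$p_value, 0.99)

  # 1 s.d. shift, 30 per class: detected in nearly every repeat
  hits <- 0
  for (i in 1:20) {
    y <- setNames(rnorm(60) + meth, acc)
    if (within_haplogroup_association(hg, meth, y)$p_value < 0.01)
      hits <- hits + 1
  }
  expect_gte(hits, 16)

  # single-class haplogroup: explicit untestable status
  one <- within_haplogroup_association(hg, setNames(rep(1, 60), acc),
                                       setNames(rnorm(60), acc))
  expect_equal(nrow(one), 0)
  expect_equal(attr(one, "untestable"), 1L)

  # quantitative mCG falls back to correlation
  q <- within_haplogroup_association(hg, setNames(runif(60), acc),
                                     setNames(rnorm(60), acc))
  expect_true(is.na(q$n_meth))
})

test_that("SV-invariant subpopulations isolate SV-driven associations", {
  set.seed(5)
  n <- 400
  # no SV polymorphism: identical to the full-population test
  mcg <- runif(n); expr <- 2 * mcg + rnorm(n, sd = 0.5)
  full_p <- cor.test(mcg, expr)$p.value
  res <- sv_invariant_test(mcg, expr, matrix(0, n, 2))
  expect_false(res$restricted)
  expect_equal(res$p_value, full_p, tolerance = 1e-12)

  # association driven entirely by the SV: lost within invariant subpop
  sv <- rbinom(n, 1, 0.4)
  mcg_sv <- sv * 0.6 + runif(n, 0, 0.05)
  expr_sv <- sv + rnorm(n, sd = 0.3)
  lost <- sv_invariant_test(mcg_sv, expr_sv, cbind(sv))
  expect_true(lost$restricted)
  expect_false(lost$verdict == "retained")

  # SV present but independent of mCG: retained
  kept <- sv_invariant_test(mcg, expr, cbind(rbinom(n, 1, 0.3)))
  expect_equal(kept$verdict, "retained")
})

test_that("LD statistics match the worked haplotype arithmetic", {
  h <- expand_haplotypes(40, 10, 10, 40)
  v <- ld_epiallele_snp(h$a, h$b)
  expect_equal(v$D, 0.15, tolerance = 1e-12)
  expect_equal(v$D_prime, 0.6, tolerance = 1e-12)
  expect_equal(v$r, 0.6, tolerance = 1e-12)

  coupled <- expand_haplotypes(50, 0, 0, 50)
  vc <- ld_epiallele_snp(coupled$a, coupled$b)
  expect_equal(vc$r, 1); expect_equal(vc$D_prime, 1)

  indep <- expand_haplotypes(25, 25, 25, 25)
  vi <- ld_epiallele_snp(indep$a, indep$b)
  expect_equal(vi$r, 0); expect_equal(vi$D_prime, 0)

  mono <- ld_epiallele_snp(rep(1, 20), rbinom(20, 1, 0.5))
  expect_true(mono$monomorphic)
  expect_error(ld_epiallele_snp(c(0, 1, 2), c(0, 1, 1)), "binary")
})

test_that("trans-PVE is 100 for a collinear SNP and ~0 under the null", {
  set.seed(6)
  n <- 625
  G <- matrix(rbinom(n * 300, 1, 0.4), n, 300,
              dimnames = list(NULL, sprintf("s%03d", 1:300)))
  perfect <- trans_pve(as.numeric(G[, 10]), G)
  expect_equal(perfect$percent, 100, tolerance = 1e-6)

  nulls <- replicate(20, {
    r <- trans_pve(runif(n), G)
    r$percent
  })
  expect_lt(mean(nulls), 1)
  expect_error(trans_pve(rep(0.2, n), G), "variance")
})

test_that("confound verdicts separate epigenetic from SNP-confounded genes", {
  set.seed(7)
  n <- 600
  correct <- 0
  for (i in 1:40) {
    G <- simulate_genotypes(population_sim_config(
      n_accessions = n, n_snps = 30, seed = 4000 + i))$genotypes
    if (i <= 20) {
      mcg <- runif(n)
      expr <- sqrt(0.15) * scale(mcg)[, 1] + sqrt(0.85) * rnorm(n)
      truth <- "retained"
    } else {
      snp <- G[, 15]
      mcg <- pmin(1, pmax(0, 0.3 * snp + 0.25 + 0.05 * rnorm(n)))
      expr <- sqrt(0.3) * scale(snp)[, 1] + sqrt(0.7) * rnorm(n)
      truth <- "lost"
    }
    v <- confound_verdict(mcg, expr, G)
    if (v$final_class == truth) correct <- correct + 1
  }
  expect_gte(correct / 40, 0.9)
})
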