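# Synthetic-data generators: every input the pipeline consumes can be
# simulated with known truth, so each downstream stage is testable without
# external downloads.

#' Configuration for the cooperative epimutation simulator
#'
#' Defines a per-site gain/loss Markov model of CG methylation dynamics
#' within a locus. Each generation an unmethylated site gains methylation
#' with probability `gain_base + gain_coop * f`, where `f` is the mean
#' methylation state of the other sites in the locus (clamped to \[0,1\]),
#' and a methylated site loses methylation with probability `loss_rate`.
#' Cooperativity (`gain_coop > 0`) produces the bimodal population
#' distribution of gene-body methylation levels characteristic of natural
#' accession panels.
#'
#' @param n_sites number of CG sites in the locus
#' @param gain_base baseline per-site per-generation gain probability
#' @param gain_coop gain-probability increment per unit methylated fraction
#'   of the neighbouring sites
#' @param loss_rate per-methylated-site per-generation loss probability
#' @param n_generations generations simulated from the unmethylated state
#' @param n_lineages number of independent accession lineages
#' @param seed integer RNG seed
#' @return an object of class `epimutation_config`
#' @export
epimutation_config <- function(n_sites = 10, gain_base = 1e-6,
                               gain_coop = 0.3, loss_rate = 0.05,
                               n_generations = 100000L, n_lineages = 740L,
                               seed = 1L) {
  for (p in c(gain_base, gain_coop, loss_rate))
    if (!is.finite(p) || p < 0 || p > 1)
      stop("epimutation probabilities must lie in [0, 1]", call. = FALSE)
  if (n_generations < 1 || n_lineages < 1 || n_sites < 1)
    stop("n_sites, n_generations and n_lineages must be >= 1", call. = FALSE)
  structure(list(n_sites = as.integer(n_sites), gain_base = gain_base,
                 gain_coop = gain_coop, loss_rate = loss_rate,
                 n_generations = as.integer(n_generations),
                 n_lineages = as.integer(n_lineages),
                 seed = as.integer(seed)),
            class = "epimutation_config")
}

#' Simulate a population of methylation lineages at steady state
#'
#' Runs the cooperative epimutation model independently for each lineage
#' from an entirely unmethylated starting state. The per-gene methylation
#' level of a lineage is the fraction of methylated sites at the final
#' generation.
#'
#' @param cfg an [epimutation_config()]
#' @param keep_trajectory also return the per-generation mean methylation
#'   level (averaged over lineages and sites)
#' @return list with `states` (lineages x sites binary matrix), `levels`
#'   (per-lineage methylated fraction) and optionally `trajectory_mean`
#' @export
simulate_epimutation_population <- function(cfg, keep_trajectory = FALSE) {
  stopifnot(inherits(cfg, "epimutation_config"))
  set.seed(cfg$seed)
  out <- .epimutation_run(cfg$n_lineages, cfg$n_sites, cfg$gain_base,
                          cfg$gain_coop, cfg$loss_rate, cfg$n_generations,
                          keep_trajectory)
  out$levels <- rowMeans(out$states)
  out
}

#' Configuration for structured genotype simulation
#'
#' Allele frequencies are drawn within `maf_range`; subpopulation
#' frequencies diverge from the ancestral frequency under a
#' Balding-Nichols model with fixation index `divergence`. Within blocks of
#' `ld_block_size` adjacent SNPs, linkage disequilibrium decays
#' geometrically with distance (latent Gaussian AR(1) with correlation
#' `ld_rho`); blocks are independent.
#'
#' @param n_accessions,n_snps panel dimensions
#' @param maf_range length-2 ancestral minor-allele-frequency range in (0, 0.5]
#' @param n_subpopulations number of subpopulations (equal sizes)
#' @param divergence Balding-Nichols F (0 = panmictic)
#' @param ld_block_size SNPs per LD block
#' @param ld_rho within-block latent AR(1) correlation
#' @param ploidy 1 for haploid 0/1 coding (inbred accessions, the default),
#'   2 for diploid 0/1/2
#' @param seed integer RNG seed
#' @return an object of class `population_sim_config`
#' @export
population_sim_config <- function(n_accessions = 600L, n_snps = 1000L,
                                  maf_range = c(0.1, 0.5),
                                  n_subpopulations = 1L, divergence = 0,
                                  ld_block_size = 20L, ld_rho = 0.7,
                                  ploidy = 1L, seed = 1L) {
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must be within (0, 0.5]", call. = FALSE)
  if (n_subpopulations < 1) stop("n_subpopulations must be >= 1", call. = FALSE)
  if (divergence < 0 || divergence >= 1)
    stop("divergence must lie in [0, 1)", call. = FALSE)
  structure(list(n_accessions = as.integer(n_accessions),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 n_subpopulations = as.integer(n_subpopulations),
                 divergence = divergence,
                 ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
                 ploidy = as.integer(ploidy), seed = as.integer(seed)),
            class = "population_sim_config")
}

# one haplotype set: accessions x snps 0/1 under block-AR(1) latent Gaussians
.sim_haplotypes <- function(n, freqs, block, rho) {
  m <- length(freqs)
  z <- matrix(0, n, m)
  for (start in seq(1, m, by = block)) {
    end <- min(start + block - 1, m)
    z[, start] <- rnorm(n)
    if (end > start) {
      for (j in (start + 1):end)
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * rnorm(n)
    }
  }
  thr <- qnorm(1 - freqs)
  g <- matrix(0L, n, m)
  for (j in seq_len(m)) g[, j] <- as.integer(z[, j] > thr[j])
  g
}

#' Simulate a structured genotype panel
#'
#' @param cfg a [population_sim_config()]
#' @return list with `genotypes` (accessions x SNPs integer matrix),
#'   `subpop` (subpopulation labels), `freq` (ancestral allele frequencies)
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "population_sim_config"))
  set.seed(cfg$seed)
  p0 <- runif(cfg$n_snps, cfg$maf_range[1], cfg$maf_range[2])
  subpop <- rep(seq_len(cfg$n_subpopulations),
                length.out = cfg$n_accessions)
  subpop <- sort(subpop)
  G <- matrix(0L, cfg$n_accessions, cfg$n_snps)
  for (s in seq_len(cfg$n_subpopulations)) {
    idx <- which(subpop == s)
    if (cfg$divergence > 0) {
      a <- p0 * (1 - cfg$divergence) / cfg$divergence
      b <- (1 - p0) * (1 - cfg$divergence) / cfg$divergence
      ps <- rbeta(cfg$n_snps, a, b)
      ps <- pmin(pmax(ps, 1e-4), 1 - 1e-4)
    } else ps <- p0
    h <- .sim_haplotypes(length(idx), ps, cfg$ld_block_size, cfg$ld_rho)
    if (cfg$ploidy == 2L)
      h <- h + .sim_haplotypes(length(idx), ps, cfg$ld_block_size, cfg$ld_rho)
    G[idx, ] <- h
  }
  rownames(G) <- sprintf("acc%04d", seq_len(cfg$n_accessions))
  colnames(G) <- sprintf("snp%05d", seq_len(cfg$n_snps))
  list(genotypes = G, subpop = subpop, freq = p0)
}

#' Simulate expression driven by gbM, teM and SNP marker groups
#'
#' For each gene, expression is the sum of group linear predictors built
#' from sparse causal effects plus Gaussian noise. Each group's predictor
#' is rescaled so that its realized variance fraction matches the target
#' (the match is exact on the simulated predictors; sampling noise enters
#' only through the residual draw).
#'
#' @param X list of marker matrices named `gbm`, `tem`, `snp` (accessions
#'   in rows); any entry may be `NULL`
#' @param targets named numeric vector of target variance fractions for the
#'   groups present (sum must be <= 1)
#' @param n_genes number of genes to simulate
#' @param n_causal named integer vector: causal markers per group
#' @param seed integer RNG seed
#' @return list with `expression` (genes x accessions), and `truth`: per
#'   gene the causal indices, effects, realized per-group variance
#'   fractions and the group predictors
#' @export
simulate_expression <- function(X, targets, n_genes = 100L,
                                n_causal = c(gbm = 5L, tem = 5L, snp = 10L),
                                seed = 1L) {
  groups <- names(targets)
  if (sum(targets) > 1 + 1e-12)
    stop("target variance fractions must sum to <= 1", call. = FALSE)
  n <- unique(vapply(X[groups], nrow, 0L))
  if (length(n) != 1)
    stop("marker matrices must share the accession axis", call. = FALSE)
  set.seed(seed)
  resid_var <- 1 - sum(targets)
  expr <- matrix(0, n_genes, n)
  truth <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    y <- rnorm(n, sd = sqrt(resid_var))
    gt <- list()
    for (g in groups) {
      M <- X[[g]]
      nc <- min(n_causal[[g]], ncol(M))
      idx <- sample.int(ncol(M), nc)
      beta <- rnorm(nc)
      u <- as.vector(M[, idx, drop = FALSE] %*% beta)
      vu <- var(u)
      if (targets[[g]] > 0 && vu > 0) {
        scl <- sqrt(targets[[g]] / vu)
        u <- u * scl
        beta <- beta * scl
      } else u <- u * 0
      y <- y + u
      gt[[g]] <- list(idx = idx, beta = beta, predictor = u)
    }
    vy <- var(y)
    realized <- vapply(gt, function(z) var(z$predictor) / vy, 0)
    truth[[i]] <- list(groups = gt, realized = realized,
                       resid_var = resid_var)
    expr[i, ] <- y
  }
  rownames(expr) <- sprintf("gene%04d", seq_len(n_genes))
  colnames(expr) <- rownames(X[[groups[1]]])
  list(expression = expr, truth = truth)
}

#' Configuration for bisulfite read-count simulation
#'
#' @param mean_depth expected reads per site (Poisson)
#' @param nonconversion_rate probability an unmethylated cytosine reads as
#'   methylated (bisulfite conversion inefficiency)
#' @param overconversion_rate probability a methylated cytosine reads as
#'   unmethylated
#' @param seed integer RNG seed
#' @return an object of class `read_sim_config`
#' @export
read_sim_config <- function(mean_depth = 30, nonconversion_rate = 0.005,
                            overconversion_rate = 0.005, seed = 1L) {
  if (mean_depth <= 0) stop("mean_depth must be > 0", call. = FALSE)
  for (r in c(nonconversion_rate, overconversion_rate))
    if (r < 0 || r >= 0.5)
      stop("conversion error rates must lie in [0, 0.5)", call. = FALSE)
  structure(list(mean_depth = mean_depth,
                 nonconversion_rate = nonconversion_rate,
                 overconversion_rate = overconversion_rate,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate site-level bisulfite read counts from true binary states
#'
#' @param true_states data.frame/data.table with columns `chrom`, `pos`,
#'   `strand`, `context`, `accession`, `state` (0/1 true methylation)
#' @param cfg a [read_sim_config()]
#' @return data.table in allc style: chrom, pos, strand, context,
#'   accession, reads_meth, reads_total
#' @export
simulate_reads <- function(true_states, cfg) {
  stopifnot(inherits(cfg, "read_sim_config"))
  set.seed(cfg$seed)
  n <- nrow(true_states)
  total <- rpois(n, cfg$mean_depth)
  pm <- ifelse(true_states$state == 1,
               1 - cfg$overconversion_rate, cfg$nonconversion_rate)
  meth <- rbinom(n, total, pm)
  data.table::data.table(
    chrom = true_states$chrom, pos = true_states$pos,
    strand = true_states$strand, context = true_states$context,
    accession = true_states$accession,
    reads_meth = meth, reads_total = total)
}

#' Simulate a quantitative trait from epialleles, SNPs and structure
#'
#' trait = causal epiallele effects + optional polygenic SNP background +
#' optional subpopulation mean shift + Gaussian noise. Variance fractions
#' are set on the realized predictors so the simulated architecture is
#' exactly the declared one.
#'
#' @param epistates binary epiallele matrix (accessions x genes; 1 = methylated
#'   class)
#' @param genotypes optional accessions x SNPs matrix for the polygenic term
#' @param causal_genes indices (or names) of causal epialleles
#' @param causal_pve total trait-variance fraction of the causal epialleles
#' @param polygenic_pve trait-variance fraction of the SNP background
#' @param subpop optional subpopulation labels
#' @param subpop_pve trait-variance fraction of subpopulation mean shifts
#' @param seed integer RNG seed
#' @return list with `trait` (named numeric vector) and `truth`
#' @export
simulate_traits <- function(epistates, genotypes = NULL,
                            causal_genes = integer(), causal_pve = 0,
                            polygenic_pve = 0, subpop = NULL,
                            subpop_pve = 0, seed = 1L) {
  n <- nrow(epistates)
  if (!is.null(genotypes) && nrow(genotypes) != n)
    stop("epistates and genotypes must share the accession axis",
         call. = FALSE)
  set.seed(seed)
  resid <- 1 - causal_pve - polygenic_pve - subpop_pve
  if (resid < 0) stop("variance fractions exceed 1", call. = FALSE)
  y <- rnorm(n, sd = sqrt(resid))
  add_scaled <- function(u, target) {
    vu <- var(u)
    if (target > 0 && vu > 0) u * sqrt(target / vu) else u * 0
  }
  eff <- NULL
  if (length(causal_genes) > 0 && causal_pve > 0) {
    M <- epistates[, causal_genes, drop = FALSE]
    eff <- rnorm(ncol(M))
    u <- add_scaled(as.vector(M %*% eff), causal_pve)
    y <- y + u
  }
  if (polygenic_pve > 0 && !is.null(genotypes)) {
    b <- rnorm(ncol(genotypes), sd = 1 / sqrt(ncol(genotypes)))
    y <- y + add_scaled(as.vector(genotypes %*% b), polygenic_pve)
  }
  if (subpop_pve > 0 && !is.null(subpop)) {
    mu <- rnorm(length(unique(subpop)))
    y <- y + add_scaled(mu[as.integer(factor(subpop))], subpop_pve)
  }
  names(y) <- rownames(epistates)
  list(trait = y,
       truth = list(causal_genes = causal_genes, causal_pve = causal_pve,
                    effects = eff, polygenic_pve = polygenic_pve,
                    subpop_pve = subpop_pve))
}

#' Simulate epiallele matrices with optional population structure
#'
#' Draws per-gene methylated-class frequencies and per-accession binary
#' epialleles, with optional Balding-Nichols divergence between
#' subpopulations (so epigenome-wide structure is mirrored in the
#' epialleles, as it is in natural panels).
#'
#' @param n_accessions,n_genes panel dimensions
#' @param freq_range range of methylated-class population frequencies
#' @param subpop optional subpopulation labels (length `n_accessions`)
#' @param divergence Balding-Nichols F between subpopulations
#' @param seed integer RNG seed
#' @return binary matrix, accessions x genes
#' @export
simulate_epialleles <- function(n_accessions, n_genes,
                                freq_range = c(0.1, 0.9), subpop = NULL,
                                divergence = 0, seed = 1L) {
  set.seed(seed)
  p0 <- runif(n_genes, freq_range[1], freq_range[2])
  M <- matrix(0L, n_accessions, n_genes)
  if (is.null(subpop)) subpop <- rep(1L, n_accessions)
  for (s in unique(subpop)) {
    idx <- which(subpop == s)
    if (divergence > 0) {
      a <- p0 * (1 - divergence) / divergence
      b <- (1 - p0) * (1 - divergence) / divergence
      ps <- pmin(pmax(rbeta(n_genes, a, b), 1e-4), 1 - 1e-4)
    } else ps <- p0
    M[idx, ] <- matrix(rbinom(length(idx) * n_genes, 1,
                              rep(ps, each = length(idx))),
                       length(idx), n_genes)
  }
  rownames(M) <- sprintf("acc%04d", seq_len(n_accessions))
  colnames(M) <- sprintf("gene%04d", seq_len(n_genes))
  M
}

#' Build true site-level methylation states for a panel of genes
#'
#' Lays out genes on one chromosome with evenly spaced cytosines and draws
#' per-site true states from each gene's assigned epigenetic state: gbM
#' genes methylate CG sites (probability `p_cg_gbm`) and never non-CG
#' sites; teM genes methylate CG and non-CG sites; UM genes are fully
#' unmethylated.
#'
#' @param gene_states character matrix (genes x accessions) of true states
#'   ("gbM", "teM", "UM")
#' @param n_cg,n_chh CG and CHH sites per gene
#' @param site_spacing bp between adjacent sites
#' @param gene_gap bp between genes
#' @param p_cg_gbm,p_cg_tem,p_chh_tem per-site methylation probabilities
#' @param seed integer RNG seed
#' @return list: `sites` (data.table of per-site true states with
#'   accession column) and `genes` (annotation data.table: gene_id, chrom,
#'   start, end, strand; 0-based half-open)
#' @export
simulate_gene_methylomes <- function(gene_states, n_cg = 12L, n_chh = 6L,
                                     site_spacing = 50L, gene_gap = 2000L,
                                     p_cg_gbm = 0.85, p_cg_tem = 0.85,
                                     p_chh_tem = 0.7, seed = 1L) {
  set.seed(seed)
  n_genes <- nrow(gene_states); n_acc <- ncol(gene_states)
  sites_per_gene <- n_cg + n_chh
  gene_len <- sites_per_gene * site_spacing + site_spacing
  starts <- (seq_len(n_genes) - 1L) * (gene_len + gene_gap)
  genes <- data.table::data.table(
    gene_id = rownames(gene_states), chrom = "Chr1",
    start = starts, end = starts + gene_len,
    strand = rep(c("+", "-"), length.out = n_genes))
  # interleave: CHH sites spread evenly among the CG sites
  ctx <- rep("CG", sites_per_gene)
  if (n_chh > 0)
    ctx[unique(round(seq(2, sites_per_gene - 1, length.out = n_chh)))] <- "CHH"
  n_cg_eff <- sum(ctx == "CG")
  offs <- seq_len(sites_per_gene) * site_spacing
  per_gene <- data.table::data.table(
    gene_id = rep(genes$gene_id, each = sites_per_gene),
    pos = rep(starts, each = sites_per_gene) + rep(offs, n_genes),
    context = rep(ctx, n_genes))
  tabs <- vector("list", n_acc)
  for (a in seq_len(n_acc)) {
    st <- rep(gene_states[, a], each = sites_per_gene)
    p <- ifelse(per_gene$context == "CG",
                ifelse(st == "gbM", p_cg_gbm,
                       ifelse(st == "teM", p_cg_tem, 0)),
                ifelse(st == "teM", p_chh_tem, 0))
    tabs[[a]] <- data.table::data.table(
      chrom = "Chr1", pos = per_gene$pos, strand = "+",
      context = per_gene$context,
      accession = colnames(gene_states)[a],
      state = rbinom(nrow(per_gene), 1, p),
      gene_id = per_gene$gene_id)
  }
  list(sites = data.table::rbindlist(tabs), genes = genes,
       n_cg_effective = n_cg_eff)
}
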