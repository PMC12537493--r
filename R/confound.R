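# Deciding whether methylation-expression/trait associations survive
# accounting for genetic variation: cis scans, nested populations fixed for
# the associated SNP, SNP-invariant haplogroups, SV-invariant
# subpopulations, LD statistics, trans-QTL variance.

# vectorized per-column correlation scan: slope, r, t-based two-sided p
.fast_scan <- function(y, G) {
  G <- as.matrix(G)
  n <- length(y)
  sy <- sd(y)
  sg <- apply(G, 2, sd)
  poly <- is.finite(sg) & sg > 0
  r <- rep(NA_real_, ncol(G))
  if (sy > 0 && any(poly))
    r[poly] <- as.vector(cor(y, G[, poly, drop = FALSE]))
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  data.frame(snp = colnames(G) %||% seq_len(ncol(G)),
             slope = r * sy / sg, r = r, t = tstat, p_value = p,
             polymorphic = poly)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Scan a gene's window SNPs against its expression (or trait)
#'
#' Per-SNP linear association with Bonferroni significance over the scan.
#'
#' @param expr expression (or trait) vector
#' @param genotypes accessions x SNPs matrix restricted to the window
#'   (gene span plus flank)
#' @param alpha family-wise level over the scan
#' @return list: `stats` (per-SNP data.frame), `significant` (SNP names),
#'   `monomorphic` (TRUE when no SNP is polymorphic)
#' @export
cis_scan <- function(expr, genotypes, alpha = 0.05) {
  st <- .fast_scan(expr, genotypes)
  m <- sum(st$polymorphic)
  if (m == 0)
    return(list(stats = st, significant = character(0),
                monomorphic = TRUE))
  sig <- st$snp[st$polymorphic & !is.na(st$p_value) &
                  st$p_value < alpha / m]
  list(stats = st, significant = as.character(sig), monomorphic = FALSE)
}

#' Re-test a methylation association within nested populations
#'
#' The population is split into the two classes fixed for the given SNP;
#' the mCG-expression (or mCG-trait) association is re-run within each
#' class that has at least `min_n` accessions and non-zero mCG variance.
#' The association is `retained` when significant in at least one valid
#' nested population, `lost` when testable but nowhere significant, and
#' `untestable` when no class can be tested.
#'
#' @param mcg,response aligned per-accession vectors
#' @param split_snp binary per-accession genotype at the colocalized SNP
#' @param alpha within-class significance level
#' @param min_n smallest analysable class
#' @return list: `per_class` data.frame (allele, n, r, p, valid),
#'   `verdict` in retained/lost/untestable
#' @export
nested_population_test <- function(mcg, response, split_snp, alpha = 0.05,
                                   min_n = 15L) {
  alleles <- sort(unique(split_snp[!is.na(split_snp)]))
  rows <- lapply(alleles, function(a) {
    idx <- which(split_snp == a)
    valid <- length(idx) >= min_n &&
      sum(complete.cases(mcg[idx], response[idx])) >= 3 &&
      sd(mcg[idx], na.rm = TRUE) > 0 && sd(response[idx], na.rm = TRUE) > 0
    if (valid) {
      ct <- cor.test(mcg[idx], response[idx])
      data.frame(allele = a, n = length(idx), r = unname(ct$estimate),
                 p_value = ct$p.value, valid = TRUE)
    } else {
      data.frame(allele = a, n = length(idx), r = NA_real_,
                 p_value = NA_real_, valid = FALSE)
    }
  })
  per_class <- do.call(rbind, rows)
  verdict <- if (!any(per_class$valid)) "untestable"
  else if (any(per_class$valid & per_class$p_value < alpha, na.rm = TRUE))
    "retained"
  else "lost"
  list(per_class = per_class, verdict = verdict)
}

#' Partition accessions into SNP-invariant haplogroups
#'
#' Haplogroups are the equivalence classes of identical genotypes over all
#' SNPs in the gene's window (gene body plus flank, default 4 kb each
#' side). Accessions with any missing window genotype are excluded rather
#' than imputed; groups smaller than `min_size` are discarded.
#'
#' @param genotypes accessions x SNPs matrix restricted to the window
#' @param min_size smallest analysable haplogroup
#' @return list of haplogroups, each with `members` (accession names or
#'   indices) and `signature`; attribute `discarded` holds the small groups
#' @export
define_haplogroups <- function(genotypes, min_size = 15L) {
  G <- as.matrix(genotypes)
  ids <- rownames(G) %||% seq_len(nrow(G))
  complete <- !apply(G, 1, anyNA)
  sig <- apply(G[complete, , drop = FALSE], 1, paste, collapse = ",")
  groups <- split(ids[complete], sig)
  keep <- vapply(groups, length, 0L) >= min_size
  res <- lapply(names(groups)[keep], function(s)
    list(members = groups[[s]], signature = s))
  attr(res, "discarded") <- lapply(names(groups)[!keep], function(s)
    list(members = groups[[s]], signature = s))
  res
}

#' Test methylation effects within haplogroups
#'
#' Within each haplogroup, the response is compared between epiallelic
#' classes with a two-sided two-sample t-test when `meth` is binary, or
#' correlated with quantitative mCG otherwise. Haplogroups carrying a
#' single class (or no mCG variance) are skipped.
#'
#' @param haplogroups from [define_haplogroups()]
#' @param meth named per-accession epiallele indicator (0/1) or mCG level
#' @param response named per-accession expression or trait values
#' @param var_equal use the pooled-variance t-test (default Welch)
#' @return data.frame, one row per testable haplogroup; attribute
#'   `untestable` counts skipped groups; zero-row output means no group was
#'   testable
#' @export
within_haplogroup_association <- function(haplogroups, meth, response,
                                          var_equal = FALSE) {
  binary <- all(meth %in% c(0, 1, NA))
  rows <- list(); skipped <- 0L
  for (i in seq_along(haplogroups)) {
    mem <- haplogroups[[i]]$members
    x <- meth[mem]; y <- response[mem]
    keep <- complete.cases(x, y)
    x <- x[keep]; y <- y[keep]
    if (length(x) < 4 || sd(x) == 0 || sd(y) == 0) {
      skipped <- skipped + 1L
      next
    }
    if (binary) {
      if (min(table(x)) < 2) { skipped <- skipped + 1L; next }
      tt <- t.test(y[x == 1], y[x == 0], var.equal = var_equal)
      rows[[length(rows) + 1]] <- data.frame(
        haplogroup = i, n = length(x), n_meth = sum(x == 1),
        effect = unname(tt$estimate[1] - tt$estimate[2]),
        p_value = tt$p.value)
    } else {
      ct <- cor.test(x, y)
      rows[[length(rows) + 1]] <- data.frame(
        haplogroup = i, n = length(x), n_meth = NA_integer_,
        effect = unname(ct$estimate), p_value = ct$p.value)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(haplogroup = integer(), n = integer(),
               n_meth = integer(), effect = numeric(),
               p_value = numeric())
  attr(out, "untestable") <- skipped
  out
}

#' Re-test an association within the largest SV-invariant subpopulation
#'
#' Restricts the panel to the largest subpopulation invariant for every
#' structural-variant (presence/absence) call in the window and re-runs
#' the mCG association there.
#'
#' @param mcg,response aligned per-accession vectors
#' @param sv_genotypes accessions x SVs binary matrix for the window (NULL
#'   or zero columns = no SV polymorphism)
#' @param alpha significance level
#' @param min_n smallest analysable subpopulation
#' @return list: `n`, `r`, `p_value`, `verdict` (retained/lost/untestable),
#'   `restricted` (FALSE when no SV polymorphism existed)
#' @export
sv_invariant_test <- function(mcg, response, sv_genotypes = NULL,
                              alpha = 0.05, min_n = 15L) {
  n_all <- length(mcg)
  if (is.null(sv_genotypes) || NCOL(sv_genotypes) == 0 ||
      all(apply(as.matrix(sv_genotypes), 2, sd, na.rm = TRUE) == 0)) {
    idx <- seq_len(n_all); restricted <- FALSE
  } else {
    sig <- apply(as.matrix(sv_genotypes), 1, paste, collapse = ",")
    counts <- table(sig)
    idx <- which(sig == names(which.max(counts)))
    restricted <- TRUE
  }
  if (length(idx) < min_n ||
      sd(mcg[idx], na.rm = TRUE) == 0 ||
      sd(response[idx], na.rm = TRUE) == 0)
    return(list(n = length(idx), r = NA_real_, p_value = NA_real_,
                verdict = "untestable", restricted = restricted))
  ct <- cor.test(mcg[idx], response[idx])
  list(n = length(idx), r = unname(ct$estimate), p_value = ct$p.value,
       verdict = if (ct$p.value < alpha) "retained" else "lost",
       restricted = restricted)
}

#' Linkage disequilibrium between an epiallele and a SNP
#'
#' Treats the two binary vectors as haplotypes (inbred accessions): `r` is
#' the Pearson correlation of the indicators, `D = p_AB - p_A p_B`,
#' `D' = D / D_max` with the standard sign-dependent `D_max`, and the
#' p-value comes from the chi-square `n r^2` on 1 df.
#'
#' @param epiallele,snp binary vectors of equal length
#' @return list: `r`, `D`, `D_prime`, `p_value`, `n`; all NA with
#'   `monomorphic = TRUE` when either vector has a single class
#' @export
ld_epiallele_snp <- function(epiallele, snp) {
  keep <- complete.cases(epiallele, snp)
  a <- epiallele[keep]; b <- snp[keep]
  if (!all(a %in% 0:1) || !all(b %in% 0:1))
    stop("inputs must be binary 0/1", call. = FALSE)
  n <- length(a)
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1))
    return(list(r = NA_real_, D = NA_real_, D_prime = NA_real_,
                p_value = NA_real_, n = n, monomorphic = TRUE))
  pAB <- mean(a == 1 & b == 1)
  D <- pAB - pA * pB
  Dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  r <- D / sqrt(pA * (1 - pA) * pB * (1 - pB))
  p <- pchisq(n * r^2, df = 1, lower.tail = FALSE)
  list(r = r, D = D, D_prime = if (Dmax > 0) abs(D) / Dmax else NA_real_,
       p_value = p, n = n, monomorphic = FALSE)
}

#' Percent methylation variance explained by trans genetic QTLs
#'
#' Genome-wide scan of the focal gene's mCG against all SNPs at the
#' Bonferroni threshold; significant SNPs are then fitted jointly and the
#' percent variance is the ratio of the SNP-marker sum of squares (after
#' fitting all other model terms) to the total sum of squares. With no
#' significant SNP the percent is 0 by convention (flagged).
#'
#' @param focal_mcg per-accession mCG of the focal gene
#' @param genotypes accessions x SNPs genome-wide matrix
#' @param covariates optional design of other model terms fitted first
#' @param alpha family-wise scan level
#' @return list: `percent`, `n_significant`, `significant`, `n`, `flagged`
#' @export
trans_pve <- function(focal_mcg, genotypes, covariates = NULL,
                      alpha = 0.05) {
  if (sd(focal_mcg, na.rm = TRUE) == 0)
    stop("focal gene has no mCG variance", call. = FALSE)
  st <- .fast_scan(focal_mcg, genotypes)
  m <- sum(st$polymorphic)
  sig <- which(st$polymorphic & !is.na(st$p_value) &
                 st$p_value < alpha / m)
  if (length(sig) == 0)
    return(list(percent = 0, n_significant = 0L,
                significant = character(0), n = length(focal_mcg),
                flagged = TRUE))
  y <- focal_mcg
  base <- if (is.null(covariates)) matrix(1, length(y), 1)
          else cbind(1, covariates)
  fit0 <- lm.fit(base, y)
  Xs <- as.matrix(genotypes)[, sig, drop = FALSE]
  fit1 <- lm.fit(cbind(base, Xs), y)
  ss_tot <- sum((y - mean(y))^2)
  ss_snp <- sum(fit0$residuals^2) - sum(fit1$residuals^2)
  list(percent = 100 * ss_snp / ss_tot, n_significant = length(sig),
       significant = as.character(st$snp[sig]), n = length(y),
       flagged = FALSE)
}

#' Full confound verdict for one gene
#'
#' Runs the cis scan; with no colocalized Bonferroni SNP the association is
#' `retained` outright; otherwise the nested-population test on the top
#' SNP decides `retained` / `lost` / `untestable` (the latter optionally
#' collapsed into `lost` for replication of analyses that did so).
#'
#' @param mcg,expr aligned per-accession vectors
#' @param window_genotypes accessions x SNPs matrix for the gene's window
#' @param alpha cis-scan family-wise level
#' @param nested_alpha within-nested-population significance level
#' @param min_n smallest analysable nested population
#' @param untestable_as_lost collapse `untestable` into `lost`
#' @return list: `final_class`, `colocalized_snp`, `cis`, `nested`
#' @export
confound_verdict <- function(mcg, expr, window_genotypes, alpha = 0.05,
                             nested_alpha = 0.05, min_n = 15L,
                             untestable_as_lost = FALSE) {
  cis <- cis_scan(expr, window_genotypes, alpha)
  if (length(cis$significant) == 0)
    return(list(final_class = "retained", colocalized_snp = NA_character_,
                cis = cis, nested = NULL))
  top <- cis$stats[cis$stats$snp %in% cis$significant, ]
  top_snp <- as.character(top$snp[which.min(top$p_value)])
  nest <- nested_population_test(
    mcg, expr, as.matrix(window_genotypes)[, top_snp],
    alpha = nested_alpha, min_n = min_n)
  cls <- nest$verdict
  if (cls == "untestable" && untestable_as_lost) cls <- "lost"
  list(final_class = cls, colocalized_snp = top_snp, cis = cis,
       nested = nest)
}
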