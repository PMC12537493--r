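# Per-gene association between intragenic mCG and expression: R, beta, PVE,
# Bonferroni/FDR tiers, and +/- eQTL sign classes.

#' Associate one gene's mCG level with its expression
#'
#' Pearson correlation with a two-sided t-distribution p-value; the slope
#' on original scales is `beta = R * sigma_P / sigma_mCG`, and the percent
#' expression variance explained is `PVE = beta^2 * V_mCG / V_P` (in
#' percent; algebraically identical to `100 R^2`). Pairs with a missing
#' value are dropped listwise.
#'
#' @param mcg per-accession mCG levels
#' @param expr per-accession expression values
#' @param gene_id,context carried through to the record
#' @return one-row data.frame: gene_id, context, n, R, p_value, beta, PVE,
#'   flagged (TRUE when the association is undefined)
#' @export
associate_gene <- function(mcg, expr, gene_id = NA_character_,
                           context = NA_character_) {
  keep <- complete.cases(mcg, expr)
  x <- mcg[keep]; y <- expr[keep]
  rec <- data.frame(gene_id = gene_id, context = context,
                    n = length(x), R = NA_real_, p_value = NA_real_,
                    beta = NA_real_, PVE = NA_real_, flagged = TRUE,
                    stringsAsFactors = FALSE)
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) return(rec)
  ct <- cor.test(x, y)
  R <- unname(ct$estimate)
  beta <- R * sd(y) / sd(x)
  pve <- 100 * beta^2 * var(x) / var(y)
  rec$R <- R; rec$p_value <- ct$p.value; rec$beta <- beta
  rec$PVE <- pve; rec$flagged <- FALSE
  rec
}

#' Eligibility filter on methylation-call frequency
#'
#' Genes qualify when their methylated-class population frequency exceeds
#' `min_freq` (computed over available calls). The threshold is 10% for
#' eQTL mapping and 20% for variance partitioning.
#'
#' @param conservation data.table from [conservation_summary()]
#' @param min_freq minimum frequency (strict: `> min_freq`)
#' @param context `"gbm"` or `"tem"`
#' @return character vector of eligible gene ids
#' @export
eligibility_filter <- function(conservation, min_freq = 0.10,
                               context = c("gbm", "tem")) {
  context <- match.arg(context)
  f <- conservation[[paste0(context, "_freq")]]
  conservation$gene_id[!is.na(f) & f > min_freq]
}

#' Apply Bonferroni and FDR tiers and sign classes
#'
#' Tier is the strictest test passed: `bonferroni` (p < alpha/m), `fdr05`,
#' `fdr10` (Benjamini-Hochberg at 0.05 and 0.10), else `none`. Tiered
#' records are classed `+eQTL` or `-eQTL` by the sign of R; untiered
#' records are `NA`.
#'
#' @param records data.frame of [associate_gene()] rows
#' @param m_tests number of tests (defaults to the number of unflagged
#'   records)
#' @param alpha_bonf Bonferroni family-wise level
#' @param fdr_levels BH levels, strictest first
#' @return records with `tier` and `sign_class` columns
#' @export
tier_and_classify <- function(records, m_tests = NULL, alpha_bonf = 0.05,
                              fdr_levels = c(0.05, 0.10)) {
  if (nrow(records) == 0) {
    records$tier <- character(0); records$sign_class <- character(0)
    return(records)
  }
  ok <- !records$flagged & !is.na(records$p_value)
  if (is.null(m_tests)) m_tests <- sum(ok)
  tier <- rep("none", nrow(records))
  q <- rep(NA_real_, nrow(records))
  q[ok] <- p.adjust(records$p_value[ok], method = "BH")
  fdr_levels <- sort(fdr_levels)
  for (lev in rev(fdr_levels))   # loosest applied first, tighter overwrite
    tier[ok & q <= lev] <- sprintf("fdr%02d", round(lev * 100))
  tier[ok & records$p_value < alpha_bonf / m_tests] <- "bonferroni"
  records$tier <- tier
  records$q_value <- q
  records$sign_class <- ifelse(tier == "none" | !ok, NA_character_,
                               ifelse(records$R > 0, "+eQTL", "-eQTL"))
  records
}

#' Distribution of association statistics across covariate bins
#'
#' Bins genes by the supplied breaks and compares the distributions of
#' `values` across bins with a Kruskal-Wallis test and pairwise Wilcoxon
#' rank-sum tests (Bonferroni-corrected). Bins with fewer than two genes
#' are excluded from the tests and reported.
#'
#' @param values per-gene statistic to compare (e.g. PVE)
#' @param covariate per-gene stratification variable (e.g. expression
#'   Shannon entropy)
#' @param breaks interior break points
#' @return list: `bins` (per-gene bin labels), `bin_sizes`, `bin_means`,
#'   `kruskal_p`, `pairwise_p` (matrix or NULL), `excluded_bins`
#' @export
stratified_summary <- function(values, covariate, breaks) {
  cuts <- cut(covariate, c(-Inf, breaks, Inf))
  sizes <- table(cuts)
  usable <- names(sizes)[sizes >= 2]
  excluded <- names(sizes)[sizes < 2]
  keep <- cuts %in% usable & !is.na(values)
  kp <- NA_real_; pw <- NULL
  if (length(usable) >= 2 && sum(keep) >= 4) {
    kp <- kruskal.test(values[keep], droplevels(cuts[keep]))$p.value
    pw <- pairwise.wilcox.test(values[keep], droplevels(cuts[keep]),
                               p.adjust.method = "bonferroni",
                               exact = FALSE)$p.value
  }
  list(bins = cuts, bin_sizes = as.vector(sizes),
       bin_means = tapply(values, cuts, mean, na.rm = TRUE),
       kruskal_p = kp, pairwise_p = pw, excluded_bins = excluded)
}

#' Map mCG-expression associations for many genes
#'
#' @param mcg genes x accessions matrix of mCG levels (NA = no call)
#' @param expression genes x accessions matrix, same row order
#' @param context label attached to every record
#' @param ... passed to [tier_and_classify()]
#' @return tiered association data.frame, one row per gene
#' @export
eqtl_scan <- function(mcg, expression, context = "gbm", ...) {
  stopifnot(nrow(mcg) == nrow(expression))
  recs <- lapply(seq_len(nrow(mcg)), function(i)
    associate_gene(mcg[i, ], expression[i, ],
                   gene_id = rownames(mcg)[i], context = context))
  tier_and_classify(do.call(rbind, recs), ...)
}
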