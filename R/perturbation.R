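# Methylation-perturbation (met1-style) expression contrasts: demethylation
# classification, promoter filter, interreplicate variability, eQTL-class
# expression shifts.

#' Classify a gene's methylation change between wild type and mutant
#'
#' A gene is `demethylated` when it has more than 10% wild-type CG
#' methylation, loses more than 5% CG methylation in the mutant, and ends
#' below 5% CG methylation. Genes failing the eligibility threshold
#' (wild-type mCG > 10%) are `ineligible`. Eligible genes that gain non-CG
#' methylation (mutant mCHG or mCHH above `noncg_max`) are
#' `excluded_noncg`; remaining eligible genes are `kept`.
#'
#' @param wt_mcg,mut_mcg wild-type and mutant mean CG methylation (0-1)
#' @param mut_mchg,mut_mchh mutant non-CG methylation levels (0-1; used for
#'   the gain filter, e.g. in h1 met1 segregants)
#' @param eligible_min,loss_min,final_max,noncg_max the printed thresholds
#' @return character vector of change classes
#' @export
classify_meth_change <- function(wt_mcg, mut_mcg, mut_mchg = 0,
                                 mut_mchh = 0, eligible_min = 0.10,
                                 loss_min = 0.05, final_max = 0.05,
                                 noncg_max = 0.01) {
  v <- c(wt_mcg, mut_mcg, mut_mchg, mut_mchh)
  if (any(!is.finite(v) | v < 0 | v > 1))
    stop("methylation levels must lie in [0, 1]", call. = FALSE)
  n <- length(wt_mcg)
  mut_mchg <- rep_len(mut_mchg, n); mut_mchh <- rep_len(mut_mchh, n)
  out <- rep("kept", n)
  out[wt_mcg <= eligible_min] <- "ineligible"
  elig <- wt_mcg > eligible_min
  out[elig & (mut_mchg > noncg_max | mut_mchh > noncg_max)] <-
    "excluded_noncg"
  demeth <- elig & out != "excluded_noncg" &
    (wt_mcg - mut_mcg) > loss_min & mut_mcg < final_max
  out[demeth] <- "demethylated"
  out
}

#' Promoter (TSS-window) methylation filter
#'
#' Genes whose CG methylation in the strand-aware window around the
#' transcription start site (default -100 bp to +250 bp) exceeds
#' `max_window_mcg` are excluded from expression contrasts. Genes with no
#' CG site in the window are kept and flagged.
#'
#' @param tss_window_mcg per-gene mean mCG in the TSS window (NA = no CG
#'   site in the window)
#' @param max_window_mcg exclusion threshold
#' @return data.frame: keep (logical), missing_window (logical)
#' @export
promoter_filter <- function(tss_window_mcg, max_window_mcg = 0.05) {
  missing <- is.na(tss_window_mcg)
  keep <- missing | tss_window_mcg <= max_window_mcg
  data.frame(keep = keep, missing_window = missing)
}

#' Mean mCG in the TSS window of each gene
#'
#' @param allc site table with `pos`, `context`, `status` and `gene_id`
#'   columns (statuses from [call_site()])
#' @param genes annotation with `gene_id`, `start`, `end`, `strand`
#'   (0-based half-open)
#' @param upstream,downstream window extent around the strand-aware TSS
#' @return named vector of window mCG per gene (NA when no called CG site)
#' @export
tss_window_mcg <- function(allc, genes, upstream = 100L,
                           downstream = 250L) {
  g <- data.table::as.data.table(genes)
  g[, tss := ifelse(strand == "-", end - 1L, start)]
  g[, `:=`(w1 = ifelse(strand == "-", tss - downstream, tss - upstream),
           w2 = ifelse(strand == "-", tss + upstream, tss + downstream))]
  dt <- data.table::as.data.table(allc)[context == "CG"]
  dt <- merge(dt, g[, .(gene_id, w1, w2)], by = "gene_id")
  dt <- dt[pos >= w1 & pos <= w2]
  res <- dt[, .(mcg = {
    m <- sum(status == "methylated"); u <- sum(status == "unmethylated")
    if (m + u > 0) m / (m + u) else NA_real_
  }), by = gene_id]
  setNames(res$mcg, res$gene_id)[g$gene_id]
}

#' Interreplicate expression variability (coefficient of variation)
#'
#' CV = sample standard deviation / mean across biological replicates.
#' Genes with any undetected replicate (value <= `detect`) are skipped, as
#' are genes with zero mean.
#'
#' @param replicates genes x replicates expression matrix (e.g. TPM)
#' @param detect detection threshold
#' @return data.frame: gene_id, cv, used (FALSE for skipped genes)
#' @export
interreplicate_cv <- function(replicates, detect = 0) {
  M <- as.matrix(replicates)
  if (ncol(M) < 2) stop("need at least 2 replicates", call. = FALSE)
  used <- apply(M, 1, function(x) all(x > detect)) & rowMeans(M) > 0
  cv <- rep(NA_real_, nrow(M))
  cv[used] <- apply(M[used, , drop = FALSE], 1, sd) /
    rowMeans(M[used, , drop = FALSE])
  data.frame(gene_id = rownames(M) %||% seq_len(nrow(M)), cv = cv,
             used = used)
}

#' Contrast expression change between eQTL classes
#'
#' Compares the mean log2 fold change of each eQTL class against the
#' non-associated (NA) class with a two-sided two-sample t-test (Welch by
#' default; pooled-variance optional).
#'
#' @param log2fc per-gene log2 fold change (mutant vs control)
#' @param class_labels per-gene labels: "+eQTL", "-eQTL" or NA (treated as
#'   the non-associated reference class)
#' @param var_equal pooled-variance t-test
#' @return data.frame: class, n, mean_log2fc, p_vs_na (NA rows for
#'   degenerate groups)
#' @export
eqtl_class_contrast <- function(log2fc, class_labels, var_equal = FALSE) {
  lab <- ifelse(is.na(class_labels), "NA", class_labels)
  ref <- log2fc[lab == "NA"]
  cls <- c("+eQTL", "-eQTL", "NA")
  rows <- lapply(cls, function(cl) {
    v <- log2fc[lab == cl]
    p <- NA_real_
    if (cl != "NA" && length(v) >= 2 && length(ref) >= 2 &&
        (sd(v) > 0 || sd(ref) > 0))
      p <- t.test(v, ref, var.equal = var_equal)$p.value
    data.frame(class = cl, n = length(v), mean_log2fc = mean(v),
               p_vs_na = p)
  })
  do.call(rbind, rows)
}

#' Binned response of expression change to wild-type gbM level
#'
#' Groups genes into bins of wild-type gbM level, reports per-bin mean
#' log2 fold change, and correlates bin means with bin centres (Pearson).
#'
#' @param wt_gbm per-gene wild-type gbM levels
#' @param log2fc per-gene log2 fold change
#' @param n_bins number of bins
#' @param quantile_bins use quantile rather than equal-width bins
#' @return list: `bins` (data.frame centre, n, mean_log2fc), `R`,
#'   `p_value`, `low_resolution` (fewer than 3 populated bins)
#' @export
mcg_binned_response <- function(wt_gbm, log2fc, n_bins = 10L,
                                quantile_bins = FALSE) {
  keep <- complete.cases(wt_gbm, log2fc)
  x <- wt_gbm[keep]; y <- log2fc[keep]
  brk <- if (quantile_bins)
    unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  else seq(min(x), max(x), length.out = n_bins + 1)
  bins <- cut(x, brk, include.lowest = TRUE)
  centres <- (head(brk, -1) + brk[-1]) / 2
  tab <- data.frame(centre = centres,
                    n = as.vector(table(bins)),
                    mean_log2fc = as.vector(tapply(y, bins, mean)))
  tab <- tab[tab$n > 0, ]
  low <- nrow(tab) < 3
  R <- NA_real_; p <- NA_real_
  if (nrow(tab) >= 3 && sd(tab$mean_log2fc) > 0) {
    ct <- cor.test(tab$centre, tab$mean_log2fc)
    R <- unname(ct$estimate); p <- ct$p.value
  } else if (nrow(tab) == 2 && sd(tab$mean_log2fc) > 0) {
    # two points define the correlation exactly; no test is possible
    R <- unname(cor(tab$centre, tab$mean_log2fc))
  }
  list(bins = tab, R = R, p_value = p, low_resolution = low)
}
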