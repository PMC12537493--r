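# Methylome state calling: per-site status from bisulfite counts, gap-merge
# segmentation, per-accession gene classification (UM/gbM/teM/both/
# indeterminate), mean mCG, and population conservation summaries.

# Coverage sufficiency, memoized per (reads_total, error_rate, alpha).
# A coverage n is sufficient when the most extreme achievable outcome
# reaches one-sided Fisher's-exact significance against an idealized
# same-coverage reference sample from BOTH alternatives: fully
# unmethylated with conversion error, and (symmetrically) fully
# methylated. At small n no outcome can separate the alternatives
# (e.g. n = 2, alpha = 0.05: the smallest attainable p is 1/6).
.coverage_sufficient <- function(n, error_rate, alpha) {
  if (n <= 0) return(FALSE)
  er <- round(n * error_rate)
  # most methylated outcome vs the unmethylated-with-error reference
  p_up <- fisher.test(matrix(c(n, 0, er, n - er), 2, 2, byrow = TRUE),
                      alternative = "greater")$p.value
  # most unmethylated outcome vs the methylated-with-error reference
  p_dn <- fisher.test(matrix(c(0, n, n - er, er), 2, 2, byrow = TRUE),
                      alternative = "less")$p.value
  p_up < alpha && p_dn < alpha
}

#' Call methylation status of cytosine sites
#'
#' Coverage sufficiency is assessed first (Fisher's exact construction, see
#' Details); for sufficiently covered sites a one-sided binomial test asks
#' whether methylated reads exceed what the conversion-error rate alone
#' would produce. Significant sites with a methylated-read fraction below
#' 0.45 are called `partial` (and are treated as missing downstream);
#' significant sites at or above 0.45 are `methylated`; non-significant
#' sufficiently covered sites are `unmethylated`.
#'
#' @details Coverage at a site is deemed sufficient when the most extreme
#' achievable outcome at that coverage reaches one-sided Fisher's-exact
#' significance against idealized same-coverage reference samples under
#' both the fully-unmethylated-with-error and fully-methylated-with-error
#' models. At `alpha = 0.05` this makes 4 reads the smallest sufficient
#' coverage.
#'
#' @param reads_meth,reads_total integer vectors of methylated and total
#'   read counts (recycled to common length)
#' @param error_rate per-accession bisulfite conversion error rate
#'   (chloroplast-derived in real data; the known simulation rate in
#'   synthetic runs), in (0, 0.5)
#' @param alpha site-level significance level
#' @param partial_cut methylated-read fraction below which a significant
#'   site is `partial` rather than `methylated`
#' @return character vector of statuses: `"methylated"`, `"unmethylated"`,
#'   `"partial"`, `"insufficient"`
#' @export
call_site <- function(reads_meth, reads_total, error_rate = 0.005,
                      alpha = 0.05, partial_cut = 0.45) {
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)", call. = FALSE)
  n <- length(reads_total)
  reads_meth <- rep_len(reads_meth, n)
  if (any(reads_meth > reads_total) || any(reads_meth < 0))
    stop("reads_meth must lie in [0, reads_total]", call. = FALSE)
  status <- rep("insufficient", n)
  suff_tab <- vapply(sort(unique(reads_total)), .coverage_sufficient,
                     logical(1), error_rate = error_rate, alpha = alpha)
  names(suff_tab) <- sort(unique(reads_total))
  ok <- suff_tab[as.character(reads_total)]
  # upper binomial tail: P(X >= reads_meth | n, error_rate)
  ptail <- pbinom(reads_meth - 1, reads_total, error_rate,
                  lower.tail = FALSE)
  frac <- ifelse(reads_total > 0, reads_meth / reads_total, 0)
  sig <- ok & ptail < alpha
  status[ok & !sig] <- "unmethylated"
  status[sig & frac >= partial_cut] <- "methylated"
  status[sig & frac < partial_cut] <- "partial"
  status
}

#' Segment methylated sites within a gene span
#'
#' Gap-merge segmentation: maximal runs of called-methylated sites (any
#' context) in which consecutive methylated sites are separated by at most
#' `max_gap` bp form segments. A segment is teM-like if it contains at
#' least one methylated non-CG site, else gbM-like. `n_cg_sites` counts all
#' CG sites (any status) inside the segment interval.
#'
#' @param sites data.frame with columns `pos` (0-based), `context`
#'   (CG/CHG/CHH) and `status` (from [call_site()]), sorted by position
#' @param max_gap maximum bp between consecutive methylated sites in a
#'   segment
#' @return data.frame of segments: `start`, `end` (half-open), `seg_class`
#'   ("gbM-like"/"teM-like"), `n_cg_sites`, `n_cg_methylated`
#' @export
segment_gene <- function(sites, max_gap = 200L) {
  if (is.unsorted(sites$pos))
    stop("sites must be sorted by position", call. = FALSE)
  meth <- sites[sites$status == "methylated", , drop = FALSE]
  empty <- data.frame(start = integer(), end = integer(),
                      seg_class = character(), n_cg_sites = integer(),
                      n_cg_methylated = integer())
  if (nrow(meth) == 0) return(empty)
  brk <- c(0L, which(diff(meth$pos) > max_gap), nrow(meth))
  segs <- lapply(seq_len(length(brk) - 1L), function(i) {
    run <- meth[(brk[i] + 1L):brk[i + 1L], , drop = FALSE]
    start <- run$pos[1]; end <- run$pos[nrow(run)] + 1L
    inside <- sites$pos >= start & sites$pos < end
    cg_in <- inside & sites$context == "CG"
    data.frame(
      start = start, end = end,
      seg_class = if (any(run$context != "CG")) "teM-like" else "gbM-like",
      n_cg_sites = sum(cg_in),
      n_cg_methylated = sum(cg_in & sites$status == "methylated"))
  })
  do.call(rbind, segs)
}

#' Classify a gene's epigenetic state in one accession
#'
#' Rules applied in order: a gene overlapped by a gbM-like segment spanning
#' three or more CG sites with at least one called methylated is gbM,
#' unless a teM-like segment at least 25% as long (bp) also overlaps it, in
#' which case it is `both`. A gene overlapped by a teM-like segment
#' spanning three or more CG sites is teM, unless a gbM-like segment at
#' least 25% as long overlaps it (`both`). A gene with no segments and at
#' least three sites called unmethylated is UM. Anything else is
#' indeterminate. `mean_mcg` is attached for gbM/teM/both genes.
#'
#' @param segments output of [segment_gene()] for this gene/accession
#' @param sites the gene's site calls (as passed to [segment_gene()])
#' @param min_um_sites unmethylated calls required for the UM class
#' @return list with `state` and `mean_mcg` (NA unless state is
#'   gbM/teM/both)
#' @export
classify_gene <- function(segments, sites, min_um_sites = 3L) {
  gb <- segments[segments$seg_class == "gbM-like", , drop = FALSE]
  te <- segments[segments$seg_class == "teM-like", , drop = FALSE]
  gb_len <- if (nrow(gb)) max(gb$end - gb$start) else 0
  te_len <- if (nrow(te)) max(te$end - te$start) else 0
  gb_ok <- nrow(gb) > 0 &&
    any(gb$n_cg_sites >= 3L & gb$n_cg_methylated >= 1L)
  te_ok <- nrow(te) > 0 && any(te$n_cg_sites >= 3L)
  state <- if (gb_ok) {
    if (te_len >= 0.25 * gb_len && te_len > 0) "both" else "gbM"
  } else if (te_ok) {
    if (gb_len >= 0.25 * te_len && gb_len > 0) "both" else "teM"
  } else if (nrow(segments) == 0 &&
             sum(sites$status == "unmethylated") >= min_um_sites) {
    "UM"
  } else "indeterminate"
  mcg <- if (state %in% c("gbM", "teM", "both"))
    gene_mean_mcg(sites) else NA_real_
  list(state = state, mean_mcg = mcg)
}

#' Mean CG methylation level of a gene
#'
#' Methylated CG sites divided by CG sites called either methylated or
#' unmethylated; partial and insufficient sites enter neither numerator
#' nor denominator. With no called CG site the level is undefined (NA).
#'
#' @param sites site-call data.frame (`context`, `status`)
#' @return fraction in \[0, 1\], or NA
#' @export
gene_mean_mcg <- function(sites) {
  cg <- sites$context == "CG"
  m <- sum(cg & sites$status == "methylated")
  u <- sum(cg & sites$status == "unmethylated")
  if (m + u == 0) return(NA_real_)
  m / (m + u)
}

#' Call the full gene-by-accession epigenetic state matrix
#'
#' Drives [call_site()], [segment_gene()] and [classify_gene()] over every
#' gene-accession pair of an allc-style site table.
#'
#' @param allc data.table with columns `pos`, `context`, `accession`,
#'   `reads_meth`, `reads_total` and `gene_id` (sites already assigned to
#'   gene spans; use [assign_sites_to_genes()] if needed)
#' @param error_rate,alpha,partial_cut passed to [call_site()]
#' @param max_gap passed to [segment_gene()]
#' @return data.table: gene_id, accession, state, mean_mcg
#' @export
call_epistate_matrix <- function(allc, error_rate = 0.005, alpha = 0.05,
                                 partial_cut = 0.45, max_gap = 200L) {
  dt <- data.table::as.data.table(allc)
  dt[, status := call_site(reads_meth, reads_total, error_rate, alpha,
                           partial_cut)]
  data.table::setorder(dt, gene_id, accession, pos)
  dt[, .classify_fast(pos, context, status, max_gap),
     by = .(gene_id, accession)]
}

# vector-level equivalent of segment_gene() + classify_gene(), used by the
# matrix driver; agreement with the documented pair is covered by tests
.classify_fast <- function(pos, context, status, max_gap,
                           min_um_sites = 3L) {
  iscg <- context == "CG"
  m <- sum(iscg & status == "methylated")
  u <- sum(iscg & status == "unmethylated")
  mcg <- if (m + u > 0) m / (m + u) else NA_real_
  mi <- which(status == "methylated")
  if (length(mi) == 0L) {
    state <- if (sum(status == "unmethylated") >= min_um_sites)
      "UM" else "indeterminate"
    return(list(state = state, mean_mcg = NA_real_))
  }
  mp <- pos[mi]; mc <- context[mi]
  brk <- c(0L, which(diff(mp) > max_gap), length(mp))
  gb_len <- 0; te_len <- 0; gb_ok <- FALSE; te_ok <- FALSE
  for (i in seq_len(length(brk) - 1L)) {
    idx <- (brk[i] + 1L):brk[i + 1L]
    s <- mp[idx[1L]]; e <- mp[idx[length(idx)]] + 1L
    ncg <- sum(iscg & pos >= s & pos < e)
    len <- e - s
    if (any(mc[idx] != "CG")) {
      te_len <- max(te_len, len)
      if (ncg >= 3L) te_ok <- TRUE
    } else {
      gb_len <- max(gb_len, len)
      if (ncg >= 3L) gb_ok <- TRUE   # run is all-CG, so >=1 methylated CG
    }
  }
  state <- if (gb_ok) {
    if (te_len >= 0.25 * gb_len && te_len > 0) "both" else "gbM"
  } else if (te_ok) {
    if (gb_len >= 0.25 * te_len && gb_len > 0) "both" else "teM"
  } else "indeterminate"
  list(state = state,
       mean_mcg = if (state %in% c("gbM", "teM", "both")) mcg else NA_real_)
}

#' Assign sites to gene spans
#'
#' @param allc site table with `chrom` and `pos` (0-based)
#' @param genes annotation data.frame: `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open)
#' @return the site table with a `gene_id` column (sites outside genes
#'   dropped)
#' @export
assign_sites_to_genes <- function(allc, genes) {
  dt <- data.table::as.data.table(allc)
  g <- data.table::as.data.table(genes)[, .(gene_id, chrom,
                                            gstart = start, gend = end)]
  dt[, `:=`(s1 = pos, s2 = pos)]
  data.table::setkey(g, chrom, gstart, gend)
  res <- data.table::foverlaps(dt, g, by.x = c("chrom", "s1", "s2"),
                               nomatch = NULL)
  res <- res[pos < gend]   # half-open gene ends
  res[, c("s1", "s2", "gstart", "gend") := NULL]
  res[]
}

#' Per-gene conservation frequencies and bins
#'
#' Frequencies are computed over available calls only (states other than
#' `indeterminate`). Genes whose call fraction falls below
#' `min_call_fraction` are flagged. Bins follow the population-frequency
#' grouping: `<10%`, `[10,90)`, `[90,100)`, `100%`.
#'
#' @param epistates data.table from [call_epistate_matrix()] (gene_id,
#'   accession, state)
#' @param min_call_fraction minimum fraction of accessions with an
#'   available call
#' @return data.table: gene_id, n_avail, gbm_freq, tem_freq, gbm_bin,
#'   tem_bin, low_call
#' @export
conservation_summary <- function(epistates, min_call_fraction = 0.7) {
  dt <- data.table::as.data.table(epistates)
  n_acc <- length(unique(dt$accession))
  bin <- function(f) {
    data.table::fcase(is.na(f), NA_character_,
                      f < 0.10, "<10%",
                      f < 0.90, "[10,90)",
                      f < 1.00, "[90,100)",
                      default = "100%")
  }
  out <- dt[, {
    avail <- state != "indeterminate" & !is.na(state)
    na_ <- sum(avail)
    list(n_avail = na_,
         gbm_freq = if (na_ > 0) sum(state == "gbM") / na_ else NA_real_,
         tem_freq = if (na_ > 0) sum(state == "teM") / na_ else NA_real_)
  }, by = gene_id]
  out[, `:=`(gbm_bin = bin(gbm_freq), tem_bin = bin(tem_freq),
             low_call = n_avail < min_call_fraction * n_acc)]
  out[]
}

#' Per-accession gbM/teM gene counts and their correlation
#'
#' @param epistates data.table from [call_epistate_matrix()]
#' @return list: `counts` (data.table accession, n_gbm, n_tem), `r`,
#'   `p_value` (Pearson; NA with a flag when a count vector is constant)
#' @export
state_count_correlation <- function(epistates) {
  dt <- data.table::as.data.table(epistates)
  counts <- dt[, .(n_gbm = sum(state == "gbM"),
                   n_tem = sum(state == "teM")), by = accession]
  if (nrow(counts) < 3)
    stop("need at least 3 accessions", call. = FALSE)
  if (sd(counts$n_gbm) == 0 || sd(counts$n_tem) == 0)
    return(list(counts = counts, r = NA_real_, p_value = NA_real_,
                constant = TRUE))
  ct <- cor.test(counts$n_gbm, counts$n_tem)
  list(counts = counts, r = unname(ct$estimate), p_value = ct$p.value,
       constant = FALSE)
}
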