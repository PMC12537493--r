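# Epigenome-wide association of epiallelic states with quantitative traits:
# LM/GLM/MLM with Q (PCA) and K (IBS kinship) structure correction,
# genomic-control lambda, FDR.

#' MAF / conservation filter for epiallele markers
#'
#' Removes rare epialleles (minor epiallele frequency below `maf_min`),
#' markers whose methylated-class frequency does not exceed
#' `conservation_min`, and monomorphic markers. Frequencies are computed
#' over non-missing calls.
#'
#' @param epistates accessions x genes binary matrix (NA = missing call)
#' @param maf_min minimum minor epiallele frequency (kept when `>=`)
#' @param conservation_min methylated-class frequency must exceed this
#' @return logical vector over markers (columns)
#' @export
maf_conservation_filter <- function(epistates, maf_min = 0.05,
                                    conservation_min = 0.10) {
  f <- colMeans(epistates, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  !is.na(f) & f > 0 & f < 1 & maf >= maf_min & f > conservation_min
}

#' Population-structure covariates from epiallelic states
#'
#' Top-k principal component scores of the (mean-imputed, centred)
#' epiallele matrix; deterministic up to sign.
#'
#' @param epistates accessions x markers matrix
#' @param k number of components
#' @return accessions x k score matrix
#' @export
pca_structure <- function(epistates, k = 3L) {
  M <- as.matrix(epistates)
  for (j in seq_len(ncol(M))) {
    cj <- M[, j]
    if (anyNA(cj)) M[is.na(cj), j] <- mean(cj, na.rm = TRUE)
  }
  rk <- qr(scale(M, scale = FALSE))$rank
  if (k >= rk) stop("k must be below the matrix rank", call. = FALSE)
  if (k == 0L) return(matrix(0, nrow(M), 0))
  pr <- prcomp(M, center = TRUE, scale. = FALSE, rank. = k)
  pr$x[, seq_len(k), drop = FALSE]
}

#' Identity-by-state kinship from epiallelic states
#'
#' `K[i, j]` is the fraction of markers with identical state among markers
#' non-missing in both accessions; the diagonal is 1. Pairs with zero
#' overlap get NA (flagged via attribute).
#'
#' @param epistates accessions x markers binary matrix
#' @return symmetric kinship matrix
#' @export
ibs_kinship <- function(epistates) {
  M <- as.matrix(epistates)
  if (!anyNA(M)) {
    # IBS for binary markers: match at 1s and at 0s
    p <- ncol(M)
    K <- (M %*% t(M) + (1 - M) %*% t(1 - M)) / p
  } else {
    obs <- !is.na(M)
    M0 <- M; M0[!obs] <- 0
    same1 <- M0 %*% t(M0)
    same0 <- ((1 - M0) * obs) %*% t((1 - M0) * obs)
    overlap <- obs %*% t(obs)
    K <- (same1 + same0) / overlap
    K[overlap == 0] <- NA
  }
  diag(K) <- 1
  attr(K, "zero_overlap") <- anyNA(K)
  K
}

#' Fixed-effects (LM/GLM-style) association scan
#'
#' Per-marker fixed-effects linear model of the trait on the marker with
#' optional structure covariates: trait and markers are projected off the
#' covariates and the association is the correlation t-test on the
#' residuals with degrees of freedom reduced accordingly (algebraically
#' the marker's partial t-test). With no covariates this is the plain LM.
#'
#' @param markers accessions x markers matrix (after filters)
#' @param trait per-accession trait vector
#' @param covariates optional accessions x q matrix (Q scores)
#' @return data.frame: marker, effect, p_value
#' @export
glm_assoc <- function(markers, trait, covariates = NULL) {
  M <- as.matrix(markers)
  keep <- complete.cases(trait)
  y <- trait[keep]; M <- M[keep, , drop = FALSE]
  q <- 0L
  if (!is.null(covariates) && NCOL(covariates) > 0) {
    C <- cbind(1, as.matrix(covariates)[keep, , drop = FALSE])
    qrC <- qr(C)
    # drop collinear covariate columns with a warning
    if (qrC$rank < ncol(C)) {
      warning("collinear covariates dropped")
      C <- C[, qrC$pivot[seq_len(qrC$rank)], drop = FALSE]
      qrC <- qr(C)
    }
    y <- qr.resid(qrC, y)
    M <- qr.resid(qrC, M)
    q <- ncol(C) - 1L
  }
  n <- length(y)
  sy <- sd(y); sm <- apply(M, 2, sd)
  poly <- is.finite(sm) & sm > 0
  r <- rep(NA_real_, ncol(M))
  if (sy > 0 && any(poly))
    r[poly] <- as.vector(cor(y, M[, poly, drop = FALSE]))
  r <- pmin(1 - 1e-15, pmax(-1 + 1e-15, r))
  df <- n - 2L - q
  tstat <- r * sqrt(df / (1 - r^2))
  data.frame(marker = colnames(M) %||% seq_len(ncol(M)),
             effect = r * sy / sm,
             p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

#' @rdname glm_assoc
#' @export
lm_assoc <- function(markers, trait) glm_assoc(markers, trait, NULL)

# REML profile for the one-random-effect mixed model on the eigenbasis of
# K; returns the variance-ratio delta = sigma2_e / sigma2_u maximising the
# restricted likelihood (EMMA-style spectral formulation).
.reml_delta <- function(yr, Xr, d, lower = 1e-5, upper = 1e5) {
  n <- length(yr); p <- ncol(Xr)
  negll <- function(log_delta) {
    delta <- exp(log_delta)
    w <- 1 / (d + delta)
    Xw <- Xr * sqrt(w); yw <- yr * sqrt(w)
    fit <- lm.fit(Xw, yw)
    rss <- sum(fit$residuals^2)
    XtWX <- crossprod(Xw)
    0.5 * ((n - p) * log(rss) + sum(log(d + delta)) +
             determinant(XtWX, logarithm = TRUE)$modulus)
  }
  opt <- optimize(negll, c(log(lower), log(upper)))
  exp(opt$minimum)
}

#' Mixed-linear-model association scan (Q + K)
#'
#' `Y = X beta + Z u + e` with `Var(u)` proportional to the kinship K.
#' Variance components are estimated once by REML under the null model
#' (trait on intercept + Q) on the eigenbasis of K and reused across
#' markers; each marker is then tested by generalized least squares after
#' whitening with the estimated covariance. Negative eigenvalues of K are
#' clipped at zero (recorded).
#'
#' @param markers accessions x markers matrix
#' @param trait per-accession trait vector
#' @param Q structure covariates (or NULL)
#' @param K kinship matrix
#' @return list: `results` (marker, effect, p_value), `delta`
#'   (sigma2_e/sigma2_u), `clipped` eigenvalue count
#' @export
mlm_assoc <- function(markers, trait, Q = NULL, K) {
  M <- as.matrix(markers)
  n <- length(trait)
  stopifnot(nrow(K) == n, nrow(M) == n)
  K <- (K + t(K)) / 2
  eig <- eigen(K, symmetric = TRUE)
  clipped <- sum(eig$values < 0)
  d <- pmax(eig$values, 0)
  if (all(d == 0)) stop("K is not positive semi-definite", call. = FALSE)
  U <- eig$vectors
  X0 <- if (is.null(Q) || NCOL(Q) == 0) matrix(1, n, 1)
        else cbind(1, as.matrix(Q))
  yr <- crossprod(U, trait)
  X0r <- crossprod(U, X0)
  delta <- .reml_delta(as.vector(yr), X0r, d)
  w <- 1 / sqrt(d + delta)
  yw <- as.vector(yr) * w
  X0w <- X0r * w
  Mw <- crossprod(U, M) * w
  p0 <- ncol(X0w)
  qr0 <- qr(X0w)
  yres <- qr.resid(qr0, yw)
  Mres <- qr.resid(qr0, Mw)
  ss <- colSums(Mres^2)
  poly <- ss > 1e-12
  beta <- rep(NA_real_, ncol(M)); tstat <- rep(NA_real_, ncol(M))
  beta[poly] <- colSums(Mres[, poly, drop = FALSE] * yres) / ss[poly]
  df <- length(yw) - p0 - 1L
  for (j in which(poly)) {
    res <- yres - Mres[, j] * beta[j]
    se <- sqrt(sum(res^2) / df / ss[j])
    tstat[j] <- beta[j] / se
  }
  res <- data.frame(marker = colnames(M) %||% seq_len(ncol(M)),
                    effect = beta,
                    p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE))
  list(results = res, delta = delta, clipped = clipped)
}

#' Genomic-control inflation factor
#'
#' P-values are converted to 1-df chi-square quantiles;
#' `lambda = median(observed chi-square) / median(expected chi-square)`
#' (the null median, `qchisq(0.5, 1)`).
#'
#' @param p_values numeric vector in (0, 1]
#' @param thin_stride optional stride to subset approximately unlinked
#'   markers (1 = use all)
#' @return list: `lambda`, `median_observed`, `median_expected`, `chisq`
#' @export
genomic_inflation <- function(p_values, thin_stride = 1L) {
  p <- p_values[!is.na(p_values)]
  if (thin_stride > 1L) p <- p[seq(1, length(p), by = thin_stride)]
  if (length(p) < 10) stop("need at least 10 p-values", call. = FALSE)
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]", call. = FALSE)
  x2 <- qchisq(p, df = 1, lower.tail = FALSE)
  med_exp <- qchisq(0.5, df = 1)
  list(lambda = median(x2) / med_exp, median_observed = median(x2),
       median_expected = med_exp, chisq = x2)
}

#' Correct p-values by the genomic-control factor
#'
#' Each statistic's 1-df chi-square is divided by lambda and the p-value
#' recomputed. By default the correction is applied as computed; set
#' `apply_if_deflated = FALSE` to leave p-values untouched when
#' `lambda < 1`.
#'
#' @param p_values numeric vector in (0, 1]
#' @param lambda genomic-control factor (> 0)
#' @param apply_if_deflated also apply when lambda < 1
#' @return corrected p-values
#' @export
lambda_correct <- function(p_values, lambda, apply_if_deflated = TRUE) {
  if (lambda <= 0) stop("lambda must be > 0", call. = FALSE)
  if (lambda < 1 && !apply_if_deflated) return(p_values)
  x2 <- qchisq(p_values, df = 1, lower.tail = FALSE)
  pchisq(x2 / lambda, df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg significant set
#'
#' @param results data.frame with a `p_value` column (lambda-corrected
#'   upstream when applicable)
#' @param q FDR level
#' @return `results` with `q_value` and `significant` columns
#' @export
fdr_qtls <- function(results, q = 0.05) {
  stopifnot(nrow(results) >= 1)
  results$q_value <- p.adjust(results$p_value, method = "BH")
  results$significant <- !is.na(results$q_value) & results$q_value <= q
  results
}

#' One-call epiGWA scan
#'
#' Applies the MAF/conservation filter, builds Q and K as requested, runs
#' the chosen model, computes lambda, corrects the p-values and applies the
#' FDR.
#'
#' @param epistates accessions x genes binary epiallele matrix
#' @param trait per-accession trait vector
#' @param model "lm", "glm" (Q only) or "mlm" (Q + K)
#' @param n_pcs principal components for Q (glm/mlm)
#' @param maf_min,conservation_min marker filters
#' @param fdr FDR level
#' @param correct_lambda apply genomic-control correction to p-values
#' @return list: `results` (per-marker data.frame with raw/corrected p and
#'   significance), `lambda`, `model`, `n_markers`
#' @export
epigwa_scan <- function(epistates, trait, model = c("mlm", "glm", "lm"),
                        n_pcs = 3L, maf_min = 0.05,
                        conservation_min = 0.10, fdr = 0.05,
                        correct_lambda = TRUE) {
  model <- match.arg(model)
  keep <- maf_conservation_filter(epistates, maf_min, conservation_min)
  M <- epistates[, keep, drop = FALSE]
  res <- switch(model,
    lm = lm_assoc(M, trait),
    glm = glm_assoc(M, trait, pca_structure(epistates, n_pcs)),
    mlm = mlm_assoc(M, trait, pca_structure(epistates, n_pcs),
                    ibs_kinship(epistates))$results)
  infl <- genomic_inflation(res$p_value)
  res$p_raw <- res$p_value
  if (correct_lambda)
    res$p_value <- lambda_correct(res$p_value, infl$lambda)
  res <- fdr_qtls(res, q = fdr)
  list(results = res, lambda = infl$lambda, model = model,
       n_markers = ncol(M))
}
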