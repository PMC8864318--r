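#' Log counts-per-million
#'
#' \code{log2((count + prior) / (libsize + 2 * prior) * 1e6)}. Library
#' sizes default to column totals; pass [median_ratio_libsize()] output to
#' absorb composition bias from strongly asymmetric differential
#' expression.
#'
#' @param counts Non-negative count matrix (genes x samples).
#' @param prior_count Positive offset guarding zero counts (default 0.5).
#' @param lib_size Optional positive per-sample library sizes (default
#'   \code{colSums(counts)}).
#' @return Matrix of log2-CPM values with a \code{"kind"} attribute of
#'   \code{"log"}.
#' @export
log_cpm <- function(counts, prior_count = 0.5, lib_size = NULL) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- if (is.null(lib_size)) colSums(counts) else lib_size
  stopifnot(length(lib) == ncol(counts))
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  if (prior_count <= 0 && any(counts == 0)) {
    stop("prior_count must be > 0 when the matrix contains zero counts")
  }
  if (prior_count < 0) stop("prior_count must be non-negative")
  out <- log2(sweep(counts + prior_count, 2, lib + 2 * prior_count, "/") * 1e6)
  attr(out, "kind") <- "log"
  out
}

#' Median-of-ratios effective library sizes
#'
#' DESeq-style size factors: each sample's median count ratio to the
#' per-gene geometric mean, rescaled so their geometric mean equals that of
#' the raw column totals. Robust to composition bias when many genes move
#' in one direction, where raw totals would distort every null gene.
#'
#' @param counts Non-negative count matrix (genes x samples).
#' @return Positive numeric vector of effective library sizes, one per
#'   sample.
#' @export
median_ratio_libsize <- function(counts) {
  stopifnot(is.matrix(counts))
  ref <- rowMeans(log(counts + 0.5))
  sf <- apply(counts, 2, function(x) exp(stats::median(log(x + 0.5) - ref)))
  tot <- colSums(counts)
  eff <- sf / exp(mean(log(sf))) * exp(mean(log(tot)))
  stats::setNames(eff, colnames(counts))
}

#' Mean-variance precision weights
#'
#' Reimplementation of the voom idea: fit each gene's unweighted linear
#' model, regress the square-root residual standard deviation on average
#' log-CPM with lowess (one pass, span \code{span}), then predict a
#' square-root sd for every observation from its fitted log-CPM and invert
#' to a precision weight \code{sd^-4}.
#'
#' @param logcpm Log-expression matrix (genes x samples).
#' @param design Design matrix (samples x coefficients), full column rank.
#' @param span Lowess span (default 0.5).
#' @return Matrix of strictly positive finite weights, same shape as
#'   \code{logcpm}.
#' @export
voom_weights <- function(logcpm, design, span = 0.5) {
  stopifnot(is.matrix(logcpm), is.matrix(design))
  if (nrow(logcpm) < 10L) stop("need >= 10 genes to fit the mean-variance trend")
  if (nrow(design) != ncol(logcpm)) stop("design rows must match samples")
  if (nrow(design) <= ncol(design)) {
    stop("fewer samples than design columns leaves no residual df")
  }
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) stop("design matrix is rank deficient")
  fit <- stats::lm.fit(design, t(logcpm))
  fitted <- t(design %*% fit$coefficients)      # genes x samples
  resid <- logcpm - fitted
  df_res <- nrow(design) - ncol(design)
  sd_g <- sqrt(rowSums(resid^2) / df_res)
  sqrt_sd <- sqrt(sd_g)
  amean <- rowMeans(logcpm)
  lo <- stats::lowess(amean, sqrt_sd, f = span)
  trend <- stats::approxfun(lo$x, lo$y, rule = 2, ties = mean)
  pred <- trend(fitted)
  pred <- pmax(pred, 1e-6)
  w <- matrix(pred^-4, nrow = nrow(logcpm), dimnames = dimnames(logcpm))
  w
}

#' Gene-wise weighted least squares
#'
#' Fits the design to every gene by (optionally weighted) least squares and
#' records what empirical-Bayes moderation needs: coefficients, unscaled
#' standard errors, residual variance and degrees of freedom.
#'
#' @param logexpr Log-expression matrix (genes x samples).
#' @param design Design matrix (samples x coefficients), full column rank.
#' @param weights Optional positive weight matrix matching \code{logexpr}.
#' @return A list of class \code{"gene_fit"} with elements
#'   \code{coefficients}, \code{stdev_unscaled} (both genes x coefficients),
#'   \code{sigma2}, \code{df_residual}, \code{amean} and \code{design}.
#' @export
fit_lm <- function(logexpr, design, weights = NULL) {
  stopifnot(is.matrix(logexpr), is.matrix(design))
  n <- ncol(logexpr)
  p <- ncol(design)
  if (nrow(design) != n) stop("design rows must match samples")
  if (n <= p) stop("no residual degrees of freedom")
  qr_d <- qr(design)
  if (qr_d$rank < p) {
    keep <- qr_d$pivot[seq_len(qr_d$rank)]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(colnames(design)[setdiff(seq_len(p), keep)], collapse = ", "))
  }
  if (!is.null(weights)) {
    stopifnot(all(dim(weights) == dim(logexpr)))
    if (any(weights <= 0) || any(!is.finite(weights))) {
      stop("weights must be strictly positive and finite")
    }
  }
  g <- nrow(logexpr)
  coefs <- matrix(NA_real_, g, p, dimnames = list(rownames(logexpr), colnames(design)))
  stdev <- coefs
  sigma2 <- numeric(g)
  if (is.null(weights)) {
    fit <- stats::lm.fit(design, t(logexpr))
    coefs[] <- t(fit$coefficients)
    xtx_inv <- chol2inv(chol(crossprod(design)))
    stdev[] <- matrix(sqrt(diag(xtx_inv)), g, p, byrow = TRUE)
    resid <- logexpr - t(design %*% fit$coefficients)
    sigma2 <- rowSums(resid^2) / (n - p)
  } else {
    for (i in seq_len(g)) {
      w <- weights[i, ]
      w <- w / mean(w)   # s^2 invariant to uniform weight rescaling
      fit <- stats::lm.wfit(design, logexpr[i, ], w)
      coefs[i, ] <- fit$coefficients
      xtwx <- crossprod(design * sqrt(w))
      stdev[i, ] <- sqrt(diag(chol2inv(chol(xtwx))))
      sigma2[i] <- sum(w * fit$residuals^2) / (n - p)
    }
  }
  structure(list(coefficients = coefs, stdev_unscaled = stdev,
                 sigma2 = sigma2, df_residual = n - p,
                 amean = rowMeans(logexpr), design = design),
            class = "gene_fit")
}

# Newton inversion of the trigamma function (x such that trigamma(x) = y).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (-dif / x < 1e-8) break
  }
  x
}

# Moment-matching estimate of the scaled-inverse-chi^2 variance prior from
# gene-wise sample variances s2 on df degrees of freedom.
estimate_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    df_prior <- 2 * trigamma_inverse(evar)
    s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  } else {
    warning("variance-prior moment estimator non-positive; ",
            "falling back to complete pooling (df_prior = Inf)")
    df_prior <- Inf
    s2_prior <- exp(emean)
  }
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Empirical-Bayes moderated t-statistics
#'
#' Shrinks gene-wise residual variances toward a common prior estimated by
#' moment matching on \code{log(s^2)}, forms moderated t-statistics for one
#' coefficient and appends Benjamini-Hochberg FDR. Genes with non-finite
#' residual variance are dropped with a warning.
#'
#' @param fit A \code{"gene_fit"} from [fit_lm()].
#' @param coef Coefficient to test (name or index; default 2, the group
#'   indicator in an intercept + group design).
#' @return A \code{DETable} data.frame: \code{gene}, \code{logFC},
#'   \code{aveExpr}, \code{t}, \code{p}, \code{q}, \code{df_res},
#'   \code{df_prior}, ordered as the input genes.
#' @export
ebayes <- function(fit, coef = 2L) {
  stopifnot(inherits(fit, "gene_fit"))
  if (length(fit$sigma2) < 10L) stop("need >= 10 genes for moderation")
  ok <- is.finite(fit$sigma2)
  if (!all(ok)) {
    warning(sum(!ok), " gene(s) with non-finite residual variance dropped")
  }
  s2 <- fit$sigma2[ok]
  d <- fit$df_residual
  prior <- estimate_variance_prior(s2, d)
  d0 <- prior$df_prior
  s2_post <- if (is.infinite(d0)) {
    rep(prior$s2_prior, length(s2))
  } else {
    (d0 * prior$s2_prior + d * s2) / (d0 + d)
  }
  beta <- fit$coefficients[ok, coef]
  se <- sqrt(s2_post) * fit$stdev_unscaled[ok, coef]
  tstat <- beta / se
  df_total <- d0 + d
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  data.frame(
    gene = rownames(fit$coefficients)[ok],
    logFC = unname(beta),
    aveExpr = unname(fit$amean[ok]),
    t = unname(tstat),
    p = unname(pval),
    q = bh_fdr(pval),
    df_res = d,
    df_prior = d0,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up FDR
#'
#' \code{q_(i) = min_{j >= i} m p_(j) / j}, capped at 1, in input order.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of q-values, same order as \code{p}.
#' @export
bh_fdr <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  q_sorted <- pmin(1, cummin(rev(m * p[o] / seq_len(m))))
  q <- numeric(m)
  q[o] <- rev(q_sorted)
  q
}

#' Build a design matrix for the HIGH-vs-WT contrast
#'
#' Intercept, a HIGH indicator, and model-matrix-expanded covariates.
#'
#' @param labels Character vector of \code{"HIGH"}/\code{"WT"} per sample.
#' @param covariates Optional data.frame of covariates (one row per sample).
#' @return Design matrix with a \code{"groupHIGH"} column.
#' @export
build_design <- function(labels, covariates = NULL) {
  if (!all(labels %in% c("HIGH", "WT"))) stop("labels must be HIGH or WT")
  group <- factor(labels, levels = c("WT", "HIGH"))
  df <- data.frame(group = group)
  form <- "~ group"
  if (!is.null(covariates)) {
    stopifnot(nrow(covariates) == length(labels))
    df <- cbind(df, covariates)
    form <- paste("~ group +", paste(names(covariates), collapse = " + "))
  }
  mm <- stats::model.matrix(stats::as.formula(form), data = df)
  colnames(mm)[1] <- "intercept"
  mm
}

#' Differential expression between HIGH and WT samples
#'
#' Convenience wrapper chaining [log_cpm()], [voom_weights()], [fit_lm()]
#' and [ebayes()] for the group coefficient.
#'
#' @param counts Count matrix (genes x samples).
#' @param labels \code{"HIGH"}/\code{"WT"} per sample (column order).
#' @param covariates Optional covariate data.frame (one row per sample).
#' @param prior_count,span See [log_cpm()] and [voom_weights()].
#' @param normalize \code{"median_ratio"} (default, composition-robust
#'   effective library sizes) or \code{"total"} (raw column totals).
#' @return A \code{DETable} data.frame (see [ebayes()]).
#' @export
de_analysis <- function(counts, labels, covariates = NULL,
                        prior_count = 0.5, span = 0.5,
                        normalize = c("median_ratio", "total")) {
  stopifnot(ncol(counts) == length(labels))
  normalize <- match.arg(normalize)
  design <- build_design(labels, covariates)
  lib <- if (normalize == "median_ratio") median_ratio_libsize(counts)
  lc <- log_cpm(counts, prior_count, lib_size = lib)
  w <- voom_weights(lc, design, span)
  fit <- fit_lm(lc, design, w)
  ebayes(fit, coef = "groupHIGH")
}

#' Upregulated genes under the default rule
#'
#' \code{logFC > lfc} and \code{q < fdr}; both thresholds configurable.
#'
#' @param de A \code{DETable}.
#' @param lfc Log2 fold-change threshold (default 0).
#' @param fdr FDR threshold (default 0.05).
#' @return Character vector of gene ids.
#' @export
upregulated_genes <- function(de, lfc = 0, fdr = 0.05) {
  de$gene[de$logFC > lfc & de$q < fdr]
}
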