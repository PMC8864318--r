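# Per-sample signature scoring, HIGH-vs-WT group comparison, and the
# correlation structure among signature activity scores.

#' Score signatures per sample
#'
#' GSVA-type activity scores (see [gsva_scores()]) for each signature with
#' at least \code{min_size} members present in the matrix; smaller
#' signatures are skipped with a warning.
#'
#' @param logexpr Log-expression matrix (genes x samples).
#' @param sigs Named list of gene sets, or \code{"signature"} objects.
#' @param min_size Minimum members present (default 5).
#' @param tau Passed to [gsva_scores()].
#' @return Score matrix, signatures x samples.
#' @export
score_signatures <- function(logexpr, sigs, min_size = 5L, tau = 1) {
  sets <- lapply(sigs, function(s) if (inherits(s, "signature")) s$members else s)
  present <- vapply(sets, function(s) length(intersect(s, rownames(logexpr))), 1L)
  keep <- present >= min_size
  if (!all(keep)) {
    warning(sum(!keep), " signature(s) below min size ", min_size,
            " skipped: ", paste(names(sets)[!keep], collapse = ", "))
  }
  if (!any(keep)) stop("no signature reaches the minimum size")
  gsva_scores(logexpr, sets[keep], tau = tau)
}

#' Compare signature scores between HIGH and WT groups
#'
#' Two-sided Wilcoxon rank-sum test per signature (exact for small
#' tie-free samples, normal approximation with tie correction otherwise,
#' as in \code{stats::wilcox.test}).
#'
#' @param scores Score matrix (signatures x samples).
#' @param calls Output of [classify_samples()] covering every score column.
#' @return Data.frame per signature: \code{signature}, \code{median_high},
#'   \code{median_wt}, \code{statistic} (rank-sum W), \code{p},
#'   \code{direction} (\code{"up"} if the HIGH median is larger,
#'   \code{"down"} if smaller, \code{"none"} if equal).
#' @export
compare_groups <- function(scores, calls) {
  stopifnot(is.matrix(scores))
  idx <- match(colnames(scores), calls$sample)
  if (anyNA(idx)) stop("calls missing for sample(s): ",
                       paste(colnames(scores)[is.na(idx)], collapse = ", "))
  lab <- calls$label[idx]
  if (!any(lab == "HIGH")) stop("group HIGH is empty")
  if (!any(lab == "WT")) stop("group WT is empty")
  out <- lapply(rownames(scores), function(sig) {
    x <- scores[sig, lab == "HIGH"]
    y <- scores[sig, lab == "WT"]
    wt <- stats::wilcox.test(x, y, alternative = "two.sided")
    dm <- stats::median(x) - stats::median(y)
    data.frame(signature = sig,
               median_high = stats::median(x), median_wt = stats::median(y),
               statistic = unname(wt$statistic), p = wt$p.value,
               direction = if (dm > 0) "up" else if (dm < 0) "down" else "none",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Correlate two per-sample score vectors
#'
#' Pearson by default (as reported in the field as "R"), Spearman behind
#' the flag; p-value from the t transform on n - 2 df.
#'
#' @param a,b Numeric score vectors over the same samples (n >= 3, both
#'   non-constant).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return List with \code{r}, \code{p}, \code{n}, \code{method}.
#' @export
correlate_scores <- function(a, b, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(a) != length(b)) stop("score vectors must have equal length")
  if (length(a) < 3L) stop("need n >= 3 samples")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant score vector")
  }
  ct <- stats::cor.test(a, b, method = method, exact = FALSE)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(a),
       method = method)
}

#' Pairwise correlations among signature scores
#'
#' @param scores Score matrix (signatures x samples).
#' @param pairs \code{"all"} (default: every unordered pair) or a 2-column
#'   character matrix / list of length-2 vectors of signature names.
#' @param method Passed to [correlate_scores()].
#' @return Data.frame with \code{a}, \code{b}, \code{r}, \code{p}, \code{n}.
#' @export
correlation_matrix <- function(scores, pairs = "all",
                               method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.matrix(scores))
  sig <- rownames(scores)
  if (identical(pairs, "all")) {
    if (length(sig) < 2L) stop("need >= 2 signatures")
    cmb <- utils::combn(sig, 2L)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  } else if (is.matrix(pairs)) {
    pairs <- lapply(seq_len(nrow(pairs)), function(i) pairs[i, ])
  }
  out <- lapply(pairs, function(pr) {
    if (!all(pr %in% sig)) {
      stop("unknown signature name(s): ",
           paste(setdiff(pr, sig), collapse = ", "))
    }
    cc <- correlate_scores(scores[pr[1], ], scores[pr[2], ], method)
    data.frame(a = pr[1], b = pr[2], r = cc$r, p = cc$p, n = cc$n,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
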