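#' Upper-tail hypergeometric probability
#'
#' \code{P(X >= k)} for \code{X ~ Hypergeometric(N, K, n)}: drawing \code{n}
#' genes from a universe of \code{N} containing \code{K} regulon targets.
#' Terms are accumulated in log space (log-binomials + log-sum-exp) for
#' stability at large counts.
#'
#' @param k Observed overlap.
#' @param K Regulon size within the universe.
#' @param n Size of the drawn (upregulated) set.
#' @param N Universe size.
#' @return The tail probability in (0, 1].
#' @export
hypergeom_tail <- function(k, K, n, N) {
  v <- c(k = k, K = K, n = n, N = N)
  if (anyNA(v) || any(v < 0) || any(v != round(v))) {
    stop("k, K, n, N must be non-negative integers")
  }
  if (k > K || k > n || K > N || n > N) {
    stop("inconsistent counts: need k <= min(K, n) <= N")
  }
  if (k == 0) return(1)
  j <- k:min(K, n)
  logp <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  mx <- max(logp)
  min(1, exp(mx + log(sum(exp(logp - mx)))))
}

#' Master-regulator enrichment of regulons in upregulated genes
#'
#' For each transcription factor, tests whether its regulon (restricted to
#' the universe of tested genes) is over-represented in the upregulated DE
#' gene set by the one-sided hypergeometric tail, with Benjamini-Hochberg
#' FDR across factors. TFs whose regulon has no universe overlap are
#' dropped with a warning.
#'
#' @param de A \code{DETable} (see [ebayes()]); its genes define the
#'   universe unless overridden.
#' @param regulons Named list mapping TF id to target gene ids (see
#'   [read_regulons()]).
#' @param universe Optional character vector of universe genes (default:
#'   the genes in \code{de}).
#' @param lfc,fdr Upregulation rule: \code{logFC > lfc} and \code{q < fdr}
#'   (defaults 0 and 0.05).
#' @param direction \code{"up"} (default) tests the upregulated set;
#'   \code{"down"} mirrors the analysis on downregulated genes.
#' @return Data.frame with one row per tested TF: \code{tf}, \code{N},
#'   \code{K}, \code{n}, \code{k}, \code{p}, \code{q},
#'   \code{overlap_genes} (comma-separated), sorted by \code{q}, then
#'   \code{p}, then TF id.
#' @export
master_regulators <- function(de, regulons, universe = NULL,
                              lfc = 0, fdr = 0.05,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (is.null(universe)) universe <- de$gene
  hit_set <- if (direction == "up") {
    de$gene[de$logFC > lfc & de$q < fdr]
  } else {
    de$gene[de$logFC < -lfc & de$q < fdr]
  }
  if (!all(hit_set %in% universe)) stop("universe must contain the selected set")
  if (length(hit_set) == 0L) {
    warning("empty ", direction, "regulated set; no enrichment computed")
    return(data.frame(tf = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p = numeric(0),
                      q = numeric(0), overlap_genes = character(0),
                      stringsAsFactors = FALSE))
  }
  N <- length(universe)
  n <- length(hit_set)
  rows <- list()
  skipped <- character(0)
  for (tf in names(regulons)) {
    targets <- intersect(regulons[[tf]], universe)
    if (length(targets) == 0L) {
      skipped <- c(skipped, tf)
      next
    }
    overlap <- intersect(targets, hit_set)
    rows[[tf]] <- data.frame(
      tf = tf, N = N, K = length(targets), n = n, k = length(overlap),
      p = hypergeom_tail(length(overlap), length(targets), n, N),
      overlap_genes = paste(sort(overlap), collapse = ","),
      stringsAsFactors = FALSE
    )
  }
  if (length(skipped)) {
    warning(length(skipped), " TF(s) with no universe overlap dropped: ",
            paste(skipped, collapse = ", "))
  }
  if (length(rows) == 0L) {
    stop("no TF regulon overlaps the universe")
  }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$q, out$p, out$tf),
             c("tf", "N", "K", "n", "k", "p", "q", "overlap_genes")]
  rownames(out) <- NULL
  out
}
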