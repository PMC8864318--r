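# Preranked gene-set enrichment (weighted KS running sum, permutation
# NES/p/FDR) and per-sample gene-set activity scores.

# Deterministic ranking: descending statistic, ties broken by gene id.
rank_genes <- function(stats) {
  if (is.null(names(stats))) stop("ranking statistic must be named by gene")
  if (anyDuplicated(names(stats))) stop("duplicate genes in ranked list")
  if (anyNA(stats)) stop("ranking statistic contains NA")
  stats[order(-stats, names(stats))]
}

# ES from hit positions in an already-sorted ranking; O(m log m).
# The running sum rises by w/sum(w) at hits and falls by 1/(N-m) between
# them, so its extrema sit just after and just before hit positions.
es_from_positions <- function(pos, absw, n_genes) {
  m <- length(pos)
  pos <- sort.int(pos)
  w <- absw[pos]
  tw <- sum(w)
  cw <- if (tw == 0) seq_len(m) / m else cumsum(w) / tw
  if (m == n_genes) {
    return(max(cw))                       # all hits: walk peaks at 1
  }
  miss <- (pos - seq_len(m)) / (n_genes - m)
  after <- cw - miss                      # value just after each hit
  before <- c(0, cw[-m]) - miss           # value just before each hit
  up <- max(after, 0)
  down <- min(before, 0)
  # magnitude ties (within accumulation noise) resolve positive
  if (up + down >= -1e-9) up else down
}

#' Weighted running-sum enrichment score
#'
#' Walks down a ranked gene list; members of the set increment the running
#' sum by \code{|stat|^weight_exponent} (normalized to sum 1 over members),
#' non-members decrement by \code{1/(N - N_hits)}. The enrichment score is
#' the signed maximum deviation from zero.
#'
#' @param stats Named numeric vector of ranking statistics (any order; genes
#'   are sorted descending, ties broken by gene id).
#' @param set Character vector of member gene ids.
#' @param weight_exponent Non-negative exponent on \code{|stat|}
#'   (default 1); 0 gives the classic unweighted KS statistic.
#' @return List with \code{es}, the \code{running} sum profile (length N,
#'   value after each step) and the logical \code{hits} indicator, both in
#'   ranked order.
#' @export
enrichment_score <- function(stats, set, weight_exponent = 1) {
  if (weight_exponent < 0) stop("weight_exponent must be non-negative")
  ranked <- rank_genes(stats)
  n <- length(ranked)
  hits <- names(ranked) %in% set
  m <- sum(hits)
  if (m == 0L) stop("gene set has no overlap with the ranked universe")
  w <- abs(ranked)^weight_exponent
  w[!hits] <- 0
  tw <- sum(w)
  if (tw == 0) {
    w[hits] <- 1 / m
  } else {
    w <- w / tw
  }
  steps <- ifelse(hits, w, if (m == n) 0 else -1 / (n - m))
  running <- cumsum(steps)
  mx <- max(running, 0)
  mn <- min(running, 0)
  # magnitude ties (within accumulation noise) resolve positive
  es <- if (mx + mn >= -1e-9) mx else mn
  list(es = es, running = unname(running), hits = unname(hits))
}

#' Permutation significance for preranked enrichment
#'
#' Null enrichment scores come from gene-label permutation: for each set
#' size, membership is redrawn uniformly from the ranked universe. NES is
#' the observed ES divided by the mean magnitude of same-sign null scores;
#' the nominal p is the one-sided permutation tail with the +1 correction;
#' FDR follows the sign-stratified pooled-null procedure of the original
#' GSEA.
#'
#' @param stats Named numeric ranking statistic (see [enrichment_score()]).
#' @param sets Named list of gene sets; sets with no overlap with the
#'   universe are skipped with a warning.
#' @param n_perm Number of permutations per set size (>= 100, default 1000).
#' @param seed Mandatory integer seed.
#' @param weight_exponent Passed to the running sum (default 1).
#' @return Data.frame with columns \code{set}, \code{size}, \code{es},
#'   \code{nes}, \code{p}, \code{q}, \code{p_floor} (TRUE when no same-sign
#'   null existed and p sits at its 1/(1+n) floor).
#' @export
gsea_significance <- function(stats, sets, n_perm = 1000L, seed,
                              weight_exponent = 1) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  ranked <- rank_genes(stats)
  n <- length(ranked)
  absw <- abs(ranked)^weight_exponent
  universe <- names(ranked)

  members <- lapply(sets, function(s) which(universe %in% s))
  keep <- vapply(members, length, 1L) > 0L
  if (!all(keep)) {
    warning(sum(!keep), " set(s) with no overlap with the ranked universe skipped: ",
            paste(names(sets)[!keep], collapse = ", "))
  }
  members <- members[keep]
  if (length(members) == 0L) stop("no gene set overlaps the ranked universe")
  sizes <- vapply(members, length, 1L)

  null_by_size <- withr::with_seed(seed, {
    out <- list()
    for (s in sort(unique(sizes))) {
      out[[as.character(s)]] <- vapply(seq_len(n_perm), function(i) {
        es_from_positions(sample.int(n, s), absw, n)
      }, numeric(1))
    }
    out
  })

  es_obs <- vapply(members, function(pos) es_from_positions(pos, absw, n),
                   numeric(1))

  normalize <- function(es, null) {
    pos_mean <- mean(null[null >= 0])
    neg_mean <- mean(abs(null[null < 0]))
    ifelse(es >= 0, es / pos_mean, es / neg_mean)
  }

  nes <- numeric(length(es_obs))
  pval <- numeric(length(es_obs))
  floored <- logical(length(es_obs))
  null_nes_pool <- numeric(0)
  for (i in seq_along(es_obs)) {
    null <- null_by_size[[as.character(sizes[i])]]
    same <- if (es_obs[i] >= 0) null[null >= 0] else null[null < 0]
    if (length(same) == 0L) {
      pval[i] <- 1 / (1 + n_perm)
      nes[i] <- NA_real_
      floored[i] <- TRUE
    } else {
      pval[i] <- (1 + sum(abs(same) >= abs(es_obs[i]))) / (1 + length(same))
      nes[i] <- es_obs[i] / mean(abs(same))
    }
    null_nes_pool <- c(null_nes_pool, normalize(null, null))
  }

  q <- vapply(seq_along(nes), function(i) {
    s <- nes[i]
    if (is.na(s)) return(NA_real_)
    if (s >= 0) {
      denom_null <- sum(null_nes_pool >= 0)
      num <- if (denom_null) sum(null_nes_pool >= s) / denom_null else 0
      obs_pos <- sum(nes >= 0, na.rm = TRUE)
      den <- if (obs_pos) sum(nes >= s, na.rm = TRUE) / obs_pos else 1
    } else {
      denom_null <- sum(null_nes_pool < 0)
      num <- if (denom_null) sum(null_nes_pool <= s) / denom_null else 0
      obs_neg <- sum(nes < 0, na.rm = TRUE)
      den <- if (obs_neg) sum(nes <= s, na.rm = TRUE) / obs_neg else 1
    }
    min(1, num / max(den, .Machine$double.eps))
  }, numeric(1))

  data.frame(set = names(members), size = sizes, es = unname(es_obs),
             nes = unname(nes), p = unname(pval), q = unname(q),
             p_floor = unname(floored), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Per-sample gene-set activity scores
#'
#' GSVA-type scoring on log-scale expression: each gene is transformed by a
#' Gaussian-kernel cross-sample CDF (bandwidth sd/4), genes are ranked per
#' sample by the transformed value, and a weighted KS-like random walk over
#' the symmetric rank statistic \code{|N/2 - rank|} yields, per set and
#' sample, the sum of the walk's largest positive and largest negative
#' deviation (the "mx.diff" convention). Scores lie in [-1, 1].
#'
#' @param logexpr Log-scale expression matrix (genes x samples), >= 3
#'   samples.
#' @param sets Named list of gene sets; sets without any member in the
#'   matrix are skipped with a warning.
#' @param tau Exponent on the symmetric rank statistic (default 1).
#' @return Score matrix, sets x samples.
#' @export
gsva_scores <- function(logexpr, sets, tau = 1) {
  stopifnot(is.matrix(logexpr))
  if (ncol(logexpr) < 3L) stop("need >= 3 samples for the kernel CDF step")
  if (is.null(rownames(logexpr))) stop("expression matrix must have gene rownames")
  present <- lapply(sets, function(s) intersect(s, rownames(logexpr)))
  keep <- vapply(present, length, 1L) >= 1L
  if (!all(keep)) {
    warning(sum(!keep), " set(s) with no member in the matrix skipped: ",
            paste(names(sets)[!keep], collapse = ", "))
  }
  present <- present[keep]
  if (length(present) == 0L) stop("no scoreable gene set")

  n_g <- nrow(logexpr)
  n_s <- ncol(logexpr)
  bw <- pmax(apply(logexpr, 1, stats::sd) / 4, 1e-8)
  z <- kcdf_gauss(logexpr, bw)
  # per-sample dense ranks of the transformed values, 1 = highest;
  # ties broken by row order for determinism
  ranks <- apply(z, 2, function(col) {
    r <- integer(n_g)
    r[order(-col, seq_len(n_g))] <- seq_len(n_g)
    r
  })
  symstat <- abs(n_g / 2 - ranks)         # genes x samples

  scores <- matrix(NA_real_, length(present), n_s,
                   dimnames = list(names(present), colnames(logexpr)))
  for (si in seq_along(present)) {
    idx <- match(present[[si]], rownames(logexpr))
    m <- length(idx)
    for (j in seq_len(n_s)) {
      pos <- sort.int(ranks[idx, j])
      w <- symstat[idx, j][order(ranks[idx, j])]^tau
      tw <- sum(w)
      if (tw == 0) w[] <- 1 / m else w <- w / tw
      cw <- cumsum(w)
      if (m == n_g) {
        scores[si, j] <- max(cw)
        next
      }
      miss <- (pos - seq_len(m)) / (n_g - m)
      after <- cw - miss
      before <- c(0, cw[-m]) - miss
      scores[si, j] <- max(0, max(after)) + min(0, min(before))
    }
  }
  scores
}
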