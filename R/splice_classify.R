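#' Spliced/full-length isoform ratio
#'
#' Ratio of the exon-10-deleted transcript abundance to the full-length
#' abundance, with an optional pseudocount guarding degenerate denominators.
#' With pseudocount 0: \code{del > 0, FL = 0} gives \code{Inf}; \code{0/0}
#' gives 0 with a warning.
#'
#' @param full_length Non-negative full-length abundance(s).
#' @param del_exon10 Non-negative exon-10-deleted abundance(s).
#' @param pseudocount Non-negative value added to numerator and denominator
#'   (default 0).
#' @return Numeric vector of ratios.
#' @export
compute_ratio <- function(full_length, del_exon10, pseudocount = 0) {
  if (length(pseudocount) != 1L || is.na(pseudocount) || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number")
  }
  if (any(full_length < 0) || any(del_exon10 < 0)) {
    stop("isoform abundances must be non-negative")
  }
  num <- del_exon10 + pseudocount
  den <- full_length + pseudocount
  ratio <- num / den
  zz <- den == 0 & num == 0
  if (any(zz)) {
    warning(sum(zz), " sample(s) with 0/0 isoform abundances; ratio set to 0")
    ratio[zz] <- 0
  }
  ratio
}

#' Classify samples by isoform ratio
#'
#' Labels a sample HIGH when its spliced/full-length ratio is at or above the
#' cutoff (boundary rule: \code{>=}), otherwise WT. The default cutoff 2.6 is
#' the published purity-adjusted threshold for samples of >85% tumor purity;
#' no additional per-sample purity correction is applied.
#'
#' @param transcripts Data.frame with columns \code{sample},
#'   \code{full_length}, \code{del_exon10} (see [read_transcripts()]), or a
#'   data.frame already carrying a \code{ratio} column.
#' @param cutoff Positive classification threshold (default 2.6).
#' @param pseudocount Passed to [compute_ratio()].
#' @return Data.frame with columns \code{sample}, \code{ratio}, \code{label}
#'   (\code{"HIGH"}/\code{"WT"}) and \code{cutoff}.
#' @export
classify_samples <- function(transcripts, cutoff = 2.6, pseudocount = 0) {
  if (length(cutoff) != 1L || is.na(cutoff) || cutoff <= 0) {
    stop("cutoff must be a single positive number")
  }
  if (nrow(transcripts) == 0L) {
    return(data.frame(sample = character(0), ratio = numeric(0),
                      label = character(0), cutoff = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ratio <- if ("ratio" %in% names(transcripts)) {
    transcripts$ratio
  } else {
    compute_ratio(transcripts$full_length, transcripts$del_exon10, pseudocount)
  }
  data.frame(
    sample = as.character(transcripts$sample),
    ratio = ratio,
    label = ifelse(ratio >= cutoff, "HIGH", "WT"),
    cutoff = cutoff,
    stringsAsFactors = FALSE
  )
}

#' HIGH-variant prevalence with exact binomial confidence intervals
#'
#' Fraction of HIGH calls overall or per stratum (e.g. disease setting), with
#' the exact (Clopper-Pearson) 95% interval.
#'
#' @param calls Output of [classify_samples()].
#' @param strata Optional character/factor vector aligned with \code{calls}
#'   giving the stratum of each sample (e.g. metadata \code{setting}).
#' @param conf_level Confidence level (default 0.95).
#' @return Data.frame with columns \code{stratum}, \code{n_high}, \code{n},
#'   \code{prevalence}, \code{ci_lower}, \code{ci_upper}.
#' @export
prevalence <- function(calls, strata = NULL, conf_level = 0.95) {
  if (nrow(calls) == 0L) stop("no calls supplied")
  if (is.null(strata)) {
    strata <- rep("all", nrow(calls))
  } else if (length(strata) != nrow(calls)) {
    stop("strata must align with calls (one value per sample)")
  }
  strata <- as.character(strata)
  if (anyNA(strata)) stop("strata contain missing values")
  out <- lapply(sort(unique(strata)), function(s) {
    lab <- calls$label[strata == s]
    k <- sum(lab == "HIGH")
    n <- length(lab)
    ci <- stats::binom.test(k, n, conf.level = conf_level)$conf.int
    data.frame(stratum = s, n_high = k, n = n, prevalence = k / n,
               ci_lower = ci[1], ci_upper = ci[2], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
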