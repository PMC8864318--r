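# Cross-cohort consensus: intersect top-K activated pathways and
# significant regulators; build consensus regulon signatures from targets
# upregulated in every dataset.

#' Top-K pathway consensus across cohorts
#'
#' From each cohort's enrichment table, takes the K most activated sets
#' (highest positive NES; ties broken by q then set name) and intersects
#' their names across cohorts.
#'
#' @param tables Named list (>= 2) of enrichment data.frames as produced by
#'   [gsea_significance()].
#' @param k Number of top sets per cohort (default 50).
#' @return List of class \code{"consensus_report"} part: \code{top_k}
#'   (per-cohort character vectors), \code{intersection}, \code{k}.
#' @export
top_k_pathway_consensus <- function(tables, k = 50L) {
  if (k < 1L) stop("k must be >= 1")
  if (length(tables) < 2L) stop("need >= 2 enrichment tables")
  if (is.null(names(tables))) names(tables) <- paste0("dataset", seq_along(tables))
  top <- lapply(tables, function(tab) {
    act <- tab[!is.na(tab$nes) & tab$nes > 0, , drop = FALSE]
    act <- act[order(-act$nes, act$q, act$set), , drop = FALSE]
    utils::head(act$set, k)
  })
  list(top_k = top, intersection = sort(Reduce(intersect, top)), k = k)
}

#' Consensus significant regulators across cohorts
#'
#' Intersects the TFs significant at the FDR threshold in every
#' master-regulator table.
#'
#' @param tables Named list (>= 2) of [master_regulators()] outputs.
#' @param fdr Significance threshold on q (default 0.05).
#' @return List with per-cohort \code{significant} TF vectors and their
#'   \code{intersection}.
#' @export
consensus_regulators <- function(tables, fdr = 0.05) {
  if (length(tables) < 2L) stop("need >= 2 master-regulator tables")
  if (is.null(names(tables))) names(tables) <- paste0("dataset", seq_along(tables))
  sig <- lapply(tables, function(tab) tab$tf[tab$q < fdr])
  list(significant = sig, intersection = sort(Reduce(intersect, sig)),
       fdr = fdr)
}

#' Build a consensus regulon signature
#'
#' Members are the TF's direct targets that are upregulated (per the stated
#' rule) in EVERY supplied DE table — a target upregulated in all but one
#' cohort is excluded. Per-dataset evidence (logFC, q) is recorded for each
#' member.
#'
#' @param tf TF identifier, present in \code{regulons}.
#' @param de_tables Named list of \code{DETable}s, one per cohort.
#' @param regulons Named list TF -> targets.
#' @param lfc,fdr Upregulation rule (defaults 0, 0.05).
#' @param min_size Minimum signature size (default 5); smaller signatures
#'   are rejected with a diagnostic error.
#' @return List of class \code{"signature"}: \code{name}, \code{members}
#'   (sorted), \code{evidence} (data.frame gene x dataset with logFC and q
#'   columns).
#' @export
build_signature <- function(tf, de_tables, regulons, lfc = 0, fdr = 0.05,
                            min_size = 5L) {
  if (!tf %in% names(regulons)) stop("unknown TF: ", tf)
  if (length(de_tables) < 1L) stop("need >= 1 DE table")
  if (is.null(names(de_tables))) {
    names(de_tables) <- paste0("dataset", seq_along(de_tables))
  }
  targets <- regulons[[tf]]
  up_per_ds <- lapply(de_tables, upregulated_genes, lfc = lfc, fdr = fdr)
  members <- sort(intersect(targets, Reduce(intersect, up_per_ds)))
  if (length(members) < min_size) {
    stop("signature for ", tf, " rejected: only ", length(members),
         " common upregulated target(s) across ", length(de_tables),
         " dataset(s) (minimum ", min_size, ")")
  }
  evidence <- do.call(cbind, lapply(names(de_tables), function(ds) {
    tab <- de_tables[[ds]]
    i <- match(members, tab$gene)
    out <- data.frame(tab$logFC[i], tab$q[i])
    names(out) <- paste0(ds, c(".logFC", ".q"))
    out
  }))
  rownames(evidence) <- members
  structure(list(name = tf, members = members, evidence = evidence),
            class = "signature")
}

#' Genes shared between two signatures
#'
#' @param a,b \code{"signature"} objects or plain character vectors.
#' @return Sorted character vector of shared genes.
#' @export
signature_overlap <- function(a, b) {
  ga <- if (inherits(a, "signature")) a$members else a
  gb <- if (inherits(b, "signature")) b$members else b
  sort(intersect(ga, gb))
}

#' Full cross-cohort consensus report
#'
#' Combines the pathway and regulator consensus with provenance.
#'
#' @param gsea_tables Named list of enrichment tables (>= 2).
#' @param mra_tables Named list of master-regulator tables (>= 2), same
#'   cohorts.
#' @param k Top-K for the pathway consensus (default 50).
#' @param fdr Regulator significance threshold (default 0.05).
#' @return List of class \code{"consensus_report"} with \code{pathways},
#'   \code{regulators} and \code{provenance}.
#' @export
consensus_report <- function(gsea_tables, mra_tables, k = 50L, fdr = 0.05) {
  pw <- top_k_pathway_consensus(gsea_tables, k)
  tf <- consensus_regulators(mra_tables, fdr)
  structure(list(
    pathways = pw,
    regulators = tf,
    provenance = list(datasets = names(gsea_tables), k = k, fdr = fdr)
  ), class = "consensus_report")
}
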