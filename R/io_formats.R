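#' Read a GMT gene-set file
#'
#' Parses the tab-separated GMT dialect used by MSigDB: one gene set per
#' line, fields \code{name}, \code{description} (may be empty but must be
#' present), then one or more member genes. Gene identifiers are opaque,
#' case-sensitive strings; no symbol mapping is performed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (one per set, member order
#'   preserved, duplicates within a line dropped with a warning), with a
#'   \code{"descriptions"} attribute carrying the second field of each line.
#' @export
read_gmt <- function(path) {
  stopifnot(is.character(path), length(path) == 1L)
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected >= 3 tab-separated fields, got ",
           length(fields))
    }
    name <- fields[[1]]
    if (name %in% names(sets)) stop("duplicate gene-set name in GMT: ", name)
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("GMT line ", i, " (", name, "): ",
              sum(duplicated(members)), " duplicate member(s) dropped")
      members <- unique(members)
    }
    if (length(members) == 0L) stop("GMT line ", i, " (", name, "): no members")
    sets[[name]] <- members
    descs[[name]] <- fields[[2]]
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' Write a gene-set collection to GMT
#'
#' @param sets Named list of character vectors; an optional
#'   \code{"descriptions"} attribute supplies the second field (empty
#'   otherwise).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(is.list(sets))
  if (length(sets) > 0 && is.null(names(sets))) stop("gene sets must be named")
  descs <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else ""
    paste(c(nm, d, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a regulon database (TF -> target edge list)
#'
#' Expects a TSV with a header and columns \code{tf}, \code{target} and
#' optionally \code{mode} (+1 / -1 / unknown). Duplicate edges collapse;
#' targets are deduplicated per TF.
#'
#' @param path Path to the edge-list TSV.
#' @return Named list mapping TF id to a character vector of targets, with a
#'   \code{"modes"} attribute (named list of per-target modes) when a mode
#'   column is present.
#' @export
read_regulons <- function(path) {
  if (!file.exists(path)) stop("regulon file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  required <- c("tf", "target")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("regulon file missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (any(!nzchar(df$tf)) || any(!nzchar(df$target))) {
    stop("regulon file contains empty tf or target values")
  }
  has_mode <- "mode" %in% names(df)
  key <- paste(df$tf, df$target, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) df <- df[!dup, , drop = FALSE]
  edges <- split(df$target, df$tf)
  edges <- lapply(edges, unique)
  if (any(vapply(edges, length, 1L) == 0L)) stop("TF with empty target set")
  if (has_mode) {
    modes <- split(df$mode, df$tf)
    attr(edges, "modes") <- modes
  }
  edges
}

#' Write a regulon database as an edge-list TSV
#'
#' @param regulons Named list of target character vectors.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_regulons <- function(regulons, path) {
  stopifnot(is.list(regulons), !is.null(names(regulons)))
  df <- data.frame(
    tf = rep(names(regulons), lengths(regulons)),
    target = unlist(regulons, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (genes x samples TSV)
#'
#' First column is the gene identifier (header cell \code{"gene"}), remaining
#' columns are samples. Missing cells are an error: the generator never emits
#' them and downstream arithmetic must stay total.
#'
#' @param path Path to the TSV.
#' @param kind \code{"counts"} (non-negative integers) or \code{"log"}
#'   (real log-expression).
#' @return Numeric matrix with gene rownames, sample colnames and a
#'   \code{"kind"} attribute.
#' @export
read_expression <- function(path, kind = c("counts", "log")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(df) < 2L) stop("expression TSV needs a gene column plus >=1 sample")
  genes <- as.character(df[[1]])
  if (anyDuplicated(genes)) {
    stop("duplicate gene identifier(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  }
  samples <- colnames(df)[-1]
  if (anyDuplicated(samples)) stop("duplicate sample identifier(s)")
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- genes
  if (anyNA(mat)) stop("missing expression values are not permitted")
  if (kind == "counts") {
    if (any(mat < 0)) stop("negative count in matrix flagged as counts")
    if (any(mat != round(mat))) stop("non-integer count in matrix flagged as counts")
  }
  attr(mat, "kind") <- kind
  mat
}

#' Write an expression matrix as TSV
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns \code{sample}, \code{cohort}, \code{setting}
#' (NDMM | RRMM), \code{purity} (fraction in [0,1]); any further columns are
#' carried as covariates.
#'
#' @param path Path to the metadata TSV.
#' @return A data.frame, one row per sample.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("metadata file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("sample", "cohort", "setting", "purity")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("metadata missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample id in metadata")
  if (any(!df$setting %in% c("NDMM", "RRMM"))) {
    stop("setting must be NDMM or RRMM")
  }
  if (any(is.na(df$purity)) || any(df$purity < 0 | df$purity > 1)) {
    stop("purity must lie in [0, 1]")
  }
  df
}

#' Write sample metadata
#' @param meta Metadata data.frame (see [read_metadata()]).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read two-isoform transcript quantification for the CRBN locus
#'
#' TSV with columns \code{sample}, \code{full_length}, \code{del_exon10}
#' (non-negative TPM-like abundances) and \code{purity}.
#'
#' @param path Path to the transcript TSV.
#' @return A data.frame, one row per sample.
#' @export
read_transcripts <- function(path) {
  if (!file.exists(path)) stop("transcript file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  required <- c("sample", "full_length", "del_exon10", "purity")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("transcript file missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$sample)) stop("duplicate sample id in transcript file")
  if (any(df$full_length < 0) || any(df$del_exon10 < 0)) {
    stop("isoform abundances must be non-negative")
  }
  if (any(df$purity < 0 | df$purity > 1)) stop("purity must lie in [0, 1]")
  df
}

#' Write transcript quantification
#' @param tq Transcript data.frame (see [read_transcripts()]).
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_transcripts <- function(tq, path) {
  utils::write.table(tq, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
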