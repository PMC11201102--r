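#' Multi-omics study container
#'
#' An `omics_study` bundles the V omics data matrices of one study. Each
#' matrix is genes-by-samples (G x Sk) with gene identifiers as row names
#' and sample identifiers as column names; all V matrices must share the
#' same genes and the same samples in the same order (samples are matched
#' across omics within a study). Missing values are not allowed.
#'
#' @param omics named list of V numeric G x Sk matrices (names are the
#'   omics-type labels, e.g. `c("rna", "meth", "prot")`)
#' @param study_id character scalar identifying the study
#' @return an object of class `omics_study` with fields `omics`,
#'   `study_id`, `gene_ids`, `sample_ids`, `sample_size` (Sk) and
#'   `n_omics` (V).
#' @export
omics_study <- function(omics, study_id = "study1") {
  stopifnot(is.list(omics), length(omics) >= 1)
  if (is.null(names(omics)) || anyNA(names(omics)) || any(names(omics) == ""))
    names(omics) <- paste0("omics", seq_along(omics))
  ref <- omics[[1]]
  if (!is.matrix(ref) || !is.numeric(ref))
    stop("each omics element must be a numeric matrix")
  if (is.null(rownames(ref)) || is.null(colnames(ref)))
    stop("omics matrices need gene row names and sample column names")
  for (v in seq_along(omics)) {
    m <- omics[[v]]
    if (!is.matrix(m) || !is.numeric(m))
      stop("each omics element must be a numeric matrix")
    if (!identical(dim(m), dim(ref)))
      stop("all omics matrices must have identical dimensions")
    if (!identical(rownames(m), rownames(ref)))
      stop("all omics matrices must share identical gene ids in identical order")
    if (!identical(colnames(m), colnames(ref)))
      stop("all omics matrices must share identical sample ids in identical order")
    if (anyNA(m))
      stop("omics matrix ", names(omics)[v], " contains missing values")
  }
  structure(
    list(omics = omics, study_id = as.character(study_id),
         gene_ids = rownames(ref), sample_ids = colnames(ref),
         sample_size = ncol(ref), n_omics = length(omics)),
    class = "omics_study")
}

#' @export
print.omics_study <- function(x, ...) {
  cat("Multi-omics study '", x$study_id, "': ",
      length(x$gene_ids), " genes x ", x$sample_size, " samples, V = ",
      x$n_omics, " omics (", paste(names(x$omics), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Load one study from delimited files
#'
#' Reads one file per omics type. Each file is a labeled numeric matrix:
#' first column gene identifier, header row sample identifiers. Gene rows
#' containing missing values are dropped (with a warning), then genes and
#' samples are restricted to those present in every file; genes are put in
#' sorted order so that downstream pair indexing is deterministic.
#'
#' @param paths character vector of V file paths, optionally named with
#'   omics-type labels
#' @param format "tsv" (default) or "csv"
#' @param study_id study identifier
#' @return an [omics_study]
#' @export
load_study <- function(paths, format = c("tsv", "csv"), study_id = "study1") {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  stopifnot(length(paths) >= 1)
  nm <- names(paths)
  if (is.null(nm)) nm <- paste0("omics", seq_along(paths))
  mats <- vector("list", length(paths))
  names(mats) <- nm
  for (v in seq_along(paths)) {
    df <- utils::read.table(paths[[v]], header = TRUE, sep = sep,
                            row.names = 1, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df)
    if (!is.numeric(m))
      stop("file '", paths[[v]], "' contains non-numeric cells")
    drop <- rownames(m)[apply(is.na(m), 1, any)]
    if (length(drop)) {
      warning("dropping ", length(drop), " gene(s) with missing values in '",
              paths[[v]], "': ", paste(drop, collapse = ", "))
      m <- m[!rownames(m) %in% drop, , drop = FALSE]
    }
    if (anyDuplicated(rownames(m)))
      stop("duplicated gene ids in '", paths[[v]], "'")
    mats[[v]] <- m
  }
  genes <- sort(Reduce(intersect, lapply(mats, rownames)))
  if (length(genes) == 0) stop("no genes common to all omics files")
  samples <- Reduce(intersect, lapply(mats, colnames))
  if (length(samples) == 0) stop("no samples common to all omics files")
  mats <- lapply(mats, function(m) m[genes, samples, drop = FALSE])
  omics_study(mats, study_id = study_id)
}

#' Per-gene sample-by-omics matrix
#'
#' Extracts the Sk x V gene-specific matrix of one gene: row i, column j is
#' the j-th omics measurement of that gene in sample i. This is the unit on
#' which the pairwise correlation measures (CC, MOC, MSOC) operate.
#'
#' @param study an [omics_study]
#' @param gene_id gene identifier present in the study
#' @return numeric Sk x V matrix (samples x omics types)
#' @export
gene_matrix <- function(study, gene_id) {
  stopifnot(inherits(study, "omics_study"))
  if (!gene_id %in% study$gene_ids)
    stop("gene '", gene_id, "' not present in study '", study$study_id, "'")
  m <- vapply(study$omics, function(M) M[gene_id, ],
              numeric(study$sample_size))
  m <- matrix(m, nrow = study$sample_size, ncol = study$n_omics,
              dimnames = list(study$sample_ids, names(study$omics)))
  m
}

#' Common gene list across studies
#'
#' @param studies list of [omics_study] objects
#' @return sorted character vector of genes present in every study
#' @export
intersect_genes <- function(studies) {
  stopifnot(is.list(studies), length(studies) >= 1)
  genes <- sort(Reduce(intersect, lapply(studies, `[[`, "gene_ids")))
  if (length(genes) == 0) stop("no genes common to all studies")
  genes
}

#' Restrict a study to a gene subset
#'
#' @param study an [omics_study]
#' @param genes character vector of gene ids (kept in the given order)
#' @return an [omics_study] containing only `genes`
#' @export
subset_genes <- function(study, genes) {
  stopifnot(inherits(study, "omics_study"))
  if (!all(genes %in% study$gene_ids))
    stop("some requested genes are absent from study '", study$study_id, "'")
  omics_study(lapply(study$omics, function(M) M[genes, , drop = FALSE]),
              study_id = study$study_id)
}
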