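#' Validate (and lightly repair) an expression matrix
#'
#' An expression matrix is a plain numeric matrix, genes in rows and samples
#' in columns, with unique non-empty dimnames, all values finite and
#' non-negative, and at least one gene and one sample. Duplicate gene rows
#' are collapsed by taking the per-cell maximum (a conservative choice for a
#' "detected expression" signature); duplicate sample ids are an error.
#' Missing values are an error: callers must impute or filter first.
#'
#' @param values numeric matrix (genes x samples) with rownames (gene ids)
#'   and colnames (sample ids).
#' @param drop_zero_genes drop genes whose row is all zero. Default keeps
#'   them: the score is rank-based and all-zero rows only shift midranks
#'   uniformly.
#' @return the validated numeric matrix (possibly with duplicate gene rows
#'   collapsed).
#' @export
as_expression_matrix <- function(values, drop_zero_genes = FALSE) {
  if (is.data.frame(values)) values <- as.matrix(values)
  if (!is.matrix(values) || !is.numeric(values))
    stop("expression input must be a numeric matrix (genes x samples)")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("expression matrix needs at least 1 gene and 1 sample")
  gid <- rownames(values)
  sid <- colnames(values)
  if (is.null(gid) || any(!nzchar(gid)))
    stop("expression matrix must have non-empty gene ids as rownames")
  if (is.null(sid) || any(!nzchar(sid)))
    stop("expression matrix must have non-empty sample ids as colnames")
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (anyNA(values))
    stop("expression matrix contains missing values; impute or filter first")
  if (any(!is.finite(values)))
    stop("expression matrix contains non-finite values")
  if (any(values < 0))
    stop("expression values must be non-negative")
  if (anyDuplicated(gid)) {
    dups <- unique(gid[duplicated(gid)])
    message("collapsing ", length(dups), " duplicated gene id(s) by maximum: ",
            paste(utils::head(dups, 5L), collapse = ", "),
            if (length(dups) > 5L) ", ..." else "")
    # rowsum-style collapse by max, preserving first-occurrence order
    keep <- !duplicated(gid)
    out <- values[keep, , drop = FALSE]
    idx <- match(gid, gid[keep])
    for (d in dups) {
      rows <- which(gid == d)
      out[match(d, gid[keep]), ] <- apply(values[rows, , drop = FALSE], 2L, max)
    }
    values <- out
  }
  if (drop_zero_genes) {
    nz <- rowSums(values) > 0
    if (!any(nz)) stop("all genes are zero; nothing left after --drop-zero-genes")
    values <- values[nz, , drop = FALSE]
  }
  values
}

#' Read an expression matrix from disk
#'
#' Dense matrices are TSV/CSV with genes in rows, the first column holding
#' gene identifiers and the header row holding sample identifiers. Sparse
#' matrices are MatrixMarket coordinate files (`format = "mtx"`) with
#' one-per-line gene and sample (cell) label files.
#'
#' @param path path to the matrix file.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"`, or `"mtx"`.
#' @param genes_file,samples_file label files for `format = "mtx"`; default
#'   `<path minus .mtx>.genes.txt` / `.samples.txt`.
#' @param drop_zero_genes see [as_expression_matrix()].
#' @return validated numeric matrix (genes x samples).
#' @export
read_expression <- function(path, format = c("auto", "tsv", "csv", "mtx"),
                            genes_file = NULL, samples_file = NULL,
                            drop_zero_genes = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", mtx = "mtx", "tsv")
  }
  if (format == "mtx") {
    stem <- sub("\\.mtx$", "", path)
    if (is.null(genes_file)) genes_file <- paste0(stem, ".genes.txt")
    if (is.null(samples_file)) samples_file <- paste0(stem, ".samples.txt")
    if (!file.exists(genes_file)) stop("gene label file not found: ", genes_file)
    if (!file.exists(samples_file)) stop("sample label file not found: ", samples_file)
    m <- as.matrix(Matrix::readMM(path))
    gid <- readLines(genes_file)
    sid <- readLines(samples_file)
    if (length(gid) != nrow(m))
      stop("gene label file has ", length(gid), " lines but matrix has ", nrow(m), " rows")
    if (length(sid) != ncol(m))
      stop("sample label file has ", length(sid), " lines but matrix has ", ncol(m), " columns")
    dimnames(m) <- list(gid, sid)
    return(as_expression_matrix(m, drop_zero_genes = drop_zero_genes))
  }
  sep <- if (format == "csv") "," else "\t"
  dt <- tryCatch(
    data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE),
    error = function(e) stop("failed to parse ", path, ": ", conditionMessage(e)))
  if (ncol(dt) < 2L) stop("malformed matrix file (need gene id column + >=1 sample): ", path)
  gid <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(dt[-1L], is.numeric, logical(1L)))[1L] + 1L
    stop("non-numeric values in column ", colnames(dt)[bad], " of ", path)
  }
  rownames(m) <- gid
  as_expression_matrix(m, drop_zero_genes = drop_zero_genes)
}

#' Write an expression matrix as TSV (genes x samples)
#' @param expr expression matrix.
#' @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Within-sample rank transform
#'
#' Ranks every gene within each sample, ascending with expression (lowest
#' expression gets rank 1) and midranks (average) for ties, so the transform
#' is deterministic on zero-inflated single-cell data. Per sample the ranks
#' sum to N_g(N_g+1)/2.
#'
#' @param expr validated expression matrix (genes x samples).
#' @return matrix of within-sample ranks with the same dimnames.
#' @export
rank_within_sample <- function(expr) {
  expr <- as_expression_matrix(expr)
  r <- apply(expr, 2L, rank, ties.method = "average")
  if (!is.matrix(r)) r <- matrix(r, nrow = nrow(expr), dimnames = dimnames(expr))
  r
}

#' Read a gene list (one id per line, or first column of a TSV)
#' @param path file path.
#' @return character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path)
  x <- trimws(vapply(strsplit(x, "\t", fixed = TRUE),
                     function(f) if (length(f)) f[[1L]] else "", character(1L)))
  x <- x[nzchar(x)]
  if (!length(x)) stop("empty gene list: ", path)
  unique(x)
}

#' Read a gene weight vector
#'
#' Accepts a two-column TSV/CSV (gene, weight; header optional) or a JSON
#' object mapping gene ids to weights. Weights are signed reals; duplicate
#' genes and non-finite weights are errors.
#'
#' @param path file path.
#' @return named numeric vector of weights.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (tolower(tools::file_ext(path)) == "json") {
    w <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    dt <- data.table::fread(path, header = "auto", data.table = FALSE)
    if (ncol(dt) < 2L) stop("weight file needs two columns (gene, weight): ", path)
    w <- as.numeric(dt[[2L]])
    names(w) <- as.character(dt[[1L]])
  }
  if (anyDuplicated(names(w)))
    stop("duplicate gene ids in weight vector: ", path)
  if (anyNA(w) || any(!is.finite(w)))
    stop("weights must all be finite: ", path)
  w
}
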