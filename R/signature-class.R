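#' Construct a gene signature
#'
#' A signature has a constituent component (the TERT-role and, optionally,
#' TERC-role gene: the subunits that are functionally deterministic of the
#' enzyme) and a marker component (genes co-expressed with the anchor that
#' carry the bulk of the score). The two sets must be disjoint and the
#' marker set non-empty.
#'
#' @param constituent character vector of length 1 or 2, ordered
#'   (TERT-role, TERC-role).
#' @param markers character vector of marker gene ids.
#' @param name free-text name/provenance.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(constituent, markers, name = "unnamed") {
  constituent <- as.character(constituent)
  markers <- as.character(markers)
  if (length(constituent) < 1L || length(constituent) > 2L)
    stop("constituent must hold 1 or 2 gene ids (TERT-role, TERC-role)")
  if (!length(markers)) stop("marker gene list must be non-empty")
  if (anyDuplicated(c(constituent, markers)))
    stop("constituent and marker sets must be disjoint and duplicate-free")
  structure(list(constituent = constituent, markers = markers,
                 name = as.character(name)[1L]),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("Gene signature:", x$name, "\n")
  cat("  constituent (", length(x$constituent), "): ",
      paste(x$constituent, collapse = ", "), "\n", sep = "")
  cat("  markers     (", length(x$markers), "): ",
      paste(x$markers, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' All genes of a signature (constituent first)
#' @param sig a `gene_signature`.
#' @return character vector.
#' @export
signature_genes <- function(sig) c(sig$constituent, sig$markers)

#' Read a signature from JSON or YAML
#'
#' The file must contain keys `constituent` (1-2 gene ids) and `markers`
#' (list of ids); `name` is optional. YAML requires the `yaml` package.
#'
#' @param path file path.
#' @return a `gene_signature`.
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML signatures requires the 'yaml' package; use JSON")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (is.null(cfg$constituent) || is.null(cfg$markers))
    stop("signature file must define 'constituent' and 'markers': ", path)
  gene_signature(cfg$constituent, cfg$markers,
                 name = if (is.null(cfg$name)) basename(path) else cfg$name)
}

#' Write a signature to JSON
#' @param sig a `gene_signature`.
#' @param path output path.
#' @export
write_signature <- function(sig, path) {
  jsonlite::write_json(
    list(name = sig$name, constituent = sig$constituent, markers = sig$markers),
    path, auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' The shipped default 13-gene telomerase signature
#'
#' Two constituent genes (TERT, TERC) and 11 markers. Only three marker
#' identities (LIN9, HELLS, POLE2) are attested in accessible text; the
#' remaining eight marker slots carry synthetic placeholder ids
#' (SYNM04..SYNM11) and are clearly labelled as such. Replace them with the
#' published membership before scoring real data; the scoring engine itself
#' is signature-agnostic and renormalises over the genes actually present.
#'
#' @return a `gene_signature` with 13 genes (2 constituent + 11 marker).
#' @export
default_signature <- function() {
  read_signature(system.file("extdata", "signature_13gene_synthetic.json",
                             package = "extendscore", mustWork = TRUE))
}
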