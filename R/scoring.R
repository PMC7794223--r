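#' Constituent component score
#'
#' Per sample, the maximum of the within-sample ranks of the constituent
#' genes that are present in the rank matrix (if only one is present, its
#' rank). With ascending ranks a larger value means the better-expressed of
#' the two core subunits sits higher in the transcriptome.
#'
#' @param ranks within-sample rank matrix (see [rank_within_sample()]).
#' @param sig a `gene_signature`.
#' @return named numeric vector (one value per sample), or `NULL` when both
#'   constituent genes are absent (the "constituent-absent" condition that
#'   [extend_score()] resolves by marker-only scoring).
#' @export
constituent_score <- function(ranks, sig) {
  present <- intersect(sig$constituent, rownames(ranks))
  if (!length(present)) return(NULL)
  sub <- ranks[present, , drop = FALSE]
  v <- apply(sub, 2L, max)
  names(v) <- colnames(ranks)
  v
}

#' Marker component score
#'
#' Per sample, the sum of within-sample ranks of the marker genes present in
#' the rank matrix (a single-sample rank-sum statistic).
#'
#' @inheritParams constituent_score
#' @return named numeric vector with attribute `n_present` (count of marker
#'   genes found). Zero present markers is a hard error: the signature is
#'   unusable.
#' @export
marker_score <- function(ranks, sig) {
  present <- intersect(sig$markers, rownames(ranks))
  if (!length(present))
    stop("none of the ", length(sig$markers),
         " marker genes are present in the matrix; signature unusable")
  v <- colSums(ranks[present, , drop = FALSE])
  names(v) <- colnames(ranks)
  attr(v, "n_present") <- length(present)
  v
}

#' Adjustment factor delta
#'
#' delta = 1 / (1 - rho), where rho is the Spearman correlation between the
#' constituent and marker component vectors, computed once per dataset. When
#' the two components track each other the constituent genes are trusted and
#' up-weighted; a poor correlation (e.g. from TERT splice isoforms)
#' down-weights them. delta is clamped to [0.5, 20] (the analytic value at
#' rho = -1 and the value at rho = 0.95) for numerical stability. Fewer than
#' 3 samples or a constant component vector yields delta = 1 with a warning.
#'
#' @param v_const,v_marker per-sample component score vectors.
#' @return scalar delta in [0.5, 20].
#' @export
adjustment_factor <- function(v_const, v_marker) {
  if (length(v_const) != length(v_marker))
    stop("component vectors differ in length")
  if (length(v_const) < 3L) {
    warning("fewer than 3 samples; delta defaults to 1")
    return(1)
  }
  if (stats::sd(v_const) == 0 || stats::sd(v_marker) == 0) {
    warning("constant component vector; delta defaults to 1")
    return(1)
  }
  rho <- stats::cor(v_const, v_marker, method = "spearman")
  delta <- if (rho >= 1) Inf else 1 / (1 - rho)
  min(max(delta, 0.5), 20)
}

#' EXTEND score per sample
#'
#' Two-component rank-sum score of a gene signature:
#' `ES_i = (delta * V_const_i + V_marker_i) / (N_g * N_m)`, where `V_const`
#' is the max within-sample rank of the constituent genes, `V_marker` the
#' rank sum of the markers, `N_g` the total number of genes in the input and
#' `N_m` the number of signature genes detected in the input. Scores are
#' then linearly scaled to [0, 1] across samples. Being rank-based, the
#' score is invariant under any strictly increasing elementwise transform of
#' the input (units, scaling normalisation).
#'
#' A signature gene counts as detected when its row exists and is not
#' all-zero. When neither constituent gene is detected (typical single-cell
#' dropout), the constituent term is dropped and scoring proceeds from the
#' marker component alone; delta is then `NA`. Because delta is recomputed
#' per input matrix, scores are dataset-relative: comparing samples across
#' datasets requires scoring them jointly.
#'
#' @param expr expression matrix (genes x samples), see
#'   [as_expression_matrix()].
#' @param sig a `gene_signature`.
#' @param scale linearly rescale raw scores to [0, 1] (default). With a
#'   single sample scaling is skipped with a warning; all-identical raw
#'   scores map to 0.5 with a warning.
#' @param drop_zero_genes drop all-zero gene rows before ranking (changes
#'   `N_g`; default keeps them).
#' @return an object of class `extend_result`: list with `sample_ids`,
#'   `raw_score`, `scaled_score`, `delta`, `n_g`, `n_m`, `v_const`,
#'   `v_marker`, `contributions` (signature-genes x samples matrix of
#'   additive shares of the raw score), `missing_genes`,
#'   `constituent_present`.
#' @export
extend_score <- function(expr, sig, scale = TRUE, drop_zero_genes = FALSE) {
  expr <- as_expression_matrix(expr, drop_zero_genes = drop_zero_genes)
  if (!inherits(sig, "gene_signature")) stop("sig must be a gene_signature")
  detected <- rownames(expr)[rowSums(expr > 0) > 0]
  const_present <- intersect(sig$constituent, detected)
  marker_present <- intersect(sig$markers, detected)
  if (!length(marker_present))
    stop("no marker gene of the signature is detected in the input")
  missing_genes <- setdiff(signature_genes(sig), c(const_present, marker_present))

  ranks <- rank_within_sample(expr)
  n_g <- nrow(expr)
  n_m <- length(const_present) + length(marker_present)

  v_marker <- colSums(ranks[marker_present, , drop = FALSE])
  denom <- n_g * n_m

  contrib <- ranks[marker_present, , drop = FALSE] / denom
  if (length(const_present)) {
    sub <- ranks[const_present, , drop = FALSE]
    v_const <- apply(sub, 2L, max)
    delta <- adjustment_factor(v_const, v_marker)
    raw <- (delta * v_const + v_marker) / denom
    # attribute the constituent term to the argmax gene (ties split evenly)
    cmat <- matrix(0, nrow = length(const_present), ncol = ncol(expr),
                   dimnames = list(const_present, colnames(expr)))
    for (j in seq_len(ncol(expr))) {
      at_max <- which(sub[, j] == v_const[j])
      cmat[at_max, j] <- delta * v_const[j] / denom / length(at_max)
    }
    contrib <- rbind(cmat, contrib)
  } else {
    v_const <- rep(NA_real_, ncol(expr))
    names(v_const) <- colnames(expr)
    delta <- NA_real_
    raw <- v_marker / denom
  }

  scaled <- raw
  if (isTRUE(scale)) {
    if (length(raw) < 2L) {
      warning("single sample: [0,1] scaling skipped, returning raw score")
    } else {
      rng <- range(raw)
      if (diff(rng) == 0) {
        warning("all raw scores identical; scaled scores set to 0.5")
        scaled <- rep(0.5, length(raw))
        names(scaled) <- names(raw)
      } else {
        scaled <- (raw - rng[1L]) / diff(rng)
      }
    }
  }

  structure(list(sample_ids = colnames(expr),
                 raw_score = raw,
                 scaled_score = scaled,
                 delta = delta,
                 n_g = n_g,
                 n_m = n_m,
                 v_const = v_const,
                 v_marker = v_marker,
                 contributions = contrib,
                 missing_genes = missing_genes,
                 constituent_present = const_present),
            class = "extend_result")
}

#' @export
print.extend_result <- function(x, ...) {
  cat("EXTEND scores: ", length(x$sample_ids), " sample(s), N_g = ", x$n_g,
      ", N_m = ", x$n_m, ", delta = ",
      if (is.na(x$delta)) "NA (marker-only)" else format(x$delta, digits = 4),
      "\n", sep = "")
  if (length(x$missing_genes))
    cat("  undetected signature genes:",
        paste(x$missing_genes, collapse = ", "), "\n")
  print(utils::head(as.data.frame(x), 6L))
  if (length(x$sample_ids) > 6L) cat("  ...\n")
  invisible(x)
}

#' @export
as.data.frame.extend_result <- function(x, ...) {
  cf <- component_contribution(x)$constituent_fraction
  data.frame(sample_id = x$sample_ids,
             raw_score = unname(x$raw_score),
             scaled_score = unname(x$scaled_score),
             n_m_present = x$n_m,
             const_fraction = unname(cf),
             row.names = NULL)
}

#' Per-gene and per-component contribution fractions
#'
#' The raw score is an additive sum over signature genes (after the delta
#' weight on the constituent term), so it decomposes exactly: this returns
#' each gene's fraction of the raw score per sample, plus the fraction
#' attributable to the whole constituent component. Fractions sum to 1 per
#' sample; with constituents absent the constituent fraction is 0.
#'
#' @param result an `extend_result`.
#' @return list with `gene_fractions` (signature-genes x samples matrix) and
#'   `constituent_fraction` (per-sample vector).
#' @export
component_contribution <- function(result) {
  if (!inherits(result, "extend_result")) stop("need an extend_result")
  raw <- result$raw_score
  frac <- sweep(result$contributions, 2L, raw, "/")
  frac[, raw == 0] <- 0
  cf <- if (length(result$constituent_present))
    colSums(frac[result$constituent_present, , drop = FALSE])
  else
    stats::setNames(rep(0, length(raw)), names(raw))
  list(gene_fractions = frac, constituent_fraction = cf)
}
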