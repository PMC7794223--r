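#' Stemness score per sample
#'
#' Spearman correlation between a fixed gene-weight vector (e.g. an
#' embryonic-stemness index) and each sample's expression vector, restricted
#' to the genes shared between the two. Values lie in [-1, 1]; a sample with
#' a constant expression vector over the shared genes gets `NA` (score
#' undefined) with a warning.
#'
#' @param expr expression matrix.
#' @param weights named numeric vector of signed gene weights (see
#'   [read_weights()]).
#' @return named numeric vector, one score per sample.
#' @export
stemness_score <- function(expr, weights) {
  expr <- as_expression_matrix(expr)
  if (is.null(names(weights)) || anyDuplicated(names(weights)))
    stop("weights must be a named vector with unique gene ids")
  if (any(!is.finite(weights))) stop("weights must all be finite")
  shared <- intersect(rownames(expr), names(weights))
  if (length(shared) < 3L)
    stop("need >= 3 genes shared between matrix and weight vector (got ",
         length(shared), ")")
  x <- expr[shared, , drop = FALSE]
  rw <- rank(weights[shared])
  rx <- apply(x, 2L, rank)  # midranks; Spearman = Pearson on midranks
  s <- suppressWarnings(as.vector(stats::cor(rw, rx)))
  names(s) <- colnames(expr)
  if (anyNA(s))
    warning(sum(is.na(s)), " sample(s) with constant expression over shared ",
            "genes; stemness score undefined (NA)")
  s
}

#' Spearman correlation between two per-sample score vectors
#'
#' Pairs with missing values are dropped listwise; at least 4 complete pairs
#' are required. P-value from [stats::cor.test()] (two-sided,
#' approximation in the presence of ties).
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `rho`, `p_value`, `n` (complete pairs used).
#' @export
correlate_scores <- function(x, y) {
  if (length(x) != length(y)) stop("score vectors differ in length")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4L) stop("need >= 4 complete paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant score vector; correlation undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Gene-label permutation test for the score-stemness correlation
#'
#' Observed statistic: Spearman rho between the EXTEND scores and the
#' stemness scores of the input matrix. Null: the gene labels of the
#' expression matrix are randomly shuffled (one shared shuffle per
#' iteration, perturbing both scorers simultaneously and preserving their
#' paired structure), both scores are recomputed and re-correlated. The
#' empirical p is the fraction of null correlations at least as large as the
#' observed one; it can be exactly 0 (`pseudocount = TRUE` switches to
#' (count + 1) / (n + 1)). Permutations whose scorer output is degenerate
#' (constant) are recorded as missing and excluded from the denominator.
#'
#' @param expr expression matrix.
#' @param sig a `gene_signature`.
#' @param weights stemness gene-weight vector.
#' @param n_perm number of permutations (>= 1; 1000 in routine use).
#' @param seed integer seed making the shuffles reproducible.
#' @param pseudocount use the (count + 1)/(n + 1) estimator.
#' @return object of class `permutation_result`: list with `observed_rho`,
#'   `null_rhos` (length `n_perm`, `NA` for degenerate draws), `n_perm`,
#'   `n_used`, `empirical_p`, `seed`.
#' @export
permutation_empirical_p <- function(expr, sig, weights, n_perm = 1000L,
                                    seed = 1L, pseudocount = FALSE) {
  expr <- as_expression_matrix(expr)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")
  es <- extend_score(expr, sig, scale = FALSE)$raw_score
  ss <- stemness_score(expr, weights)
  observed <- correlate_scores(es, ss)$rho

  gid <- rownames(expr)
  null_rhos <- rep(NA_real_, n_perm)
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm <- expr
    rownames(perm) <- gid[sample.int(length(gid))]
    r <- tryCatch({
      esb <- suppressWarnings(extend_score(perm, sig, scale = FALSE)$raw_score)
      ssb <- suppressWarnings(stemness_score(perm, weights))
      correlate_scores(esb, ssb)$rho
    }, error = function(e) NA_real_)
    null_rhos[b] <- r
  }
  used <- sum(!is.na(null_rhos))
  if (!used) stop("all permutations degenerate; cannot form an empirical p")
  hits <- sum(null_rhos >= observed, na.rm = TRUE)
  p <- if (pseudocount) (hits + 1) / (used + 1) else hits / used
  structure(list(observed_rho = observed, null_rhos = null_rhos,
                 n_perm = n_perm, n_used = used, empirical_p = p,
                 seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Gene-label permutation test: observed rho =",
      format(x$observed_rho, digits = 4),
      "| empirical p =", format(x$empirical_p, digits = 4),
      sprintf("(%d/%d permutations used, seed %d)\n",
              x$n_used, x$n_perm, x$seed))
  invisible(x)
}

#' Cell-cycle phase grouping for single cells
#'
#' Per-cell G1-S and G2-M scores are the mean log2(x + 1) expression of the
#' present phase-marker genes (>= 5 required from each list). Cells are
#' partitioned by k-means (k = 3, 10 restarts, seed-controlled) on the two
#' scores; clusters are labelled by their centroid pattern: the cluster with
#' the lowest combined centroid is non-cycling, and of the remaining two the
#' one with the higher G1-S minus G2-M centroid is G1-S, the other G2-M.
#' Cells in a cycling cluster whose two scores differ by less than `margin`
#' (log2 units) are labelled ambiguous, mirroring the exclusion of
#' ambiguous cycling groups.
#'
#' @param expr expression matrix (genes x cells).
#' @param g1s_genes,g2m_genes phase marker gene lists.
#' @param margin ambiguity margin on the log2 scale (default 0.1).
#' @param seed seed for the k-means restarts (default 1).
#' @return data.frame (class `phase_assignment`) with `cell_id`, `phase`
#'   (factor: G1-S, G2-M, non-cycling, ambiguous), `g1s_score`, `g2m_score`.
#' @export
classify_cell_cycle <- function(expr, g1s_genes, g2m_genes,
                                margin = 0.1, seed = 1L) {
  expr <- as_expression_matrix(expr)
  lev <- c("G1-S", "G2-M", "non-cycling", "ambiguous")
  g1 <- intersect(g1s_genes, rownames(expr))
  g2 <- intersect(g2m_genes, rownames(expr))
  if (length(g1) < 5L || length(g2) < 5L)
    stop("need >= 5 genes from each phase marker list present (got ",
         length(g1), " G1-S, ", length(g2), " G2-M)")
  lx <- log2(expr + 1)
  g1s <- colMeans(lx[g1, , drop = FALSE])
  g2m <- colMeans(lx[g2, , drop = FALSE])
  feats <- cbind(g1s = g1s, g2m = g2m)

  out <- data.frame(cell_id = colnames(expr),
                    phase = factor(rep("non-cycling", ncol(expr)), levels = lev),
                    g1s_score = unname(g1s), g2m_score = unname(g2m),
                    row.names = NULL)
  if (nrow(unique(feats)) < 3L) {
    warning("fewer than 3 distinct score pairs; all cells labelled non-cycling")
    class(out) <- c("phase_assignment", "data.frame")
    return(out)
  }
  set.seed(seed)
  km <- stats::kmeans(feats, centers = 3L, nstart = 10L)
  cen <- km$centers
  noncyc <- which.min(rowSums(cen))
  cyc <- setdiff(seq_len(3L), noncyc)
  g1s_cl <- cyc[which.max(cen[cyc, "g1s"] - cen[cyc, "g2m"])]
  g2m_cl <- setdiff(cyc, g1s_cl)
  lab <- character(3L)
  lab[noncyc] <- "non-cycling"; lab[g1s_cl] <- "G1-S"; lab[g2m_cl] <- "G2-M"
  phase <- lab[km$cluster]
  phase[phase %in% c("G1-S", "G2-M") & abs(g1s - g2m) < margin] <- "ambiguous"
  out$phase <- factor(phase, levels = lev)
  class(out) <- c("phase_assignment", "data.frame")
  out
}

#' Pairwise group comparison of per-sample scores
#'
#' All pairwise two-sided Welch t-tests between groups, with
#' Bonferroni-adjusted p-values (factor = number of pairs tested).
#' Singleton groups are excluded with a warning. Two groups with identical
#' values give t = 0, p = 1.
#'
#' @param scores numeric vector of per-sample scores.
#' @param labels group label per sample.
#' @return data.frame with `group1`, `group2`, `t`, `p_value`,
#'   `p_bonferroni`, `n1`, `n2`.
#' @export
compare_groups <- function(scores, labels) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- as.character(labels[keep])
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    warning("excluding singleton group(s): ",
            paste(names(sizes)[sizes < 2L], collapse = ", "))
    keep <- labels %in% names(sizes)[sizes >= 2L]
    scores <- scores[keep]; labels <- labels[keep]
  }
  groups <- sort(unique(labels))
  if (length(groups) < 2L) stop("need >= 2 groups with >= 2 samples each")
  pairs <- utils::combn(groups, 2L)
  res <- apply(pairs, 2L, function(pr) {
    x <- scores[labels == pr[1L]]; y <- scores[labels == pr[2L]]
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      c(t = 0, p = 1)
    } else {
      tt <- stats::t.test(x, y, alternative = "two.sided")
      c(t = unname(tt$statistic), p = tt$p.value)
    }
  })
  out <- data.frame(group1 = pairs[1L, ], group2 = pairs[2L, ],
                    t = res["t", ], p_value = res["p", ],
                    p_bonferroni = pmin(1, res["p", ] * ncol(pairs)),
                    n1 = as.integer(sizes[pairs[1L, ]]),
                    n2 = as.integer(sizes[pairs[2L, ]]),
                    row.names = NULL)
  out
}
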