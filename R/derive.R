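#' One-sided differential upregulation filter
#'
#' Per-gene Welch one-sided t-test for mean(group A) > mean(group B), run on
#' log2(x + 1) values by default, combined with a fold-change filter. Fold
#' change is computed from group means on the expression scale with a
#' pseudo-count of 1 (RSEM-style inputs contain zeros):
#' `log2_fc = log2((mean_A + 1) / (mean_B + 1))`. A gene passes when
#' `p <= p_threshold` and `log2_fc > fc_threshold`.
#'
#' No multiple-testing correction is applied by default (thresholding on the
#' raw p); `fdr = TRUE` switches the p filter to Benjamini-Hochberg adjusted
#' values.
#'
#' @param expr expression matrix.
#' @param group_a,group_b disjoint sample id vectors, each with >= 3 samples.
#' @param p_threshold raw p-value cutoff (default 0.05).
#' @param fc_threshold log2 fold-change cutoff (default 1.5, i.e. fold
#'   change > 2^1.5).
#' @param log_transform run the t-test on log2(x + 1) (default TRUE).
#' @param fdr use BH-adjusted p-values in the filter (default FALSE).
#' @return data.frame (class `differential_result`) with columns `gene_id`,
#'   `p_value`, `log2_fc`, `passed`.
#' @export
differential_upregulation <- function(expr, group_a, group_b,
                                      p_threshold = 0.05, fc_threshold = 1.5,
                                      log_transform = TRUE, fdr = FALSE) {
  expr <- as_expression_matrix(expr)
  group_a <- as.character(group_a); group_b <- as.character(group_b)
  if (length(intersect(group_a, group_b)))
    stop("groups overlap: ", paste(intersect(group_a, group_b), collapse = ", "))
  miss <- setdiff(c(group_a, group_b), colnames(expr))
  if (length(miss)) stop("sample ids not in matrix: ", paste(miss, collapse = ", "))
  if (length(group_a) < 3L || length(group_b) < 3L)
    stop("each group needs >= 3 samples")

  xa_raw <- expr[, group_a, drop = FALSE]
  xb_raw <- expr[, group_b, drop = FALSE]
  log2_fc <- log2((rowMeans(xa_raw) + 1) / (rowMeans(xb_raw) + 1))

  xa <- if (log_transform) log2(xa_raw + 1) else xa_raw
  xb <- if (log_transform) log2(xb_raw + 1) else xb_raw
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2) / (na - 1)
  vb <- rowSums((xb - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- stats::pt(tstat, df, lower.tail = FALSE)
  # degenerate genes: zero variance in both groups
  degen <- se2 == 0
  p[degen & ma > mb] <- 0
  p[degen & ma <= mb] <- 1
  log2_fc[degen & ma == mb] <- 0

  p_filter <- if (fdr) stats::p.adjust(p, method = "BH") else p
  res <- data.frame(gene_id = rownames(expr),
                    p_value = unname(p),
                    log2_fc = unname(log2_fc),
                    passed = unname(p_filter <= p_threshold & log2_fc > fc_threshold),
                    row.names = NULL)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Anchor-gene co-expression threshold scan
#'
#' For each correlation cutoff on the grid, collects the genes (excluding
#' the anchor itself) whose Pearson correlation with the anchor gene, over
#' the given samples, is at least the cutoff. Gene counts are non-increasing
#' along the grid by construction. The default grid spans 0.20-0.70 in steps
#' of 0.05 (11 thresholds). The robust threshold is picked by
#' [select_threshold()] from the percentage differences between consecutive
#' counts and stored in the result.
#'
#' Correlations are computed on log2(x + 1) values by default: Pearson
#' correlation on raw log-normal expression is systematically deflated by
#' the heavy right tail, and co-expression analyses of RNA-seq
#' conventionally work on the log scale.
#'
#' @param expr expression matrix.
#' @param anchor anchor gene id (must be present and non-constant over
#'   `samples`).
#' @param samples sample ids to correlate over (default: all).
#' @param thresholds ascending cutoff grid.
#' @param log_transform correlate log2(x + 1) values (default TRUE).
#' @return object of class `threshold_scan`: list with `thresholds`,
#'   `gene_counts`, `pct_diff`, `selected`, `selected_genes`, `correlations`.
#' @export
coexpression_scan <- function(expr, anchor, samples = NULL,
                              thresholds = seq(0.20, 0.70, by = 0.05),
                              log_transform = TRUE) {
  expr <- as_expression_matrix(expr)
  if (is.null(samples)) samples <- colnames(expr)
  miss <- setdiff(samples, colnames(expr))
  if (length(miss)) stop("sample ids not in matrix: ", paste(miss, collapse = ", "))
  if (length(samples) < 3L) stop("co-expression scan needs >= 3 samples")
  if (!anchor %in% rownames(expr)) stop("anchor gene not in matrix: ", anchor)
  thresholds <- sort(as.numeric(thresholds))
  x <- expr[, samples, drop = FALSE]
  if (log_transform) x <- log2(x + 1)
  av <- x[anchor, ]
  if (stats::sd(av) == 0)
    stop("anchor gene is constant across the chosen samples; correlation undefined")
  others <- setdiff(rownames(x), anchor)
  r <- suppressWarnings(as.vector(stats::cor(av, t(x[others, , drop = FALSE]))))
  names(r) <- others
  r <- r[is.finite(r)]  # constant genes have undefined correlation

  counts <- vapply(thresholds, function(t) sum(r >= t), integer(1L))
  scan <- structure(list(thresholds = thresholds,
                         gene_counts = counts,
                         pct_diff = pct_difference(counts),
                         selected = NA_real_,
                         selected_genes = character(0L),
                         correlations = r),
                    class = "threshold_scan")
  scan$selected <- select_threshold(scan)
  scan$selected_genes <- names(r)[r >= scan$selected]
  scan
}

# percentage difference between consecutive counts, indexed at the upper
# threshold of each pair (position k holds 100*(c[k-1]-c[k])/c[k-1])
pct_difference <- function(counts) {
  k <- length(counts)
  if (k < 2L) return(numeric(0L))
  c(NA_real_, 100 * (counts[-k] - counts[-1L]) / counts[-k])
}

#' Elbow selection over a threshold scan
#'
#' The percentage difference between consecutive gene counts grows while
#' raising the cutoff keeps pruning effectively; the chosen threshold is the
#' first one at which the percentage difference drops below its predecessor
#' (further increases would no longer remove candidates as effectively). If
#' the percentage difference never decreases, the last threshold is returned
#' with a message. Zero counts truncate the scan: selection happens over the
#' prefix of strictly positive counts.
#'
#' @param scan a `threshold_scan` (or a list with `thresholds` and
#'   `gene_counts`).
#' @return the selected threshold (scalar).
#' @export
select_threshold <- function(scan) {
  counts <- scan$gene_counts
  thr <- scan$thresholds
  nz <- which(counts == 0L)
  if (length(nz)) {
    counts <- counts[seq_len(nz[1L] - 1L)]
    thr <- thr[seq_len(nz[1L] - 1L)]
  }
  if (length(counts) < 3L)
    stop("need >= 3 thresholds with nonzero counts to select an elbow")
  pd <- pct_difference(counts)
  for (k in 3L:length(pd)) {
    if (pd[k] < pd[k - 1L]) return(thr[k])
  }
  message("percentage difference never decreased; returning last threshold ",
          thr[length(thr)])
  thr[length(thr)]
}

#' Derive a telomerase-style signature from a two-group cohort
#'
#' Reproduces the derivation pipeline: (1) one-sided differential
#' upregulation of group A over group B; (2) anchor-gene co-expression scan
#' with percentage-difference elbow selection; (3) intersection of the two
#' gene sets; (4) augmentation of the constituent component with the
#' TERC-role gene. The marker set is the intersection minus the anchor and
#' the TERC-role gene; the constituent pair is (anchor, terc_like) even if
#' `terc_like` is absent from the matrix (scoring then falls back to the
#' anchor alone).
#'
#' By default the co-expression scan runs over all cohort samples; pass
#' `scan_samples = group_a` to restrict it to the anchor-high group (the
#' behaviour of the original derivation on TERT-promoter-mutant cases).
#'
#' @inheritParams differential_upregulation
#' @param anchor anchor (TERT-role) gene id.
#' @param terc_like TERC-role gene id appended to the constituent component.
#' @param thresholds correlation cutoff grid.
#' @param scan_samples samples used for the co-expression scan (default:
#'   group_a and group_b combined).
#' @return a `gene_signature` with attributes `differential` (the
#'   `differential_result`) and `scan` (the `threshold_scan`) as audit trail.
#' @export
derive_signature <- function(expr, group_a, group_b, anchor, terc_like,
                             p_threshold = 0.05, fc_threshold = 1.5,
                             thresholds = seq(0.20, 0.70, by = 0.05),
                             scan_samples = NULL,
                             log_transform = TRUE, fdr = FALSE) {
  de <- differential_upregulation(expr, group_a, group_b,
                                  p_threshold = p_threshold,
                                  fc_threshold = fc_threshold,
                                  log_transform = log_transform, fdr = fdr)
  if (is.null(scan_samples)) scan_samples <- c(group_a, group_b)
  scan <- coexpression_scan(expr, anchor, samples = scan_samples,
                            thresholds = thresholds,
                            log_transform = log_transform)
  up <- de$gene_id[de$passed]
  markers <- setdiff(intersect(scan$selected_genes, up), c(anchor, terc_like))
  if (!length(markers))
    stop("empty intersection of co-expressed and upregulated genes\n",
         "  co-expressed at ", scan$selected, ": ",
         paste(utils::head(scan$selected_genes, 20L), collapse = ", "), "\n",
         "  upregulated: ", paste(utils::head(up, 20L), collapse = ", "))
  sig <- gene_signature(constituent = c(anchor, terc_like), markers = markers,
                        name = sprintf("derived (threshold %.2f, %d markers)",
                                       scan$selected, length(markers)))
  attr(sig, "differential") <- de
  attr(sig, "scan") <- scan
  sig
}
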