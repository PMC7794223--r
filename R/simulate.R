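#' Synthetic bulk cohort with planted telomerase-activity structure
#'
#' Generates a genes x samples matrix of log-normal expression with a
#' planted, mutually co-expressed, upregulated 13-gene module anchored on a
#' TERT-like constituent gene. Each sample carries a latent telomerase
#' activity in [0, 1]: the telomerase-positive group is graded near-maximal
#' (activity ~ U(0.9, 1)), while the ALT-like and no-TMM groups have zero
#' activity (ALT tumours maintain telomeres without telomerase). The planted
#' genes (TERT, TERC and the markers) receive an additive log2-scale shift
#' of `effect_size * activity`, which simultaneously upregulates them in the
#' active group and makes them mutually co-expressed across the cohort --
#' the minimal structure under which the derivation pipeline is
#' identifiable. Background genes are pure log-normal noise around fixed
#' per-gene baselines (log2 baseline ~ N(7, 1)).
#'
#' @param n_genes total genes (> n_markers + 2).
#' @param n_samples total samples.
#' @param n_markers planted marker genes (default 11, the signature size).
#' @param effect_size log2-scale shift per unit activity (default 2).
#' @param noise_sd log2-scale noise standard deviation (default 1).
#' @param group_fractions named proportions for the telomerase-positive,
#'   ALT-like and no-TMM groups (must sum to 1).
#' @param seed RNG seed; identical seed + parameters give bit-identical
#'   cohorts.
#' @return object of class `synthetic_cohort`: list with `expr` (expression
#'   matrix), `activity` (per-sample latent activity), `group` (per-sample
#'   label), `planted_signature` (a `gene_signature`), `seed`, `params`.
#' @export
simulate_bulk <- function(n_genes = 200L, n_samples = 100L, n_markers = 11L,
                          effect_size = 2, noise_sd = 1,
                          group_fractions = c(telomerase = 0.4, alt = 0.4,
                                              none = 0.2),
                          seed = 1L) {
  n_genes <- as.integer(n_genes); n_samples <- as.integer(n_samples)
  n_markers <- as.integer(n_markers)
  if (n_markers + 2L >= n_genes)
    stop("need n_markers + 2 < n_genes")
  if (length(group_fractions) != 3L || any(group_fractions < 0) ||
      abs(sum(group_fractions) - 1) > 1e-8)
    stop("group_fractions must be 3 non-negative proportions summing to 1")
  if (is.null(names(group_fractions)))
    names(group_fractions) <- c("telomerase", "alt", "none")

  set.seed(as.integer(seed))
  sizes <- diff(round(cumsum(c(0, group_fractions)) * n_samples))
  group <- rep(names(group_fractions), times = sizes)
  activity <- numeric(n_samples)
  activity[group == names(group_fractions)[1L]] <-
    stats::runif(sizes[1L], 0.9, 1)

  markers <- sprintf("M%02d", seq_len(n_markers))
  gene_ids <- c("TERT", "TERC", markers,
                sprintf("BG%04d", seq_len(n_genes - n_markers - 2L)))
  sample_ids <- sprintf("S%03d", seq_len(n_samples))

  baseline <- stats::rnorm(n_genes, mean = 7, sd = 1)
  logx <- matrix(stats::rnorm(n_genes * n_samples, sd = noise_sd),
                 nrow = n_genes) + baseline
  planted <- seq_len(n_markers + 2L)
  logx[planted, ] <- logx[planted, ] +
    matrix(effect_size * activity, nrow = length(planted),
           ncol = n_samples, byrow = TRUE)
  expr <- 2^logx
  dimnames(expr) <- list(gene_ids, sample_ids)
  names(activity) <- sample_ids
  names(group) <- sample_ids

  structure(list(expr = expr, activity = activity, group = group,
                 planted_signature = gene_signature(c("TERT", "TERC"), markers,
                                                    name = "planted"),
                 seed = as.integer(seed),
                 params = list(n_genes = n_genes, n_samples = n_samples,
                               n_markers = n_markers,
                               effect_size = effect_size, noise_sd = noise_sd,
                               group_fractions = group_fractions)),
            class = "synthetic_cohort")
}

#' Synthetic sparse single-cell cohort with planted cell-cycle phases
#'
#' Generates Poisson counts from per-gene log-normal rates with Bernoulli
#' dropout, three planted cell populations (G1-S, G2-M, non-cycling) whose
#' phase marker genes (30 per phase, near-binary on/off with a +5 log2
#' shift, as strong cycling markers are) are elevated in the matching
#' phase, and a planted 13-gene telomerase signature whose marker genes are
#' elevated in cycling cells via a latent activity (cycling ~ U(0.7, 1),
#' non-cycling ~ U(0, 0.1)). With `constituent_dropout` the TERT/TERC rows
#' are zeroed everywhere, emulating bulk-undetectable constituent
#' transcripts in single-cell protocols.
#'
#' @param n_genes total genes (>= 100).
#' @param n_cells total cells.
#' @param dropout_rate Bernoulli probability of zeroing any count
#'   (default 0.3, in [0, 1)).
#' @param constituent_dropout zero the TERT/TERC rows entirely.
#' @param phase_fractions named proportions for G1-S, G2-M and non-cycling
#'   cells (sum to 1).
#' @param seed RNG seed.
#' @return a `synthetic_cohort` whose extra fields `phase`, `g1s_genes` and
#'   `g2m_genes` carry the planted phases and marker lists.
#' @export
simulate_single_cell <- function(n_genes = 300L, n_cells = 300L,
                                 dropout_rate = 0.3,
                                 constituent_dropout = FALSE,
                                 phase_fractions = c(g1s = 0.25, g2m = 0.25,
                                                     noncycling = 0.5),
                                 seed = 1L) {
  n_genes <- as.integer(n_genes); n_cells <- as.integer(n_cells)
  if (n_genes < 100L) stop("need n_genes >= 100 (markers + phases + background)")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  if (length(phase_fractions) != 3L || any(phase_fractions < 0) ||
      abs(sum(phase_fractions) - 1) > 1e-8)
    stop("phase_fractions must be 3 non-negative proportions summing to 1")

  set.seed(as.integer(seed))
  sizes <- diff(round(cumsum(c(0, phase_fractions)) * n_cells))
  phase <- rep(c("G1-S", "G2-M", "non-cycling"), times = sizes)
  cycling <- phase != "non-cycling"
  activity <- ifelse(cycling, stats::runif(n_cells, 0.7, 1),
                     stats::runif(n_cells, 0, 0.1))

  markers <- sprintf("M%02d", 1:11)
  g1s_genes <- sprintf("G1S%02d", 1:30)
  g2m_genes <- sprintf("G2M%02d", 1:30)
  n_bg <- n_genes - 2L - 11L - 60L
  gene_ids <- c("TERT", "TERC", markers, g1s_genes, g2m_genes,
                sprintf("BG%04d", seq_len(n_bg)))
  cell_ids <- sprintf("C%04d", seq_len(n_cells))

  baseline <- stats::rnorm(n_genes, mean = 2, sd = 1)
  shift <- matrix(0, n_genes, n_cells, dimnames = list(gene_ids, NULL))
  shift[c("TERT", "TERC"), ] <- rep(2 * activity, each = 2L)
  shift[markers, ] <- rep(2 * activity, each = 11L)
  shift[g1s_genes, phase == "G1-S"] <- 5
  shift[g2m_genes, phase == "G2-M"] <- 5
  lograte <- baseline + shift + matrix(stats::rnorm(n_genes * n_cells, sd = 0.5),
                                       n_genes, n_cells)
  counts <- matrix(stats::rpois(n_genes * n_cells, 2^lograte),
                   n_genes, n_cells, dimnames = list(gene_ids, cell_ids))
  keep <- matrix(stats::rbinom(n_genes * n_cells, 1L, 1 - dropout_rate),
                 n_genes, n_cells)
  counts <- counts * keep
  if (constituent_dropout) counts[c("TERT", "TERC"), ] <- 0

  names(phase) <- cell_ids
  names(activity) <- cell_ids
  structure(list(expr = counts, activity = activity,
                 group = ifelse(cycling, "cycling", "non-cycling"),
                 phase = phase,
                 g1s_genes = g1s_genes, g2m_genes = g2m_genes,
                 planted_signature = gene_signature(c("TERT", "TERC"), markers,
                                                    name = "planted"),
                 seed = as.integer(seed),
                 params = list(n_genes = n_genes, n_cells = n_cells,
                               dropout_rate = dropout_rate,
                               constituent_dropout = constituent_dropout,
                               phase_fractions = phase_fractions)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$expr), "genes x", ncol(x$expr),
      if (is.null(x$phase)) "samples" else "cells",
      "(seed", paste0(x$seed, ")"), "\n")
  print(table(x$group))
  invisible(x)
}

#' Area under the ROC curve for scores against a binary truth
#'
#' Rank-based (Mann-Whitney) AUC: the probability that a random positive
#' sample scores above a random negative one, ties counted half.
#'
#' @param scores numeric scores.
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in [0, 1].
#' @export
score_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  if (!any(positive) || all(positive)) stop("need both classes")
  r <- rank(scores)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
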