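# Independent brute-force oracles. These re-derive every quantity from first
# principles (sorting loops, explicit formulas) without touching the package
# internals, so agreement is meaningful.

# midranks of a single vector via sorting positions and tie averaging
oracle_rank_vector <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

oracle_rank_matrix <- function(m) {
  out <- m
  for (j in seq_len(ncol(m))) out[, j] <- oracle_rank_vector(m[, j])
  out
}

# Spearman correlation as Pearson on oracle midranks, explicit formula
oracle_spearman <- function(x, y) {
  rx <- oracle_rank_vector(x); ry <- oracle_rank_vector(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# per-sample loop implementation of the two-component rank-sum score
oracle_extend <- function(expr, constituent, markers, scale = TRUE) {
  detected <- rownames(expr)[apply(expr, 1L, function(r) any(r > 0))]
  cp <- constituent[constituent %in% detected]
  mp <- markers[markers %in% detected]
  stopifnot(length(mp) > 0L)
  n_g <- nrow(expr)
  n_m <- length(cp) + length(mp)
  ranks <- oracle_rank_matrix(expr)
  v_const <- v_marker <- numeric(ncol(expr))
  for (j in seq_len(ncol(expr))) {
    if (length(cp)) {
      best <- -Inf
      for (g in cp) best <- max(best, ranks[g, j])
      v_const[j] <- best
    }
    s <- 0
    for (g in mp) s <- s + ranks[g, j]
    v_marker[j] <- s
  }
  if (length(cp)) {
    delta <- if (length(v_const) < 3L || length(unique(v_const)) == 1L ||
                 length(unique(v_marker)) == 1L) 1
             else {
               rho <- oracle_spearman(v_const, v_marker)
               if (rho >= 1) Inf else 1 / (1 - rho)
             }
    delta <- min(max(delta, 0.5), 20)
    raw <- (delta * v_const + v_marker) / (n_g * n_m)
  } else {
    raw <- v_marker / (n_g * n_m)
  }
  out <- raw
  if (scale && length(raw) >= 2L && diff(range(raw)) > 0)
    out <- (raw - min(raw)) / (max(raw) - min(raw))
  list(raw = raw, scaled = out)
}

# small labelled random expression matrix
random_expr <- function(n_genes, n_samples, seed, lambda = NULL) {
  set.seed(seed)
  m <- if (is.null(lambda))
    matrix(2^rnorm(n_genes * n_samples, 5, 1), n_genes, n_samples)
  else
    matrix(rpois(n_genes * n_samples, lambda), n_genes, n_samples)
  dimnames(m) <- list(sprintf("G%04d", seq_len(n_genes)),
                      sprintf("S%03d", seq_len(n_samples)))
  m
}

# hand-written 6-gene x 3-sample toy used across scoring tests
toy_matrix <- function() {
  m <- matrix(c(10, 8, 6, 1, 2, 3,
                1, 2, 3, 4, 5, 6,
                5, 5, 5, 5, 1, 9),
              nrow = 6,
              dimnames = list(c("C1", "M1", "M2", "B1", "B2", "B3"),
                              c("S1", "S2", "S3")))
  m
}

toy_signature <- function() gene_signature("C1", c("M1", "M2"))
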