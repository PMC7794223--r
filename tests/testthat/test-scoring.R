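test_that("gene_signature enforces disjointness and non-empty markers", {
  expect_error(gene_signature(c("TERT", "TERC"), character(0)), "non-empty")
  expect_error(gene_signature(c("TERT", "TERC"), c("TERT", "X")), "disjoint")
  expect_error(gene_signature(character(0), "X"), "1 or 2")
  sig <- gene_signature(c("TERT", "TERC"), c("A", "B"))
  expect_identical(signature_genes(sig), c("TERT", "TERC", "A", "B"))
})

test_that("signature JSON round-trip preserves content", {
  sig <- gene_signature(c("TERT", "TERC"), sprintf("M%02d", 1:11), name = "t")
  f <- withr::local_tempfile(fileext = ".json")
  write_signature(sig, f)
  back <- read_signature(f)
  expect_identical(back$constituent, sig$constituent)
  expect_identical(back$markers, sig$markers)
})

test_that("constituent_score: max rule, singleton fallback, loop oracle", {
  m <- random_expr(50, 10, seed = 11)
  rownames(m)[1:2] <- c("TERT", "TERC")
  r <- rank_within_sample(m)
  sig <- gene_signature(c("TERT", "TERC"), rownames(m)[3:8])
  v <- constituent_score(r, sig)
  expect_equal(unname(v), unname(pmax(r["TERT", ], r["TERC", ])))
  # elementwise max against an explicit loop
  loop <- vapply(seq_len(ncol(r)), function(j) max(r["TERT", j], r["TERC", j]),
                 numeric(1))
  expect_equal(unname(v), loop)
  # one constituent absent -> its rank alone
  r1 <- r[setdiff(rownames(r), "TERC"), ]
  expect_equal(constituent_score(r1, sig), r["TERT", ])
  # both absent -> NULL flags the constituent-absent condition
  expect_null(constituent_score(r[-(1:2), ], sig))
})

test_that("marker_score: rank sum, midrank tie case, loop oracle", {
  r0 <- matrix(c(10, 20, 30), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  sig0 <- gene_signature("z", c("a", "b", "c"))
  expect_equal(as.numeric(marker_score(r0, sig0)), 60)

  # all 11 markers tied at the bottom of a 50-gene sample: forced midrank sum
  m <- matrix(c(rep(0, 11), seq_len(39)) + 0, 50, 1,
              dimnames = list(sprintf("g%02d", 1:50), "s"))
  sig <- gene_signature("g50", sprintf("g%02d", 1:11))
  expect_equal(as.numeric(marker_score(rank_within_sample(m), sig)), 11 * 6)

  big <- random_expr(500, 20, seed = 12)
  sigb <- gene_signature(rownames(big)[1], rownames(big)[2:12])
  rb <- rank_within_sample(big)
  loop <- vapply(seq_len(ncol(rb)), function(j) {
    s <- 0
    for (g in sigb$markers) s <- s + oracle_rank_vector(big[, j])[match(g, rownames(big))]
    s
  }, numeric(1))
  expect_equal(as.numeric(marker_score(rb, sigb)), loop)
  attr_n <- attr(marker_score(rb, sigb), "n_present")
  expect_identical(attr_n, 11L)
  expect_error(marker_score(rb[20:30, ], sigb), "unusable")
})

test_that("adjustment_factor: formula values, clamps, degenerate inputs", {
  x <- 1:4
  expect_equal(adjustment_factor(x, c(2, 4, 1, 3)), 1)    # rho = 0
  expect_equal(adjustment_factor(1:5, c(1, 4, 2, 5, 3)), 2)  # rho = 0.5
  expect_equal(adjustment_factor(1:10, (1:10)^2), 20)     # rho = 1 -> clamp
  expect_equal(adjustment_factor(1:10, 10:1), 0.5)        # rho = -1 -> clamp
  expect_warning(d <- adjustment_factor(1:2, 2:1), "fewer than 3")
  expect_equal(d, 1)
  expect_warning(d2 <- adjustment_factor(rep(1, 5), 1:5), "constant")
  expect_equal(d2, 1)
})

test_that("extend_score reproduces frozen hand-computed toy values", {
  res <- extend_score(toy_matrix(), toy_signature())
  # delta: Spearman(V_const = (6,1,3.5), V_marker = (9,5,7)) = 1 -> clamp 20
  expect_equal(res$delta, 20)
  expect_equal(unname(res$v_const), c(6, 1, 3.5))
  expect_equal(unname(res$v_marker), c(9, 5, 7))
  expect_equal(unname(res$raw_score), c(129, 25, 77) / 18, tolerance = 1e-12)
  expect_equal(unname(res$scaled_score), c(1, 0, 0.5), tolerance = 1e-12)
  expect_identical(res$n_g, 6L)
  expect_identical(res$n_m, 3L)
})

test_that("scaled extremes: all signature genes at top vs bottom give (1, 0)", {
  n <- 30
  sig <- gene_signature("TERT", sprintf("M%d", 1:4))
  m <- matrix(2^rnorm(n * 2, 5, 0.2), n, 2,
              dimnames = list(c(signature_genes(sig), sprintf("B%02d", 1:(n - 5))),
                              c("hi", "lo")))
  m[signature_genes(sig), "hi"] <- max(m) * c(10, 11, 12, 13, 14)
  m[signature_genes(sig), "lo"] <- min(m) * c(0.10, 0.11, 0.12, 0.13, 0.14)
  res <- suppressWarnings(extend_score(m, sig))
  expect_equal(unname(res$scaled_score), c(1, 0))
})

test_that("edge cases of scaling: single sample, identical scores", {
  m <- toy_matrix()
  w1 <- capture_warnings(r1 <- extend_score(m[, 1, drop = FALSE], toy_signature()))
  expect_match(w1, "single sample", all = FALSE)
  expect_equal(r1$scaled_score, r1$raw_score)
  flat <- matrix(rep(c(5, 4, 3, 2, 1, 0.5), 3), 6, 3,
                 dimnames = dimnames(m))
  w2 <- capture_warnings(r2 <- extend_score(flat, toy_signature()))
  expect_match(w2, "identical", all = FALSE)
  expect_equal(unname(r2$scaled_score), rep(0.5, 3))
})

test_that("contributions decompose the raw score additively and sum to 1", {
  for (seed in c(21, 22)) {
    m <- random_expr(80, 12, seed = seed)
    sig <- gene_signature(rownames(m)[1:2], rownames(m)[3:13])
    res <- extend_score(m, sig)
    expect_equal(unname(colSums(res$contributions)), unname(res$raw_score),
                 tolerance = 1e-9)
    cc <- component_contribution(res)
    expect_equal(unname(colSums(cc$gene_fractions)), rep(1, 12),
                 tolerance = 1e-9)
    expect_equal(unname(cc$constituent_fraction),
                 unname(res$delta * res$v_const /
                          (res$delta * res$v_const + res$v_marker)),
                 tolerance = 1e-12)
  }
})

test_that("marker-only fallback: zero constituent rows, fraction 0", {
  m <- random_expr(60, 8, seed = 23)
  sig <- gene_signature(rownames(m)[1:2], rownames(m)[3:13])
  m[1:2, ] <- 0  # constituent genes below detection everywhere
  res <- extend_score(m, sig)
  expect_true(all(is.finite(res$raw_score)))
  expect_true(is.na(res$delta))
  expect_identical(res$n_m, 11L)
  expect_setequal(res$missing_genes, rownames(m)[1:2])
  # equals the marker-only computation on the same matrix
  r <- rank_within_sample(m)
  expect_equal(res$raw_score,
               colSums(r[sig$markers, ]) / (nrow(m) * 11), tolerance = 1e-12)
  cc <- component_contribution(res)
  expect_equal(unname(cc$constituent_fraction), rep(0, 8))
})

test_that("score properties: monotone invariance, permutation equivariance, marker monotonicity", {
  m <- random_expr(100, 15, seed = 24)
  sig <- gene_signature(rownames(m)[1:2], rownames(m)[3:13])
  res <- extend_score(m, sig)
  expect_identical(extend_score(log2(m + 1), sig)$scaled_score, res$scaled_score)
  expect_identical(extend_score(m^3, sig)$scaled_score, res$scaled_score)

  perm <- sample(ncol(m))
  resp <- extend_score(m[, perm], sig)
  expect_equal(resp$raw_score, res$raw_score[perm])
  expect_equal(resp$delta, res$delta)

  # raising one marker in one sample never lowers that sample's raw score
  for (k in 1:5) {
    m2 <- m
    m2[sig$markers[k], 3] <- m2[sig$markers[k], 3] * (1 + k)
    r2 <- extend_score(m2, sig, scale = FALSE)
    expect_gte(r2$raw_score[3] + 1e-12, res$raw_score[3])
  }
})

test_that("as.data.frame output carries the CLI columns", {
  res <- extend_score(toy_matrix(), toy_signature())
  df <- as.data.frame(res)
  expect_identical(names(df),
                   c("sample_id", "raw_score", "scaled_score", "n_m_present",
                     "const_fraction"))
  expect_equal(nrow(df), 3L)
})
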