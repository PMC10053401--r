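test_that("score_samples is the mean over signature genes", {
  vals <- matrix(c(2, 1, 4, 3, 6, 5), 2, 3,
                 dimnames = list(c("s1", "s2"), c("gA", "gB", "gC")))
  m <- toy_matrix(vals)
  expect_equal(score_samples(m, signature_set("two", c("gA", "gB"))),
               c(s1 = 3, s2 = 2))
  # a single-gene signature is disallowed by construction (>= 2 genes),
  # but a duplicated-column pair reproduces the single column
  m2 <- toy_matrix(cbind(vals, gD = vals[, "gA"]))
  expect_equal(score_samples(m2, signature_set("dup", c("gA", "gD"))),
               vals[, "gA"])
  expect_error(score_samples(m, signature_set("x", c("gA", "gZ"))), "gZ")
})

test_that("score_samples is linear in the expression matrix", {
  set.seed(5)
  v1 <- matrix(rnorm(20, 5), 4, 5,
               dimnames = list(paste0("s", 1:4), paste0("g", 1:5)))
  v2 <- matrix(rnorm(20, 5), 4, 5, dimnames = dimnames(v1))
  sig <- signature_set("t", c("g1", "g3", "g5"))
  avg <- toy_matrix((v1 + v2) / 2)
  expect_equal(score_samples(avg, sig),
               (score_samples(toy_matrix(v1), sig) +
                  score_samples(toy_matrix(v2), sig)) / 2)
})

test_that("zscore_genes standardizes each gene", {
  m <- toy_matrix(matrix(c(1, 2, 3, 10, 20, 30), 3, 2,
                         dimnames = list(paste0("s", 1:3), c("gA", "gB"))))
  z <- zscore_genes(m)
  expect_equal(z[, "gA"], c(s1 = -1, s2 = 0, s3 = 1))
  expect_lt(max(abs(colMeans(z))), 1e-10)
  expect_equal(apply(z, 2, sd), c(gA = 1, gB = 1))
  # idempotent and permutation-equivariant
  expect_lt(max(abs(zscore_genes(toy_matrix(z)) - z)), 1e-10)
  perm <- c(3, 1, 2)
  zp <- zscore_genes(toy_matrix(unclass(m)[perm, ]))
  expect_equal(zp, z[perm, ])
  const <- toy_matrix(matrix(c(1, 1, 1, 1, 2, 3), 3, 2,
                             dimnames = list(paste0("s", 1:3),
                                             c("gA", "gB"))))
  expect_error(zscore_genes(const), "constant gene")
})

test_that("complete-linkage clustering matches hand agglomeration", {
  x <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), "g1"))
  hc <- hclust_complete(toy_matrix(x), axis = "samples")
  expect_equal(hc$height, c(1, 10))
  expect_true(!is.unsorted(hc$height))  # complete linkage is monotone
  # identical items merge at height zero
  y <- matrix(c(5, 5, 9), 3, 1, dimnames = list(c("a", "b", "c"), "g1"))
  expect_equal(min(hclust_complete(toy_matrix(y))$height), 0)
})

test_that("clustering equals the brute-force O(n^3) reference", {
  for (s in 1:5) {
    set.seed(s)
    n <- sample(5:12, 1)
    x <- matrix(rnorm(n * 3), n, 3,
                dimnames = list(sprintf("it%02d", seq_len(n)), paste0("d", 1:3)))
    hc <- hclust_complete(toy_matrix(x), axis = "samples")
    ref <- bf_complete_linkage(x)
    expect_equal(sort(hc$height), sort(ref$heights))
    coph <- as.matrix(stats::cophenetic(hc))
    labs <- rownames(ref$cophenetic)
    expect_equal(coph[labs, labs], ref$cophenetic)
  }
})

test_that("gene_gene_corr returns a unit-diagonal symmetric matrix", {
  set.seed(2)
  vals <- matrix(rnorm(60, 5), 10, 6,
                 dimnames = list(sprintf("s%02d", 1:10), paste0("g", 1:6)))
  vals[, "g6"] <- vals[, "g1"]
  m <- toy_matrix(vals)
  sig <- signature_set("t", paste0("g", 1:6))
  cc <- gene_gene_corr(m, sig)
  expect_equal(diag(cc), setNames(rep(1, 6), paste0("g", 1:6)))
  expect_equal(cc, t(cc))
  expect_equal(cc["g1", "g6"], 1)
  # constant genes are dropped, not imputed
  vals[, "g2"] <- 3
  expect_message(cc2 <- gene_gene_corr(toy_matrix(vals), sig), "constant")
  expect_false("g2" %in% rownames(cc2))
})

test_that("planted co-expression shows up at the configured strength", {
  b <- generate_panel(synthetic_config(n_samples = 500, n_genes = 100,
                                       within_block_r = 0.7, seed = 23))
  cc <- gene_gene_corr(b$expression, signature_set("t", b$truth))
  off <- cc[upper.tri(cc)]
  expect_gt(mean(off), 0.6)
  expect_lt(mean(off), 0.8)
})

test_that("pca_on_signature centers pooled cohorts", {
  # data exactly on a line: PC1 explains everything
  t_ <- seq(-2, 2, length.out = 20)
  line <- cbind(g1 = 5 + t_, g2 = 3 - 2 * t_, g3 = 1 + 0.5 * t_)
  rownames(line) <- sprintf("s%02d", 1:20)
  sig <- signature_set("t", colnames(line))
  p <- pca_on_signature(list(a = toy_matrix(line)), sig)
  expect_equal(p$explained[1], 1, tolerance = 1e-9)
  expect_true(all(diff(p$explained) <= 1e-12))

  # isotropic noise spreads variance evenly across components
  set.seed(31)
  iso <- matrix(rnorm(5000 * 4), 5000, 4,
                dimnames = list(sprintf("s%04d", 1:5000), paste0("g", 1:4)))
  pi_ <- pca_on_signature(list(a = toy_matrix(iso)),
                          signature_set("t", paste0("g", 1:4)))
  expect_lt(pi_$explained[1] / pi_$explained[2] - 1, 0.05)

  # cohort projection does not depend on concatenation order (up to sign)
  set.seed(32)
  A <- matrix(rnorm(30, 5), 10, 3,
              dimnames = list(paste0("a", 1:10), paste0("g", 1:3)))
  B <- matrix(rnorm(24, 6), 8, 3,
              dimnames = list(paste0("b", 1:8), paste0("g", 1:3)))
  sig3 <- signature_set("t", paste0("g", 1:3))
  p1 <- pca_on_signature(list(A = toy_matrix(A), B = toy_matrix(B)), sig3)
  p2 <- pca_on_signature(list(B = toy_matrix(B), A = toy_matrix(A)), sig3)
  a1 <- p1$scores[p1$scores$cohort == "A", c("PC1", "PC2")]
  a2 <- p2$scores[p2$scores$cohort == "A", c("PC1", "PC2")]
  s1 <- sign(sum(a1$PC1 * a2$PC1)); s2 <- sign(sum(a1$PC2 * a2$PC2))
  expect_equal(a1$PC1, s1 * a2$PC1)
  expect_equal(a1$PC2, s2 * a2$PC2)
  expect_error(pca_on_signature(list(a = toy_matrix(A[1, , drop = FALSE])),
                                sig3), "at least 2 samples")
})

test_that("reduce_signature removes a pure-noise member first", {
  set.seed(41)
  n <- 60
  sv <- rnorm(n)
  vals <- cbind(gA = sv + rnorm(n, sd = 0.05),
                gB = sv + rnorm(n, sd = 0.05),
                gC = sv + rnorm(n, sd = 0.05),
                gNoise = rnorm(n))
  rownames(vals) <- sprintf("s%02d", 1:n)
  m <- toy_matrix(vals, units = "normalized_protein", layer = "proteomics")
  s <- sensitivity_vector(setNames(exp(sv), rownames(vals)), "ec50")
  red <- reduce_signature(signature_set("t", colnames(vals)), m, s)
  expect_identical(red$removed[1], "gNoise")
  expect_true(all(diff(red$trace$r_abs) >= 0))
  expect_gte(length(red$signature$genes), 2)
})

test_that("responder_fraction counts scores at or below the reference", {
  sc <- setNames(c(1, 2, 3, 4), paste0("t", 1:4))
  ent <- rep("LUAD", 4)
  expect_equal(responder_fraction(sc, ent, 0.5)$responder_fraction, 0)
  expect_equal(responder_fraction(sc, ent, 10)$responder_fraction, 1)
  # ties count as responders
  expect_equal(responder_fraction(sc, ent, 2)$responder_fraction, 0.5)
  # two entities, one empty after NA removal
  sc2 <- c(sc, t5 = NA_real_)
  ent2 <- c(ent, "UVM")
  expect_message(rf <- responder_fraction(sc2, ent2, 2), "omitted")
  expect_identical(rf$entity, "LUAD")

  # a 576-tumor cohort with the reference at its 0.8th percentile
  set.seed(55)
  cohort <- rnorm(576, mean = 7, sd = 1.2)
  ref <- quantile(cohort, probs = 0.008, type = 1)
  frac <- responder_fraction(setNames(cohort, paste0("t", 1:576)),
                             rep("LUAD", 576), ref)$responder_fraction
  expect_lt(frac, 0.01)
})
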