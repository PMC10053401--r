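test_that("correlation_vector places a compound in signature space", {
  b <- generate_panel(synthetic_config(n_samples = 31, n_genes = 100,
                                       n_signature = 8, seed = 9))
  sig <- signature_set("t", b$truth)
  # response equal to one signature gene's own expression
  g <- b$truth[3]
  resp <- setNames(unclass(b$expression)[, g], rownames(b$expression))
  v <- correlation_vector(b$expression, sig, resp)
  expect_length(v, 8)
  expect_identical(names(v), sig$genes)
  expect_equal(unname(v[g]), 1)
  # the reference drug response correlates positively with all planted
  # genes (the signature is repressed in sensitive, low-EC50 lines)
  v_ref <- correlation_vector(b$expression, sig, b$sensitivity)
  expect_true(all(v_ref > 0))
  expect_error(
    correlation_vector(b$expression, sig,
                       setNames(rep(1, 31), rownames(b$expression))),
    "constant response")
})

test_that("a permuted response decorrelates from every gene", {
  b <- generate_panel(synthetic_config(n_samples = 500, n_genes = 60,
                                       n_signature = 10, seed = 14))
  sig <- signature_set("t", b$truth)
  set.seed(15)
  resp <- setNames(sample(log(as.numeric(b$sensitivity))),
                   rownames(b$expression))
  v <- correlation_vector(b$expression, sig, resp)
  expect_true(all(abs(v) < 0.15))
})

test_that("distance_to_reference is a metric on correlation vectors", {
  expect_equal(distance_to_reference(c(0.5, -0.2), c(0.5, -0.2)), 0)
  expect_equal(distance_to_reference(c(0.6, -0.8), c(0, 0)), 1)
  expect_error(distance_to_reference(1:3, 1:4), "length")
  set.seed(16)
  for (i in 1:20) {
    a <- runif(5, -1, 1); b <- runif(5, -1, 1); c <- runif(5, -1, 1)
    expect_equal(distance_to_reference(a, b), distance_to_reference(b, a))
    expect_lte(distance_to_reference(a, c),
               distance_to_reference(a, b) + distance_to_reference(b, c)
               + 1e-12)
  }
})

# a hand-built library: a clone of the reference, an unrelated compound and
# an anti-correlated compound
make_triple_library <- function(b) {
  sids <- rownames(b$expression)
  ln_ec50 <- log(as.numeric(b$sensitivity))
  set.seed(17)
  responses <- cbind(clone = ln_ec50,
                     null = rnorm(length(sids)),
                     anti = -ln_ec50,
                     reference = ln_ec50)
  rownames(responses) <- sids
  responses
}

test_that("ranking is ascending in distance with stable tie-breaks", {
  b <- generate_panel(synthetic_config(n_samples = 31, n_genes = 80,
                                       n_signature = 6, seed = 18))
  sig <- signature_set("t", b$truth)
  responses <- make_triple_library(b)
  pr <- compound_profiles(b$expression, sig, responses,
                          reactive = c(clone = TRUE, null = FALSE,
                                       anti = FALSE, reference = TRUE),
                          reference_id = "reference")
  rk <- rank_by_distance(pr)
  expect_false("reference" %in% rk$compound_id)
  expect_identical(rk$compound_id[1], "clone")
  expect_equal(rk$distance[1], 0)
  expect_identical(rk$compound_id[3], "anti")
  expect_true(!is.unsorted(rk$distance))
  # invariant to input column order
  pr2 <- compound_profiles(b$expression, sig,
                           responses[, c("anti", "reference", "clone", "null")],
                           reactive = c(clone = TRUE, null = FALSE,
                                        anti = FALSE, reference = TRUE),
                           reference_id = "reference")
  expect_identical(rank_by_distance(pr2)$compound_id, rk$compound_id)
  # relative distance is distance over the maximum observed
  expect_equal(pr$relative_distance, pr$distance / max(pr$distance))
})

test_that("roc_reactive reproduces the confusion-matrix sweep", {
  mk_ranked <- function(dist, flags)
    structure(data.frame(rank = seq_along(dist),
                         compound_id = sprintf("c%03d", seq_along(dist)),
                         distance = dist, relative_distance = dist / max(dist),
                         reactive = flags),
              class = c("ranked_compounds", "data.frame"))
  # perfect separation: all 10 reactive compounds rank first out of 40
  perfect <- mk_ranked(sort(runif(40)), rep(c(TRUE, FALSE), c(10, 30)))
  expect_equal(roc_reactive(perfect)$roc_auc, 1)
  # reversal maps the area to its complement
  rev_ranked <- mk_ranked(perfect$distance,
                          rev(perfect$reactive))
  expect_equal(roc_reactive(rev_ranked)$roc_auc,
               1 - roc_reactive(perfect)$roc_auc)
  # random labels on a large library sit near 0.5
  set.seed(190)
  rnd <- mk_ranked(sort(runif(2000)), sample(rep(c(TRUE, FALSE), 1000)))
  expect_lt(abs(roc_reactive(rnd)$roc_auc - 0.5), 0.03)
  # exact agreement with the brute-force sweep, including tied distances
  set.seed(20)
  for (i in 1:5) {
    d <- sort(sample(round(runif(60), 2)))  # forces ties
    fl <- runif(60) < plogis(-4 * d + 1)
    if (!any(fl) || all(fl)) next
    rk <- mk_ranked(d, fl)
    expect_equal(roc_reactive(rk)$roc_auc, bf_roc_auc(d, fl))
  }
  # the stored curve is the cumulative-recall walk
  roc <- roc_reactive(perfect)
  expect_true(all(diff(roc$curve$cum_reactive_fraction) >= 0))
  expect_equal(max(roc$curve$cum_reactive_fraction), 1)
  expect_error(roc_reactive(mk_ranked(1:4 / 4, rep(TRUE, 4))),
               "both reactive and non-reactive")
})

test_that("fold_enrichment normalizes to the background rate", {
  ranked <- structure(data.frame(
    rank = 1:20, compound_id = sprintf("c%02d", 1:20),
    distance = seq(0.1, 2, by = 0.1), relative_distance = NA,
    reactive = rep(c(TRUE, FALSE), 10)),
    class = c("ranked_compounds", "data.frame"))
  # a set matching the background rate has fold 1
  fe <- fold_enrichment(ranked, cutoff = 1.05)
  expect_equal(fe$set_size, 10)
  expect_equal(fe$fold_enrichment, 1)
  # the whole library self-normalizes to exactly 1
  expect_equal(fold_enrichment(ranked, cutoff = 99)$fold_enrichment, 1)
  # strictness of the cutoff
  expect_equal(fold_enrichment(ranked, cutoff = 0.2)$set_size, 1)
  # empty set: fold undefined but counts reported
  expect_message(fe0 <- fold_enrichment(ranked, cutoff = 0.05), "undefined")
  expect_true(is.na(fe0$fold_enrichment))
  expect_equal(fe0$set_size, 0)
  # k-nearest alternative
  expect_equal(fold_enrichment(ranked, n_nearest = 4)$reactive_in_set, 2)
})
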