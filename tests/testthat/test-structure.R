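# Strict autosomal filtering, PCA, F_ST, Nei distance and AMOVA.

test_that("strict autosomal filter drops sex-linked, incomplete and irreproducible loci", {
  calls <- rbind(rep(0L, 4), rep(2L, 4), c(0L, NA, 1L, 2L), rep(1L, 4))
  x <- make_snp(calls, rep_avg = c(1, 1, 1, 0.99))
  kept <- filter_autosomal_strict(x, sexlink_ids = "L01")
  # L01 sex-linked, L03 call rate < 1, L04 rep_avg < 1
  expect_identical(kept$locus_id, "L02")
  expect_error(filter_autosomal_strict(x, sexlink_ids = x$locus_id),
               "no loci pass")
  sim <- simulate_dataset(sim_config(n_males = 5, n_females = 5, n_clusters = 1,
                                     n_autosomal = 100, n_autosomal_pa = 0,
                                     n_sexlinked_snp = 0, n_sexlinked_pa = 0,
                                     missing_rate = 0, seed = 70))
  expect_equal(nrow(filter_autosomal_strict(sim$snp)), 100)
})

test_that("PCA separates simulated clusters and respects duplicates and ordering", {
  sim <- simulate_dataset(sim_config(n_males = 10, n_females = 10, n_clusters = 2,
                                     fst_target = 0.24, n_autosomal = 1500,
                                     n_autosomal_pa = 0, n_sexlinked_snp = 0,
                                     n_sexlinked_pa = 0, missing_rate = 0,
                                     seed = 71))
  pc <- pca_scores(sim$snp)
  cl <- sim$samples$cluster[match(pc$scores$sample_id, sim$samples$sample_id)]
  r1 <- range(pc$scores$PC1[cl == 1]); r2 <- range(pc$scores$PC1[cl == 2])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])  # zero overlap on PC1
  expect_true(all(diff(pc$explained) <= 1e-12))
  expect_lte(sum(pc$explained), 1 + 1e-8)
  # duplicated sample -> identical scores
  m <- calls_matrix(sim$snp)[1:200, 1:6]
  m[, 6] <- m[, 1]
  pc2 <- pca_scores(make_snp(m))
  expect_equal(unlist(pc2$scores[6, -1]), unlist(pc2$scores[1, -1]),
               tolerance = 1e-8)
  # sample reordering leaves scores invariant up to sign
  x6 <- make_snp(m)
  ids <- sample_ids(x6)
  perm <- c(3, 1, 2, 6, 4, 5)
  pc3 <- pca_scores(make_snp(calls_matrix(x6)[, perm],
                             sample_ids = ids[perm]))
  a <- pc2$scores$PC1[match(ids, pc2$scores$sample_id)]
  b <- pc3$scores$PC1[match(ids, pc3$scores$sample_id)]
  expect_equal(abs(cor(a, b)), 1, tolerance = 1e-8)
  expect_error(pca_scores(make_snp(matrix(1L, 3, 4))), "constant")
})

test_that("Weir-Cockerham F_ST hits the trivial anchors", {
  set.seed(72)
  # identical allele frequencies -> ~0
  calls <- matrix(sample(0:2, 5000 * 20, replace = TRUE,
                         prob = c(.25, .25, .5)), 5000)
  x <- make_snp(calls)
  cl <- tibble::tibble(sample_id = sample_ids(x), cluster = rep(1:2, each = 10))
  est <- pairwise_fst(x, cl)$fst
  expect_lt(abs(est), 0.01)
  # fixed opposite clusters -> 1
  fixed <- make_snp(matrix(rep(rep(c(0L, 1L), each = 5), 50), 50, byrow = TRUE))
  cl2 <- tibble::tibble(sample_id = sample_ids(fixed), cluster = rep(1:2, each = 5))
  expect_equal(pairwise_fst(fixed, cl2)$fst, 1)
  # monomorphic-only input is NA with warning
  mono <- make_snp(matrix(0L, 10, 10))
  cl3 <- tibble::tibble(sample_id = sample_ids(mono), cluster = rep(1:2, each = 5))
  expect_warning(est <- pairwise_fst(mono, cl3)$fst, "undefined")
  expect_true(is.na(est))
})

test_that("F_ST estimate increases with the simulated divergence", {
  mean_fst <- vapply(c(0.05, 0.1, 0.2, 0.4), function(f) {
    est <- vapply(1:3, function(s) {
      sim <- simulate_dataset(sim_config(n_males = 8, n_females = 8,
                                         n_clusters = 2, fst_target = f,
                                         n_autosomal = 1200, n_autosomal_pa = 0,
                                         n_sexlinked_snp = 0, n_sexlinked_pa = 0,
                                         missing_rate = 0, seed = 200 + s))
      pairwise_fst(sim$snp, sim$samples[, c("sample_id", "cluster")])$fst
    }, numeric(1))
    mean(est)
  }, numeric(1))
  expect_true(all(diff(mean_fst) > 0))
})

test_that("Nei distance matches the hand-computed two-locus value and its anchors", {
  # cluster X alt-allele freqs (0.5, 0.9), cluster Y (0.5, 0.1):
  # J_x = J_y = (0.5 + 0.82)/2 = 0.66, J_xy = (0.5 + 0.18)/2 = 0.34,
  # D = -ln(0.34/0.66) = 0.663294
  X <- cbind(c(1L, 1L), c(1L, 1L), c(2L, 1L), c(0L, 1L), c(0L, 2L))
  Y <- cbind(c(1L, 0L), c(1L, 0L), c(2L, 0L), c(0L, 0L), c(0L, 2L))
  x <- make_snp(cbind(X, Y))
  cl <- tibble::tibble(sample_id = sample_ids(x), cluster = rep(1:2, each = 5))
  expect_equal(nei_distance(x, cl)$nei_d, -log(0.34 / 0.66), tolerance = 1e-12)
  # identical clusters -> D = 0
  ident <- make_snp(cbind(X, X))
  expect_equal(nei_distance(ident, cl)$nei_d, 0)
})

test_that("individual allele-sharing distance is 0 for self and matches hand values", {
  # hom_ref vs hom_alt shares 0 alleles (d=1); het vs hom shares half (d=.5)
  x <- make_snp(cbind(c(0L, 0L), c(1L, 2L), c(0L, 0L)))
  cl <- tibble::tibble(sample_id = sample_ids(x), cluster = c(1, 1, 1))
  wd <- within_cluster_distance(x, cl)
  # pairs: (s1,s2): (1 + .5)/2 = .75; (s1,s3): 0; (s2,s3): .75
  expect_equal(wd$mean_dist, mean(c(0.75, 0, 0.75)))
  expect_equal(wd$n_pairs, 3L)
})

test_that("AMOVA sums of squares match the definitional allele-vector oracle", {
  set.seed(73)
  for (rep in 1:3) {
    calls <- matrix(sample(0:2, 30 * 12, replace = TRUE), 30)
    x <- make_snp(calls)
    cl <- tibble::tibble(sample_id = sample_ids(x),
                         cluster = rep(1:2, c(7, 5)))
    res <- amova(x, cl, permutations = 0)
    dos <- t(matrix(c(0, 2, 1)[calls + 1L], nrow = nrow(calls)))
    want <- oracle_amova_ss(dos, factor(rep(1:2, c(7, 5))))
    tbl <- res$table
    expect_equal(tbl$sum_sq[tbl$component == "between_clusters"],
                 want$among_clusters)
    expect_equal(tbl$sum_sq[tbl$component == "between_samples_within_clusters"],
                 want$among_ind_within)
    expect_equal(tbl$sum_sq[tbl$component == "within_samples"], want$within_ind)
    expect_equal(tbl$sum_sq[tbl$component == "total"], want$total)
    # structural invariants
    expect_equal(sum(tbl$percent_variance[tbl$component != "total"]), 100,
                 tolerance = 1e-9)
    expect_equal(tbl$df, c(1, 10, 12, 23))
    expect_equal(sum(tbl$sigma_raw[tbl$component != "total"]),
                 tbl$sigma_raw[tbl$component == "total"])
    expect_equal(tbl$mean_sq[1:3], tbl$sum_sq[1:3] / tbl$df[1:3])
  }
})

test_that("AMOVA permutation p-values separate structured from unstructured labels", {
  sim <- simulate_dataset(sim_config(n_males = 10, n_females = 10, n_clusters = 2,
                                     fst_target = 0.24, n_autosomal = 600,
                                     n_autosomal_pa = 0, n_sexlinked_snp = 0,
                                     n_sexlinked_pa = 0, missing_rate = 0,
                                     seed = 74))
  cl <- sim$samples[, c("sample_id", "cluster")]
  res <- amova(sim$snp, cl, permutations = 99, seed = 75)
  tbl <- res$table
  expect_lt(tbl$p_value[tbl$component == "between_clusters"], 0.05)
  expect_gt(tbl$percent_variance[tbl$component == "between_clusters"], 10)
  # random labels on a single population: small between-cluster share
  sim0 <- simulate_dataset(sim_config(n_males = 10, n_females = 10, n_clusters = 1,
                                      n_autosomal = 600, n_autosomal_pa = 0,
                                      n_sexlinked_snp = 0, n_sexlinked_pa = 0,
                                      missing_rate = 0, seed = 76))
  cl0 <- tibble::tibble(sample_id = sim0$samples$sample_id,
                        cluster = rep(1:2, 10))
  res0 <- amova(sim0$snp, cl0, permutations = 99, seed = 77)
  tbl0 <- res0$table
  expect_lt(tbl0$percent_variance[tbl0$component == "between_clusters"], 2)
  expect_gt(tbl0$p_value[tbl0$component == "between_clusters"], 0.05)
})

test_that("AMOVA rejects degenerate designs and drops incomplete loci", {
  x <- make_snp(matrix(sample(0:2, 40, replace = TRUE), 4))
  cl <- tibble::tibble(sample_id = sample_ids(x),
                       cluster = rep(1:2, c(1, 9)))
  expect_error(amova(x, cl), ">= 2 individuals")
  calls <- matrix(sample(0:2, 40, replace = TRUE), 4)
  calls[1, 1] <- NA
  y <- make_snp(calls)
  cl2 <- tibble::tibble(sample_id = sample_ids(y), cluster = rep(1:2, each = 5))
  expect_message(res <- amova(y, cl2, permutations = 0), "dropping 1")
  expect_equal(res$n_loci_used, 3)
})
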