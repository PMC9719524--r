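# Sex-linkage classification, false-positive test and the scan.

test_that("call-rate filter keeps loci at the threshold (inclusive) and drops below", {
  calls <- rbind(c(rep(0L, 35), rep(NA, 9)),   # 35/44 = 0.795 -> dropped
                 c(rep(0L, 36), rep(NA, 8)),   # 36/44 = 0.818 -> retained
                 rep(2L, 44))
  x <- make_snp(calls)
  kept <- filter_call_rate(x, 0.8)
  expect_identical(kept$locus_id, c("L02", "L03"))
  expect_equal(attr(kept, "n_dropped"), 1)
  expect_identical(filter_call_rate(x, 0)$locus_id, x$locus_id)
  # exact boundary: 4/5 = 0.8 kept at threshold 0.8
  y <- make_snp(matrix(c(0L, 0L, 0L, 0L, NA), 1))
  expect_equal(nrow(filter_call_rate(y, 0.8)), 1)
})

test_that("perfect and moderate XY classification match the worked examples", {
  crit <- sex_link_criteria()
  # 19 males all HET, 17 females all HOM_REF -> XY PERFECT
  r <- classify_snp_locus(rep(c(2L, 0L), c(19, 17)),
                          rep(c("M", "F"), c(19, 17)), crit)
  expect_identical(r$system_call, "XY")
  expect_identical(r$linkage_class, "PERFECT")
  expect_equal(r$het_or_present_frac_males, 1)
  # 16/19 males HET (0.842), 14/17 females HOM (0.824) -> XY MODERATE
  g <- c(rep(2L, 16), rep(0L, 3), rep(0L, 10), rep(1L, 4), rep(2L, 3))
  r <- classify_snp_locus(g, rep(c("M", "F"), c(19, 17)), crit)
  expect_identical(r$system_call, "XY")
  expect_identical(r$linkage_class, "MODERATE")
  expect_equal(r$het_or_present_frac_males, 16 / 19)
  expect_equal(r$hom_or_absent_frac, 14 / 17)
  # same locus fails under strict mode
  r <- classify_snp_locus(g, rep(c("M", "F"), c(19, 17)),
                          sex_link_criteria(strict = TRUE))
  expect_identical(r$system_call, "NONE")
})

test_that("UNKNOWN-sex samples are excluded and sparse loci are unevaluable", {
  g <- c(2L, 2L, 0L, 0L, 1L)
  sexes <- c("M", "M", "F", "F", "UNKNOWN")
  r <- classify_snp_locus(g, sexes)
  expect_identical(r$system_call, "XY")
  expect_equal(r$n_called_males, 2)
  expect_equal(r$n_called_females, 2)
  r <- classify_snp_locus(c(NA, NA, 0L, 0L), c("M", "M", "F", "F"))
  expect_false(r$evaluable)
  expect_true(is.na(r$system_call))
})

test_that("PA classification mirrors SNP with presence as the heterogametic state", {
  sexes <- rep(c("M", "F"), c(5, 3))
  r <- classify_pa_locus(rep(c(1L, 0L), c(5, 3)), sexes)
  expect_identical(r$system_call, "XY")
  expect_identical(r$linkage_class, "PERFECT")
  # present 4/5 males, absent 2/3 females (0.667) -> NONE at 0.8 and strict
  g <- c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 1L)
  expect_identical(classify_pa_locus(g, sexes)$system_call, "NONE")
  expect_identical(classify_pa_locus(g, sexes,
                                     sex_link_criteria(strict = TRUE))$system_call,
                   "NONE")
  # no sex contrast
  expect_identical(classify_pa_locus(rep(1L, 8), sexes)$system_call, "NONE")
})

test_that("classification equals the brute-force inequalities over all 3^6 vectors", {
  sexes <- rep(c("M", "F"), each = 3)
  crit08 <- sex_link_criteria()
  crit10 <- sex_link_criteria(strict = TRUE)
  grid <- expand.grid(rep(list(0:2), 6))
  for (i in seq_len(nrow(grid))) {
    g <- as.integer(grid[i, ])
    for (crit in list(crit08, crit10)) {
      cmin <- if (crit$strict) 1 else crit$concordance_min
      want <- oracle_classify(g, sexes, cmin, het_state = 2L,
                              hom_states = c(0L, 1L))
      got <- classify_snp_locus(g, sexes, crit)
      expect_identical(got$system_call, want$system)
      expect_identical(got$linkage_class, want$class)
    }
  }
})

test_that("XY and ZW are mutually exclusive and calls are monotone in the threshold", {
  set.seed(77)
  sexes <- rep(c("M", "F"), c(6, 5))
  thresholds <- c(0.6, 0.7, 0.8, 0.9, 1)
  for (i in 1:300) {
    g <- sample(c(0:2, NA), 11, replace = TRUE, prob = c(.3, .3, .3, .1))
    calls <- vapply(thresholds, function(th) {
      r <- classify_snp_locus(g, sexes, sex_link_criteria(concordance_min = th))
      r$system_call %||% NA_character_
    }, character(1))
    linked <- !is.na(calls) & calls != "NONE"
    # once a locus stops qualifying it never re-qualifies at a higher bar
    expect_true(all(diff(linked) <= 0))
    # no vector may qualify as XY and ZW at the same threshold (single call
    # by construction); check both inequality systems directly
    for (th in thresholds) {
      w1 <- oracle_classify(g, sexes, th, 2L, c(0L, 1L))
      if (!is.na(w1$system) && w1$system == "XY") {
        gm <- g[sexes == "M"]; gm <- gm[!is.na(gm)]
        gf <- g[sexes == "F"]; gf <- gf[!is.na(gf)]
        expect_false(mean(gf == 2L) >= th && mean(gm %in% c(0L, 1L)) >= th)
      }
    }
  }
})

test_that("false-positive test uses the single majority homozygote class", {
  crit <- sex_link_criteria()
  sexes <- rep("F", 9)
  expect_true(false_positive_test(rep(0L, 9), sexes, "XY", crit)$fp_pass)
  # 5 HOM_REF + 4 HOM_ALT: majority class 5/9 = 0.56 -> fail even though
  # total homozygosity is 100%
  r <- false_positive_test(c(rep(0L, 5), rep(1L, 4)), sexes, "XY", crit)
  expect_false(r$fp_pass)
  expect_equal(r$fp_frac, 5 / 9)
  # 8 HOM_REF + 1 HET: 8/9 = 0.889 -> pass
  expect_true(false_positive_test(c(rep(0L, 8), 2L), sexes, "XY", crit)$fp_pass)
  # ZW call tests males instead
  r <- false_positive_test(c(rep(1L, 5), rep(2L, 9)),
                           rep(c("M", "F"), c(5, 9)), "ZW", crit)
  expect_true(r$fp_pass)
  # no called homogametic samples -> unevaluable fail
  r <- false_positive_test(c(2L, 2L, NA), c("M", "M", "F"), "XY", crit)
  expect_false(r$fp_pass)
  expect_false(r$fp_evaluable)
})

test_that("scan auto-enables strict mode below 13 per sex and can be overridden", {
  d <- make_perfect_xy()
  expect_message(scan <- scan_sex_linked(d$snp, d$pa, d$sheet),
                 "strict mode auto-enabled")
  expect_true(attr(scan, "strict_used"))
  expect_true(all(scan$linkage_class[scan$reported] == "PERFECT"))
  scan2 <- scan_sex_linked(d$snp, d$pa, d$sheet,
                           sex_link_criteria(auto_strict = FALSE))
  expect_false(attr(scan2, "strict_used"))
})

test_that("strict-mode hits are a subset of standard-mode hits", {
  sim <- simulate_dataset(sim_config(n_males = 15, n_females = 15, n_clusters = 1,
                                     n_autosomal = 500, n_autosomal_pa = 200,
                                     n_sexlinked_snp = 20, n_sexlinked_pa = 20,
                                     discordance = 0.1, missing_rate = 0.05,
                                     seed = 55))
  std <- scan_sex_linked(sim$snp, sim$pa, sim$samples, sex_link_criteria())
  strict <- scan_sex_linked(sim$snp, sim$pa, sim$samples,
                            sex_link_criteria(strict = TRUE))
  expect_true(all(sex_linked_ids(strict) %in% sex_linked_ids(std)))
})

test_that("the vectorized scan agrees with the per-locus classifiers", {
  sim <- simulate_dataset(sim_config(n_males = 8, n_females = 7, n_clusters = 1,
                                     n_autosomal = 120, n_autosomal_pa = 60,
                                     n_sexlinked_snp = 6, n_sexlinked_pa = 6,
                                     discordance = 0.2, missing_rate = 0.15,
                                     seed = 56))
  crit <- sex_link_criteria(auto_strict = FALSE)
  scan <- scan_sex_linked(sim$snp, sim$pa, sim$samples, crit)
  m <- calls_matrix(sim$snp)
  sexes <- sim$samples$sex[match(colnames(m), sim$samples$sample_id)]
  snp_rows <- scan[scan$marker_type == "SNP", ]
  for (i in sample(seq_len(nrow(snp_rows)), 40)) {
    lid <- snp_rows$locus_id[i]
    r <- classify_snp_locus(m[lid, ], sexes, crit)
    expect_identical(snp_rows$system_call[i], r$system_call)
    expect_equal(snp_rows$het_or_present_frac_males[i],
                 r$het_or_present_frac_males)
    if (!is.na(r$system_call) && r$system_call != "NONE") {
      fp <- false_positive_test(m[lid, ], sexes, r$system_call, crit)
      expect_equal(snp_rows$fp_frac[i], fp$fp_frac)
      expect_identical(snp_rows$fp_pass[i], fp$fp_pass)
    }
  }
})

test_that("scan refuses single-sex cohorts and unknown samples", {
  d <- make_perfect_xy()
  allm <- make_sheet(d$sheet$sample_id, rep("M", 8))
  expect_error(scan_sex_linked(d$snp, d$pa, allm), "both sexes")
  expect_error(scan_sex_linked(d$snp, d$pa, d$sheet[1:3, ]), "absent from")
})

test_that("scan log conserves locus counts through the call-rate filter", {
  sim <- simulate_dataset(sim_config(n_males = 14, n_females = 14, n_clusters = 1,
                                     n_autosomal = 300, n_autosomal_pa = 100,
                                     n_sexlinked_snp = 5, n_sexlinked_pa = 5,
                                     missing_rate = 0.25, seed = 57))
  scan <- scan_sex_linked(sim$snp, sim$pa, sim$samples)
  log <- attr(scan, "log")
  expect_equal(log$n_in[log$marker_type == "SNP"], 305)
  expect_equal(sum(scan$marker_type == "SNP"),
               log$n_out[log$marker_type == "SNP"])
  expect_true(all(log$n_out + (log$n_in - log$n_out) == log$n_in))
})
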