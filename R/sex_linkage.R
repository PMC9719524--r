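# Sex-linkage scan: call-rate filter, per-locus XY/ZW concordance
# classification, false-positive homozygosity test, perfect/moderate
# linkage grading.

#' Sex-linkage filtering criteria
#'
#' Thresholds for [scan_sex_linked()] and the per-locus classifiers. The
#' defaults implement the standard pipeline: loci below 80% call rate are
#' discarded; a locus is sex-linked if it is at least 80% heterozygous (or
#' present, for PA loci) in one sex and at least 80% homozygous (absent) in
#' the opposite sex; candidate SNPs must additionally show at least 80%
#' homozygosity for a single homozygote class in the homogametic sex (the
#' false-positive test). With fewer than `auto_strict_threshold` (13)
#' individuals in either sex, chance concordance becomes likely and the
#' scan auto-enables strict mode, which requires 100% concordance.
#'
#' @param call_rate_min Minimum per-locus call rate, in `[0, 1]`.
#' @param concordance_min Minimum per-sex concordance fraction, in
#'   `(0.5, 1]`; values above 0.5 guarantee that XY and ZW calls are
#'   mutually exclusive.
#' @param strict If `TRUE`, `concordance_min` is forced to 1 (only
#'   100%-concordant loci are called).
#' @param auto_strict Auto-enable strict mode when the smaller sex has
#'   fewer than `auto_strict_threshold` individuals; set `FALSE` to
#'   override.
#' @param auto_strict_threshold Per-sex sample count below which strict
#'   mode is auto-enabled (default 13).
#' @param fp_homozygosity_min Minimum single-class homozygosity fraction in
#'   the homogametic sex for the false-positive test.
#' @param min_called_per_sex Minimum called samples per sex for a locus to
#'   be evaluable.
#' @return A `sexlink_criteria` list.
#' @export
sex_link_criteria <- function(call_rate_min = 0.8, concordance_min = 0.8,
                              strict = FALSE, auto_strict = TRUE,
                              auto_strict_threshold = 13,
                              fp_homozygosity_min = 0.8,
                              min_called_per_sex = 1) {
  stopifnot(call_rate_min >= 0, call_rate_min <= 1,
            concordance_min > 0.5, concordance_min <= 1,
            fp_homozygosity_min > 0.5, fp_homozygosity_min <= 1,
            min_called_per_sex >= 1)
  structure(list(call_rate_min = call_rate_min,
                 concordance_min = concordance_min,
                 strict = isTRUE(strict),
                 auto_strict = isTRUE(auto_strict),
                 auto_strict_threshold = auto_strict_threshold,
                 fp_homozygosity_min = fp_homozygosity_min,
                 min_called_per_sex = min_called_per_sex),
            class = "sexlink_criteria")
}

.effective_concordance <- function(criteria, strict_used) {
  if (strict_used) 1 else criteria$concordance_min
}

#' Filter loci by call rate
#'
#' Retains loci whose call rate, recomputed from the calls, is at least
#' `threshold` (inclusive).
#'
#' @param x A `dart_snp` or `dart_pa` object.
#' @param threshold Minimum call rate in `[0, 1]`.
#' @return The filtered object (same class), with attribute `n_dropped`.
#' @export
filter_call_rate <- function(x, threshold = 0.8) {
  stopifnot(threshold >= 0, threshold <= 1)
  cr <- locus_stats(x)$call_rate
  keep <- cr >= threshold - 1e-12
  out <- .subset_loci(x, keep)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

# Shared per-locus fraction computation. g: integer calls; het_state: the
# code counted as "heterozygous or present" (2 for SNP, 1 for PA).
.sex_fractions <- function(g, sexes, het_state, hom_states) {
  use_m <- sexes == "M" & !is.na(g)
  use_f <- sexes == "F" & !is.na(g)
  n_m <- sum(use_m); n_f <- sum(use_f)
  list(
    n_called_males = n_m,
    n_called_females = n_f,
    het_m = if (n_m) mean(g[use_m] == het_state) else NA_real_,
    het_f = if (n_f) mean(g[use_f] == het_state) else NA_real_,
    hom_m = if (n_m) mean(g[use_m] %in% hom_states) else NA_real_,
    hom_f = if (n_f) mean(g[use_f] %in% hom_states) else NA_real_)
}

.classify_locus <- function(g, sexes, criteria, het_state, hom_states,
                            strict_used = criteria$strict) {
  cm <- .effective_concordance(criteria, strict_used)
  fr <- .sex_fractions(g, sexes, het_state, hom_states)
  evaluable <- fr$n_called_males >= criteria$min_called_per_sex &&
    fr$n_called_females >= criteria$min_called_per_sex
  tol <- 1e-12
  if (!evaluable) {
    system_call <- NA_character_; class <- NA_character_; hom_frac <- NA_real_
  } else if (fr$het_m >= cm - tol && fr$hom_f >= cm - tol) {
    system_call <- "XY"
    hom_frac <- fr$hom_f
    class <- if (fr$het_m >= 1 - tol && fr$hom_f >= 1 - tol) "PERFECT" else "MODERATE"
  } else if (fr$het_f >= cm - tol && fr$hom_m >= cm - tol) {
    system_call <- "ZW"
    hom_frac <- fr$hom_m
    class <- if (fr$het_f >= 1 - tol && fr$hom_m >= 1 - tol) "PERFECT" else "MODERATE"
  } else {
    system_call <- "NONE"; class <- "NONE"; hom_frac <- NA_real_
  }
  tibble(system_call = system_call,
         het_or_present_frac_males = fr$het_m,
         het_or_present_frac_females = fr$het_f,
         hom_or_absent_frac = hom_frac,
         linkage_class = class,
         evaluable = evaluable,
         n_called_males = fr$n_called_males,
         n_called_females = fr$n_called_females)
}

#' Classify a single SNP locus as XY-linked, ZW-linked or unlinked
#'
#' Fractions are computed over called samples of each phenotypic sex
#' (UNKNOWN-sex samples are excluded). The locus is called `XY` when the
#' heterozygote fraction in males and the homozygote fraction (both
#' classes) in females both reach `concordance_min`; `ZW` with the sexes
#' swapped; `NONE` otherwise. The linkage class is `PERFECT` when both
#' qualifying fractions equal 1, `MODERATE` otherwise. A locus with fewer
#' than `min_called_per_sex` called samples in either sex is unevaluable
#' (`evaluable = FALSE`, `system_call = NA`).
#'
#' @param genotypes Integer vector of SNP codes (0/1/2, NA missing).
#' @param sexes Character vector (`"M"`, `"F"`, `"UNKNOWN"`), same length.
#' @param criteria A [sex_link_criteria()] object.
#' @return One-row tibble: `system_call`, `het_or_present_frac_males`,
#'   `het_or_present_frac_females`, `hom_or_absent_frac`, `linkage_class`,
#'   `evaluable`, `n_called_males`, `n_called_females`.
#' @examples
#' classify_snp_locus(rep(c(2L, 0L), c(19, 17)),
#'                    rep(c("M", "F"), c(19, 17)))  # XY, PERFECT
#' @export
classify_snp_locus <- function(genotypes, sexes, criteria = sex_link_criteria()) {
  stopifnot(length(genotypes) == length(sexes))
  .classify_locus(as.integer(genotypes), sexes, criteria,
                  het_state = 2L, hom_states = c(0L, 1L))
}

#' Classify a single presence-absence locus
#'
#' As [classify_snp_locus()] with presence in the heterogametic sex playing
#' the role of heterozygosity: `XY` when the presence fraction in males and
#' the absence fraction in females both reach the concordance threshold,
#' `ZW` mirrored.
#'
#' @param states Integer vector of PA codes (1 present, 0 absent, NA).
#' @inheritParams classify_snp_locus
#' @return One-row tibble as in [classify_snp_locus()].
#' @export
classify_pa_locus <- function(states, sexes, criteria = sex_link_criteria()) {
  stopifnot(length(states) == length(sexes))
  .classify_locus(as.integer(states), sexes, criteria,
                  het_state = 1L, hom_states = 0L)
}

#' False-positive homozygosity test for a candidate sex-linked SNP
#'
#' Chance concordance can satisfy the heterozygosity criterion with small
#' samples; a true sex-linked SNP should in addition be homozygous for a
#' single consistent allele class in the homogametic sex (females under
#' XY, males under ZW). The test passes when the fraction of called
#' homogametic-sex samples homozygous for the majority homozygote class is
#' at least `fp_homozygosity_min`.
#'
#' @inheritParams classify_snp_locus
#' @param system_call `"XY"` or `"ZW"`.
#' @return One-row tibble: `fp_frac` (majority-class homozygosity
#'   fraction), `fp_pass`, `fp_evaluable` (`FALSE`, with `fp_pass = FALSE`,
#'   when no homogametic-sex sample is called).
#' @examples
#' false_positive_test(c(rep(0L, 5), rep(1L, 4)), rep("F", 9), "XY")
#' # majority class 5/9 = 0.56 -> fail
#' @export
false_positive_test <- function(genotypes, sexes, system_call,
                                criteria = sex_link_criteria()) {
  stopifnot(system_call %in% c("XY", "ZW"),
            length(genotypes) == length(sexes))
  g <- as.integer(genotypes)
  homogametic <- if (system_call == "XY") "F" else "M"
  use <- sexes == homogametic & !is.na(g)
  if (!any(use)) {
    return(tibble(fp_frac = NA_real_, fp_pass = FALSE, fp_evaluable = FALSE))
  }
  frac <- max(sum(g[use] == 0L), sum(g[use] == 1L)) / sum(use)
  tibble(fp_frac = frac,
         fp_pass = frac >= criteria$fp_homozygosity_min - 1e-12,
         fp_evaluable = TRUE)
}

# Vectorized fraction table for a whole matrix; must agree exactly with the
# per-locus classifiers (asserted in the tests).
.scan_matrix <- function(x, samples, criteria, strict_used, type) {
  m <- calls_matrix(x)
  sex <- samples$sex[match(colnames(m), samples$sample_id)]
  het_state <- if (type == "snp") 2L else 1L
  hom_states <- if (type == "snp") c(0L, 1L) else 0L
  called <- !is.na(m)
  m_mask <- matrix(rep(sex == "M", each = nrow(m)), nrow = nrow(m))
  f_mask <- matrix(rep(sex == "F", each = nrow(m)), nrow = nrow(m))
  n_m <- unname(rowSums(called & m_mask))
  n_f <- unname(rowSums(called & f_mask))
  is_het <- !is.na(m) & m == het_state
  is_hom <- !is.na(m) & matrix(m %in% hom_states, nrow = nrow(m))
  het_m <- ifelse(n_m > 0, unname(rowSums(is_het & m_mask)) / n_m, NA_real_)
  het_f <- ifelse(n_f > 0, unname(rowSums(is_het & f_mask)) / n_f, NA_real_)
  hom_m <- ifelse(n_m > 0, unname(rowSums(is_hom & m_mask)) / n_m, NA_real_)
  hom_f <- ifelse(n_f > 0, unname(rowSums(is_hom & f_mask)) / n_f, NA_real_)
  cm <- .effective_concordance(criteria, strict_used)
  tol <- 1e-12
  evaluable <- n_m >= criteria$min_called_per_sex &
    n_f >= criteria$min_called_per_sex
  xy <- evaluable & het_m >= cm - tol & hom_f >= cm - tol
  zw <- evaluable & !xy & het_f >= cm - tol & hom_m >= cm - tol
  system_call <- dplyr::case_when(!evaluable ~ NA_character_,
                                  xy ~ "XY", zw ~ "ZW", TRUE ~ "NONE")
  perfect <- (xy & het_m >= 1 - tol & hom_f >= 1 - tol) |
    (zw & het_f >= 1 - tol & hom_m >= 1 - tol)
  linkage_class <- dplyr::case_when(
    !evaluable ~ NA_character_,
    perfect ~ "PERFECT",
    xy | zw ~ "MODERATE",
    TRUE ~ "NONE")
  res <- tibble(
    locus_id = x$locus_id,
    marker_type = toupper(type),
    system_call = system_call,
    het_or_present_frac_males = het_m,
    het_or_present_frac_females = het_f,
    hom_or_absent_frac = ifelse(xy, hom_f, ifelse(zw, hom_m, NA_real_)),
    linkage_class = linkage_class,
    evaluable = evaluable,
    n_called_males = n_m,
    n_called_females = n_f)

  if (type == "snp") {
    fp_frac <- rep(NA_real_, nrow(res)); fp_pass <- rep(NA, nrow(res))
    cand <- which(xy | zw)
    if (length(cand)) {
      # per-candidate loop: candidates are few relative to loci
      for (i in cand) {
        fp <- false_positive_test(m[i, ], sex, res$system_call[i], criteria)
        fp_frac[i] <- fp$fp_frac
        fp_pass[i] <- fp$fp_pass
      }
    }
    res$fp_frac <- fp_frac
    res$fp_pass <- fp_pass
    res$reported <- !is.na(res$system_call) & res$system_call != "NONE" &
      !is.na(fp_pass) & fp_pass
  } else {
    res$fp_frac <- NA_real_
    res$fp_pass <- NA
    res$reported <- !is.na(res$system_call) & res$system_call != "NONE"
  }
  res
}

#' Scan SNP and PA matrices for sex-linked markers
#'
#' The full marker-discovery procedure: (1) drop loci below the call-rate
#' threshold; (2) classify every remaining locus as XY-linked, ZW-linked or
#' unlinked from its per-sex concordance fractions; (3) apply the
#' false-positive homozygosity test to candidate SNPs (PA loci have no
#' genotypic homozygosity, their presence/absence criterion is already the
#' concordance test). When either sex has fewer than
#' `auto_strict_threshold` individuals, strict mode (100% concordance) is
#' auto-enabled unless `criteria$auto_strict` or `criteria$strict` says
#' otherwise.
#'
#' @param snp A `dart_snp` object, or `NULL`.
#' @param pa A `dart_pa` object, or `NULL`.
#' @param samples Sample sheet tibble (`sample_id`, `sex`, ...); every
#'   matrix sample must be present. Needs both sexes.
#' @param criteria A [sex_link_criteria()] object.
#' @return A `sexlink_scan` tibble with one row per locus that survived the
#'   call-rate filter: `locus_id`, `marker_type`, `system_call` (`"XY"`,
#'   `"ZW"`, `"NONE"`, `NA` when unevaluable), per-sex concordance
#'   fractions, `linkage_class` (`"PERFECT"`/`"MODERATE"`/`"NONE"`),
#'   `evaluable`, called counts, `fp_frac`/`fp_pass` (SNP only) and
#'   `reported` (final sex-linked call). Attributes: `strict_used`,
#'   `criteria`, `log` (per-stage locus counts). Use [glance()] for the
#'   marker-count summary and [sex_linked_ids()] for the reported ids.
#' @examples
#' sim <- simulate_dataset(sim_config(n_males = 8, n_females = 8,
#'   n_clusters = 1, n_autosomal = 100, n_autosomal_pa = 50,
#'   n_sexlinked_snp = 5, n_sexlinked_pa = 5, discordance = 0,
#'   missing_rate = 0, seed = 7))
#' scan <- scan_sex_linked(sim$snp, sim$pa, sim$samples,
#'   sex_link_criteria(auto_strict = FALSE))
#' glance(scan)
#' @export
scan_sex_linked <- function(snp = NULL, pa = NULL, samples,
                            criteria = sex_link_criteria()) {
  if (is.null(snp) && is.null(pa)) abort("need at least one of `snp`, `pa`")
  all_samples <- unique(c(if (!is.null(snp)) sample_ids(snp),
                          if (!is.null(pa)) sample_ids(pa)))
  missing_sheet <- setdiff(all_samples, samples$sample_id)
  if (length(missing_sheet)) {
    abort(paste0("samples absent from the sample sheet: ",
                 paste(head(missing_sheet, 5), collapse = ", ")))
  }
  sex <- samples$sex[match(all_samples, samples$sample_id)]
  n_m <- sum(sex == "M"); n_f <- sum(sex == "F")
  if (n_m == 0 || n_f == 0) {
    abort("both sexes must be present to scan for sex linkage")
  }
  strict_used <- criteria$strict ||
    (criteria$auto_strict && min(n_m, n_f) < criteria$auto_strict_threshold)
  if (strict_used && !criteria$strict) {
    inform(sprintf(
      "strict mode auto-enabled: %d males / %d females (< %d per sex)",
      n_m, n_f, criteria$auto_strict_threshold))
  }

  log <- list(); parts <- list()
  if (!is.null(snp)) {
    kept <- filter_call_rate(snp, criteria$call_rate_min)
    log$snp <- tibble(stage = "call_rate_filter", marker_type = "SNP",
                      n_in = nrow(snp), n_out = nrow(kept))
    parts$snp <- .scan_matrix(kept, samples, criteria, strict_used, "snp")
  }
  if (!is.null(pa)) {
    kept <- filter_call_rate(pa, criteria$call_rate_min)
    log$pa <- tibble(stage = "call_rate_filter", marker_type = "PA",
                     n_in = nrow(pa), n_out = nrow(kept))
    parts$pa <- .scan_matrix(kept, samples, criteria, strict_used, "pa")
  }
  res <- dplyr::bind_rows(parts)
  structure(res,
            class = c("sexlink_scan", class(tibble())),
            strict_used = strict_used,
            criteria = criteria,
            n_males = n_m, n_females = n_f,
            log = dplyr::bind_rows(log))
}

#' Locus ids reported as sex-linked by a scan
#'
#' @param scan A `sexlink_scan` object.
#' @param marker_type Optional filter, `"SNP"` or `"PA"`.
#' @param system Optional filter, `"XY"` or `"ZW"`.
#' @return Character vector of locus ids.
#' @export
sex_linked_ids <- function(scan, marker_type = NULL, system = NULL) {
  stopifnot(inherits(scan, "sexlink_scan"))
  keep <- scan$reported
  if (!is.null(marker_type)) keep <- keep & scan$marker_type %in% marker_type
  if (!is.null(system)) keep <- keep & scan$system_call %in% system
  scan$locus_id[keep]
}

#' @export
print.sexlink_scan <- function(x, ...) {
  cat(sprintf("<sexlink_scan> %d loci evaluated (%s mode)\n", nrow(x),
              if (attr(x, "strict_used")) "strict" else "standard"))
  print(glance(x))
  invisible(x)
}
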