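#' Recompute per-locus summary statistics from the calls
#'
#' Recomputes, from the coded calls alone, the per-locus quantities DArT
#' reports as metadata: call rate (fraction of non-missing calls), genotype
#' or state frequencies over the called samples and, for SNP loci,
#' polymorphism information content. PIC is computed in its
#' expected-heterozygosity form, `1 - sum(p_i^2)` over the two allele
#' frequencies; it is informational and never used for filtering.
#'
#' @param x A `dart_snp` or `dart_pa` object.
#' @return A tibble with one row per locus. For SNP input the columns are
#'   `locus_id`, `n_called`, `call_rate`, `freq_hom_ref`, `freq_hom_snp`,
#'   `freq_hets`, `one_ratio_ref`, `one_ratio_snp`, `allele_freq_alt`,
#'   `pic_ref`, `pic_snp`, `avg_pic`; for PA input `locus_id`, `n_called`,
#'   `call_rate`, `freq_present`, `freq_absent`. Frequencies of an
#'   all-missing locus are `NA` (call rate 0).
#' @examples
#' g <- as_dart_snp(tibble::tibble(locus_id = "L1",
#'   a = 2L, b = 2L, c = 0L, d = NA_integer_))
#' locus_stats(g)  # call_rate 0.75, freq_hets 2/3
#' @export
locus_stats <- function(x) {
  type <- .dart_type(x)
  m <- calls_matrix(x)
  n <- ncol(m)
  called <- unname(rowSums(!is.na(m)))
  call_rate <- called / n
  safe_frac <- function(cnt) ifelse(called > 0, cnt / called, NA_real_)
  if (type == "snp") {
    n_ref <- unname(rowSums(m == 0L, na.rm = TRUE))
    n_alt <- unname(rowSums(m == 1L, na.rm = TRUE))
    n_het <- unname(rowSums(m == 2L, na.rm = TRUE))
    p_alt <- ifelse(called > 0, (2 * n_alt + n_het) / (2 * called), NA_real_)
    one_ref <- safe_frac(n_ref + n_het)
    one_alt <- safe_frac(n_alt + n_het)
    # DArT-style per-allele PIC from the one-ratios; AvgPIC from the
    # allele frequencies (1 - sum p_i^2 = 2pq for a biallelic locus).
    pic1 <- function(p) 1 - (p^2 + (1 - p)^2)
    tibble(
      locus_id = x$locus_id,
      n_called = called,
      call_rate = call_rate,
      freq_hom_ref = safe_frac(n_ref),
      freq_hom_snp = safe_frac(n_alt),
      freq_hets = safe_frac(n_het),
      one_ratio_ref = one_ref,
      one_ratio_snp = one_alt,
      allele_freq_alt = p_alt,
      pic_ref = pic1(one_ref),
      pic_snp = pic1(one_alt),
      avg_pic = pic1(p_alt))
  } else {
    n_pres <- unname(rowSums(m == 1L, na.rm = TRUE))
    tibble(
      locus_id = x$locus_id,
      n_called = called,
      call_rate = call_rate,
      freq_present = safe_frac(n_pres),
      freq_absent = safe_frac(called - n_pres))
  }
}

#' Validate internal consistency of a genotype table
#'
#' Checks the container invariants: unique locus ids, calls restricted to
#' the coding alphabet (enforced on construction), stored `call_rate`
#' matching the recomputed call rate, and (SNP) stored genotype
#' frequencies summing to 1 over called samples.
#'
#' @param x A `dart_snp` or `dart_pa` object.
#' @param tol Numeric tolerance for recomputed-vs-stored comparisons.
#' @return `x` invisibly; problems are raised as warnings.
#' @export
validate_dart <- function(x, tol = 1e-6) {
  st <- locus_stats(x)
  if ("call_rate" %in% names(x)) {
    off <- which(!is.na(x$call_rate) & abs(x$call_rate - st$call_rate) > tol)
    if (length(off)) {
      warn(sprintf("call_rate mismatch at %d locus/loci (first: %s)",
                   length(off), x$locus_id[off[1]]))
    }
  }
  if (.dart_type(x) == "snp" &&
      all(c("freq_hom_ref", "freq_hom_snp", "freq_hets") %in% names(x))) {
    s <- x$freq_hom_ref + x$freq_hom_snp + x$freq_hets
    off <- which(!is.na(s) & abs(s - 1) > tol)
    if (length(off)) {
      warn(sprintf("genotype frequencies do not sum to 1 at %d locus/loci (first: %s)",
                   length(off), x$locus_id[off[1]]))
    }
  }
  invisible(x)
}
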