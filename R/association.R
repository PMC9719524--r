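# Association of candidate loci with phenotypic sex: pairwise Hamming
# distances (pairwise-complete normalization), within/between-sex distance
# summaries, Cochran-Armitage trend test.

#' Pairwise Hamming distance matrix between samples
#'
#' For each sample pair the distance is the number of loci with differing
#' codes divided by the number of loci called in both samples
#' (pairwise-complete normalization, so values lie in `[0, 1]`). Genotype
#' codes are compared as categorical states: a heterozygote differs from
#' either homozygote. A pair with no co-called loci gets an undefined
#' (`NA`) distance and raises a warning.
#'
#' @param x A `dart_snp` or `dart_pa` object.
#' @param loci Optional character vector restricting the computation to a
#'   locus subset (e.g. the reported sex-linked markers).
#' @return A `hamming_dist` object: list with `d` (symmetric distance
#'   matrix, zero diagonal), `n_overlap` (co-called locus counts) and
#'   `sample_ids`. Use [tidy()] for a long tibble and [autoplot()] for a
#'   heatmap.
#' @export
hamming_matrix <- function(x, loci = NULL) {
  m <- calls_matrix(x)
  if (!is.null(loci)) {
    keep <- rownames(m) %in% loci
    if (!any(keep)) abort("locus subset matches no loci")
    m <- m[keep, , drop = FALSE]
  }
  if (nrow(m) == 0) abort("no loci to compute distances over")
  ns <- ncol(m)
  d <- matrix(0, ns, ns, dimnames = list(colnames(m), colnames(m)))
  nov <- matrix(nrow(m), ns, ns, dimnames = dimnames(d))
  called <- !is.na(m)
  for (i in seq_len(ns - 1)) {
    for (j in (i + 1):ns) {
      both <- called[, i] & called[, j]
      nb <- sum(both)
      nov[i, j] <- nov[j, i] <- nb
      dij <- if (nb == 0) NA_real_ else sum(m[both, i] != m[both, j]) / nb
      d[i, j] <- d[j, i] <- dij
    }
  }
  diag(nov) <- rowSums(t(called))
  if (anyNA(d[upper.tri(d)])) {
    warn("some sample pairs share no called loci; their distances are NA")
  }
  structure(list(d = d, n_overlap = nov, sample_ids = colnames(m)),
            class = "hamming_dist")
}

#' @export
print.hamming_dist <- function(x, ...) {
  cat(sprintf("<hamming_dist> %d samples, mean distance %.3f\n",
              length(x$sample_ids), mean(x$d[upper.tri(x$d)], na.rm = TRUE)))
  invisible(x)
}

#' Within- and between-sex distance summary
#'
#' Arithmetic means of the pairwise distances within males, within females
#' and between the sexes, over defined (non-`NA`) pairs. A category with no
#' defined pairs yields `NA` with a warning.
#'
#' @param dm A [hamming_matrix()] result.
#' @param samples Sample sheet tibble with `sample_id` and `sex`.
#' @return One-row tibble: `mean_within_males`, `mean_within_females`,
#'   `mean_between`, plus the pair counts.
#' @export
distance_summary <- function(dm, samples) {
  stopifnot(inherits(dm, "hamming_dist"))
  sex <- samples$sex[match(dm$sample_ids, samples$sample_id)]
  if (!any(sex == "M", na.rm = TRUE) || !any(sex == "F", na.rm = TRUE)) {
    abort("both sexes must be present in the distance matrix")
  }
  ut <- upper.tri(dm$d)
  pair_sex <- function(a, b) {
    sel <- ut & outer(sex == a, sex == b) | ut & outer(sex == b, sex == a)
    vals <- dm$d[sel]
    vals[!is.na(vals)]
  }
  mm <- pair_sex("M", "M"); ff <- pair_sex("F", "F"); mf <- pair_sex("M", "F")
  mean_or_na <- function(v, what) {
    if (!length(v)) {
      warn(paste0("no defined ", what, " pairs"))
      NA_real_
    } else mean(v)
  }
  tibble(mean_within_males = mean_or_na(mm, "male-male"),
         mean_within_females = mean_or_na(ff, "female-female"),
         mean_between = mean_or_na(mf, "male-female"),
         n_pairs_males = length(mm), n_pairs_females = length(ff),
         n_pairs_between = length(mf))
}

.catt_chi2 <- function(score, y) {
  # classic Armitage trend statistic: N * r^2, r = Pearson correlation
  # between the dosage score and the binary trait
  if (var(score) == 0 || var(y) == 0) return(NA_real_)
  length(y) * cor(score, y)^2
}

#' Cochran-Armitage trend test for association with sex
#'
#' Tests for a dose-ordered association between genotype and phenotypic
#' sex. Genotype codes are mapped to alternate-allele dosage scores
#' (HOM_REF 0, HET 1, HOM_ALT 2 by default) and the classic Armitage trend
#' statistic `chi2 = N * r^2` is computed over called, known-sex samples,
#' with an asymptotic p-value from the 1-df chi-square distribution.
#' Optionally a permutation p-value is obtained by shuffling the sex
#' labels. Because the permutation distribution of the statistic is
#' discrete (heavy ties), the mid-p estimate is used --
#' `(#{chi2_perm > obs} + (#{chi2_perm == obs} + 1) / 2) / (permutations
#' + 1)` with the observed statistic included among its own ties -- which
#' keeps the null distribution of the p-value uniform.
#'
#' @inheritParams classify_snp_locus
#' @param scores Length-3 numeric: scores for HOM_REF, HET, HOM_ALT.
#' @param permutations Number of label permutations (0 = asymptotic only).
#' @param seed Optional integer seed for the permutations.
#' @return One-row tibble: `chi2`, `p_asymptotic`, `p_permutation`,
#'   `n_used`, `evaluable`. A constant genotype or single-sex input yields
#'   `chi2 = NA`, `evaluable = FALSE`.
#' @examples
#' catt_test(rep(c(2L, 0L), c(19, 17)), rep(c("M", "F"), c(19, 17)))
#' # chi2 = 36 (N = 36, perfect correlation)
#' @export
catt_test <- function(genotypes, sexes, scores = c(0, 1, 2),
                      permutations = 0, seed = NULL) {
  stopifnot(length(scores) == 3, length(genotypes) == length(sexes))
  g <- as.integer(genotypes)
  use <- !is.na(g) & sexes %in% c("M", "F")
  g <- g[use]
  y <- as.numeric(sexes[use] == "M")
  n <- length(g)
  # code -> dosage score: HOM_REF(0)->scores[1], HOM_ALT(1)->scores[3],
  # HET(2)->scores[2]
  score <- c(scores[1], scores[3], scores[2])[g + 1L]
  chi2 <- if (n < 2) NA_real_ else .catt_chi2(score, y)
  if (is.na(chi2)) {
    return(tibble(chi2 = NA_real_, p_asymptotic = NA_real_,
                  p_permutation = NA_real_, n_used = n, evaluable = FALSE))
  }
  p_perm <- NA_real_
  if (permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    stats <- vapply(seq_len(permutations), function(b) {
      .catt_chi2(score, sample(y))
    }, numeric(1))
    stats <- stats[!is.na(stats)]
    greater <- sum(stats > chi2 + 1e-9)
    ties <- sum(abs(stats - chi2) <= 1e-9)
    p_perm <- (greater + (ties + 1) / 2) / (length(stats) + 1)
  }
  tibble(chi2 = chi2,
         p_asymptotic = pchisq(chi2, df = 1, lower.tail = FALSE),
         p_permutation = p_perm, n_used = n, evaluable = TRUE)
}

#' Trend tests across a candidate locus set
#'
#' Runs [catt_test()] per locus and, because a joint test over a marker
#' panel is often wanted, also a combined test on the first principal
#' component score of the dosage matrix (an extension beyond the per-locus
#' tests; clearly labelled in the output attributes).
#'
#' @param snp A `dart_snp` object.
#' @param samples Sample sheet tibble.
#' @param loci Optional locus subset.
#' @inheritParams catt_test
#' @return A `catt_scan` tibble (one row per locus, [catt_test()] columns
#'   plus `locus_id`). Attribute `combined` holds the first-principal-score
#'   test; [glance()] reports median/min chi2, min p and the combined
#'   test.
#' @export
catt_scan <- function(snp, samples, loci = NULL, scores = c(0, 1, 2),
                      permutations = 0, seed = NULL) {
  m <- calls_matrix(snp)
  if (!is.null(loci)) {
    keep <- rownames(m) %in% loci
    if (!any(keep)) abort("locus subset matches no loci")
    m <- m[keep, , drop = FALSE]
  }
  sex <- samples$sex[match(colnames(m), samples$sample_id)]
  if (!is.null(seed)) set.seed(seed)
  res <- purrr::map_dfr(seq_len(nrow(m)), function(i) {
    catt_test(m[i, ], sex, scores = scores, permutations = permutations)
  })
  res <- dplyr::bind_cols(tibble(locus_id = rownames(m)), res)

  combined <- NULL
  if (nrow(m) >= 2 && sum(sex %in% c("M", "F")) >= 3) {
    dos <- matrix(c(0, 2, 1)[m + 1L], nrow = nrow(m))  # dosage, NA kept
    imp <- t(apply(dos, 1, function(v) {
      v[is.na(v)] <- mean(v, na.rm = TRUE); v
    }))
    keepv <- apply(imp, 1, var) > 0
    if (sum(keepv) >= 1) {
      pc1 <- prcomp(t(imp[keepv, , drop = FALSE]), center = TRUE)$x[, 1]
      usek <- sex %in% c("M", "F")
      y <- as.numeric(sex[usek] == "M")
      chi2 <- .catt_chi2(pc1[usek], y)
      combined <- tibble(
        chi2 = chi2,
        p_asymptotic = pchisq(chi2, df = 1, lower.tail = FALSE),
        n_used = sum(usek))
    }
  }
  structure(res, class = c("catt_scan", class(tibble())),
            combined = combined)
}
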