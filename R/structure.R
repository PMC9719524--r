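# Population structure: strict autosomal filtering, PCA on dosage,
# Weir-Cockerham F_ST, Nei (1972) distance, allele-level hierarchical
# AMOVA with permutation significance.

# Resolve a cluster assignment to a vector aligned with the matrix samples.
.cluster_vector <- function(x, clusters) {
  sc <- sample_ids(x)
  if (is.data.frame(clusters)) {
    cl_col <- intersect(c("cluster", "cluster_label", "pop"), names(clusters))
    if (!length(cl_col) || !"sample_id" %in% names(clusters)) {
      abort("cluster table needs `sample_id` and `cluster` columns")
    }
    cl <- clusters[[cl_col[1]]][match(sc, clusters$sample_id)]
  } else {
    cl <- if (!is.null(names(clusters))) clusters[sc] else {
      stopifnot(length(clusters) == length(sc))
      clusters
    }
  }
  factor(cl)
}

#' Strict autosomal locus filter for population-structure analysis
#'
#' Drops the identified sex-linked loci, then keeps only loci with exactly
#' 100% call rate (recomputed) and 100% reproducibility (`rep_avg`), the
#' stringent subset used for PCA, F_ST, Nei distance and AMOVA so that
#' structure estimates are not distorted by missingness, technical noise
#' or sex-chromosome signal.
#'
#' @param snp A `dart_snp` object.
#' @param sexlink_ids Character vector of sex-linked locus ids to exclude
#'   (may be empty).
#' @return The filtered `dart_snp`. Errors when no locus survives.
#' @export
filter_autosomal_strict <- function(snp, sexlink_ids = character()) {
  stopifnot(inherits(snp, "dart_snp"))
  keep <- !(snp$locus_id %in% sexlink_ids)
  cr <- locus_stats(snp)$call_rate
  keep <- keep & cr >= 1 - 1e-12
  if ("rep_avg" %in% names(snp) && !all(is.na(snp$rep_avg))) {
    keep <- keep & !is.na(snp$rep_avg) & snp$rep_avg >= 1 - 1e-12
  }
  if (!any(keep)) {
    abort(paste0("no loci pass the strict autosomal filter (100% call rate,",
                 " 100% reproducibility); relax thresholds or check input"))
  }
  .subset_loci(snp, keep)
}

# samples x loci dosage matrix (alternate-allele count), mean-imputed.
.dosage_matrix <- function(snp, impute = TRUE) {
  m <- calls_matrix(snp)
  dos <- matrix(c(0, 2, 1)[m + 1L], nrow = nrow(m), dimnames = dimnames(m))
  dos <- t(dos)  # samples x loci
  if (impute) {
    cm <- colMeans(dos, na.rm = TRUE)
    idx <- which(is.na(dos), arr.ind = TRUE)
    if (nrow(idx)) dos[idx] <- cm[idx[, 2]]
  }
  dos
}

#' Principal component analysis of the genotype matrix
#'
#' Encodes genotypes as alternate-allele dosage (0/1/2), mean-imputes
#' missing calls per locus, centers columns and eigendecomposes the sample
#' covariance (via [stats::prcomp()]).
#'
#' @param snp A `dart_snp` object with at least 2 samples and 2 loci.
#' @param n_axes Number of axes to retain in the scores.
#' @return A `pop_pca` object: `scores` (tibble, `sample_id` + `PC1..`),
#'   `explained` (variance fractions, non-increasing) and `sdev`. Errors
#'   on a constant matrix.
#' @export
pca_scores <- function(snp, n_axes = 10) {
  dos <- .dosage_matrix(snp)
  if (nrow(dos) < 2 || ncol(dos) < 2) abort("need >= 2 samples and >= 2 loci")
  keep <- apply(dos, 2, var) > 0
  if (!any(keep)) abort("genotype matrix is constant; PCA undefined")
  pc <- prcomp(dos[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  n_axes <- min(n_axes, ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(n_axes), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample_id = rownames(dos)), scores)
  structure(list(scores = scores,
                 explained = pc$sdev^2 / sum(pc$sdev^2),
                 sdev = pc$sdev),
            class = "pop_pca")
}

#' @export
print.pop_pca <- function(x, ...) {
  cat(sprintf("<pop_pca> %d samples; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$scores), 100 * x$explained[1],
              100 * (x$explained[2] %||% NA)))
  invisible(x)
}

# Per-locus Weir-Cockerham (1984) variance components for one pair of
# populations; returns the a, b, c sums over loci.
.wc_components <- function(m, cl) {
  # m: loci x samples integer codes; cl: factor of 2 levels
  lev <- levels(cl)
  comp <- vapply(seq_len(nrow(m)), function(l) {
    g <- m[l, ]
    a_sum <- 0; b_sum <- 0; c_sum <- 0
    n_i <- p_i <- h_i <- numeric(2)
    for (k in 1:2) {
      gk <- g[cl == lev[k] & !is.na(g)]
      n_i[k] <- length(gk)
      if (n_i[k] == 0) return(c(NA_real_, NA_real_, NA_real_))
      p_i[k] <- mean(c(0, 2, 1)[gk + 1L]) / 2  # alternate-allele freq
      h_i[k] <- mean(gk == 2L)
    }
    r <- 2
    nbar <- mean(n_i)
    if (nbar <= 1) return(c(NA_real_, NA_real_, NA_real_))
    nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    if (nc == 0) return(c(NA_real_, NA_real_, NA_real_))
    a <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    c(a, b, cc)
  }, numeric(3))
  comp
}

#' Pairwise Weir-Cockerham F_ST between clusters
#'
#' Multi-locus ratio-of-sums Weir & Cockerham (1984) theta for every pair
#' of clusters: `theta = sum(a) / sum(a + b + c)` over polymorphic loci
#' with data in both clusters.
#'
#' @param snp A `dart_snp` object.
#' @param clusters Cluster assignment: a tibble with `sample_id` and
#'   `cluster`, or a (named) vector aligned with the samples. Needs >= 2
#'   clusters with >= 2 samples each.
#' @return Tibble: `cluster_a`, `cluster_b`, `fst`, `n_loci_used`. `fst`
#'   is `NA` (flagged by warning) when only monomorphic loci are
#'   available.
#' @export
pairwise_fst <- function(snp, clusters) {
  cl <- .cluster_vector(snp, clusters)
  m <- calls_matrix(snp)
  keep_samples <- !is.na(cl)
  m <- m[, keep_samples, drop = FALSE]
  cl <- droplevels(cl[keep_samples])
  lev <- levels(cl)
  if (length(lev) < 2) abort("need at least two clusters")
  if (any(table(cl) < 2)) abort("each cluster needs >= 2 samples")
  pairs <- utils::combn(lev, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(p) {
    sel <- cl %in% pairs[, p]
    comp <- .wc_components(m[, sel, drop = FALSE], droplevels(cl[sel]))
    ok <- !is.na(comp[1, ])
    denom <- sum(comp[1, ok] + comp[2, ok] + comp[3, ok])
    fst <- if (sum(ok) == 0 || denom == 0) {
      warn("F_ST undefined (monomorphic or empty locus set)")
      NA_real_
    } else sum(comp[1, ok]) / denom
    tibble(cluster_a = pairs[1, p], cluster_b = pairs[2, p],
           fst = fst, n_loci_used = sum(ok))
  })
}

# Cluster allele frequencies: loci x clusters (alternate allele).
.cluster_freqs <- function(m, cl) {
  lev <- levels(cl)
  vapply(lev, function(k) {
    sub <- m[, cl == k, drop = FALSE]
    dos <- matrix(c(0, 2, 1)[sub + 1L], nrow = nrow(sub))
    rowMeans(dos, na.rm = TRUE) / 2
  }, numeric(nrow(m)))
}

#' Nei (1972) standard genetic distance between clusters
#'
#' `D = -ln( J_xy / sqrt(J_x * J_y) )` where `J_x`, `J_y`, `J_xy` are the
#' arithmetic means over loci of the homozygosity / identity sums of the
#' cluster allele frequencies.
#'
#' @inheritParams pairwise_fst
#' @return Tibble: `cluster_a`, `cluster_b`, `nei_d`, `n_loci_used`.
#' @export
nei_distance <- function(snp, clusters) {
  cl <- .cluster_vector(snp, clusters)
  m <- calls_matrix(snp)
  keep_samples <- !is.na(cl)
  m <- m[, keep_samples, drop = FALSE]
  cl <- droplevels(cl[keep_samples])
  lev <- levels(cl)
  if (length(lev) < 2) abort("need at least two clusters")
  pairs <- utils::combn(lev, 2)
  freqs <- .cluster_freqs(m, cl)
  purrr::map_dfr(seq_len(ncol(pairs)), function(pp) {
    p <- freqs[, pairs[1, pp]]; q <- freqs[, pairs[2, pp]]
    ok <- !is.na(p) & !is.na(q)
    jx <- mean(p[ok]^2 + (1 - p[ok])^2)
    jy <- mean(q[ok]^2 + (1 - q[ok])^2)
    jxy <- mean(p[ok] * q[ok] + (1 - p[ok]) * (1 - q[ok]))
    tibble(cluster_a = pairs[1, pp], cluster_b = pairs[2, pp],
           nei_d = -log(jxy / sqrt(jx * jy)), n_loci_used = sum(ok))
  })
}

#' Mean individual-pair genetic distance within each cluster
#'
#' Individual-level distance is 1 minus the mean proportion of shared
#' alleles across co-called loci (allele-sharing convention: identical
#' homozygotes share 1, heterozygote vs. anything shares at least 1/2,
#' opposite homozygotes share 0).
#'
#' @inheritParams pairwise_fst
#' @return Tibble: `cluster`, `mean_dist`, `n_pairs`.
#' @export
within_cluster_distance <- function(snp, clusters) {
  cl <- .cluster_vector(snp, clusters)
  m <- calls_matrix(snp)
  dos <- matrix(c(0, 2, 1)[m + 1L], nrow = nrow(m))
  purrr::map_dfr(levels(cl), function(k) {
    idx <- which(cl == k)
    if (length(idx) < 2) {
      return(tibble(cluster = k, mean_dist = NA_real_, n_pairs = 0L))
    }
    pairs <- utils::combn(idx, 2)
    dvals <- vapply(seq_len(ncol(pairs)), function(pp) {
      a <- dos[, pairs[1, pp]]; b <- dos[, pairs[2, pp]]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) return(NA_real_)
      mean(abs(a[ok] - b[ok]) / 2)  # 1 - allele-sharing proportion
    }, numeric(1))
    tibble(cluster = k, mean_dist = mean(dvals, na.rm = TRUE),
           n_pairs = ncol(pairs))
  })
}

# ---------------------------------------------------------------------------
# AMOVA

# Allele-level sums of squares from the 0/1 allele representation.
# For 0/1 data the SS around the group mean per locus is m * p * (1 - p)
# with m alleles and allele frequency p; summing over loci gives the
# squared-distance (allele mismatch) formulation.
.amova_ss <- function(dos, cl) {
  # dos: samples x loci dosage (0/1/2), complete data; cl: factor
  n <- nrow(dos); L <- ncol(dos)
  m_tot <- 2 * n
  tot <- colSums(dos)
  p_tot <- tot / m_tot
  ss_total <- sum(m_tot * p_tot * (1 - p_tot))
  ss_wc <- 0
  for (k in levels(cl)) {
    sub <- dos[cl == k, , drop = FALSE]
    mk <- 2 * nrow(sub)
    pk <- colSums(sub) / mk
    ss_wc <- ss_wc + sum(mk * pk * (1 - pk))
  }
  # within individuals: each heterozygote contributes (0-.5)^2+(1-.5)^2 = .5
  ss_wi <- 0.5 * sum(dos == 1)
  list(total = ss_total, among_clusters = ss_total - ss_wc,
       among_ind_within = ss_wc - ss_wi, within_ind = ss_wi)
}

.amova_components <- function(ss, cl) {
  n <- length(cl); k <- nlevels(cl)
  m_c <- 2 * as.numeric(table(cl)); M <- 2 * n
  df <- c(k - 1, n - k, n)
  ms <- c(ss$among_clusters, ss$among_ind_within, ss$within_ind) / df
  n0 <- (M - sum(m_c^2) / M) / (k - 1)
  sigma_w <- ms[3]
  sigma_b <- (ms[2] - ms[3]) / 2
  sigma_a <- (ms[1] - ms[2]) / n0
  list(df = df, ss = c(ss$among_clusters, ss$among_ind_within, ss$within_ind),
       ms = ms, sigma = c(sigma_a, sigma_b, sigma_w), n0 = n0)
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Allele-level AMOVA with three strata: between clusters, between samples
#' (individuals) within clusters, and within samples. Each diploid
#' individual contributes two allele vectors; sums of squares use allele
#' mismatch distances, and variance components come from the standard
#' method-of-moments equations (degrees of freedom `k-1`, `N-k`, `N`,
#' total `2N-1`). Negative component estimates are truncated at zero for
#' the percentage decomposition and reported raw in `sigma_raw`.
#' Significance is assessed by permutation: cluster labels of individuals
#' for the between-cluster component; alleles across individuals within
#' clusters for the between-sample component; alleles across all
#' individuals for the within-sample component.
#'
#' @inheritParams pairwise_fst
#' @param permutations Number of permutations for the significance tests.
#' @param seed Optional integer seed for the permutations.
#' @return An `amova_result` whose `table` has rows `between_clusters`,
#'   `between_samples_within_clusters`, `within_samples`, `total` and
#'   columns `df`, `sum_sq`, `mean_sq`, `sigma`, `sigma_raw`,
#'   `percent_variance`, `p_value`. Percentages sum to 100. Loci with any
#'   missing call are dropped (message). Use [tidy()] / [glance()].
#' @export
amova <- function(snp, clusters, permutations = 99, seed = NULL) {
  cl <- .cluster_vector(snp, clusters)
  m <- calls_matrix(snp)
  keep_samples <- !is.na(cl)
  m <- m[, keep_samples, drop = FALSE]
  cl <- droplevels(cl[keep_samples])
  if (nlevels(cl) < 2) abort("need at least two clusters")
  if (any(table(cl) < 2)) abort("each cluster needs >= 2 individuals")
  dos <- t(matrix(c(0, 2, 1)[m + 1L], nrow = nrow(m),
                  dimnames = dimnames(m)))
  complete <- !apply(dos, 2, anyNA)
  if (!all(complete)) {
    inform(sprintf("amova: dropping %d locus/loci with missing calls",
                   sum(!complete)))
  }
  dos <- dos[, complete, drop = FALSE]
  if (!ncol(dos)) abort("no complete loci for AMOVA")
  n <- nrow(dos); k <- nlevels(cl)

  obs <- .amova_components(.amova_ss(dos, cl), cl)
  sigma_raw <- obs$sigma
  sigma <- pmax(sigma_raw, 0)
  total_sigma <- sum(sigma)
  pct <- 100 * sigma / total_sigma

  if (!is.null(seed)) set.seed(seed)
  p_between <- p_among_ind <- p_within <- NA_real_
  if (permutations > 0) {
    # between clusters: permute individuals across clusters
    stat_a <- vapply(seq_len(permutations), function(b) {
      clp <- cl[sample.int(n)]
      .amova_components(.amova_ss(dos, clp), clp)$sigma[1]
    }, numeric(1))
    p_between <- (1 + sum(stat_a >= obs$sigma[1] - 1e-12)) / (permutations + 1)

    # explode individuals into their two allele vectors
    alleles <- matrix(0L, 2 * n, ncol(dos))
    alleles[seq(1, 2 * n, 2), ] <- pmin(dos, 1)
    alleles[seq(2, 2 * n, 2), ] <- pmax(dos - 1, 0)
    ind_of_allele <- rep(seq_len(n), each = 2)

    perm_sigma <- function(scope) {
      vapply(seq_len(permutations), function(b) {
        ord <- seq_len(2 * n)
        if (scope == "within_clusters") {
          for (kk in levels(cl)) {
            rows <- which(cl[ind_of_allele] == kk)
            ord[rows] <- rows[sample.int(length(rows))]
          }
        } else {
          ord <- sample.int(2 * n)
        }
        ap <- alleles[ord, , drop = FALSE]
        dosp <- ap[seq(1, 2 * n, 2), , drop = FALSE] +
          ap[seq(2, 2 * n, 2), , drop = FALSE]
        .amova_components(.amova_ss(dosp, cl), cl)$sigma
      }, numeric(3))
    }
    # between samples within clusters: alleles permuted within clusters
    sb <- perm_sigma("within_clusters")
    p_among_ind <- (1 + sum(sb[2, ] >= obs$sigma[2] - 1e-12)) / (permutations + 1)
    # within samples: alleles permuted across all individuals; small
    # observed within-individual variance relative to the null indicates
    # structure, so the test is left-tailed on sigma_w
    sw <- perm_sigma("all")
    p_within <- (1 + sum(sw[3, ] <= obs$sigma[3] + 1e-12)) / (permutations + 1)
  }

  table <- tibble(
    component = c("between_clusters", "between_samples_within_clusters",
                  "within_samples", "total"),
    df = c(obs$df, 2 * n - 1),
    sum_sq = c(obs$ss, sum(obs$ss)),
    mean_sq = c(obs$ms, sum(obs$ss) / (2 * n - 1)),
    sigma = c(sigma, total_sigma),
    sigma_raw = c(sigma_raw, sum(sigma_raw)),
    percent_variance = c(pct, 100),
    p_value = c(p_between, p_among_ind, p_within, NA_real_))
  structure(list(table = table, n = n, k = k, n_loci_used = ncol(dos),
                 permutations = permutations, n0 = obs$n0),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat(sprintf("<amova_result> %d individuals, %d clusters, %d loci, %d permutations\n",
              x$n, x$k, x$n_loci_used, x$permutations))
  print(x$table)
  invisible(x)
}
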