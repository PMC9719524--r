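# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written as direct, slow transcriptions of the
# definitions, sharing no code with the package internals.

# Sex-linkage classification: direct evaluation of the two inequalities.
oracle_classify <- function(g, sexes, cmin, het_state, hom_states,
                            min_called = 1) {
  gm <- g[sexes == "M"]; gf <- g[sexes == "F"]
  gm <- gm[!is.na(gm)]; gf <- gf[!is.na(gf)]
  if (length(gm) < min_called || length(gf) < min_called) {
    return(list(system = NA_character_, class = NA_character_))
  }
  het_m <- sum(gm == het_state) / length(gm)
  het_f <- sum(gf == het_state) / length(gf)
  hom_m <- sum(gm %in% hom_states) / length(gm)
  hom_f <- sum(gf %in% hom_states) / length(gf)
  if (het_m >= cmin && hom_f >= cmin) {
    list(system = "XY",
         class = if (het_m == 1 && hom_f == 1) "PERFECT" else "MODERATE")
  } else if (het_f >= cmin && hom_m >= cmin) {
    list(system = "ZW",
         class = if (het_f == 1 && hom_m == 1) "PERFECT" else "MODERATE")
  } else {
    list(system = "NONE", class = "NONE")
  }
}

# Hamming distance: per-cell double loop.
oracle_hamming <- function(m) {
  ns <- ncol(m)
  d <- matrix(0, ns, ns)
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (i == j) next
      ndiff <- 0; nov <- 0
      for (l in seq_len(nrow(m))) {
        if (!is.na(m[l, i]) && !is.na(m[l, j])) {
          nov <- nov + 1
          if (m[l, i] != m[l, j]) ndiff <- ndiff + 1
        }
      }
      d[i, j] <- if (nov == 0) NA_real_ else ndiff / nov
    }
  }
  d
}

# Cochran-Armitage trend statistic from the 2x3 contingency table
# (textbook form; equals N * r^2 for the dosage scores).
oracle_catt <- function(g, sexes, scores = c(0, 1, 2)) {
  dosage <- c(0, 2, 1)[g + 1L]  # code -> alt-allele dosage
  use <- !is.na(dosage) & sexes %in% c("M", "F")
  dosage <- dosage[use]
  case <- sexes[use] == "M"
  N <- length(dosage); R <- sum(case)
  n_i <- sapply(0:2, function(k) sum(dosage == k))
  r_i <- sapply(0:2, function(k) sum(dosage == k & case))
  s <- scores
  num <- (N * sum(s * r_i) - R * sum(s * n_i))^2
  den <- R * (N - R) * (N * sum(s^2 * n_i) - sum(s * n_i)^2)
  if (den == 0) return(NA_real_)
  N * num / den
}

# AMOVA sums of squares from explicit allele vectors and group means
# (definitional route, no allele-frequency shortcut).
oracle_amova_ss <- function(dos, cl) {
  n <- nrow(dos)
  alleles <- matrix(NA_real_, 2 * n, ncol(dos))
  for (i in seq_len(n)) {
    alleles[2 * i - 1, ] <- pmin(dos[i, ], 1)
    alleles[2 * i, ] <- pmax(dos[i, ] - 1, 0)
  }
  ind <- rep(seq_len(n), each = 2)
  grp <- cl[ind]
  ssd <- function(rows) {
    if (!length(rows)) return(0)
    mu <- colMeans(alleles[rows, , drop = FALSE])
    sum(sweep(alleles[rows, , drop = FALSE], 2, mu)^2)
  }
  total <- ssd(seq_len(2 * n))
  within_cl <- sum(sapply(levels(cl), function(k) ssd(which(grp == k))))
  within_ind <- sum(sapply(seq_len(n), function(i) ssd(which(ind == i))))
  list(total = total,
       among_clusters = total - within_cl,
       among_ind_within = within_cl - within_ind,
       within_ind = within_ind)
}

# Small deterministic genotype table builders -------------------------------

make_snp <- function(calls, locus_ids = NULL, sample_ids = NULL, ...) {
  calls <- as.matrix(calls)
  locus_ids <- locus_ids %||% sprintf("L%02d", seq_len(nrow(calls)))
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(ncol(calls)))
  tbl <- tibble::tibble(locus_id = locus_ids, ...)
  for (j in seq_along(sample_ids)) tbl[[sample_ids[j]]] <- as.integer(calls[, j])
  as_dart_snp(tbl, sample_cols = sample_ids)
}

make_pa <- function(calls, locus_ids = NULL, sample_ids = NULL, ...) {
  calls <- as.matrix(calls)
  locus_ids <- locus_ids %||% sprintf("P%02d", seq_len(nrow(calls)))
  sample_ids <- sample_ids %||% sprintf("s%02d", seq_len(ncol(calls)))
  tbl <- tibble::tibble(locus_id = locus_ids, ...)
  for (j in seq_along(sample_ids)) tbl[[sample_ids[j]]] <- as.integer(calls[, j])
  as_dart_pa(tbl, sample_cols = sample_ids)
}

make_sheet <- function(sample_ids, sexes, cluster = NA_integer_) {
  tibble::tibble(sample_id = sample_ids, sex = sexes, site = "site_1",
                 cluster = cluster)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A perfectly XY-concordant strict-mode dataset: 5 males all HET, 3 females
# all HOM_REF at every SNP locus; PA present in males, absent in females.
make_perfect_xy <- function(n_snp = 12, n_pa = 12) {
  sids <- c(sprintf("M%d", 1:5), sprintf("F%d", 1:3))
  sexes <- rep(c("M", "F"), c(5, 3))
  snp <- make_snp(matrix(rep(rep(c(2L, 0L), c(5, 3)), each = n_snp), n_snp),
                  sample_ids = sids)
  pa <- make_pa(matrix(rep(rep(c(1L, 0L), c(5, 3)), each = n_pa), n_pa),
                sample_ids = sids)
  list(snp = snp, pa = pa, sheet = make_sheet(sids, sexes))
}
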