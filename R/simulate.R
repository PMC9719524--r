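# DArTseq-like dataset simulator. Autosomal SNP divergence between clusters
# follows the Balding-Nichols model; sex-linked loci follow the expected
# XY/ZW heterozygosity (SNP) or presence (PA) pattern with a per-individual
# discordance probability.

#' Simulation configuration
#'
#' Builds the configuration for [simulate_dataset()]. Defaults emulate the
#' study conditions the package targets: a 44-frog cohort (19 males, 25
#' females) split into two genetic clusters of 36 (14M/22F) and 8 (5M/3F)
#' individuals, between-cluster divergence F_ST 0.24, 11 sex-linked SNP and
#' 24 sex-linked PA loci under male heterogamety, per-individual discordance
#' 0.1 (< 20%, the moderate-linkage bound) and 5% missing calls.
#'
#' @param n_males,n_females Individuals per cluster (scalar or one value per
#'   cluster).
#' @param n_clusters Number of genetic clusters (1 or 2).
#' @param fst_target Between-cluster divergence in `[0, 1)`; the F parameter
#'   of the Balding-Nichols allele-frequency model.
#' @param n_autosomal Number of autosomal SNP loci.
#' @param n_autosomal_pa Number of autosomal presence-absence loci.
#' @param n_sexlinked_snp,n_sexlinked_pa Number of sex-linked SNP / PA loci.
#' @param system `"XY"` (male heterogamety) or `"ZW"` (female heterogamety).
#' @param discordance Per-individual probability that a sex-linked locus
#'   violates its expected pattern, in `[0, 1)`.
#' @param missing_rate I.i.d. probability a call is missing, in `[0, 1)`.
#' @param seed Integer seed; fixes the full output bit-for-bit.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_males = c(14, 5), n_females = c(22, 3),
                       n_clusters = 2, fst_target = 0.24,
                       n_autosomal = 5000, n_autosomal_pa = 1000,
                       n_sexlinked_snp = 11, n_sexlinked_pa = 24,
                       system = c("XY", "ZW"), discordance = 0.1,
                       missing_rate = 0.05, seed = 1L) {
  system <- match.arg(system)
  stopifnot(n_clusters %in% c(1L, 2L),
            fst_target >= 0, fst_target < 1,
            discordance >= 0, discordance < 1,
            missing_rate >= 0, missing_rate < 1,
            n_autosomal >= 0, n_autosomal_pa >= 0,
            n_sexlinked_snp >= 0, n_sexlinked_pa >= 0)
  n_males <- rep_len(as.integer(n_males), n_clusters)
  n_females <- rep_len(as.integer(n_females), n_clusters)
  stopifnot(all(n_males >= 0), all(n_females >= 0),
            sum(n_males + n_females) >= 2)
  structure(list(
    n_males = n_males, n_females = n_females, n_clusters = as.integer(n_clusters),
    fst_target = fst_target, n_autosomal = as.integer(n_autosomal),
    n_autosomal_pa = as.integer(n_autosomal_pa),
    n_sexlinked_snp = as.integer(n_sexlinked_snp),
    n_sexlinked_pa = as.integer(n_sexlinked_pa),
    system = system, discordance = discordance,
    missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_config")
}

# Balding-Nichols cluster-specific allele frequency around ancestral p.
.bn_freq <- function(p, fst) {
  if (fst <= 0) return(p)
  a <- p * (1 - fst) / fst
  b <- (1 - p) * (1 - fst) / fst
  rbeta(length(p), a, b)
}

.random_seq <- function(n, len = 64L) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate a DArTseq-like dataset with known truth
#'
#' Generates a SNP matrix, a presence-absence matrix, a sample sheet and a
#' ground-truth locus table under a seeded model:
#' \itemize{
#'   \item Autosomal SNP loci: ancestral alternate-allele frequency drawn
#'     from Uniform(0.05, 0.95); cluster-specific frequencies from the
#'     Balding-Nichols Beta distribution with parameters
#'     `p(1-F)/F, (1-p)(1-F)/F` where `F = fst_target`; genotypes drawn in
#'     Hardy-Weinberg proportions within cluster.
#'   \item Sex-linked SNP loci (XY): each male heterozygous with probability
#'     `1 - discordance`, otherwise homozygous for the locus's fixed
#'     homozygote class; each female homozygous for that fixed class with
#'     probability `1 - discordance`, otherwise heterozygous. ZW mirrors
#'     with the sexes swapped.
#'   \item Sex-linked PA loci: present in the heterogametic sex and absent
#'     in the homogametic sex, each call flipped with probability
#'     `discordance`. Autosomal PA loci get cluster-specific presence
#'     frequencies by the same Balding-Nichols draw.
#'   \item Missing calls applied i.i.d. at `missing_rate`; locus metadata
#'     (CallRate, frequencies, PIC; RepAvg = 1) recomputed from the
#'     realized matrix.
#' }
#'
#' @param config A [sim_config()] object.
#' @return A `sim_dataset` list with elements `snp` (`dart_snp`), `pa`
#'   (`dart_pa`), `samples` (sample sheet tibble with `cluster`), `truth`
#'   (tibble: `locus_id`, `marker_type`, `category`, `system`,
#'   `conc_males`, `conc_females` — realized pre-missingness per-sex
#'   concordance of sex-linked loci) and `config`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_males = 5, n_females = 3,
#'   n_clusters = 1, n_autosomal = 50, n_autosomal_pa = 20,
#'   discordance = 0, missing_rate = 0, seed = 42))
#' sim$truth
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_clusters == 2 && config$fst_target == 0) {
    warn("fst_target = 0 with 2 clusters: clusters will be indistinguishable")
  }
  set.seed(config$seed)

  # --- cohort -------------------------------------------------------------
  samples <- purrr::map_dfr(seq_len(config$n_clusters), function(cl) {
    tibble(
      sample_id = c(sprintf("C%d_M%02d", cl, seq_len(config$n_males[cl])),
                    sprintf("C%d_F%02d", cl, seq_len(config$n_females[cl]))),
      sex = rep(c("M", "F"), c(config$n_males[cl], config$n_females[cl])),
      site = paste0("site_", cl),
      cluster = cl)
  })
  n <- nrow(samples)
  is_m <- samples$sex == "M"
  het_sex <- if (config$system == "XY") is_m else !is_m

  draw_genotypes <- function(freq_by_cluster) {
    # freq_by_cluster: loci x clusters matrix of alternate-allele freqs
    t(vapply(seq_len(nrow(freq_by_cluster)), function(l) {
      p <- freq_by_cluster[l, samples$cluster]
      dosage <- rbinom(n, 2L, p)
      c(0L, 2L, 1L)[dosage + 1L]  # dosage 0/1/2 -> HOM_REF/HET/HOM_ALT
    }, integer(n)))
  }

  # --- autosomal SNP ------------------------------------------------------
  snp_blocks <- list(); snp_truth <- list()
  if (config$n_autosomal > 0) {
    p_anc <- runif(config$n_autosomal, 0.05, 0.95)
    freqs <- vapply(seq_len(config$n_clusters), function(cl) {
      .bn_freq(p_anc, if (config$n_clusters > 1) config$fst_target else 0)
    }, numeric(config$n_autosomal))
    freqs <- matrix(freqs, ncol = config$n_clusters)
    g <- draw_genotypes(freqs)
    ids <- sprintf("SNPAUT_%05d", seq_len(config$n_autosomal))
    snp_blocks$aut <- g
    snp_truth$aut <- tibble(locus_id = ids, marker_type = "SNP",
                            category = "AUTOSOMAL", system = NA_character_,
                            conc_males = NA_real_, conc_females = NA_real_)
    rownames(snp_blocks$aut) <- ids
  }

  # --- sex-linked SNP -----------------------------------------------------
  if (config$n_sexlinked_snp > 0) {
    ids <- sprintf("SNPSEX_%05d", seq_len(config$n_sexlinked_snp))
    hom_class <- sample(c(0L, 1L), config$n_sexlinked_snp, replace = TRUE)
    g <- t(vapply(seq_len(config$n_sexlinked_snp), function(l) {
      concordant <- runif(n) >= config$discordance
      ifelse(het_sex == concordant, 2L, hom_class[l])
    }, integer(n)))
    rownames(g) <- ids
    snp_blocks$sex <- g
    cm <- rowMeans((g[, is_m, drop = FALSE] == 2L) == het_sex[is_m][1])
    cf <- rowMeans((g[, !is_m, drop = FALSE] == 2L) == het_sex[!is_m][1])
    snp_truth$sex <- tibble(locus_id = ids, marker_type = "SNP",
                            category = "SEXLINKED", system = config$system,
                            conc_males = cm, conc_females = cf)
  }

  # --- autosomal PA -------------------------------------------------------
  pa_blocks <- list(); pa_truth <- list()
  if (config$n_autosomal_pa > 0) {
    q_anc <- runif(config$n_autosomal_pa, 0.1, 0.9)
    freqs <- vapply(seq_len(config$n_clusters), function(cl) {
      .bn_freq(q_anc, if (config$n_clusters > 1) config$fst_target else 0)
    }, numeric(config$n_autosomal_pa))
    freqs <- matrix(freqs, ncol = config$n_clusters)
    ids <- sprintf("PAAUT_%05d", seq_len(config$n_autosomal_pa))
    g <- t(vapply(seq_len(config$n_autosomal_pa), function(l) {
      rbinom(n, 1L, freqs[l, samples$cluster])
    }, integer(n)))
    rownames(g) <- ids
    pa_blocks$aut <- g
    pa_truth$aut <- tibble(locus_id = ids, marker_type = "PA",
                           category = "AUTOSOMAL", system = NA_character_,
                           conc_males = NA_real_, conc_females = NA_real_)
  }

  # --- sex-linked PA ------------------------------------------------------
  if (config$n_sexlinked_pa > 0) {
    ids <- sprintf("PASEX_%05d", seq_len(config$n_sexlinked_pa))
    g <- t(vapply(seq_len(config$n_sexlinked_pa), function(l) {
      concordant <- runif(n) >= config$discordance
      as.integer(het_sex == concordant)
    }, integer(n)))
    rownames(g) <- ids
    pa_blocks$sex <- g
    cm <- rowMeans((g[, is_m, drop = FALSE] == 1L) == het_sex[is_m][1])
    cf <- rowMeans((g[, !is_m, drop = FALSE] == 1L) == het_sex[!is_m][1])
    pa_truth$sex <- tibble(locus_id = ids, marker_type = "PA",
                           category = "SEXLINKED", system = config$system,
                           conc_males = cm, conc_females = cf)
  }

  apply_missing <- function(g) {
    if (config$missing_rate > 0 && length(g)) {
      g[runif(length(g)) < config$missing_rate] <- NA_integer_
    }
    g
  }

  snp_calls <- apply_missing(do.call(rbind, snp_blocks))
  pa_calls <- apply_missing(do.call(rbind, pa_blocks))

  snp <- .assemble_snp(snp_calls, samples$sample_id)
  pa <- .assemble_pa(pa_calls, samples$sample_id)
  truth <- dplyr::bind_rows(c(snp_truth, pa_truth))

  structure(list(snp = snp, pa = pa, samples = samples[, c("sample_id", "sex", "site", "cluster")],
                 truth = truth, config = config),
            class = "sim_dataset")
}

# Build a dart_snp with DArT-style metadata recomputed from the calls.
.assemble_snp <- function(calls, sample_ids) {
  if (is.null(calls)) calls <- matrix(integer(0), 0, length(sample_ids))
  ids <- rownames(calls) %||% character(0)
  seqs <- .random_seq(nrow(calls))
  pos <- if (nrow(calls)) sample.int(64L, nrow(calls), replace = TRUE) - 1L else integer(0)
  bases <- c("A", "C", "G", "T")
  ref <- substr(seqs, pos + 1, pos + 1)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1),
                USE.NAMES = FALSE)
  tbl <- tibble(
    locus_id = ids,
    allele_id = ids,
    clone_id = ids,
    allele_sequence = seqs,
    trimmed_sequence = seqs,
    snp = ifelse(nchar(ids) > 0, sprintf("%d:%s>%s", pos, ref, alt), NA_character_),
    snp_position = as.numeric(pos))
  df <- as.data.frame(calls)
  names(df) <- sample_ids
  x <- as_dart_snp(dplyr::bind_cols(tbl, as_tibble(df)),
                   sample_cols = sample_ids)
  st <- locus_stats(x)
  x$call_rate <- st$call_rate
  x$one_ratio_ref <- st$one_ratio_ref
  x$one_ratio_snp <- st$one_ratio_snp
  x$freq_hom_ref <- st$freq_hom_ref
  x$freq_hom_snp <- st$freq_hom_snp
  x$freq_hets <- st$freq_hets
  x$pic_ref <- st$pic_ref
  x$pic_snp <- st$pic_snp
  x$avg_pic <- st$avg_pic
  x$avg_count_ref <- round(runif(nrow(x), 5, 60), 1)
  x$avg_count_snp <- round(runif(nrow(x), 5, 60), 1)
  x$rep_avg <- rep(1, nrow(x))
  as_dart_snp(x[, c("locus_id", .meta_cols("snp"), sample_ids)],
              sample_cols = sample_ids)
}

.assemble_pa <- function(calls, sample_ids) {
  if (is.null(calls)) calls <- matrix(integer(0), 0, length(sample_ids))
  ids <- rownames(calls) %||% character(0)
  df <- as.data.frame(calls)
  names(df) <- sample_ids
  x <- as_dart_pa(dplyr::bind_cols(
    tibble(locus_id = ids, clone_id = ids),
    as_tibble(df)), sample_cols = sample_ids)
  x$call_rate <- locus_stats(x)$call_rate
  x$rep_avg <- rep(1, nrow(x))
  as_dart_pa(x[, c("locus_id", .meta_cols("pa"), sample_ids)],
             sample_cols = sample_ids)
}

#' Write a simulated dataset to CSV files
#'
#' Writes `snp.csv`, `pa.csv`, `samples.csv` and `truth.csv` in the
#' DArTseq dialects read by [read_dart_snp()], [read_dart_pa()] and
#' [read_sample_sheet()].
#'
#' @param sim A `sim_dataset` from [simulate_dataset()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(snp = file.path(dir, "snp.csv"), pa = file.path(dir, "pa.csv"),
             samples = file.path(dir, "samples.csv"),
             truth = file.path(dir, "truth.csv"))
  write_dart_snp(sim$snp, paths[["snp"]])
  write_dart_pa(sim$pa, paths[["pa"]])
  write_sample_sheet(sim$samples, paths[["samples"]])
  readr::write_csv(sim$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sim_dataset> %d samples in %d cluster(s); %d SNP loci (%d sex-linked), %d PA loci (%d sex-linked); system %s, discordance %.2f, missing %.2f, seed %d\n",
    nrow(x$samples), cfg$n_clusters, nrow(x$snp), cfg$n_sexlinked_snp,
    nrow(x$pa), cfg$n_sexlinked_pa, cfg$system, cfg$discordance,
    cfg$missing_rate, cfg$seed))
  invisible(x)
}
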