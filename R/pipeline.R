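# End-to-end orchestration: (simulate | read) -> population structure ->
# cluster split -> per-cluster sex-linkage scans -> association -> report.

#' Pipeline configuration
#'
#' Exactly one of `sim` (a [sim_config()]) or the three input paths must be
#' given.
#'
#' @param sim A [sim_config()] object, or `NULL` to read files.
#' @param snp_path,pa_path,samples_path CSV paths in the DArTseq dialects.
#' @param criteria [sex_link_criteria()] for the scans.
#' @param cluster_mode `"GIVEN"` (use the sample sheet's `cluster` column)
#'   or `"FROM_PCA"` (2-means on the first two principal components).
#' @param permutations Permutation count for AMOVA and trend tests.
#' @param out_dir Optional output directory for the report files.
#' @param seed Integer seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, snp_path = NULL, pa_path = NULL,
                            samples_path = NULL,
                            criteria = sex_link_criteria(),
                            cluster_mode = c("GIVEN", "FROM_PCA"),
                            permutations = 99, out_dir = NULL, seed = 1L) {
  cluster_mode <- match.arg(cluster_mode)
  from_files <- !is.null(snp_path) || !is.null(pa_path) || !is.null(samples_path)
  if (is.null(sim) == !from_files) {
    abort("give exactly one of `sim` or the input file paths")
  }
  if (from_files && (is.null(snp_path) || is.null(samples_path))) {
    abort("file input needs at least `snp_path` and `samples_path`")
  }
  structure(list(sim = sim, snp_path = snp_path, pa_path = pa_path,
                 samples_path = samples_path, criteria = criteria,
                 cluster_mode = cluster_mode, permutations = permutations,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

.log_row <- function(stage, matrix, n_in, n_out) {
  tibble(stage = stage, matrix = matrix,
         n_in = as.integer(n_in), n_out = as.integer(n_out),
         n_dropped = as.integer(n_in - n_out))
}

.run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full marker-discovery pipeline
#'
#' Stages, in order: load or simulate the dataset; preliminary whole-cohort
#' sex-linkage scan (its hits are excluded from the structure analysis);
#' strict autosomal filtering, PCA, cluster assignment (given labels or
#' 2-means on the PCA scores), pairwise F_ST, Nei distance and AMOVA;
#' per-cluster sex-linkage scans (strict mode auto-enables for small
#' clusters); per-cluster Hamming-distance summaries and trend tests over
#' the reported markers. Every filter logs its in/out locus counts.
#'
#' @param config A [pipeline_config()] object.
#' @return A `sexlink_report` list: `samples` (with `cluster_used`),
#'   `structure` (`pca`, `fst`, `nei`, `within_dist`, `amova`,
#'   `n_autosomal`), `scans` (per-cluster `sexlink_scan`), `association`
#'   (per-cluster distance summaries and trend tests), `marker_counts`
#'   (tibble of reported marker counts by cluster, marker type, system and
#'   linkage class), `log`, `seed`. When `config$out_dir` is set the
#'   report is also written there (`report.json`, per-stage CSVs,
#'   candidate FASTA).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  log <- list()

  # --- load ---------------------------------------------------------------
  if (!is.null(config$sim)) {
    sim <- .run_stage("simulate", simulate_dataset(config$sim))
    snp <- sim$snp; pa <- sim$pa; samples <- sim$samples
  } else {
    snp <- .run_stage("read_snp", read_dart_snp(config$snp_path))
    pa <- if (!is.null(config$pa_path)) .run_stage("read_pa", read_dart_pa(config$pa_path)) else NULL
    samples <- .run_stage("read_samples", read_sample_sheet(config$samples_path))
  }

  # --- preliminary scan for sex-linked exclusion --------------------------
  pre <- .run_stage("preliminary_scan",
                    scan_sex_linked(snp, pa, samples, config$criteria))
  sexlink_ids <- sex_linked_ids(pre)
  log$pre <- attr(pre, "log")

  # --- population structure ----------------------------------------------
  auto <- .run_stage("autosomal_filter",
                     filter_autosomal_strict(snp, sexlink_ids))
  log$auto <- .log_row("strict_autosomal_filter", "SNP", nrow(snp), nrow(auto))
  pca <- .run_stage("pca", pca_scores(auto))

  if (config$cluster_mode == "GIVEN") {
    if (!"cluster" %in% names(samples) || all(is.na(samples$cluster))) {
      abort("cluster_mode GIVEN requires a `cluster` column in the sample sheet")
    }
    cluster_used <- samples$cluster
  } else {
    km <- kmeans(as.matrix(pca$scores[, c("PC1", "PC2")]), centers = 2,
                 nstart = 10)
    cluster_used <- km$cluster[match(samples$sample_id, pca$scores$sample_id)]
  }
  samples$cluster_used <- cluster_used

  k <- length(unique(stats::na.omit(cluster_used)))
  structure_res <- list(pca = pca, n_autosomal = nrow(auto))
  if (k >= 2) {
    cl_tbl <- tibble(sample_id = samples$sample_id, cluster = cluster_used)
    structure_res$fst <- .run_stage("fst", pairwise_fst(auto, cl_tbl))
    structure_res$nei <- .run_stage("nei", nei_distance(auto, cl_tbl))
    structure_res$within_dist <-
      .run_stage("within_dist", within_cluster_distance(auto, cl_tbl))
    structure_res$amova <-
      .run_stage("amova", amova(auto, cl_tbl,
                                permutations = config$permutations,
                                seed = config$seed + 1L))
  }

  # --- per-cluster scans and association ----------------------------------
  clusters <- sort(unique(stats::na.omit(cluster_used)))
  scans <- list(); assoc <- list(); counts <- list()
  for (cli in clusters) {
    key <- paste0("cluster_", cli)
    ids <- samples$sample_id[!is.na(cluster_used) & cluster_used == cli]
    snp_c <- .subset_samples(snp, ids)
    pa_c <- if (!is.null(pa)) .subset_samples(pa, ids) else NULL
    sc <- .run_stage(paste0("scan_", key),
                     scan_sex_linked(snp_c, pa_c, samples, config$criteria))
    scans[[key]] <- sc
    log[[paste0("scan_", key)]] <- dplyr::mutate(attr(sc, "log"), stage =
      paste0(.data$stage, "_", key))

    counts[[key]] <- tidy(sc) |>
      dplyr::filter(.data$reported) |>
      dplyr::count(.data$marker_type, .data$system_call, .data$linkage_class,
                   name = "n_markers") |>
      dplyr::mutate(cluster = cli, .before = 1)

    assoc[[key]] <- .cluster_association(snp_c, pa_c, sc, samples,
                                         config$permutations,
                                         config$seed + 10L + as.integer(cli))
  }

  marker_counts <- dplyr::bind_rows(counts)
  report <- structure(list(
    samples = samples,
    structure = structure_res,
    scans = scans,
    association = assoc,
    marker_counts = marker_counts,
    log = dplyr::bind_rows(log),
    seed = config$seed,
    criteria = config$criteria), class = "sexlink_report")

  if (!is.null(config$out_dir)) {
    write_report(report, config$out_dir, snp = snp)
  }
  report
}

# Keep only the given samples (columns) of a matrix.
.subset_samples <- function(x, ids) {
  type <- .dart_type(x)
  sc <- sample_ids(x)
  keep <- intersect(sc, ids)
  tbl <- as_tibble(as.data.frame(x))[, c("locus_id",
                                         intersect(.meta_cols(type), names(x)),
                                         keep)]
  .new_dart(tbl, type, keep)
}

.cluster_association <- function(snp_c, pa_c, scan, samples, permutations, seed) {
  out <- list()
  snp_ids <- sex_linked_ids(scan, marker_type = "SNP")
  if (length(snp_ids)) {
    dm <- hamming_matrix(snp_c, loci = snp_ids)
    out$snp_distance <- distance_summary(dm, samples)
    out$snp_hamming <- dm
    out$snp_catt <- catt_scan(snp_c, samples, loci = snp_ids,
                              permutations = permutations, seed = seed)
  }
  pa_ids <- sex_linked_ids(scan, marker_type = "PA")
  if (!is.null(pa_c) && length(pa_ids)) {
    dm <- hamming_matrix(pa_c, loci = pa_ids)
    out$pa_distance <- distance_summary(dm, samples)
    out$pa_hamming <- dm
  }
  out
}

#' Write a pipeline report to disk
#'
#' Emits `report.json` (marker counts, distance summaries, AMOVA table,
#' F_ST/Nei, log), per-stage CSV files and, when locus sequences are
#' available, a FASTA of the candidate sex-linked markers.
#'
#' @param report A `sexlink_report` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @param snp Optional `dart_snp` used for the candidate FASTA export.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir, snp = NULL) {
  stopifnot(inherits(report, "sexlink_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$marker_counts, file.path(dir, "marker_counts.csv"),
                   progress = FALSE)
  readr::write_csv(report$log, file.path(dir, "pipeline_log.csv"),
                   progress = FALSE)
  for (key in names(report$scans)) {
    readr::write_csv(as_tibble(report$scans[[key]]),
                     file.path(dir, paste0("scan_", key, ".csv")),
                     progress = FALSE)
  }
  json <- list(
    seed = report$seed,
    marker_counts = report$marker_counts,
    log = report$log)
  if (!is.null(report$structure$fst)) json$fst <- report$structure$fst
  if (!is.null(report$structure$nei)) json$nei <- report$structure$nei
  if (!is.null(report$structure$amova)) {
    json$amova <- report$structure$amova$table
    readr::write_csv(report$structure$amova$table,
                     file.path(dir, "amova.csv"), progress = FALSE)
  }
  json$distance_summaries <- purrr::imap(report$association, function(a, key) {
    out <- list()
    if (!is.null(a$snp_distance)) out$snp <- a$snp_distance
    if (!is.null(a$pa_distance)) out$pa <- a$pa_distance
    out
  })
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(snp)) {
    cand <- unique(unlist(lapply(report$scans, function(s)
      sex_linked_ids(s, marker_type = "SNP"))))
    if (length(cand) && "trimmed_sequence" %in% names(snp) &&
        !all(is.na(snp$trimmed_sequence))) {
      write_locus_fasta(snp, file.path(dir, "candidates.fasta"), loci = cand)
    }
  }
  invisible(dir)
}

#' @export
print.sexlink_report <- function(x, ...) {
  cat(sprintf("<sexlink_report> %d samples, %d cluster(s); seed %d\n",
              nrow(x$samples), length(x$scans), x$seed))
  if (nrow(x$marker_counts)) print(x$marker_counts) else cat("no reported markers\n")
  invisible(x)
}
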