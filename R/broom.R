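# broom-style tidiers for the package's result objects.

#' Tidy a sex-linkage scan
#'
#' @param x A `sexlink_scan`.
#' @param ... Unused.
#' @return The underlying per-locus tibble.
#' @method tidy sexlink_scan
#' @export
tidy.sexlink_scan <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' Summarize a sex-linkage scan
#'
#' Marker counts by type, inferred system and linkage class among reported
#' loci, plus the scan settings.
#'
#' @inheritParams tidy.sexlink_scan
#' @return A tibble with one row per (marker_type, system, class) cell.
#' @method glance sexlink_scan
#' @export
glance.sexlink_scan <- function(x, ...) {
  tbl <- as_tibble(as.data.frame(x))
  out <- tbl |>
    dplyr::filter(.data$reported) |>
    dplyr::count(.data$marker_type, .data$system_call, .data$linkage_class,
                 name = "n_markers")
  out$strict_used <- attr(x, "strict_used")
  out$n_evaluated <- nrow(tbl)
  out
}

#' @method tidy hamming_dist
#' @export
tidy.hamming_dist <- function(x, ...) {
  d <- x$d; nov <- x$n_overlap
  idx <- which(upper.tri(d), arr.ind = TRUE)
  tibble(sample_a = rownames(d)[idx[, 1]],
         sample_b = colnames(d)[idx[, 2]],
         distance = d[idx],
         n_overlap = nov[idx])
}

#' @method tidy pop_pca
#' @export
tidy.pop_pca <- function(x, ...) x$scores

#' @method glance pop_pca
#' @export
glance.pop_pca <- function(x, ...) {
  tibble(axis = seq_along(x$explained),
         explained_variance = x$explained)
}

#' @method tidy amova_result
#' @export
tidy.amova_result <- function(x, ...) x$table

#' @method glance amova_result
#' @export
glance.amova_result <- function(x, ...) {
  tbl <- x$table
  sig <- tbl$sigma[match(c("between_clusters", "between_samples_within_clusters",
                           "within_samples", "total"), tbl$component)]
  tibble(
    phi_ct = sig[1] / sig[4],
    phi_sc = if (sig[2] + sig[3] > 0) sig[2] / (sig[2] + sig[3]) else NA_real_,
    phi_it = (sig[1] + sig[2]) / sig[4],
    p_between_clusters = tbl$p_value[tbl$component == "between_clusters"],
    n = x$n, k = x$k, n_loci_used = x$n_loci_used,
    permutations = x$permutations)
}

#' @method tidy catt_scan
#' @export
tidy.catt_scan <- function(x, ...) as_tibble(as.data.frame(x))

#' @method glance catt_scan
#' @export
glance.catt_scan <- function(x, ...) {
  tbl <- as_tibble(as.data.frame(x))
  ok <- tbl$evaluable
  combined <- attr(x, "combined")
  tibble(
    n_loci = nrow(tbl),
    median_chi2 = stats::median(tbl$chi2[ok], na.rm = TRUE),
    min_chi2 = suppressWarnings(min(tbl$chi2[ok], na.rm = TRUE)),
    min_p_asymptotic = suppressWarnings(min(tbl$p_asymptotic[ok], na.rm = TRUE)),
    combined_chi2 = if (!is.null(combined)) combined$chi2 else NA_real_,
    combined_p = if (!is.null(combined)) combined$p_asymptotic else NA_real_)
}
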