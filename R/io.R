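# Readers/writers for the one-row coded DArTseq CSV dialects.
# Null alleles are "-" (ASCII) or the Unicode minus on disk; both are
# accepted on read, "-" is emitted on write.

.missing_tokens <- c("-", "−", "", "NA")

.parse_call_col <- function(chr, ok, locus_ids, sample, type) {
  chr <- trimws(chr)
  out <- rep(NA_integer_, length(chr))
  is_missing <- is.na(chr) | chr %in% .missing_tokens
  val <- suppressWarnings(as.integer(chr))
  good <- !is_missing & !is.na(val) & val %in% ok
  bad <- which(!is_missing & !good)
  if (length(bad)) {
    abort(sprintf(
      "unparseable %s call '%s' at locus %s, sample %s (expected %s or '-')",
      toupper(type), chr[bad[1]], locus_ids[bad[1]], sample,
      paste(ok, collapse = "/")))
  }
  out[good] <- val[good]
  out
}

.read_dart <- function(path, type, delim, id_col) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- readr::read_delim(path, delim = delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, na = character())
  if (nrow(raw) == 0) abort(paste0("no loci in ", path))
  meta_map <- if (type == "snp") .snp_meta_map else .pa_meta_map
  if (!id_col %in% names(raw)) {
    abort(sprintf("header must contain a '%s' column (one-row coded dialect)", id_col))
  }
  meta_present <- meta_map[meta_map %in% names(raw)]
  sample_cols <- setdiff(names(raw), unname(meta_map))
  sample_cols <- setdiff(sample_cols, id_col)
  if (!length(sample_cols)) abort("no sample columns found")

  tbl <- tibble(locus_id = trimws(raw[[id_col]]))
  num_meta <- if (type == "snp") .snp_numeric_meta else .pa_numeric_meta
  for (nm in names(meta_map)) {
    if (nm %in% names(meta_present)) {
      v <- raw[[meta_present[[nm]]]]
      if (nm %in% num_meta) {
        v <- suppressWarnings(as.numeric(v))
      } else {
        v[v %in% c("", "NA")] <- NA_character_
      }
      tbl[[nm]] <- v
    } else {
      # flagged unavailable: column present but all NA
      tbl[[nm]] <- if (nm %in% num_meta) NA_real_ else NA_character_
    }
  }
  ok <- .allowed_codes(type)
  for (s in sample_cols) {
    tbl[[s]] <- .parse_call_col(raw[[s]], ok, tbl$locus_id, s, type)
  }
  x <- .new_dart(tbl, type, sample_cols)
  attr(x, "meta_unavailable") <- setdiff(names(meta_map), names(meta_present))
  .warn_stale_call_rate(x)
  x
}

# DArT files round CallRate to ~2 decimals; warn only on real disagreement.
.warn_stale_call_rate <- function(x, tol = 0.005) {
  if (!"call_rate" %in% names(x)) return(invisible(x))
  stored <- x$call_rate
  recomputed <- locus_stats(x)$call_rate
  off <- which(!is.na(stored) & abs(stored - recomputed) > tol)
  if (length(off)) {
    warn(sprintf(
      "stored CallRate disagrees with recomputed call rate at %d locus/loci (first: %s, stored %.3f vs %.3f)",
      length(off), x$locus_id[off[1]], stored[off[1]], recomputed[off[1]]))
  }
  invisible(x)
}

#' Read a DArTseq SNP matrix (one-row coded dialect)
#'
#' Parses a CSV whose rows are loci and whose columns are the 18 DArT locus
#' metadata fields (AlleleID, CloneID, ..., RepAvg; any subset, matched by
#' header) plus one column per sample with calls coded `0` (homozygous
#' reference), `1` (homozygous alternate), `2` (heterozygous) and `-`
#' (null allele / missing). Metadata columns absent from the file are kept
#' as all-`NA` columns and listed in the `meta_unavailable` attribute.
#'
#' @param path Path to the CSV file.
#' @param delim Field delimiter (default `","`).
#' @return A [as_dart_snp()] tibble. A warning is raised when a stored
#'   `CallRate` disagrees with the call rate recomputed from the calls.
#' @examples
#' # a small synthetic example file shipped with the package
#' snp <- read_dart_snp(system.file("extdata", "synthetic_snp_mini.csv",
#'                                  package = "sexlinkr"))
#' locus_stats(snp)
#' @export
read_dart_snp <- function(path, delim = ",") {
  .read_dart(path, "snp", delim, id_col = "AlleleID")
}

#' Read a SilicoDArT presence-absence matrix
#'
#' As [read_dart_snp()] but for the dominant presence-absence dialect:
#' calls are `1` (fragment present), `0` (absent), `-` (missing); metadata
#' columns are CloneID, CallRate and RepAvg.
#'
#' @inheritParams read_dart_snp
#' @return A [as_dart_pa()] tibble.
#' @export
read_dart_pa <- function(path, delim = ",") {
  .read_dart(path, "pa", delim, id_col = "CloneID")
}

.write_dart <- function(x, path, type) {
  meta_map <- if (type == "snp") .snp_meta_map else .pa_meta_map
  id_col <- if (type == "snp") "AlleleID" else "CloneID"
  sc <- sample_ids(x)
  out <- tibble(.rows = nrow(x))
  out[[id_col]] <- x$locus_id
  for (nm in names(meta_map)) {
    hdr <- meta_map[[nm]]
    if (hdr == id_col) next
    if (nm %in% names(x)) out[[hdr]] <- x[[nm]]
  }
  for (s in sc) {
    v <- x[[s]]
    out[[s]] <- ifelse(is.na(v), "-", as.character(v))
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Write DArTseq-dialect CSV files
#'
#' Inverse of [read_dart_snp()] / [read_dart_pa()]: missing calls are
#' written as `"-"`. Reading the file back yields identical calls and
#' metadata.
#'
#' @param x A `dart_snp` or `dart_pa` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_dart_snp <- function(x, path) {
  stopifnot(inherits(x, "dart_snp"))
  .write_dart(x, path, "snp")
}

#' @rdname write_dart_snp
#' @export
write_dart_pa <- function(x, path) {
  stopifnot(inherits(x, "dart_pa"))
  .write_dart(x, path, "pa")
}

#' Read a sample sheet
#'
#' Expects columns `sample_id` (or `id`), `sex` (or `phenotypic_sex`),
#' optionally `site` and `cluster` (or `cluster_label`). Sex labels are
#' normalized to `"M"`, `"F"` or `"UNKNOWN"` (accepting e.g. "male",
#' "Female", "u", empty).
#'
#' @param path Path to the CSV file.
#' @return Tibble with columns `sample_id`, `sex`, `site`, `cluster`.
#' @export
read_sample_sheet <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  nm <- tolower(names(raw))
  pick <- function(...) {
    cand <- c(...)
    hit <- match(cand, nm)
    hit <- hit[!is.na(hit)]
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  id <- pick("sample_id", "id", "sample")
  if (is.null(id)) abort("sample sheet needs a sample_id column")
  sex <- pick("sex", "phenotypic_sex")
  if (is.null(sex)) abort("sample sheet needs a sex column")
  site <- pick("site", "location") %||% NA_character_
  cluster <- pick("cluster", "cluster_label", "pop")
  cluster <- if (is.null(cluster)) NA_integer_ else suppressWarnings(as.integer(cluster))
  out <- tibble(sample_id = trimws(id),
                sex = normalize_sex(sex),
                site = site,
                cluster = cluster)
  if (anyDuplicated(out$sample_id)) {
    abort("duplicate sample_id in sample sheet")
  }
  out
}

#' Normalize phenotypic sex labels
#'
#' @param x Character vector of sex labels.
#' @return Character vector with values `"M"`, `"F"` or `"UNKNOWN"`.
#' @export
normalize_sex <- function(x) {
  key <- toupper(trimws(as.character(x)))
  out <- dplyr::case_when(
    key %in% c("M", "MALE") ~ "M",
    key %in% c("F", "FEMALE") ~ "F",
    is.na(key) | key %in% c("", "U", "UNKNOWN", "NA") ~ "UNKNOWN",
    TRUE ~ NA_character_)
  bad <- which(is.na(out))
  if (length(bad)) {
    abort(paste0("unrecognized sex label: '", x[bad[1]], "'"))
  }
  out
}

#' Write a sample sheet CSV
#'
#' @param samples Tibble as returned by [read_sample_sheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(samples, path) {
  readr::write_csv(samples, path, progress = FALSE)
  invisible(path)
}

#' Export locus sequences as FASTA
#'
#' Writes the `trimmed_sequence` of the selected loci to a FASTA file
#' (header = locus id), e.g. to BLAST candidate sex-linked markers against
#' a reference genome.
#'
#' @param x A `dart_snp` object with a `trimmed_sequence` column.
#' @param path Output FASTA path.
#' @param loci Optional character vector of locus ids (default: all).
#' @return `path`, invisibly.
#' @export
write_locus_fasta <- function(x, path, loci = NULL) {
  stopifnot(inherits(x, "dart_snp"))
  if (!"trimmed_sequence" %in% names(x) || all(is.na(x$trimmed_sequence))) {
    abort("no trimmed_sequence metadata available for FASTA export")
  }
  keep <- if (is.null(loci)) rep(TRUE, nrow(x)) else x$locus_id %in% loci
  if (!any(keep)) abort("no matching loci to export")
  seqs <- x$trimmed_sequence[keep]
  if (anyNA(seqs)) abort("selected loci have missing sequences")
  ss <- Biostrings::DNAStringSet(seqs)
  names(ss) <- x$locus_id[keep]
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
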