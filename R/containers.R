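# In-memory genotype coding follows the DArTseq one-row dialect:
#   SNP: 0 = homozygous reference, 1 = homozygous alternate, 2 = heterozygous
#   PA : 1 = fragment present, 0 = fragment absent
# Missing ("-" on disk) is NA in memory.

#' Genotype code constants
#'
#' Integer codes used in `dart_snp` / `dart_pa` sample columns. SNP calls are
#' `HOM_REF = 0`, `HOM_ALT = 1`, `HET = 2`; presence-absence calls are
#' `PRESENT = 1`, `ABSENT = 0`. Missing calls are `NA` in memory and `"-"`
#' on disk.
#'
#' @format Named integer vector.
#' @export
dart_codes <- c(HOM_REF = 0L, HOM_ALT = 1L, HET = 2L,
                PRESENT = 1L, ABSENT = 0L)

# Locus metadata columns of the two dialects (snake_case <-> DArT header).
.snp_meta_map <- c(
  allele_id        = "AlleleID",
  clone_id         = "CloneID",
  allele_sequence  = "AlleleSequence",
  trimmed_sequence = "TrimmedSequence",
  snp              = "SNP",
  snp_position     = "SnpPosition",
  call_rate        = "CallRate",
  one_ratio_ref    = "OneRatioRef",
  one_ratio_snp    = "OneRatioSnp",
  freq_hom_ref     = "FreqHomRef",
  freq_hom_snp     = "FreqHomSnp",
  freq_hets        = "FreqHets",
  pic_ref          = "PICRef",
  pic_snp          = "PICSnp",
  avg_pic          = "AvgPIC",
  avg_count_ref    = "AvgCountRef",
  avg_count_snp    = "AvgCountSnp",
  rep_avg          = "RepAvg"
)

.pa_meta_map <- c(
  clone_id  = "CloneID",
  call_rate = "CallRate",
  rep_avg   = "RepAvg"
)

.snp_numeric_meta <- c("snp_position", "call_rate", "one_ratio_ref",
                       "one_ratio_snp", "freq_hom_ref", "freq_hom_snp",
                       "freq_hets", "pic_ref", "pic_snp", "avg_pic",
                       "avg_count_ref", "avg_count_snp", "rep_avg")
.pa_numeric_meta <- c("call_rate", "rep_avg")

.meta_cols <- function(type) {
  if (type == "snp") names(.snp_meta_map) else names(.pa_meta_map)
}

.allowed_codes <- function(type) {
  if (type == "snp") c(0L, 1L, 2L) else c(0L, 1L)
}

.dart_type <- function(x) {
  if (inherits(x, "dart_snp")) "snp"
  else if (inherits(x, "dart_pa")) "pa"
  else abort("expected a `dart_snp` or `dart_pa` object")
}

.new_dart <- function(tbl, type, sample_cols) {
  tbl <- as_tibble(tbl)
  stopifnot(all(sample_cols %in% names(tbl)), "locus_id" %in% names(tbl))
  if (anyDuplicated(tbl$locus_id)) {
    dup <- unique(tbl$locus_id[duplicated(tbl$locus_id)])
    abort(paste0("duplicate locus id(s): ", paste(head(dup, 5), collapse = ", "),
                 " (the one-row coded dialect requires unique locus ids;",
                 " two-row allele files are not supported)"))
  }
  ok <- .allowed_codes(type)
  for (s in sample_cols) {
    v <- tbl[[s]]
    if (!is.numeric(v)) abort(paste0("sample column `", s, "` is not numeric"))
    bad <- which(!is.na(v) & !(v %in% ok))
    if (length(bad)) {
      abort(sprintf("invalid %s code %s at locus %s, sample %s",
                    toupper(type), format(v[bad[1]]),
                    tbl$locus_id[bad[1]], s))
    }
    tbl[[s]] <- as.integer(v)
  }
  structure(tbl,
            class = c(paste0("dart_", type), class(as_tibble(tbl))),
            sample_cols = sample_cols)
}

#' Build a SNP genotype table
#'
#' Constructs a `dart_snp` object: a tibble with one row per locus, a
#' `locus_id` column, optional locus metadata columns (`clone_id`,
#' `trimmed_sequence`, `call_rate`, `rep_avg`, ...) and one integer column
#' per sample holding the coded calls (see [dart_codes]).
#'
#' @param tbl A data frame with `locus_id` plus sample columns.
#' @param sample_cols Character vector naming the sample columns. Defaults to
#'   every column that is not `locus_id` or a recognized metadata column.
#' @return A `dart_snp` tibble.
#' @examples
#' g <- as_dart_snp(tibble::tibble(
#'   locus_id = c("L1", "L2"),
#'   s1 = c(0L, 2L), s2 = c(2L, 1L), s3 = c(NA, 0L)))
#' sample_ids(g)
#' @export
as_dart_snp <- function(tbl, sample_cols = NULL) {
  sample_cols <- sample_cols %||%
    setdiff(names(tbl), c("locus_id", .meta_cols("snp")))
  .new_dart(tbl, "snp", sample_cols)
}

#' Build a presence-absence (SilicoDArT) table
#'
#' @inheritParams as_dart_snp
#' @return A `dart_pa` tibble (calls coded 1 = present, 0 = absent, NA
#'   missing).
#' @export
as_dart_pa <- function(tbl, sample_cols = NULL) {
  sample_cols <- sample_cols %||%
    setdiff(names(tbl), c("locus_id", .meta_cols("pa")))
  .new_dart(tbl, "pa", sample_cols)
}

#' Sample identifiers of a genotype table
#'
#' @param x A `dart_snp` or `dart_pa` object.
#' @return Character vector of sample column names.
#' @export
sample_ids <- function(x) {
  sc <- attr(x, "sample_cols")
  if (is.null(sc)) sc <- setdiff(names(x), c("locus_id", .meta_cols(.dart_type(x))))
  sc
}

#' Extract the calls as a loci x samples integer matrix
#'
#' @param x A `dart_snp` or `dart_pa` object.
#' @return Integer matrix, rownames = locus ids, colnames = sample ids,
#'   `NA` = missing.
#' @export
calls_matrix <- function(x) {
  sc <- sample_ids(x)
  m <- as.matrix(as.data.frame(x)[, sc, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- x$locus_id
  m
}

# Row-subset while keeping class + sample_cols.
.subset_loci <- function(x, keep) {
  type <- .dart_type(x)
  sc <- sample_ids(x)
  .new_dart(as_tibble(as.data.frame(x))[keep, , drop = FALSE], type, sc)
}

#' @export
print.dart_snp <- function(x, ...) {
  cat(sprintf("<dart_snp> %d loci x %d samples\n", nrow(x), length(sample_ids(x))))
  NextMethod()
}

#' @export
print.dart_pa <- function(x, ...) {
  cat(sprintf("<dart_pa> %d loci x %d samples\n", nrow(x), length(sample_ids(x))))
  NextMethod()
}
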