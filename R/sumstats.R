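#' Read a GWAS summary-statistics file
#'
#' Expects six whitespace- or tab-delimited columns: rsid, chromosome,
#' base-pair position, allele 1 (reference allele), allele 2 (alternative
#' allele), and a value column holding either the study reference-allele
#' frequency (`mode = "af"`) or the association Z-score (`mode = "z"`).
#' A header row is auto-detected from a non-numeric bp field. Malformed rows
#' (wrong field count, non-numeric fields, invalid alleles, `a1 == a2`,
#' AF outside `[0, 1]`, non-finite Z) are dropped and counted.
#'
#' @param path input text file.
#' @param mode `"af"` or `"z"`.
#' @return A data.frame of class `sumstats` with columns `rsid`, `chrom`,
#'   `bp`, `a1`, `a2`, `value`; attributes `mode` and `n_rejected`.
#' @export
read_sumstats <- function(path, mode = c("af", "z")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stopf("summary-statistics file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("no parseable rows in %s", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  # header: bp field (3rd) not numeric
  if (suppressWarnings(is.na(as.numeric(fields[[1]][3])))) {
    fields <- fields[-1]
    if (!length(fields)) stopf("no parseable rows in %s", path)
  }
  n_in <- length(fields)
  ok_len <- lengths(fields) == 6L
  m <- do.call(rbind, fields[ok_len])
  if (is.null(m)) stopf("no parseable rows in %s (expected 6 columns)", path)
  bp <- suppressWarnings(as.numeric(m[, 3]))
  value <- suppressWarnings(as.numeric(m[, 6]))
  a1 <- toupper(m[, 4]); a2 <- toupper(m[, 5])
  good <- is.finite(bp) & bp >= 1 & bp == round(bp) &
    a1 %in% VALID_BASES & a2 %in% VALID_BASES & a1 != a2 & is.finite(value)
  if (mode == "af") {
    out_of_range <- good & (value < 0 | value > 1)
    if (sum(out_of_range) > 0.5 * max(1L, sum(good))) {
      stopf(paste("mode mismatch: %d of %d rows in %s have values outside",
                  "[0, 1]; this looks like a Z-score file (use mode = \"z\")"),
            sum(out_of_range), sum(good), path)
    }
    good <- good & !out_of_range
  }
  rejected <- n_in - sum(good)
  if (!any(good)) {
    extra <- if (mode == "af" &&
                 any(is.finite(value) & (value < 0 | value > 1))) {
      " (values outside [0, 1]; mode mismatch? an association Z-score file needs mode = \"z\")"
    } else ""
    stopf("no valid rows in %s%s", path, extra)
  }
  out <- data.frame(rsid = m[good, 1], chrom = m[good, 2],
                    bp = as.integer(bp[good]), a1 = a1[good], a2 = a2[good],
                    value = value[good], stringsAsFactors = FALSE)
  attr(out, "mode") <- mode
  attr(out, "n_rejected") <- rejected
  class(out) <- c("sumstats", "data.frame")
  out
}

#' Write summary statistics in the six-column text format
#'
#' @param records a `sumstats` data.frame (or anything with the six columns).
#' @param path output file.
#' @param header write a header row?
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(records, path, header = TRUE) {
  df <- records[, c("rsid", "chrom", "bp", "a1", "a2", "value")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = header)
  invisible(path)
}

#' Align summary statistics to a reference panel
#'
#' Matches each record to the panel SNP index (by rsid, position, or both)
#' and harmonizes the value to the panel's allele orientation: when the
#' record's alleles equal the panel's `(a1, a2)` the value is kept; when they
#' equal `(a2, a1)` the value is flipped (AF becomes `1 - AF`, Z becomes
#' `-Z`) and counted; strand-ambiguous SNPs (A/T, C/G) are dropped when
#' `drop_ambiguous` is set, because a strand flip is undetectable for them;
#' anything else is unmatched and dropped. The output is ordered by panel
#' position.
#'
#' @param records a [read_sumstats()] result (or equivalent data.frame with
#'   a `mode` attribute, or pass `mode`).
#' @param panel a [reference_panel].
#' @param drop_ambiguous drop strand-ambiguous SNPs (default `TRUE`).
#' @param match_by `"both"` (rsid and position, the default), `"rsid"`, or
#'   `"position"`.
#' @param mode `"af"` or `"z"`; defaults to the records' mode attribute.
#' @return An object of class `study_vector`: list with `mode`, `values`
#'   (aligned to the panel subset), `index_map` (strictly increasing panel
#'   row indices), and counts `n_matched`, `n_flipped`,
#'   `n_dropped_ambiguous`, `n_unmatched`.
#' @export
harmonize <- function(records, panel, drop_ambiguous = TRUE,
                      match_by = c("both", "rsid", "position"),
                      mode = NULL) {
  match_by <- match.arg(match_by)
  stopifnot(inherits(panel, "reference_panel"))
  mode <- mode %||% attr(records, "mode")
  if (is.null(mode)) stopf("records carry no mode; pass mode = \"af\" or \"z\"")
  n_in <- nrow(records)
  key <- function(df, what) {
    switch(what,
           rsid = df$rsid,
           position = paste(df$chrom, df$bp, sep = ":"),
           both = paste(df$rsid, df$chrom, df$bp, sep = ":"))
  }
  pos <- match(key(records, match_by), key(panel$snps, match_by))
  hit <- !is.na(pos)
  # allele comparison for matched records
  pa1 <- panel$snps$a1[pos[hit]]; pa2 <- panel$snps$a2[pos[hit]]
  ra1 <- records$a1[hit]; ra2 <- records$a2[hit]
  same <- ra1 == pa1 & ra2 == pa2
  swapped <- ra1 == pa2 & ra2 == pa1
  ambig <- is_ambiguous_pair(ra1, ra2)
  use <- (same | swapped)
  dropped_ambig <- 0L
  if (drop_ambiguous) {
    dropped_ambig <- sum(use & ambig)
    use <- use & !ambig
  }
  values <- records$value[hit][use]
  flip <- swapped[use]
  if (any(flip)) {
    values[flip] <- if (mode == "af") 1 - values[flip] else -values[flip]
  }
  idx <- pos[hit][use]
  o <- order(idx)
  idx <- idx[o]; values <- values[o]; flip <- flip[o]
  if (anyDuplicated(idx)) {
    keep <- !duplicated(idx)
    values <- values[keep]; flip <- flip[keep]; idx <- idx[keep]
  }
  if (!length(idx)) stopf("no summary-statistics SNP matched the panel")
  structure(
    list(mode = mode, values = values, index_map = idx,
         n_matched = length(idx), n_flipped = sum(flip),
         n_dropped_ambiguous = dropped_ambig,
         n_unmatched = n_in - length(idx) - dropped_ambig),
    class = "study_vector")
}

#' Construct a study vector directly from values aligned to a panel
#'
#' Convenience constructor used when study allele frequencies or Z-scores are
#' produced in panel order (e.g. by the cohort simulator) and no file
#' harmonization is needed.
#'
#' @param values numeric vector.
#' @param mode `"af"` or `"z"`.
#' @param index_map panel row indices (default: `seq_along(values)`).
#' @return A `study_vector`.
#' @export
study_vector <- function(values, mode = c("af", "z"),
                         index_map = seq_along(values)) {
  mode <- match.arg(mode)
  if (length(values) != length(index_map)) {
    stopf("values and index_map lengths differ")
  }
  if (is.unsorted(index_map, strictly = TRUE)) {
    stopf("index_map must be strictly increasing")
  }
  keep <- is.finite(values)
  structure(
    list(mode = mode, values = values[keep], index_map = index_map[keep],
         n_matched = sum(keep), n_flipped = 0L, n_dropped_ambiguous = 0L,
         n_unmatched = sum(!keep)),
    class = "study_vector")
}

#' @export
print.study_vector <- function(x, ...) {
  cat(sprintf("study_vector (%s mode): %d SNPs matched, %d flipped, %d ambiguous dropped, %d unmatched\n",
              x$mode, x$n_matched, x$n_flipped, x$n_dropped_ambiguous,
              x$n_unmatched))
  invisible(x)
}
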