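#' Multi-population reference panel
#'
#' A `reference_panel` bundles an ordered SNP index, per-population metadata,
#' a matrix of reference-allele frequencies (one column per population), and,
#' optionally, per-population genotype dosage matrices. It is the container
#' every estimator in the package works against.
#'
#' Allele 1 (`a1`) is the reference allele throughout: allele frequencies and
#' dosages count copies of `a1`. Coordinates are 1-based; chromosomes are kept
#' as strings so non-autosomes ("X") are representable.
#'
#' @param snps data.frame with columns `rsid`, `chrom`, `bp`, `a1`, `a2`
#'   defining the SNP index. Row order is the panel order.
#' @param meta data.frame with columns `pop` (unique short code), `super`
#'   (super-population code) and `n` (number of subjects, >= 1). Column order
#'   of `afs` and the order of `dosages` follow `meta$pop`.
#' @param afs numeric matrix `n_snps x K` of reference-allele frequencies in
#'   `[0, 1]`; columns named by population code.
#' @param dosages optional named list (one element per population, in
#'   `meta$pop` order) of integer matrices `n_snps x n_subjects` with entries
#'   in `{0, 1, 2}` counting copies of `a1`. When present, each population's
#'   AF column must equal `colMeans`-style dosage means / 2 (tolerance 1e-12).
#' @param super_codes character vector of admissible super-population codes.
#'
#' @return An object of class `reference_panel`.
#' @seealso [load_panel()], [write_panel()], [generate_panel()]
#' @export
reference_panel <- function(snps, meta, afs,
                            dosages = NULL,
                            super_codes = default_super_codes()) {
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  need <- c("rsid", "chrom", "bp", "a1", "a2")
  if (!all(need %in% names(snps))) {
    stopf("snp index must have columns %s", paste(need, collapse = ", "))
  }
  if (nrow(snps) == 0L) stopf("empty panel: no SNPs")
  if (!all(c("pop", "super", "n") %in% names(meta))) {
    stopf("panel metadata must have columns pop, super, n")
  }
  snps$chrom <- as.character(snps$chrom)
  snps$bp <- as.integer(snps$bp)
  if (anyDuplicated(snps$rsid)) {
    stopf("duplicate rsid in panel: %s",
          paste(unique(snps$rsid[duplicated(snps$rsid)])[1:3], collapse = ", "))
  }
  if (any(snps$bp < 1L)) stopf("bp coordinates must be >= 1 (1-based)")
  if (!all(snps$a1 %in% VALID_BASES) || !all(snps$a2 %in% VALID_BASES)) {
    stopf("alleles must be one of A, C, G, T")
  }
  if (any(snps$a1 == snps$a2)) stopf("a1 must differ from a2")
  if (anyDuplicated(meta$pop)) stopf("duplicate population code in metadata")
  if (any(meta$n < 1)) stopf("each population needs n >= 1 subjects")
  if (!all(meta$super %in% super_codes)) {
    stopf("unknown super-population code(s): %s",
          paste(setdiff(meta$super, super_codes), collapse = ", "))
  }
  afs <- as.matrix(afs)
  if (nrow(afs) != nrow(snps) || ncol(afs) != nrow(meta)) {
    stopf("afs must be %d x %d (SNPs x populations)", nrow(snps), nrow(meta))
  }
  if (any(!is.finite(afs)) || any(afs < 0) || any(afs > 1)) {
    stopf("allele frequencies must lie in [0, 1]")
  }
  dimnames(afs) <- list(NULL, meta$pop)
  if (!is.null(dosages)) {
    if (!setequal(names(dosages), meta$pop)) {
      stopf("dosage list must cover exactly the panel populations")
    }
    dosages <- dosages[meta$pop]
    for (k in seq_along(dosages)) {
      D <- dosages[[k]]
      if (nrow(D) != nrow(snps)) {
        stopf("dosage/AF row-count mismatch for population %s", meta$pop[k])
      }
      if (ncol(D) != meta$n[k]) {
        stopf("population %s: dosage columns (%d) != n_subjects (%d)",
              meta$pop[k], ncol(D), meta$n[k])
      }
      if (!all(D %in% c(0L, 1L, 2L))) {
        stopf("population %s: dosages must be 0, 1 or 2", meta$pop[k])
      }
      if (max(abs(rowMeans(D) / 2 - afs[, k])) > 1e-12) {
        stopf("population %s: AF column does not match dosage means", meta$pop[k])
      }
    }
  }
  structure(
    list(snps = snps, meta = meta, afs = afs, dosages = dosages,
         super_codes = super_codes),
    class = "reference_panel")
}

#' Default super-population vocabulary
#'
#' The five continental codes used to aggregate population-level weights.
#' @return Character vector `c("AFR", "AMR", "ASN", "EUR", "SAS")`.
#' @export
default_super_codes <- function() c("AFR", "AMR", "ASN", "EUR", "SAS")

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d SNPs, %d populations, %d super populations%s\n",
              nrow(x$snps), nrow(x$meta), length(unique(x$meta$super)),
              if (is.null(x$dosages)) " (AFs only)" else ""))
  tab <- stats::aggregate(n ~ super, data = x$meta, FUN = sum)
  for (i in seq_len(nrow(tab))) {
    pops <- x$meta$pop[x$meta$super == tab$super[i]]
    cat(sprintf("  %s: %s (n = %d)\n", tab$super[i],
                paste(pops, collapse = ", "), tab$n[i]))
  }
  invisible(x)
}

n_pops <- function(panel) nrow(panel$meta)

has_dosages <- function(panel) !is.null(panel$dosages)

#' Reference-allele frequencies from a dosage matrix
#'
#' Per-SNP frequency of allele 1: the mean dosage over subjects divided by 2.
#'
#' @param dosages matrix `n_snps x n_subjects` with entries in `{0, 1, 2}`.
#' @return Numeric vector of length `n_snps` with values in `[0, 1]`.
#' @export
population_afs <- function(dosages) {
  dosages <- as.matrix(dosages)
  if (length(dosages) == 0L) stopf("empty dosage matrix")
  if (!all(dosages %in% c(0L, 1L, 2L))) stopf("dosages must be 0, 1 or 2")
  rowMeans(dosages) / 2
}

#' Aggregate population weights to super populations
#'
#' Sums the mean per-population weights of a fit over each population's
#' super-population group. Mass is conserved exactly.
#'
#' @param est an `ancestry_fit` object (see [estimate_ancestry()]), or a
#'   named numeric vector of population weights.
#' @param meta data.frame with columns `pop` and `super` mapping each
#'   population code to its super population (defaults to the panel metadata
#'   stored in the fit).
#' @return Named numeric vector of super-population weights, in sorted
#'   super-code order.
#' @export
aggregate_superpop <- function(est, meta = NULL) {
  if (inherits(est, "ancestry_fit")) {
    w <- est$weights
    meta <- meta %||% est$meta
  } else {
    w <- est
  }
  if (is.null(meta)) stopf("population metadata required for aggregation")
  if (is.null(names(w))) stopf("weights must be named by population code")
  idx <- match(names(w), meta$pop)
  if (anyNA(idx)) {
    stopf("unknown population code(s): %s",
          paste(names(w)[is.na(idx)], collapse = ", "))
  }
  sup <- meta$super[idx]
  out <- tapply(w, sup, sum)
  res <- as.numeric(out)
  names(res) <- names(out)
  res[order(names(res))]
}

# ---- serialization -------------------------------------------------------

#' Write a reference panel as tab-separated text
#'
#' Writes `panel_afs.tsv` (header `rsid chrom bp a1 a2 <POP1> ...`),
#' `panel_meta.tsv` (header `pop super n`), and, when dosages are present,
#' one `dosages_<POP>.tsv` per population (rsid column followed by one column
#' per subject).
#'
#' @param panel a [reference_panel].
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  af <- cbind(panel$snps,
              as.data.frame(signif(panel$afs, 12), check.names = FALSE))
  utils::write.table(af, file.path(dir, "panel_afs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(panel$meta, file.path(dir, "panel_meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (has_dosages(panel)) {
    for (pop in panel$meta$pop) {
      D <- panel$dosages[[pop]]
      df <- data.frame(rsid = panel$snps$rsid, D, check.names = FALSE)
      names(df) <- c("rsid", sprintf("S%d", seq_len(ncol(D))))
      utils::write.table(df, file.path(dir, sprintf("dosages_%s.tsv", pop)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  invisible(dir)
}

#' Load a reference panel from tab-separated text
#'
#' Reads the layout written by [write_panel()]: an allele-frequency table
#' with one column per population, a metadata table mapping populations to
#' super populations and subject counts, and optional per-population dosage
#' tables. SNPs whose frequencies fall outside `[0, 1]` are rejected.
#'
#' @param dir directory containing `panel_afs.tsv` / `panel_meta.tsv` /
#'   `dosages_<POP>.tsv`. Alternatively pass explicit paths below.
#' @param af_path,meta_path explicit file paths (override `dir`).
#' @param dosage_paths optional named character vector of per-population
#'   dosage file paths; `NA` or missing entries are skipped. By default any
#'   `dosages_<POP>.tsv` found next to the AF file is read.
#' @param super_codes admissible super-population codes.
#' @return A [reference_panel].
#' @export
load_panel <- function(dir = NULL, af_path = NULL, meta_path = NULL,
                       dosage_paths = NULL,
                       super_codes = default_super_codes()) {
  if (!is.null(dir)) {
    af_path <- af_path %||% file.path(dir, "panel_afs.tsv")
    meta_path <- meta_path %||% file.path(dir, "panel_meta.tsv")
  }
  if (is.null(af_path) || is.null(meta_path)) {
    stopf("need a panel directory or explicit af_path and meta_path")
  }
  for (p in c(af_path, meta_path)) {
    if (!file.exists(p)) stopf("panel file not found: %s", p)
  }
  af <- utils::read.table(af_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA)
  meta <- utils::read.table(meta_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
  if (nrow(af) == 0L) stopf("empty panel: %s has no data rows", af_path)
  miss <- setdiff(meta$pop, names(af))
  if (length(miss)) {
    stopf("AF file lacks column(s) for population(s): %s",
          paste(miss, collapse = ", "))
  }
  snps <- af[, c("rsid", "chrom", "bp", "a1", "a2")]
  if (anyDuplicated(snps$rsid)) {
    stopf("duplicate rsid in %s: %s", af_path,
          snps$rsid[duplicated(snps$rsid)][1])
  }
  afs <- as.matrix(af[, meta$pop, drop = FALSE])
  bad <- !is.finite(afs) | afs < 0 | afs > 1
  if (any(bad)) {
    keep <- rowSums(bad) == 0L
    warnf("rejecting %d SNP(s) with AF outside [0, 1]", sum(!keep))
    snps <- snps[keep, , drop = FALSE]
    afs <- afs[keep, , drop = FALSE]
    if (nrow(snps) == 0L) stopf("empty panel: no SNP passed AF validation")
  }
  dosages <- NULL
  if (is.null(dosage_paths)) {
    guess <- file.path(dirname(af_path), sprintf("dosages_%s.tsv", meta$pop))
    if (all(file.exists(guess))) {
      dosage_paths <- stats::setNames(guess, meta$pop)
    }
  }
  if (!is.null(dosage_paths)) {
    miss <- setdiff(meta$pop, names(dosage_paths))
    if (length(miss)) stopf("no dosage path for population(s): %s",
                            paste(miss, collapse = ", "))
    dosages <- lapply(meta$pop, function(pop) {
      d <- utils::read.table(dosage_paths[[pop]], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
      if (nrow(d) != nrow(snps) || !identical(d$rsid, snps$rsid)) {
        stopf("dosage/AF row mismatch for population %s", pop)
      }
      as.matrix(d[, -1, drop = FALSE])
    })
    names(dosages) <- meta$pop
  }
  reference_panel(snps, meta, afs, dosages, super_codes = super_codes)
}

#' Convert a VCF to per-population dosage tables
#'
#' Reads biallelic SNVs from a VCF 4.x file (GT field) and writes one
#' `dosages_<POP>.tsv` per population, plus `panel_afs.tsv`/`panel_meta.tsv`,
#' using a sample-to-population map. Requires the `vcfR` package.
#'
#' @param vcf_path path to a (possibly gzipped) VCF file.
#' @param sample_map data.frame with columns `sample`, `pop`, `super`.
#' @param dir output directory.
#' @param super_codes admissible super-population codes.
#' @return The [reference_panel], invisibly (also written to `dir`).
#' @export
vcf_to_panel <- function(vcf_path, sample_map, dir,
                         super_codes = default_super_codes()) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stopf("vcf_to_panel requires the vcfR package")
  }
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  keep <- nchar(fix[, "REF"]) == 1L & nchar(fix[, "ALT"]) == 1L &
    fix[, "REF"] %in% VALID_BASES & fix[, "ALT"] %in% VALID_BASES
  if (!any(keep)) stopf("no biallelic SNVs in %s", vcf_path)
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  # copies of REF (= allele 1): 2 - ALT allele count
  alt_count <- function(g) {
    ifelse(is.na(g), NA_integer_,
           vapply(strsplit(gsub("\\|", "/", g), "/"),
                  function(a) sum(a == "1"), integer(1)))
  }
  dos_all <- apply(gt, 2, alt_count)
  dos_all <- 2L - matrix(as.integer(dos_all), nrow = nrow(gt),
                         dimnames = dimnames(gt))
  if (anyNA(dos_all)) stopf("missing genotypes are not supported")
  sample_map <- as.data.frame(sample_map, stringsAsFactors = FALSE)
  miss <- setdiff(sample_map$sample, colnames(dos_all))
  if (length(miss)) stopf("sample(s) absent from VCF: %s",
                          paste(miss, collapse = ", "))
  pops <- unique(sample_map$pop)
  dosages <- lapply(pops, function(p) {
    dos_all[, sample_map$sample[sample_map$pop == p], drop = FALSE]
  })
  names(dosages) <- pops
  meta <- data.frame(
    pop = pops,
    super = sample_map$super[match(pops, sample_map$pop)],
    n = vapply(dosages, ncol, integer(1)))
  rsid <- fix[, "ID"]
  rsid[is.na(rsid) | rsid == "."] <- sprintf(
    "%s:%s", fix[is.na(rsid) | rsid == ".", "CHROM"],
    fix[is.na(rsid) | rsid == ".", "POS"])
  snps <- data.frame(rsid = rsid, chrom = fix[, "CHROM"],
                     bp = as.integer(fix[, "POS"]),
                     a1 = fix[, "REF"], a2 = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  afs <- vapply(dosages, function(D) rowMeans(D) / 2, numeric(nrow(snps)))
  panel <- reference_panel(snps, meta, afs, dosages, super_codes = super_codes)
  write_panel(panel, dir)
  invisible(panel)
}
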