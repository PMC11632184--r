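#' Default layout for a synthetic structured reference panel
#'
#' Thirteen populations in five super-population groups, mirroring the
#' coarse structure of continental human reference panels: two African-analog
#' populations (least drifted from the ancestral frequencies, as African
#' populations carry the most diversity in real panels), two admixed-American
#' analogs, four East-Asian analogs, four European analogs and one
#' South-Asian analog. `group_fst` is the drift of each super group from the
#' ancestral allele frequencies; `fst` is the additional drift of each
#' population from its group. The defaults give pairwise between-group FST of
#' roughly 0.08-0.15 and within-group FST of roughly 0.006-0.02.
#'
#' @return A list with a `pops` data.frame (`pop`, `super`, `fst`) and a
#'   named `group_fst` vector.
#' @export
sim_panel_template <- function() {
  list(
    pops = data.frame(
      pop = c("AFR1", "AFR2", "AMR1", "AMR2",
              "ASN1", "ASN2", "ASN3", "ASN4",
              "EUR1", "EUR2", "EUR3", "EUR4", "SAS1"),
      super = c("AFR", "AFR", "AMR", "AMR",
                "ASN", "ASN", "ASN", "ASN",
                "EUR", "EUR", "EUR", "EUR", "SAS"),
      fst = c(0.006, 0.005, 0.010, 0.008,
              0.004, 0.005, 0.006, 0.008,
              0.003, 0.004, 0.005, 0.006, 0.005),
      stringsAsFactors = FALSE),
    group_fst = c(AFR = 0.05, AMR = 0.04, ASN = 0.09, EUR = 0.05, SAS = 0.07))
}

#' Generate a synthetic structured reference panel
#'
#' Hierarchical Balding-Nichols construction. Per SNP an ancestral frequency
#' `q ~ Uniform(0.05, 0.95)` is drawn; each super group g draws a group
#' frequency from `Beta(q(1-Fg)/Fg, (1-q)(1-Fg)/Fg)` (skipped when
#' `group_fst` is 0, the flat single-level model); each population k draws
#' its frequency from the group frequency with its own drift `F_k`; subject
#' dosages are independent `Binomial(2, p_k)` draws. Allele frequencies are
#' recomputed from the realized dosages, so monomorphic and near-monomorphic
#' SNPs occur at their natural rates and are retained. SNPs are generated
#' independently (no linkage disequilibrium).
#'
#' @param pops data.frame with columns `pop`, `super`, `fst` (per-population
#'   drift in (0, 0.5]). Default: [sim_panel_template()].
#' @param group_fst named vector of per-super-group drift values in
#'   `[0, 0.5]`; 0 collapses the hierarchy for that group. Default from the
#'   template.
#' @param n_snps number of SNPs.
#' @param n_per_pop subjects per population (>= 2). Either a single value or
#'   one per population.
#' @param seed integer seed; the same seed reproduces the panel bit for bit.
#' @param super_codes admissible super-population codes.
#' @return A [reference_panel] with dosages.
#' @export
generate_panel <- function(pops = sim_panel_template()$pops,
                           group_fst = sim_panel_template()$group_fst,
                           n_snps = 20000, n_per_pop = 200, seed = 1,
                           super_codes = default_super_codes()) {
  pops <- as.data.frame(pops, stringsAsFactors = FALSE)
  K <- nrow(pops)
  if (K < 1) stopf("need at least one population")
  if (any(pops$fst <= 0 | pops$fst > 0.5)) {
    stopf("per-population fst must lie in (0, 0.5]")
  }
  groups <- unique(pops$super)
  if (is.null(group_fst)) group_fst <- stats::setNames(rep(0, length(groups)), groups)
  if (!all(groups %in% names(group_fst))) {
    stopf("group_fst missing entries for: %s",
          paste(setdiff(groups, names(group_fst)), collapse = ", "))
  }
  if (any(group_fst < 0 | group_fst > 0.5)) {
    stopf("group fst must lie in [0, 0.5]")
  }
  n_per_pop <- rep_len(n_per_pop, K)
  if (any(n_per_pop < 2)) stopf("n_per_pop must be >= 2")
  with_seed(seed, {
    q <- stats::runif(n_snps, 0.05, 0.95)
    bn_draw <- function(q, f) {
      if (f == 0) return(q)
      p <- stats::rbeta(length(q), q * (1 - f) / f, (1 - q) * (1 - f) / f)
      # guard against numerically degenerate beta draws
      pmin(pmax(p, 0), 1)
    }
    qg <- vapply(groups, function(g) bn_draw(q, group_fst[[g]]),
                 numeric(n_snps))
    colnames(qg) <- groups
    dosages <- vector("list", K)
    for (k in seq_len(K)) {
      pk <- bn_draw(qg[, pops$super[k]], pops$fst[k])
      dosages[[k]] <- matrix(stats::rbinom(n_snps * n_per_pop[k], 2L, pk),
                             nrow = n_snps, ncol = n_per_pop[k])
    }
    names(dosages) <- pops$pop
    afs <- vapply(dosages, function(D) rowMeans(D) / 2, numeric(n_snps))
    snps <- data.frame(
      rsid = sprintf("rs%06d", seq_len(n_snps)),
      chrom = as.character(1L + (seq_len(n_snps) - 1L) %% 22L),
      bp = 1L + 1000L * ((seq_len(n_snps) - 1L) %/% 22L) +
        (seq_len(n_snps) - 1L) %% 22L,
      a1 = c("A", "C")[1L + seq_len(n_snps) %% 2L],
      a2 = c("G", "T")[1L + seq_len(n_snps) %% 2L],
      stringsAsFactors = FALSE)
    meta <- data.frame(pop = pops$pop, super = pops$super, n = n_per_pop,
                       stringsAsFactors = FALSE)
    reference_panel(snps, meta, afs, dosages, super_codes = super_codes)
  })
}

#' Simulate a GWAS cohort by resampling reference subjects
#'
#' Builds an admixed cohort by drawing, for each source population k,
#' `n_k = round(p_k * N)` subject columns with replacement from that
#' population's panel dosage matrix, then concatenating the draws. Fractional
#' `p_k * N` are resolved by the largest-remainder method so the counts sum
#' to `N` exactly.
#'
#' @param panel a [reference_panel] carrying dosages for every source
#'   population.
#' @param proportions named numeric vector of mixing proportions over panel
#'   population codes; must sum to 1 (tolerance 1e-9).
#' @param n_subjects cohort size N.
#' @param seed integer seed.
#' @return A list of class `cohort` with elements `dosages`
#'   (`n_snps x N` matrix), `source_counts` (named integer vector),
#'   `proportions`, and the panel `snps` index.
#' @export
simulate_cohort <- function(panel, proportions, n_subjects, seed = 1) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!has_dosages(panel)) stopf("panel carries no dosages")
  if (is.null(names(proportions))) stopf("proportions must be named")
  if (abs(sum(proportions) - 1) > 1e-9) stopf("proportions must sum to 1")
  if (any(proportions < 0)) stopf("proportions must be non-negative")
  miss <- setdiff(names(proportions), panel$meta$pop)
  if (length(miss)) stopf("population(s) not in panel: %s",
                          paste(miss, collapse = ", "))
  if (!is_count(n_subjects)) stopf("n_subjects must be a positive integer")
  nk <- largest_remainder(proportions * n_subjects)
  with_seed(seed, {
    blocks <- lapply(seq_along(proportions), function(j) {
      if (nk[j] == 0L) return(NULL)
      D <- panel$dosages[[names(proportions)[j]]]
      D[, sample.int(ncol(D), nk[j], replace = TRUE), drop = FALSE]
    })
    dos <- do.call(cbind, blocks[!vapply(blocks, is.null, logical(1))])
    structure(
      list(dosages = dos,
           source_counts = stats::setNames(nk, names(proportions)),
           proportions = proportions,
           snps = panel$snps),
      class = "cohort")
  })
}

# Round x to integers preserving sum(x) (assumed integral) by assigning the
# leftover units to the largest fractional remainders.
largest_remainder <- function(x) {
  fl <- floor(x)
  deficit <- round(sum(x)) - sum(fl)
  if (deficit > 0) {
    add <- order(x - fl, decreasing = TRUE)[seq_len(deficit)]
    fl[add] <- fl[add] + 1
  }
  as.integer(fl)
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d SNPs x %d subjects\n",
              nrow(x$dosages), ncol(x$dosages)))
  src <- x$source_counts[x$source_counts > 0]
  cat("  sources:", paste(sprintf("%s=%d", names(src), src), collapse = ", "),
      "\n")
  invisible(x)
}

#' Study allele frequencies of a simulated cohort
#'
#' @param cohort a [simulate_cohort()] result.
#' @return Numeric vector of per-SNP reference-allele frequencies.
#' @export
cohort_afs <- function(cohort) population_afs(cohort$dosages)

#' Null association Z-scores for a simulated cohort
#'
#' Draws one standard-normal dummy phenotype vector shared across SNPs, then
#' for every SNP regresses the phenotype on the dosage row; the Z-score is
#' the slope estimate divided by its standard error (the t statistic of the
#' simple linear regression). Sharing a single phenotype across SNPs
#' preserves the cross-SNP correlation structure of the Z-scores, which the
#' Z-score estimator relies on. SNPs with zero genotype variance are flagged
#' invalid (`valid = FALSE`, `z = NA`).
#'
#' @param cohort a [simulate_cohort()] result with `N >= 10` subjects.
#' @param seed integer seed for the phenotype draw.
#' @return A list with `z` (numeric vector, `NA` where invalid) and `valid`
#'   (logical mask).
#' @export
simulate_zscores <- function(cohort, seed = 1) {
  G <- cohort$dosages
  N <- ncol(G)
  if (N < 10) stopf("need at least 10 subjects")
  with_seed(seed, {
    y <- stats::rnorm(N)
    yc <- y - mean(y)
    syy <- sum(yc^2)
    sxx <- rowSums(G^2) - rowSums(G)^2 / N
    valid <- sxx > 1e-12
    if (!any(valid)) stopf("no polymorphic SNPs")
    sxy <- as.numeric(G %*% yc)
    r <- sxy / sqrt(pmax(sxx, 1e-300) * syy)
    z <- r * sqrt((N - 2) / pmax(1 - r^2, 1e-300))
    z[!valid] <- NA_real_
    list(z = z, valid = valid)
  })
}

#' Read a simulation scenario from YAML
#'
#' A scenario file holds `proportions` (a map population code -> fraction),
#' `n_subjects` and optionally `seed`. The four cohort scenarios shipped
#' under `inst/extdata/scenarios/` mirror the standard benchmark mixtures:
#' cohort1 25/25/25/25 across the European-analog group, cohort2 the same
#' across the East-Asian-analog group, cohort3 equal thirds across three
#' groups, and cohort4 a 50/25/15/10 African/admixed-American mixture.
#'
#' @param path YAML file path, or the name of a shipped scenario
#'   (`"cohort1"` .. `"cohort4"`).
#' @return A list with `proportions` (named numeric), `n_subjects`, `seed`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    shipped <- system.file("extdata", "scenarios", paste0(path, ".yaml"),
                           package = "ancmix")
    if (nzchar(shipped)) path <- shipped else stopf("scenario not found: %s", path)
  }
  sc <- yaml::read_yaml(path)
  if (is.null(sc$proportions)) stopf("scenario lacks 'proportions'")
  props <- unlist(sc$proportions)
  if (abs(sum(props) - 1) > 1e-9) stopf("scenario proportions must sum to 1")
  list(proportions = props,
       n_subjects = sc$n_subjects %||% 2000L,
       seed = sc$seed %||% 1L)
}
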