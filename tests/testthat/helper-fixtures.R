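# Shared fixtures. Everything is generated in code; the acceptance-scale
# panel and scenario sweep are built lazily and cached so several test files
# can share one copy.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# Small three-population panel with dosages, for unit tests.
small_panel <- function(n_snps = 1200, n_per_pop = 60, seed = 101) {
  cache_get(sprintf("small_%d_%d_%d", n_snps, n_per_pop, seed), function() {
    pops <- data.frame(pop = c("POPA", "POPB", "POPC"),
                       super = c("AFR", "EUR", "ASN"),
                       fst = c(0.05, 0.05, 0.08))
    generate_panel(pops, group_fst = c(AFR = 0, EUR = 0, ASN = 0),
                   n_snps = n_snps, n_per_pop = n_per_pop, seed = seed)
  })
}

# Hand-built 4-SNP, 2-population AF-only panel with known alleles,
# including one strand-ambiguous (A/T) SNP.
toy_panel <- function() {
  snps <- data.frame(
    rsid = c("rs1", "rs2", "rs3", "rs4"),
    chrom = c("1", "1", "2", "X"),
    bp = c(100L, 200L, 300L, 400L),
    a1 = c("A", "C", "A", "G"),
    a2 = c("G", "T", "T", "C"),
    stringsAsFactors = FALSE)
  meta <- data.frame(pop = c("P1", "P2"), super = c("EUR", "AFR"),
                     n = c(4L, 4L))
  afs <- matrix(c(0.2, 0.5, 0.7, 0.4,
                  0.6, 0.3, 0.8, 0.9), ncol = 2,
                dimnames = list(NULL, c("P1", "P2")))
  reference_panel(snps, meta, afs)
}

sumstats_df <- function(snps, values, mode) {
  df <- data.frame(snps[, c("rsid", "chrom", "bp", "a1", "a2")],
                   value = values, stringsAsFactors = FALSE)
  attr(df, "mode") <- mode
  class(df) <- c("sumstats", "data.frame")
  df
}

# ---- acceptance-scale fixtures ------------------------------------------

# The study conditions of the scaled scenario replays: a 13-population,
# 5-super-group panel of 20000 independent SNPs with 200 subjects per
# population; cohorts of 2000 subjects; 200 quasi-independent sets and a
# 5000-pair cap for the Z-score estimator.
ACC <- list(n_snps = 20000L, n_per_pop = 200L, n_cohort = 2000L,
            n_sets_z = 200L, max_pairs = 5000L, panel_seed = 42L,
            n_seeds = 10L)

acc_panel <- function() {
  cache_get("acc_panel", function() {
    generate_panel(n_snps = ACC$n_snps, n_per_pop = ACC$n_per_pop,
                   seed = ACC$panel_seed)
  })
}

acc_scenarios <- function() {
  lapply(c(cohort1 = "cohort1", cohort2 = "cohort2",
           cohort3 = "cohort3", cohort4 = "cohort4"),
         function(nm) read_scenario(nm)$proportions)
}

acc_true_super <- function(panel, props) {
  w <- stats::setNames(rep(0, nrow(panel$meta)), panel$meta$pop)
  w[names(props)] <- props
  aggregate_superpop(w, panel$meta)
}

# Z-score sweep over the four scenarios x n_seeds replicate seeds: for each
# run, super-population weights from zmix and from the legacy baseline.
acc_zmix_sweep <- function() {
  cache_get("acc_zmix_sweep", function() {
    panel <- acc_panel()
    scenarios <- acc_scenarios()
    out <- list()
    for (nm in names(scenarios)) {
      props <- scenarios[[nm]]
      runs <- lapply(seq_len(ACC$n_seeds), function(s) {
        cohort <- simulate_cohort(panel, props, ACC$n_cohort, seed = 1000 + s)
        zs <- simulate_zscores(cohort, seed = 2000 + s)
        zv <- study_vector(zs$z, "z")
        fz <- zmix(zv, panel, n_sets = ACC$n_sets_z,
                   max_pairs_per_set = ACC$max_pairs, seed = 3000 + s)
        fl <- zmix_legacy(zv, panel, n_sets = ACC$n_sets_z)
        list(zmix = aggregate_superpop(fz),
             legacy = aggregate_superpop(fl))
      })
      out[[nm]] <- list(
        true_super = acc_true_super(panel, props),
        zmix = do.call(rbind, lapply(runs, `[[`, "zmix")),
        legacy = do.call(rbind, lapply(runs, `[[`, "legacy")))
    }
    out
  })
}
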