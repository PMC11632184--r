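#' Partition SNPs into quasi-independent strided sets
#'
#' Set g (g = 1..n_sets) contains the g-th, (g + n_sets)-th, ... SNP of the
#' index, so members of a set are far apart along the genome and effectively
#' unlinked. Empty sets (when `n_sets > n_snps`) are removed.
#'
#' @param n_snps number of (harmonized) SNPs.
#' @param n_sets number of sets (default 1000).
#' @return List of class `snp_partition`: `sets` (list of strictly increasing
#'   integer vectors) and `n_sets`.
#' @export
partition_snps <- function(n_snps, n_sets = 1000) {
  stopifnot(is_count(n_snps), is_count(n_sets))
  idx <- seq_len(n_snps)
  sets <- split(idx, (idx - 1L) %% n_sets)
  sets <- unname(sets[order(as.integer(names(sets)))])
  structure(list(sets = sets, n_sets = length(sets)), class = "snp_partition")
}

# Estimators reduce the requested set count when SNPs are scarce: below 10
# SNPs per set, within-set covariances degenerate.
effective_n_sets <- function(n_snps, n_sets) {
  if (n_snps < 10 * n_sets && n_sets > 1) {
    n_new <- max(1L, n_snps %/% 10L)
    if (n_new < n_sets) {
      warnf("only %d SNPs for %d sets; reducing to %d sets",
            n_snps, n_sets, n_new)
      return(n_new)
    }
  }
  n_sets
}

#' Standardize genotype dosages under Hardy-Weinberg proportions
#'
#' Row i is transformed as `(g - 2 p_i) / sqrt(2 p_i (1 - p_i))`, giving each
#' SNP mean zero and unit variance when `p_i` is its true allele frequency.
#'
#' @param dosages matrix `m x n` of dosages.
#' @param p allele-frequency vector of length m, strictly inside (0, 1);
#'   monomorphic SNPs must be excluded upstream.
#' @return The standardized `m x n` matrix.
#' @export
normalize_genotypes <- function(dosages, p) {
  dosages <- as.matrix(dosages)
  if (length(p) != nrow(dosages)) stopf("p must have one entry per SNP row")
  bad <- which(p <= 0 | p >= 1)
  if (length(bad)) {
    stopf("allele frequency at SNP row %d is %g; monomorphic SNPs cannot be standardized",
          bad[1], p[bad[1]])
  }
  (dosages - 2 * p) / sqrt(2 * p * (1 - p))
}

#' Per-population genotype correlations for SNP pairs
#'
#' For each pair (i, l) and each panel population k, the Pearson correlation
#' between the population's genotype vectors at SNPs i and l. Standardization
#' cancels in a correlation, so raw dosages are used. A SNP monomorphic
#' within a population contributes correlation 0 for that population (no
#' information).
#'
#' @param panel a [reference_panel] with dosages; every population needs at
#'   least 3 subjects.
#' @param pairs two-column integer matrix of SNP row indices.
#' @return Matrix `n_pairs x K` with entries in `[-1, 1]`, columns named by
#'   population.
#' @export
pair_correlations <- function(panel, pairs) {
  stopifnot(inherits(panel, "reference_panel"))
  if (!has_dosages(panel)) stopf("panel carries no dosages")
  if (any(panel$meta$n < 3)) {
    stopf("population %s has fewer than 3 subjects",
          panel$meta$pop[which(panel$meta$n < 3)[1]])
  }
  pairs <- matrix(as.integer(pairs), ncol = 2)
  snps <- sort(unique(as.integer(pairs)))
  loc <- match(pairs, snps)
  dim(loc) <- dim(pairs)
  K <- n_pops(panel)
  out <- matrix(0, nrow(pairs), K, dimnames = list(NULL, panel$meta$pop))
  for (k in seq_len(K)) {
    R <- cor_rows(panel$dosages[[k]][snps, , drop = FALSE])
    out[, k] <- R[cbind(loc[, 1], loc[, 2])]
  }
  out
}

# Row-wise correlation matrix with monomorphic rows contributing 0
# (diagonal kept at 1 for polymorphic rows).
cor_rows <- function(X) {
  Xc <- X - rowMeans(X)
  v <- rowSums(Xc^2)
  poly <- v > 1e-12
  Xs <- Xc
  Xs[poly, ] <- Xc[poly, , drop = FALSE] / sqrt(v[poly])
  Xs[!poly, ] <- 0
  R <- tcrossprod(Xs)
  # clamp rounding spill
  R[R > 1] <- 1; R[R < -1] <- -1
  R
}

#' Least squares on the probability simplex
#'
#' Solves `min ||response - design w||^2` subject to `sum(w) = 1` and
#' `0 <= w <= 1`, via quadratic programming. The returned solution is
#' certified by a Karush-Kuhn-Tucker residual below `1e-6` (relative to the
#' gradient scale); if the QP solver fails certification an exact active-set
#' refinement is run.
#'
#' @param design numeric matrix `M x K`.
#' @param response numeric vector of length M.
#' @param ridge small diagonal loading added to the normal matrix, as a
#'   fraction of its mean diagonal (default 1e-10), for rank-deficient
#'   designs.
#' @return Weight vector of length K (named after design columns).
#' @export
solve_simplex_ls <- function(design, response, ridge = 1e-10) {
  design <- as.matrix(design)
  if (!all(is.finite(design)) || !all(is.finite(response))) {
    stopf("non-finite values in the least-squares system")
  }
  if (nrow(design) != length(response)) stopf("dimension mismatch")
  K <- ncol(design)
  C <- crossprod(design)
  d <- as.numeric(crossprod(design, response))
  w <- solve_simplex_qp(C, d, ridge = ridge)
  names(w) <- colnames(design)
  w
}

# Simplex-constrained QP on normal equations: min 1/2 w'Cw - d'w on the
# probability simplex. Used by all estimators so that pooled and per-set
# solves share one code path.
solve_simplex_qp <- function(C, d, ridge = 1e-10) {
  K <- ncol(C)
  if (K == 1L) return(1)
  tr <- sum(diag(C))
  if (tr <= 0) tr <- 1
  Cr <- C + diag(ridge * tr / K, K)
  w <- tryCatch({
    res <- pracma::quadprog(Cr, -d, Aeq = matrix(1, 1, K), beq = 1,
                            lb = rep(0, K), ub = rep(1, K))
    res$xmin
  }, error = function(e) NULL)
  if (is.null(w) || kkt_residual(Cr, d, w) > 1e-6) {
    w <- simplex_qp_activeset(Cr, d)
    if (kkt_residual(Cr, d, w) > 1e-6) {
      stopf("simplex QP failed KKT certification")
    }
  }
  w <- pmin(pmax(w, 0), 1)
  w / sum(w)
}

# Relative KKT stationarity residual for min 1/2 w'Cw - d'w on the simplex.
kkt_residual <- function(C, d, w) {
  g <- as.numeric(C %*% w) - d
  mu <- sum(w * g)  # at the optimum, g_i = mu on the support
  scale <- max(1, max(abs(g)))
  on_sup <- w > 1e-9
  r1 <- if (any(on_sup)) max(abs(g[on_sup] - mu)) else 0
  r2 <- if (any(!on_sup)) max(0, max(mu - g[!on_sup])) else 0
  feas <- abs(sum(w) - 1) + max(0, -min(w))
  (max(r1, r2) / scale) + feas
}

# Exact primal active-set solver for the simplex-constrained QP. K is small
# (a few dozen populations at most), so iterating over supports is cheap.
simplex_qp_activeset <- function(C, d, max_iter = 200) {
  K <- ncol(C)
  w <- rep(1 / K, K)
  free <- rep(TRUE, K)
  for (iter in seq_len(max_iter)) {
    # equality-constrained solve on the free support
    idx <- which(free)
    A <- rbind(cbind(C[idx, idx, drop = FALSE], 1), c(rep(1, length(idx)), 0))
    rhs <- c(d[idx], 1)
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) {
      sol <- c(qr.solve(A, rhs, tol = 1e-12))
    }
    wf <- sol[seq_along(idx)]
    if (all(wf >= -1e-12)) {
      w[] <- 0; w[idx] <- pmax(wf, 0)
      # check KKT for dropped coordinates; re-add the worst violator
      g <- as.numeric(C %*% w) - d
      mu <- sol[length(sol)]
      viol <- which(!free & (mu - g) > 1e-10)
      if (!length(viol)) return(w / sum(w))
      free[viol[which.max((mu - g)[viol])]] <- TRUE
    } else {
      # step toward wf until the first coordinate hits zero; fix it there
      wcur <- w[idx]
      delta <- wf - wcur
      neg <- which(wf < 0)
      alpha <- min(wcur[neg] / (wcur[neg] - wf[neg]))
      wnew <- wcur + alpha * delta
      w[] <- 0; w[idx] <- pmax(wnew, 0)
      drop_i <- idx[which(wnew <= 1e-14)]
      free[drop_i] <- FALSE
      if (sum(free) == 1L) { w[] <- 0; w[free] <- 1; return(w) }
    }
  }
  w / sum(w)
}

# ---- shared estimator plumbing ------------------------------------------

# Subset panel rows via a study vector; apply the MAF filter and the
# all-population-monomorphic exclusion. Returns aligned study values, panel
# AF matrix, row indices into the panel, and filter diagnostics.
prepare_inputs <- function(study, panel, maf_min) {
  stopifnot(inherits(study, "study_vector"), inherits(panel, "reference_panel"))
  idx <- study$index_map
  afs <- panel$afs[idx, , drop = FALSE]
  values <- study$values
  pool_af <- rowMeans(afs)
  keep <- pmin(pool_af, 1 - pool_af) >= maf_min
  # drop SNPs monomorphic in every population regardless of the MAF setting
  keep <- keep & apply(afs > 0 & afs < 1, 1, any)
  if (study$mode == "af" && maf_min > 0) {
    keep <- keep & pmin(values, 1 - values) >= maf_min
  }
  list(values = values[keep], afs = afs[keep, , drop = FALSE],
       panel_rows = idx[keep],
       n_input = length(values), n_filtered = sum(!keep))
}

new_weight_estimate <- function(method, mean_weights, per_set_weights,
                                n_sets_used, n_sets_skipped, panel,
                                diagnostics = list(), call = sys.call(-1)) {
  pop <- panel$meta$pop
  mean_weights <- stats::setNames(as.numeric(mean_weights), pop)
  if (!is.null(per_set_weights)) {
    colnames(per_set_weights) <- pop
    sd_weights <- apply(per_set_weights, 2, stats::sd)
    if (nrow(per_set_weights) < 2) sd_weights[] <- 0
  } else {
    per_set_weights <- matrix(mean_weights, nrow = 1,
                              dimnames = list(NULL, pop))
    sd_weights <- stats::setNames(rep(0, length(pop)), pop)
  }
  structure(
    list(method = method, weights = mean_weights,
         per_set_weights = per_set_weights,
         sd_weights = stats::setNames(as.numeric(sd_weights), pop),
         n_sets_used = n_sets_used, n_sets_skipped = n_sets_skipped,
         meta = panel$meta, diagnostics = diagnostics, call = call),
    class = "ancestry_fit")
}

# ---- afmix ---------------------------------------------------------------

#' Covariance-based allele-frequency ancestry estimator
#'
#' For each quasi-independent SNP set, solves the moment relationship
#' `Cov(S, P) = Cov(P) W` — with `S` the study reference-allele frequencies
#' and `P` the panel AF matrix — via the closed form
#' `W = Cov(P)^(-1) Cov(S, P)` (sample covariances over the set's SNPs).
#' Singular within-set covariances receive a small ridge; still-singular sets
#' are skipped, as are sets with fewer than K + 1 SNPs.
#'
#' The closed form does not respect the simplex constraints, so a constraint
#' step is applied according to `constrain`:
#' * `"average"` (default): the unconstrained per-set solutions are averaged
#'   and the average is projected onto the simplex once. Averaging before
#'   projecting avoids the centre-of-simplex bias that per-set projection
#'   incurs when sets are small.
#' * `"per_set"`: each per-set solution is clipped at zero and renormalized,
#'   then averaged (the classic construction; appropriate when each set has
#'   thousands of SNPs).
#' * `"strict_qp"`: each set is solved as simplex-constrained least squares
#'   on centred variables, then averaged.
#'
#' `per_set_weights` always stores the per-set clipped-and-renormalized
#' (or QP) solutions, so its rows satisfy the simplex invariants and the
#' across-set spread is reported as `sd_weights`.
#'
#' @param study a `study_vector` in AF mode.
#' @param panel a [reference_panel].
#' @param n_sets number of quasi-independent sets (see [partition_snps()]).
#' @param maf_min minor-allele-frequency filter applied to the pooled panel
#'   AF and the study AF (default 0.01; 0 disables).
#' @param constrain constraint policy, see above.
#' @return An [ancestry_fit].
#' @export
afmix <- function(study, panel, n_sets = 1000, maf_min = 0.01,
                  constrain = c("average", "per_set", "strict_qp")) {
  constrain <- match.arg(constrain)
  if (study$mode != "af") stopf("afmix needs an AF-mode study vector")
  inp <- prepare_inputs(study, panel, maf_min)
  K <- n_pops(panel)
  n_sets <- effective_n_sets(length(inp$values), n_sets)
  part <- partition_snps(length(inp$values), n_sets)
  W_raw <- W_con <- matrix(NA_real_, 0, K)
  skipped <- 0L
  for (s in part$sets) {
    if (length(s) < K + 1) { skipped <- skipped + 1L; next }
    Pm <- inp$afs[s, , drop = FALSE]
    Sv <- inp$values[s]
    CP <- stats::cov(Pm)
    cs <- as.numeric(stats::cov(Sv, Pm))
    CPr <- CP + diag(1e-8 * sum(diag(CP)) / K, K)
    w_raw <- tryCatch(solve(CPr, cs), error = function(e) NULL)
    if (is.null(w_raw)) { skipped <- skipped + 1L; next }
    if (constrain == "strict_qp") {
      w_con <- solve_simplex_qp(CPr, cs)
    } else {
      w_con <- pmax(w_raw, 0)
      w_con <- if (sum(w_con) > 0) w_con / sum(w_con) else rep(1 / K, K)
    }
    W_raw <- rbind(W_raw, as.numeric(w_raw))
    W_con <- rbind(W_con, as.numeric(w_con))
  }
  if (nrow(W_raw) == 0L) stopf("all SNP sets were skipped")
  mean_w <- switch(constrain,
                   average = project_simplex(colMeans(W_raw)),
                   per_set = colMeans(W_con),
                   strict_qp = colMeans(W_con))
  new_weight_estimate("afmix", mean_w, W_con,
                      n_sets_used = nrow(W_raw), n_sets_skipped = skipped,
                      panel = panel,
                      diagnostics = c(inp[c("n_input", "n_filtered")],
                                      list(constrain = constrain)))
}

# Euclidean projection onto the probability simplex (as a QP).
project_simplex <- function(w) {
  solve_simplex_qp(diag(length(w)), w)
}

# ---- summix --------------------------------------------------------------

#' Simplex-constrained least-squares allele-frequency estimator
#'
#' Minimizes `sum_i (S_i - sum_k w_k P_ik)^2` over the probability simplex in
#' a single solve using all matched SNPs: the study AF vector is regressed on
#' the panel AF columns under `w_k >= 0`, `sum w_k = 1`.
#'
#' @inheritParams afmix
#' @return An [ancestry_fit]; `per_set_weights` has a single row and
#'   `sd_weights` is zero.
#' @export
summix <- function(study, panel, maf_min = 0.01) {
  if (study$mode != "af") stopf("summix needs an AF-mode study vector")
  inp <- prepare_inputs(study, panel, maf_min)
  K <- n_pops(panel)
  if (length(inp$values) < K) {
    stopf("fewer matched SNPs (%d) than populations (%d)",
          length(inp$values), K)
  }
  w <- solve_simplex_ls(inp$afs, inp$values)
  new_weight_estimate("summix", w, NULL, n_sets_used = 1L,
                      n_sets_skipped = 0L, panel = panel,
                      diagnostics = inp[c("n_input", "n_filtered")])
}

# ---- zmix ----------------------------------------------------------------

#' Z-score-only ancestry estimator
#'
#' Under the null, the product of the Z-scores of two distant SNPs has
#' expectation `sum_k w_k Cor(G'_ik, G'_lk)`, the mixture of the
#' per-population correlations of the standardized genotypes. zmix forms all
#' SNP pairs within each quasi-independent set (subsampled down to
#' `max_pairs_per_set` when necessary), computes the per-population pair
#' correlations from the reference panel, and minimizes
#' `sum_(i!=l) (Z_i Z_l - sum_k w_k Cor_k(i, l))^2` on the probability
#' simplex.
#'
#' With `combine = "pooled"` (default) the objective is minimized jointly
#' over all sets — the per-set normal equations are accumulated and solved
#' once. With `combine = "per_set"` each set is solved separately under the
#' simplex constraints and the solutions are averaged; this matches the
#' classic construction but is only information-rich when each set provides
#' many pairs, and at small set sizes the per-set projections bias the
#' average toward the centre of the simplex. Per-set constrained solutions
#' are reported in `per_set_weights` either way (their spread is
#' `sd_weights`).
#'
#' @param study a `study_vector` in Z mode.
#' @param panel a [reference_panel] with dosages.
#' @param n_sets number of quasi-independent sets (default 1000; reduced with
#'   a warning when SNPs are scarce, see [partition_snps()]).
#' @param max_pairs_per_set cap on pairs per set; beyond it pairs are
#'   subsampled uniformly under `seed` (default 5000).
#' @param maf_min pooled-panel minor-allele-frequency filter (default 0.01).
#' @param seed integer seed controlling pair subsampling only.
#' @param combine `"pooled"` or `"per_set"`, see above.
#' @return An [ancestry_fit].
#' @export
zmix <- function(study, panel, n_sets = 1000, max_pairs_per_set = 5000,
                 maf_min = 0.01, seed = 1,
                 combine = c("pooled", "per_set")) {
  combine <- match.arg(combine)
  zmix_engine(study, panel, n_sets = n_sets,
              max_pairs_per_set = max_pairs_per_set, maf_min = maf_min,
              seed = seed, combine = combine, legacy = FALSE)
}

#' Consecutive-pair unconstrained baseline estimator
#'
#' The historical Z-score construction that zmix supersedes: within each
#' quasi-independent set only consecutive pairs (i, i+1) are formed, the
#' regression of `Z_i Z_(i+1)` on the per-population pair correlations is
#' solved by ordinary (unconstrained) least squares, negative weights are
#' clipped to zero and renormalized, and the per-set results are averaged.
#' The exact historical pairing rule was never published; this consecutive-
#' pair reconstruction is the package's explicit interpretation. Provided as
#' a comparison baseline; expect it to underperform [zmix()].
#'
#' @inheritParams zmix
#' @return An [ancestry_fit].
#' @export
zmix_legacy <- function(study, panel, n_sets = 1000, maf_min = 0.01) {
  zmix_engine(study, panel, n_sets = n_sets, max_pairs_per_set = Inf,
              maf_min = maf_min, seed = 1, combine = "per_set", legacy = TRUE)
}

zmix_engine <- function(study, panel, n_sets, max_pairs_per_set, maf_min,
                        seed, combine, legacy) {
  if (study$mode != "z") stopf("zmix needs a Z-mode study vector")
  if (!has_dosages(panel)) stopf("panel carries no dosages")
  inp <- prepare_inputs(study, panel, maf_min)
  K <- n_pops(panel)
  n <- length(inp$values)
  if (n < 2) stopf("fewer than 2 usable SNPs")
  n_sets <- effective_n_sets(n, n_sets)
  part <- partition_snps(n, n_sets)
  Cacc <- matrix(0, K, K)
  dacc <- rep(0, K)
  W_con <- matrix(NA_real_, 0, K)
  skipped <- 0L
  with_seed(seed, {
    for (s in part$sets) {
      m <- length(s)
      if (m < 2) { skipped <- skipped + 1L; next }
      rows <- inp$panel_rows[s]
      if (legacy) {
        pr <- cbind(seq_len(m - 1L), seq_len(m - 1L) + 1L)
      } else {
        pr <- which(upper.tri(diag(m)), arr.ind = TRUE)
        if (nrow(pr) > max_pairs_per_set) {
          pr <- pr[sample.int(nrow(pr), max_pairs_per_set), , drop = FALSE]
        }
      }
      # per-population correlation matrices over the set's SNPs
      des <- matrix(0, nrow(pr), K)
      for (k in seq_len(K)) {
        R <- cor_rows(panel$dosages[[k]][rows, , drop = FALSE])
        des[, k] <- R[pr]
      }
      z <- inp$values[s]
      resp <- z[pr[, 1]] * z[pr[, 2]]
      if (legacy) {
        w_raw <- tryCatch(
          qr.solve(des, resp, tol = 1e-12), error = function(e) NULL)
        if (is.null(w_raw)) { skipped <- skipped + 1L; next }
        w_con <- pmax(as.numeric(w_raw), 0)
        w_con <- if (sum(w_con) > 0) w_con / sum(w_con) else rep(1 / K, K)
      } else {
        Cs <- crossprod(des)
        ds <- as.numeric(crossprod(des, resp))
        Cacc <- Cacc + Cs
        dacc <- dacc + ds
        w_con <- solve_simplex_qp(Cs, ds)
      }
      W_con <- rbind(W_con, w_con)
    }
  })
  if (nrow(W_con) == 0L) stopf("all SNP sets were skipped")
  mean_w <- if (legacy || combine == "per_set") {
    colMeans(W_con)
  } else {
    solve_simplex_qp(Cacc, dacc)
  }
  new_weight_estimate(if (legacy) "zmix_legacy" else "zmix", mean_w, W_con,
                      n_sets_used = nrow(W_con), n_sets_skipped = skipped,
                      panel = panel,
                      diagnostics = c(inp[c("n_input", "n_filtered")],
                                      list(combine = combine, seed = seed,
                                           max_pairs_per_set = max_pairs_per_set)))
}
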