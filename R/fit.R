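#' Estimate ancestry mixing proportions from GWAS summary statistics
#'
#' Unified front end over the package's estimators. Given a study vector of
#' allele frequencies or association Z-scores aligned to a reference panel,
#' returns the estimated mixing proportions of the K panel populations on the
#' probability simplex.
#'
#' @param study a `study_vector` (see [harmonize()] / [study_vector()]).
#' @param panel a [reference_panel].
#' @param method one of `"afmix"`, `"summix"` (AF mode), `"zmix"`,
#'   `"zmix_legacy"` (Z mode).
#' @param ... passed to the chosen estimator ([afmix()], [summix()],
#'   [zmix()], [zmix_legacy()]).
#' @return An object of class `ancestry_fit` with components `weights`
#'   (named mean mixing proportions, on the simplex), `per_set_weights`
#'   (per-quasi-independent-set simplex-constrained solutions), `sd_weights`
#'   (across-set standard deviation per population), `n_sets_used`,
#'   `n_sets_skipped`, `meta` (population metadata) and `diagnostics`.
#' @examples
#' panel <- generate_panel(n_snps = 2000, n_per_pop = 50, seed = 1)
#' cohort <- simulate_cohort(panel, c(EUR1 = 0.5, EUR2 = 0.5), 500, seed = 2)
#' study <- study_vector(cohort_afs(cohort), "af")
#' fit <- estimate_ancestry(study, panel, method = "summix")
#' coef(fit)
#' summary(fit)
#' @export
estimate_ancestry <- function(study, panel,
                              method = c("afmix", "summix", "zmix",
                                         "zmix_legacy"),
                              ...) {
  method <- match.arg(method)
  fit <- switch(method,
                afmix = afmix(study, panel, ...),
                summix = summix(study, panel, ...),
                zmix = zmix(study, panel, ...),
                zmix_legacy = zmix_legacy(study, panel, ...))
  fit$call <- match.call()
  fit
}

#' @export
print.ancestry_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Ancestry mixing proportions (%s, %d set%s used%s)\n",
              x$method, x$n_sets_used, if (x$n_sets_used == 1) "" else "s",
              if (x$n_sets_skipped > 0)
                sprintf(", %d skipped", x$n_sets_skipped) else ""))
  w <- round(x$weights, digits)
  print(w[w > 0 | x$weights > 1e-4])
  invisible(x)
}

#' @export
summary.ancestry_fit <- function(object, ...) {
  sup <- aggregate_superpop(object)
  tab <- data.frame(pop = names(object$weights),
                    super = object$meta$super[match(names(object$weights),
                                                   object$meta$pop)],
                    weight = as.numeric(object$weights),
                    sd = as.numeric(object$sd_weights))
  structure(list(method = object$method, populations = tab,
                 super_weights = sup, n_sets_used = object$n_sets_used,
                 n_sets_skipped = object$n_sets_skipped,
                 diagnostics = object$diagnostics),
            class = "summary.ancestry_fit")
}

#' @export
print.summary.ancestry_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Method: %s (%d set%s used, %d skipped)\n", x$method,
              x$n_sets_used, if (x$n_sets_used == 1) "" else "s",
              x$n_sets_skipped))
  cat("\nPopulation weights:\n")
  tab <- x$populations
  tab$weight <- round(tab$weight, digits)
  tab$sd <- round(tab$sd, digits)
  print(tab, row.names = FALSE)
  cat("\nSuper-population weights:\n")
  print(round(x$super_weights, digits))
  invisible(x)
}

#' @export
coef.ancestry_fit <- function(object, ...) object$weights

#' @export
plot.ancestry_fit <- function(x, ...) {
  sup <- x$meta$super[match(names(x$weights), x$meta$pop)]
  cols <- grDevices::hcl.colors(length(unique(sup)), "Dark 3")
  graphics::barplot(x$weights, col = cols[as.integer(factor(sup))],
                    las = 2, ylab = "mixing proportion",
                    main = sprintf("ancestry proportions (%s)", x$method), ...)
  graphics::legend("topright", legend = levels(factor(sup)), fill = cols,
                   bty = "n")
  invisible(x)
}

#' Write an ancestry fit as TSV and JSON reports
#'
#' Writes `<prefix>_weights.tsv` (columns pop, super, weight, sd, followed by
#' an aggregated super-population block) and `<prefix>_weights.json`
#' (machine-readable: weights, super-population weights, set counts,
#' harmonization diagnostics, the resolved configuration and the package
#' version). Content is fully determined by the fit, so identical fits give
#' byte-identical reports.
#'
#' @param fit an `ancestry_fit`.
#' @param prefix output path prefix.
#' @param config optional named list echoed into the report (seed, input
#'   paths, flags).
#' @return Invisibly, the two file paths.
#' @export
write_report <- function(fit, prefix, config = list()) {
  s <- summary(fit)
  tsv <- paste0(prefix, "_weights.tsv")
  json <- paste0(prefix, "_weights.json")
  con <- file(tsv, "w")
  writeLines(sprintf("# ancmix %s method=%s",
                     as.character(utils::packageVersion("ancmix")),
                     fit$method), con)
  if (length(config)) {
    writeLines(sprintf("# config: %s",
                       paste(sprintf("%s=%s", names(config),
                                     vapply(config, function(v)
                                       paste(format(v), collapse = ","),
                                       character(1))),
                             collapse = " ")), con)
  }
  tab <- s$populations
  tab$weight <- sprintf("%.6f", tab$weight)
  tab$sd <- sprintf("%.6f", tab$sd)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines("", con)
  sup <- data.frame(super = names(s$super_weights),
                    weight = sprintf("%.6f", s$super_weights))
  utils::write.table(sup, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  payload <- list(
    tool = "ancmix",
    version = as.character(utils::packageVersion("ancmix")),
    method = fit$method,
    config = config,
    weights = as.list(fit$weights),
    sd_weights = as.list(fit$sd_weights),
    super_weights = as.list(s$super_weights),
    n_sets_used = fit$n_sets_used,
    n_sets_skipped = fit$n_sets_skipped,
    diagnostics = fit$diagnostics)
  jsonlite::write_json(payload, json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(tsv = tsv, json = json))
}
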