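# Workflow wrappers tying the modules together: per-site assessment,
# scenario table, stability run. Each accepts in-memory objects or CSV
# paths and optionally writes headered UTF-8 CSV output. These functions
# (plus the thin command-line script in inst/cli/) are the package's
# user-facing entry points.

# accept a dbi_pool or a checklist CSV path
as_pool <- function(checklist) {
  if (inherits(checklist, "dbi_pool")) return(checklist)
  if (is.character(checklist) && length(checklist) == 1L) {
    return(read_checklist(checklist))
  }
  stop("checklist must be a dbi_pool or the path to a checklist CSV")
}

# accept a named list of site samples or a community-matrix CSV path
as_samples <- function(communities, orientation) {
  if (is.character(communities) && length(communities) == 1L) {
    return(read_community_matrix(communities, orientation))
  }
  if (is.list(communities) && length(communities) > 0L &&
      !is.null(names(communities))) {
    return(communities)
  }
  stop("communities must be a community-matrix CSV path or a named list of site samples")
}

#' Assess sites: richness, DBI_sum, DBI_mean and potential
#'
#' The 'calculate everything' workflow: resolves every site sample against
#' the checklist and reports richness, DBI_sum, DBI_mean and the
#' permutational DBI potential per site, together with the permutation
#' settings used. Values are kept at full precision; the customary display
#' rounding (two decimals for DBI_mean, three for the potential) is applied
#' only when printing or writing. Resolution warnings (unmatched names,
#' zero-abundance records) are raised per site and, when writing, collected
#' into a machine-readable sidecar CSV next to the output.
#'
#' @param checklist A [dbi_pool()] or checklist CSV path.
#' @param communities A named list of site samples (as accepted by
#'   [resolve_community()]) or a community-matrix CSV path.
#' @param n_perm Permutations per site (default 10000).
#' @param base_x Probability-weight base (default 2).
#' @param seed Integer master seed; per-site seeds are derived from it.
#' @param strict Strict name matching (unmatched names are errors).
#' @param orientation Community-matrix orientation, see
#'   [read_community_matrix()].
#' @param out Optional output CSV path; a `<out>_warnings.csv` sidecar is
#'   written alongside when any warnings occurred.
#' @return Data frame with one row per site: `site`, `richness`,
#'   `dbi_sum`, `dbi_mean`, `potential`, `n_perm`, `base_x`, `seed`.
#' @export
run_assessment <- function(checklist, communities, n_perm = 10000,
                           base_x = 2, seed = 1, strict = FALSE,
                           orientation = "sites_as_rows", out = NULL) {
  pool <- as_pool(checklist)
  samples <- as_samples(communities, orientation)
  scheme <- weight_scheme(base_x)
  child <- derive_seeds(seed, length(samples))
  warn <- list()
  rows <- lapply(seq_along(samples), function(i) {
    site <- names(samples)[i]
    comm <- resolve_community(samples[[i]], pool, strict = strict, site = site)
    for (u in comm$report$unmatched) {
      warning("site '", site, "': species '", u, "' not in the checklist; dropped",
              call. = FALSE)
      warn[[length(warn) + 1L]] <<- data.frame(site = site, kind = "unmatched",
                                               detail = u, stringsAsFactors = FALSE)
    }
    pot <- permutational_potential(comm, pool, n_perm = n_perm,
                                   scheme = scheme, seed = child[i])
    data.frame(site = site, richness = richness(comm),
               dbi_sum = dbi_sum(comm, pool), dbi_mean = dbi_mean(comm, pool),
               potential = pot$potential, n_perm = as.integer(n_perm),
               base_x = base_x, seed = child[i], stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (!is.null(out)) {
    disp <- report
    disp$dbi_mean <- round(disp$dbi_mean, 2)
    disp$potential <- round(disp$potential, 3)
    utils::write.csv(disp, out, row.names = FALSE, fileEncoding = "UTF-8")
    if (length(warn) > 0L) {
      utils::write.csv(do.call(rbind, warn),
                       sub("(\\.csv)?$", "_warnings.csv", out, ignore.case = TRUE),
                       row.names = FALSE, fileEncoding = "UTF-8")
    }
  }
  report
}

#' Run the benchmark scenario table
#'
#' Evaluates the 13 benchmark scenarios (or user-supplied specs) on a
#' pool: one row per scenario with DBI_sum, DBI_mean, potential, the three
#' dense rank columns and substitution notes.
#'
#' @inheritParams run_assessment
#' @param specs List of [scenario_spec()]s (default [default_scenarios()]).
#' @param out Optional output CSV path.
#' @return The [evaluate_scenarios()] data frame.
#' @export
run_scenarios <- function(checklist, specs = default_scenarios(),
                          n_perm = 10000, base_x = 2, seed = 1, out = NULL) {
  pool <- as_pool(checklist)
  res <- evaluate_scenarios(specs, pool, n_perm = n_perm,
                            scheme = weight_scheme(base_x), seed = seed)
  if (!is.null(out)) {
    disp <- res
    disp$dbi_mean <- round(disp$dbi_mean, 2)
    disp$potential <- round(disp$potential, 3)
    utils::write.csv(disp, out, row.names = FALSE, fileEncoding = "UTF-8")
  }
  res
}

#' Run the stability diagnostic over sites
#'
#' Computes the potential `reps` times per site and compares sites
#' pairwise with Bonferroni-adjusted two-sample KS tests. With `out_prefix`
#' two CSVs are written: `<prefix>_distributions.csv` (long format: site,
#' repetition, potential) and `<prefix>_pairs.csv` (the pairwise report).
#'
#' @inheritParams run_assessment
#' @param reps Repetitions per site (default 100; at least 2).
#' @param alpha Significance level for the discrimination flag.
#' @param out_prefix Optional output path prefix.
#' @return List with `distributions` (list of `dbi_potential_dist`) and
#'   `report` (a [stability_report()]).
#' @export
run_stability <- function(checklist, communities, reps = 100, n_perm = 10000,
                          base_x = 2, seed = 1, alpha = 0.05, strict = FALSE,
                          orientation = "sites_as_rows", out_prefix = NULL) {
  if (reps < 2L) stop("stability mode needs reps >= 2")
  pool <- as_pool(checklist)
  samples <- as_samples(communities, orientation)
  if (length(samples) < 2L) stop("stability mode needs at least two sites")
  scheme <- weight_scheme(base_x)
  site_seed <- derive_seeds(seed, length(samples))
  dists <- lapply(seq_along(samples), function(i) {
    comm <- resolve_community(samples[[i]], pool, strict = strict,
                              site = names(samples)[i])
    repeat_potential(comm, pool, reps = reps, n_perm = n_perm,
                     scheme = scheme, seed = site_seed[i])
  })
  report <- stability_report(dists, alpha = alpha)
  if (!is.null(out_prefix)) {
    long <- do.call(rbind, lapply(dists, function(d) {
      data.frame(site = d$site, repetition = seq_along(d$values),
                 potential = d$values, stringsAsFactors = FALSE)
    }))
    utils::write.csv(long, paste0(out_prefix, "_distributions.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
    utils::write.csv(as.data.frame(report), paste0(out_prefix, "_pairs.csv"),
                     row.names = FALSE, fileEncoding = "UTF-8")
  }
  list(distributions = dists, report = report)
}
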