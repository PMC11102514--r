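# Stability diagnostic for the permutational potential: repeated
# computation per community, pairwise two-sample Kolmogorov-Smirnov
# comparison, Bonferroni correction and a discrimination report.

#' Repeat the permutational potential for one community
#'
#' Computes the potential `reps` times, each repetition from `n_perm` fresh
#' permutations, giving an empirical distribution of the statistic for the
#' site. Child seeds for the repetitions are derived deterministically from
#' the master seed, so the whole distribution is reproducible.
#'
#' @inheritParams permutational_potential
#' @param reps Number of repetitions (default 100).
#' @param seed Integer master seed.
#' @param site Site label; defaults to the community's own label.
#' @return Object of class `dbi_potential_dist`: list with `site`, `values`
#'   (length `reps`, each in \[0, 1\]), `reps`, `n_perm`, `seed`.
#' @export
repeat_potential <- function(community, pool, reps = 100, n_perm = 10000,
                             scheme = weight_scheme(), seed = 1,
                             site = NULL) {
  reps <- as.integer(reps)
  if (reps < 1L) stop("reps must be at least 1")
  if (is.null(site)) {
    site <- if (inherits(community, "dbi_community")) community$site else "site"
  }
  child <- derive_seeds(seed, reps)
  values <- vapply(child, function(s) {
    permutational_potential(community, pool, n_perm = n_perm, scheme = scheme,
                            seed = s)$potential
  }, numeric(1))
  structure(
    list(site = as.character(site), values = values, reps = reps,
         n_perm = as.integer(n_perm), seed = as.integer(seed)),
    class = "dbi_potential_dist"
  )
}

#' @export
print.dbi_potential_dist <- function(x, ...) {
  cat(sprintf("Potential distribution for '%s': %d repetitions of %d permutations\n",
              x$site, x$reps, x$n_perm))
  print(summary(x$values))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' The KS statistic D is the supremum absolute difference between the two
#' empirical distribution functions; the p-value comes from the standard
#' two-sided asymptotic KS distribution (appropriate at the default 100
#' repetitions per site; potential values are heavily tied, so the exact
#' small-sample p would be unavailable anyway).
#'
#' @param a,b Non-empty numeric samples.
#' @return List with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Pairwise stability report over potential distributions
#'
#' Runs the two-sample KS test on every unordered pair of site
#' distributions and Bonferroni-adjusts the p-values over the
#' `n (n - 1) / 2` comparisons. A pair is flagged as *indistinct* when both
#' distributions are degenerate at the same point (the asymptotic KS
#' p-value is uninformative there, e.g. two sites whose potential is 1.000
#' in every repetition), or when its adjusted p-value is at or above
#' `alpha`. Both raw and adjusted p-values are reported so users can apply
#' their own threshold.
#'
#' @param dists List of at least two [repeat_potential()] results (or lists
#'   with `site` and `values`).
#' @param alpha Significance level for the discrimination flag
#'   (default 0.05).
#' @return Object of class `dbi_stability`: a long-format data frame with
#'   columns `site_i`, `site_j`, `D`, `p`, `p_adj`, `degenerate_equal`,
#'   `indistinct`; attributes `n_comparisons` and `alpha`.
#' @export
stability_report <- function(dists, alpha = 0.05) {
  if (!is.list(dists) || length(dists) < 2L) {
    stop("at least two potential distributions are required")
  }
  sites <- vapply(dists, function(d) as.character(d$site), character(1))
  values <- lapply(dists, function(d) {
    v <- d$values
    if (!is.numeric(v) || length(v) == 0L) stop("each distribution needs non-empty numeric values")
    if (any(v < 0 | v > 1)) stop("potential values must lie in [0, 1]")
    v
  })
  pairs <- utils::combn(length(dists), 2L)
  m <- ncol(pairs)
  rows <- lapply(seq_len(m), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    a <- values[[i1]]; b <- values[[i2]]
    degen <- stats::var(a) == 0 && stats::var(b) == 0 && a[1L] == b[1L]
    ks <- ks_two_sample(a, b)
    data.frame(site_i = sites[i1], site_j = sites[i2],
               D = ks$D, p = ks$p, degenerate_equal = degen,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- pmin(1, out$p * m)
  out$indistinct <- out$degenerate_equal | out$p_adj >= alpha
  out <- out[, c("site_i", "site_j", "D", "p", "p_adj",
                 "degenerate_equal", "indistinct")]
  structure(out, n_comparisons = m, alpha = alpha,
            class = c("dbi_stability", "data.frame"))
}

#' @export
print.dbi_stability <- function(x, ...) {
  m <- attr(x, "n_comparisons")
  cat(sprintf("Stability report: %d pairwise KS comparisons (Bonferroni over %d), alpha = %g\n",
              m, m, attr(x, "alpha")))
  ind <- x[x$indistinct, , drop = FALSE]
  if (nrow(ind) == 0L) {
    cat("  all site pairs discriminated\n")
  } else {
    cat(sprintf("  %d indistinct pair(s): %s\n", nrow(ind),
                paste(sprintf("%s/%s", ind$site_i, ind$site_j), collapse = ", ")))
  }
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more pairs\n", nrow(x) - 10L))
  invisible(x)
}
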