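# Fixtures built in code: tiny pools and CSV writers used across the suite.

# pool from a vector of total DBI scores; names sp01, sp02, ...
make_pool <- function(totals, region = "test-pool") {
  dbi_pool(sprintf("sp%02d", seq_along(totals)), dbi = totals,
           region_label = region)
}

# write a checklist CSV from raw columns (possibly with blanks/errors)
write_checklist_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
  path
}

# brute-force ECDF sweep: supremum |F_a - F_b| over the pooled sample points
ks_D_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

# brute-force subset count for equal-weight pools: every k-subset is
# equiprobable, so the exact potential is #(subsets with lower sum) / C(n,k)
equal_weight_potential <- function(totals, members_idx) {
  k <- length(members_idx)
  target <- sum(totals[members_idx])
  subs <- utils::combn(length(totals), k)
  mean(apply(subs, 2, function(ix) sum(totals[ix]) < target))
}

# independent ordered-draw enumeration (distinct code path from the
# package oracle: iterates over explicit permutations of index vectors)
ordered_draw_potential <- function(totals, w, k, target) {
  w <- unname(w)
  n <- length(totals)
  idx_tuples <- as.matrix(expand.grid(rep(list(seq_len(n)), k)))
  acc <- 0
  for (r in seq_len(nrow(idx_tuples))) {
    tup <- idx_tuples[r, ]
    if (anyDuplicated(tup)) next
    prob <- 1
    remaining <- rep(TRUE, n)
    for (i in tup) {
      prob <- prob * w[i] / sum(w[remaining])
      remaining[i] <- FALSE
    }
    if (sum(totals[tup]) < target) acc <- acc + prob
  }
  acc
}
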