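# Weighted community assembly and the permutational DBI potential.

test_that("weight schemes are geometric in the DBI value", {
  w <- weight_scheme(2)
  expect_equal(unname(w[1:10]), 2^-(0:9))
  expect_true(all(diff(unclass(w)) < 0))
  expect_true(all(w > 0))
  expect_equal(unname(weight_scheme(1)[1:10]), rep(1, 10))
  expect_error(weight_scheme(0), "positive")
  expect_error(weight_scheme(-2), "positive")
})

test_that("sampling draws each species proportionally to remaining weights", {
  # two species, DBI 0 and 1, x = 2: first-draw odds 1 : 0.5
  pool <- dbi_pool(c("common sp", "rare sp"), dbi = c(0, 1))
  set.seed(101)
  n_draw <- 1e5
  hits <- sum(vapply(seq_len(n_draw),
                     function(i) sample_community(pool, 1) == "common sp",
                     logical(1)))
  p <- 2 / 3
  expect_lt(abs(hits / n_draw - p), 3 * sqrt(p * (1 - p) / n_draw))
})

test_that("equal weights make every subset equiprobable", {
  # 5 species of equal DBI, richness 3: all C(5,3) = 10 subsets uniform
  pool <- make_pool(rep(4, 5))
  set.seed(202)
  n_draw <- 4000
  key <- replicate(n_draw, paste(sort(sample_community(pool, 3)), collapse = "+"))
  counts <- table(key)
  expect_equal(length(counts), 10L)
  expect_gt(stats::chisq.test(counts)$p.value, 1e-3)

  # base_x = 1 reduces to simple random subsets even with unequal DBI
  pool2 <- make_pool(c(0, 2, 5, 7, 9))
  set.seed(203)
  key2 <- replicate(n_draw, paste(sort(sample_community(pool2, 3, weight_scheme(1))),
                                  collapse = "+"))
  expect_gt(stats::chisq.test(table(key2))$p.value, 1e-3)
})

test_that("sampling respects richness bounds", {
  pool <- make_pool(c(1, 3, 5))
  # richness = pool size: the full pool, always
  for (i in 1:5) {
    expect_setequal(sample_community(pool, 3), pool$species)
  }
  expect_error(sample_community(pool, 4), "pool size")
  expect_error(sample_community(pool, 0), "between 1")
})

test_that("the exact oracle matches brute-force enumerations", {
  # frozen hand-enumerated case: pool scores {0,1,2,3}, x = 2, community {2,3}
  pool <- make_pool(0:3)
  expect_equal(exact_potential_oracle(c("sp03", "sp04"), pool), 0.9802198,
               tolerance = 1e-6)

  # community at the minimum achievable sum -> exactly 0
  expect_equal(exact_potential_oracle(c("sp01", "sp02"), pool), 0)

  # equal weights: hypergeometric-style subset count
  set.seed(31)
  for (i in 1:5) {
    totals <- sample(0:9, 6, replace = TRUE)
    pl <- make_pool(totals)
    k <- sample(2:3, 1)
    members <- sample(seq_len(6), k)
    expect_equal(
      exact_potential_oracle(pl$species[members], pl, weight_scheme(1)),
      equal_weight_potential(totals, members),
      tolerance = 1e-12
    )
  }

  # unequal weights: independent ordered-draw enumeration agrees
  set.seed(32)
  for (i in 1:3) {
    totals <- sample(0:9, 5, replace = TRUE)
    pl <- make_pool(totals)
    members <- sample(seq_len(5), 2)
    w <- weight_scheme(2)[totals + 1]
    expect_equal(
      exact_potential_oracle(pl$species[members], pl),
      ordered_draw_potential(totals, w, 2, sum(totals[members])),
      tolerance = 1e-12
    )
  }

  # guard against non-enumerable instances
  big <- make_pool(rep(0:9, length.out = 11))
  expect_error(exact_potential_oracle(big$species[1:2], big), "too large")
  p10 <- make_pool(rep(0:4, 2))
  expect_error(exact_potential_oracle(p10$species[1:5], p10), "too large")
})

test_that("Monte-Carlo potential agrees with the oracle and is reproducible", {
  pool <- make_pool(0:3)
  comm <- c("sp03", "sp04")
  exact <- exact_potential_oracle(comm, pool)
  res <- permutational_potential(comm, pool, n_perm = 10000, seed = 5)
  expect_lt(abs(res$potential - exact),
            3 * sqrt(exact * (1 - exact) / 10000))

  # bookkeeping invariants
  expect_equal(res$potential, res$n_strictly_lower / res$n_permutations)
  expect_lte(res$n_strictly_lower + res$n_equal, res$n_permutations)
  expect_equal(res$richness, 2)
  expect_equal(res$actual_sum, 5)

  # identical seed -> identical result; different seed -> same contract
  res2 <- permutational_potential(comm, pool, n_perm = 10000, seed = 5)
  expect_identical(res, res2)

  # mid-p credits half the ties
  midp <- permutational_potential(comm, pool, n_perm = 2000, seed = 8,
                                  mid_p = TRUE)
  plain <- permutational_potential(comm, pool, n_perm = 2000, seed = 8)
  expect_equal(midp$potential,
               plain$potential + 0.5 * plain$n_equal / plain$n_permutations)
})

test_that("minimum-sum communities score exactly zero, independent of seed", {
  pool <- make_pool(c(0, 0, 1, 2, 5, 7, 9))
  minimal <- c("sp01", "sp02", "sp03")  # the richness-3 minimum (sum 1)
  for (s in c(1, 99, 123456)) {
    res <- permutational_potential(minimal, pool, n_perm = 500, seed = s)
    expect_identical(res$potential, 0)
  }
})

test_that("higher DBI_sum at equal richness never lowers the exact potential", {
  pool <- make_pool(c(0, 1, 2, 4, 6, 9))
  pairs <- utils::combn(6, 2)
  pots <- apply(pairs, 2, function(ix) exact_potential_oracle(pool$species[ix], pool))
  sums <- apply(pairs, 2, function(ix) sum(pool$dbi[ix]))
  ord <- order(sums)
  expect_true(all(diff(pots[ord]) >= -1e-12))
})

test_that("degenerate and invalid inputs are handled", {
  pool <- make_pool(c(1, 2, 3))
  expect_warning(
    res <- permutational_potential(pool$species, pool, n_perm = 50, seed = 1),
    "full pool")
  expect_identical(res$potential, 0)
  expect_error(permutational_potential("sp01", pool, n_perm = 0, seed = 1),
               "at least 1")
  expect_error(permutational_potential(c("sp01", "nope"), pool, n_perm = 10),
               "nope")
})
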