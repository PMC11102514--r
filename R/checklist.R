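# Species checklist (pool) data model, CSV I/O, validation, synthetic pool
# generation and occupancy-based calibration of the probability-weight base.

#' Normalize a species name for matching
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace
#' to a single space and folds case. Used for duplicate detection and for
#' matching sample names against a checklist; the original spelling is
#' always preserved for output.
#'
#' @param x Character vector of species names.
#' @return Character vector of normalized names.
#' @keywords internal
normalize_name <- function(x) {
  tolower(gsub("[[:space:]]+", " ", trimws(as.character(x))))
}

#' Construct a DBI species pool
#'
#' A `dbi_pool` is a validated checklist of species with Dragonfly Biotic
#' Index scores: the three subindices (geographical distribution, IUCN
#' threat status, sensitivity to disturbance), each scored 0--3, and the
#' total DBI score 0--9 which is their sum. A total-only pool (subindices
#' `NA`) is accepted; subindex-dependent operations (such as occupancy
#' calibration) are then unavailable.
#'
#' @param species Character vector of species names (non-empty, unique after
#'   case/whitespace normalization).
#' @param dbi Integer vector of total DBI scores in 0--9. If `NULL`, it is
#'   derived as the sum of the three subindices, which must then be given.
#' @param dbi_d,dbi_t,dbi_s Optional integer vectors of the distribution,
#'   threat and sensitivity subindices, each in 0--3. Either all three or
#'   none must be supplied.
#' @param region_label Free-text label of the regional pool.
#' @return An object of class `dbi_pool`: a data frame with columns
#'   `species`, `dbi_d`, `dbi_t`, `dbi_s`, `dbi` and attribute
#'   `region_label`.
#' @examples
#' dbi_pool(c("Aeshna alpha", "Libellula beta"), dbi = c(7, 0))
#' @export
dbi_pool <- function(species, dbi = NULL, dbi_d = NULL, dbi_t = NULL,
                     dbi_s = NULL, region_label = "user-pool") {
  sub_given <- !is.null(dbi_d) || !is.null(dbi_t) || !is.null(dbi_s)
  if (sub_given && (is.null(dbi_d) || is.null(dbi_t) || is.null(dbi_s))) {
    stop("either all three subindices (dbi_d, dbi_t, dbi_s) or none must be supplied")
  }
  n <- length(species)
  if (!sub_given) {
    dbi_d <- dbi_t <- dbi_s <- rep(NA_integer_, n)
  }
  if (is.null(dbi)) {
    if (!sub_given) stop("supply 'dbi' totals or the three subindices")
    dbi <- dbi_d + dbi_t + dbi_s
  }
  df <- data.frame(
    species = as.character(species),
    dbi_d = as.integer(dbi_d), dbi_t = as.integer(dbi_t),
    dbi_s = as.integer(dbi_s), dbi = as.integer(dbi),
    stringsAsFactors = FALSE
  )
  validate_dbi_pool(df)
  structure(df,
    region_label = as.character(region_label),
    class = c("dbi_pool", "data.frame")
  )
}

# Enforces the per-species and pool-level invariants; stops with a message
# naming every offending species.
validate_dbi_pool <- function(df) {
  if (nrow(df) == 0L) stop("a species pool must contain at least one species")
  if (anyNA(df$species) || any(!nzchar(trimws(df$species)))) {
    stop("species names must be non-empty")
  }
  key <- normalize_name(df$species)
  if (anyDuplicated(key)) {
    dups <- unique(df$species[duplicated(key) | duplicated(key, fromLast = TRUE)])
    stop("duplicate species names (after normalization): ",
         paste(dups, collapse = ", "))
  }
  if (anyNA(df$dbi) || any(df$dbi < 0L | df$dbi > 9L)) {
    bad <- df$species[is.na(df$dbi) | df$dbi < 0L | df$dbi > 9L]
    stop("total DBI score must be an integer in 0..9; offending species: ",
         paste(bad, collapse = ", "))
  }
  has_sub <- !is.na(df$dbi_d)
  if (any(has_sub != !is.na(df$dbi_t)) || any(has_sub != !is.na(df$dbi_s))) {
    stop("subindices must be given either completely or not at all per species")
  }
  if (any(has_sub)) {
    sub <- df[has_sub, , drop = FALSE]
    out_of_range <- with(sub, dbi_d < 0L | dbi_d > 3L | dbi_t < 0L | dbi_t > 3L |
                           dbi_s < 0L | dbi_s > 3L)
    if (any(out_of_range)) {
      stop("each DBI subindex must lie in 0..3; offending species: ",
           paste(sub$species[out_of_range], collapse = ", "))
    }
    mism <- sub$dbi != sub$dbi_d + sub$dbi_t + sub$dbi_s
    if (any(mism)) {
      stop("total DBI must equal the sum of the three subindices; offending species: ",
           paste(sub$species[mism], collapse = ", "))
    }
  }
  invisible(df)
}

#' @export
print.dbi_pool <- function(x, ...) {
  cat(sprintf("DBI species pool '%s': %d species, total scores %d..%d\n",
              attr(x, "region_label"), nrow(x), min(x$dbi), max(x$dbi)))
  if (all(is.na(x$dbi_d))) cat("  (total scores only; no subindices)\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), row.names = FALSE)
  if (nrow(x) > 10L) cat(sprintf("  ... and %d more species\n", nrow(x) - 10L))
  invisible(x)
}

#' Does the pool carry the three DBI subindices?
#'
#' @param pool A [dbi_pool()].
#' @return `TRUE` if every species has the distribution/threat/sensitivity
#'   subindices, `FALSE` for a total-only pool.
#' @export
has_subindices <- function(pool) {
  stopifnot(inherits(pool, "dbi_pool"))
  !anyNA(pool$dbi_d)
}

#' Read a DBI checklist from CSV
#'
#' Expects a UTF-8, comma-separated file with a header using the canonical
#' column names `species`, `dbi_d`, `dbi_t`, `dbi_s`, `dbi`. Either the
#' total (`dbi`) column, the three subindex columns, or both must be
#' present; when both are present their consistency is checked. Rows whose
#' total score is missing/blank and cannot be derived from complete
#' subindices are excluded from the pool with a message; the excluded
#' species are recorded in the `excluded` attribute of the result (the
#' common situation of a regional checklist in which only part of the
#' fauna has defined DBI scores). Scores are never imputed.
#'
#' @param path Path to the CSV file.
#' @param region_label Label for the pool; defaults to the file name.
#' @return A [dbi_pool()] with attributes `excluded` (character vector of
#'   species names dropped for missing scores) and `n_excluded`.
#' @seealso [write_checklist()]
#' @export
read_checklist <- function(path, region_label = basename(path)) {
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                    strip.white = TRUE),
    error = function(e) stop("malformed checklist CSV '", path, "': ",
                             conditionMessage(e))
  )
  names(df) <- tolower(trimws(names(df)))
  if (!"species" %in% names(df)) stop("checklist must have a 'species' column")
  sub_cols <- c("dbi_d", "dbi_t", "dbi_s")
  sub_present <- all(sub_cols %in% names(df))
  if (!sub_present && !"dbi" %in% names(df)) {
    stop("checklist must have a 'dbi' total column and/or the three subindex columns dbi_d, dbi_t, dbi_s")
  }
  as_score <- function(x) {
    x <- trimws(as.character(x))
    x[!nzchar(x)] <- NA
    suppressWarnings(as.integer(x))
  }
  total <- if ("dbi" %in% names(df)) as_score(df$dbi) else rep(NA_integer_, nrow(df))
  if (sub_present) {
    d <- as_score(df$dbi_d); tt <- as_score(df$dbi_t); s <- as_score(df$dbi_s)
    complete_sub <- !is.na(d) & !is.na(tt) & !is.na(s)
    derived <- ifelse(complete_sub, d + tt + s, NA_integer_)
    mism <- !is.na(total) & !is.na(derived) & total != derived
    if (any(mism)) {
      stop("total DBI must equal the sum of the three subindices; offending species: ",
           paste(df$species[mism], collapse = ", "))
    }
    total <- ifelse(is.na(total), derived, total)
  } else {
    d <- tt <- s <- rep(NA_integer_, nrow(df))
    complete_sub <- rep(FALSE, nrow(df))
  }
  keep <- !is.na(total)
  excluded <- as.character(df$species[!keep])
  if (length(excluded) > 0L) {
    message(length(excluded), " species without a defined DBI score excluded: ",
            paste(excluded, collapse = ", "))
  }
  if (!any(keep)) stop("no species with defined DBI scores in '", path, "'")
  # a row with a total but incomplete subindices keeps its total, subindices NA
  d[!complete_sub] <- NA_integer_
  tt[!complete_sub] <- NA_integer_
  s[!complete_sub] <- NA_integer_
  pool <- dbi_pool(
    species = df$species[keep], dbi = total[keep],
    dbi_d = if (sub_present) d[keep] else NULL,
    dbi_t = if (sub_present) tt[keep] else NULL,
    dbi_s = if (sub_present) s[keep] else NULL,
    region_label = region_label
  )
  attr(pool, "excluded") <- excluded
  attr(pool, "n_excluded") <- length(excluded)
  pool
}

#' Write a DBI checklist to CSV
#'
#' Writes the canonical checklist columns (`species`, `dbi_d`, `dbi_t`,
#' `dbi_s`, `dbi`) so that [read_checklist()] round-trips the pool exactly
#' (order and values).
#'
#' @param pool A [dbi_pool()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(pool, path) {
  stopifnot(inherits(pool, "dbi_pool"))
  utils::write.csv(as.data.frame(pool), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# all (d,t,s) compositions with parts in 0..3, indexed by total 0..9
.dbi_compositions <- local({
  g <- expand.grid(d = 0:3, t = 0:3, s = 0:3)
  split(g, g$d + g$t + g$s)
})

#' Generate a synthetic regional species pool
#'
#' Builds a pool emulating a Central-European-like regional checklist
#' (default 68 scored species): every total DBI value 0--9 is represented
#' by at least one species, and the number of species per total value
#' decreases geometrically with the value (target proportions
#' `decay^-value`), reflecting that high-scoring restricted specialists are
#' much rarer in the pool than widespread generalists. Counts per value are
#' allocated deterministically (largest-remainder rounding of the target
#' quotas on top of the guaranteed one species per value); the seed only
#' drives the random split of each total into the three subindices.
#'
#' @param n_species Number of species, at least 10 (one per total value).
#' @param seed Integer seed; identical arguments give identical pools.
#' @param decay Geometric decay base of the species-frequency profile
#'   (default 2, mirroring the halving of occupancy with each DBI step).
#' @param region_label Label for the pool.
#' @return A [dbi_pool()] of `n_species` synthetic species.
#' @examples
#' pool <- synthetic_pool(68, seed = 1)
#' table(pool$dbi)
#' @export
synthetic_pool <- function(n_species = 68, seed = 1, decay = 2,
                           region_label = "synthetic-central-european") {
  if (n_species < 10L) stop("n_species must be >= 10 to cover every total DBI value 0..9")
  if (decay <= 0) stop("decay must be positive")
  counts <- 1L + largest_remainder(n_species - 10L, decay^-(0:9))
  totals <- rep(0:9, counts)
  with_preserved_rng({
    set.seed(as.integer(seed))
    sub <- do.call(rbind, lapply(totals, function(v) {
      comps <- .dbi_compositions[[as.character(v)]]
      comps[sample.int(nrow(comps), 1L), ]
    }))
  })
  dbi_pool(
    species = sprintf("synthetic_sp_%03d", seq_len(n_species)),
    dbi = totals, dbi_d = sub$d, dbi_t = sub$t, dbi_s = sub$s,
    region_label = region_label
  )
}

# Deterministic largest-remainder (Hamilton) apportionment of `n` units to
# weights `w`; ties go to the earlier class.
largest_remainder <- function(n, w) {
  q <- n * w / sum(w)
  counts <- floor(q)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(q - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Target proportions of the synthetic pool
#'
#' Normalized target proportions of species per total DBI value used by
#' [synthetic_pool()], i.e. `decay^-value` over values 0--9.
#'
#' @param decay Geometric decay base.
#' @return Named numeric vector of length 10 summing to 1.
#' @export
synthetic_pool_proportions <- function(decay = 2) {
  w <- decay^-(0:9)
  stats::setNames(w / sum(w), 0:9)
}

#' Read an occupancy table from CSV
#'
#' Columns: `species`, `quadrats` (occupied-quadrat count, non-negative
#' integer) and `dbi_d` (distribution subindex, 0--3).
#'
#' @param path Path to the CSV file.
#' @return A data frame with columns `species`, `quadrats`, `dbi_d`.
#' @export
read_occupancy <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                        strip.white = TRUE)
  names(df) <- tolower(trimws(names(df)))
  need <- c("species", "quadrats", "dbi_d")
  if (!all(need %in% names(df))) {
    stop("occupancy CSV must have columns: ", paste(need, collapse = ", "))
  }
  df$quadrats <- as.integer(df$quadrats)
  df$dbi_d <- as.integer(df$dbi_d)
  if (anyNA(df$quadrats) || any(df$quadrats < 0L)) {
    stop("quadrat counts must be non-negative integers")
  }
  df[need]
}

#' Calibrate the probability-weight base x from quadrat occupancy
#'
#' The weight base `x` of the permutational potential (weights `x^-DBI`) is
#' estimated from how quickly species frequency falls with the distribution
#' subindex (DBID). Each species' occupancy rate is its occupied-quadrat
#' count divided by the count of the most common species; rates are averaged
#' within DBID classes 0, 1 and 2 (class 3 is excluded: such species sit at
#' range edges and their distribution subindex is confounded with threat and
#' sensitivity). The successive class-mean ratios R1/R0 and R2/R1 measure
#' the per-step frequency drop; the recommended `x` is the reciprocal of
#' their geometric mean, rounded to the nearest integer (the unrounded value
#' is reported too). Class means near a halving per step recommend `x = 2`.
#'
#' @param occ Either an occupancy data frame as from [read_occupancy()], or
#'   a numeric vector of length 3 giving the pre-computed mean occupancy
#'   rates for DBID classes 0, 1, 2.
#' @return An object of class `dbi_calibration`: list with `class_means`,
#'   `ratios`, `geo_mean_ratio`, `x_raw` and integer recommendation `x`.
#' @examples
#' calibrate_weight_base(c(0.80, 0.38, 0.18)) # recommends x = 2
#' @export
calibrate_weight_base <- function(occ) {
  if (is.numeric(occ) && is.null(dim(occ))) {
    if (length(occ) != 3L) stop("class-mean input must have length 3 (DBID classes 0, 1, 2)")
    class_means <- stats::setNames(as.numeric(occ), 0:2)
  } else {
    if (!is.data.frame(occ)) stop("occ must be an occupancy data frame or 3 class means")
    need <- c("quadrats", "dbi_d")
    if (!all(need %in% names(occ))) stop("occupancy table needs columns 'quadrats' and 'dbi_d'")
    if (nrow(occ) == 0L || all(occ$quadrats == 0L)) {
      stop("occupancy table must contain at least one species with a positive quadrat count")
    }
    rate <- occ$quadrats / max(occ$quadrats)
    class_means <- vapply(0:2, function(k) {
      r <- rate[occ$dbi_d == k]
      if (length(r) == 0L) stop("no species in DBID class ", k,
                                "; classes 0, 1 and 2 are all required")
      mean(r)
    }, numeric(1))
    names(class_means) <- 0:2
  }
  if (any(class_means <= 0)) stop("class mean occupancy rates must be positive")
  ratios <- stats::setNames(class_means[2:3] / class_means[1:2], c("R1/R0", "R2/R1"))
  g <- exp(mean(log(ratios)))
  x_raw <- 1 / g
  structure(
    list(class_means = class_means, ratios = ratios, geo_mean_ratio = g,
         x_raw = x_raw, x = as.integer(round(x_raw))),
    class = "dbi_calibration"
  )
}

#' @export
print.dbi_calibration <- function(x, ...) {
  cat("Occupancy calibration of the probability-weight base\n")
  cat("  mean occupancy rate by DBID class:",
      paste(sprintf("R%s = %.3f", names(x$class_means), x$class_means),
            collapse = ", "), "\n")
  cat(sprintf("  successive ratios: %.4f, %.4f (geometric mean %.4f)\n",
              x$ratios[1], x$ratios[2], x$geo_mean_ratio))
  cat(sprintf("  recommended x = %d (unrounded %.4f)\n", x$x, x$x_raw))
  invisible(x)
}

# Runs `expr` without disturbing the caller's RNG stream.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  force(expr)
}
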