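# Community resolution against a pool, DBI_sum and DBI_mean, and the
# site x species community-matrix reader.

#' Resolve a raw site sample against a species pool
#'
#' Coerces abundances to presence (abundance > 0), collapses duplicate
#' records, matches names against the pool using the same normalization as
#' the checklist (whitespace/case-insensitive) and returns a validated
#' community. In strict mode an unmatched name is an error; in lenient mode
#' unmatched names are dropped and listed in the resolution report.
#'
#' @param raw The site sample: a character vector of species names
#'   (presence), a named numeric vector of abundances, or a data frame with
#'   columns `species` and `abundance`.
#' @param pool A [dbi_pool()].
#' @param strict If `TRUE`, any name not found in the pool is an error.
#' @param site Site label attached to the community.
#' @return An object of class `dbi_community`: list with `species` (pool
#'   spellings of the resolved members), `site`, and `report` (list with
#'   `unmatched`, `n_zero_abundance`, `n_collapsed`).
#' @examples
#' pool <- dbi_pool(c("Aeshna alpha", "Libellula beta"), dbi = c(7, 0))
#' resolve_community(c("aeshna  alpha", "Libellula beta"), pool)
#' @export
resolve_community <- function(raw, pool, strict = FALSE, site = "site") {
  stopifnot(inherits(pool, "dbi_pool"))
  if (is.data.frame(raw)) {
    if (!all(c("species", "abundance") %in% names(raw))) {
      stop("a data-frame sample needs columns 'species' and 'abundance'")
    }
    nm <- as.character(raw$species)
    ab <- raw$abundance
  } else if (is.character(raw)) {
    nm <- raw
    ab <- rep(1, length(raw))
  } else if (is.numeric(raw) && !is.null(names(raw))) {
    nm <- names(raw)
    ab <- unname(raw)
  } else {
    stop("raw sample must be a character vector, a named numeric vector, or a species/abundance data frame")
  }
  if (length(nm) == 0L) stop("raw sample is empty")
  if (!is.numeric(ab) || anyNA(suppressWarnings(as.numeric(ab)))) {
    stop("abundances must be numeric; non-numeric cells are an error, not absence")
  }
  ab <- as.numeric(ab)
  present <- ab > 0
  n_zero <- sum(!present)
  nm <- nm[present]
  key <- normalize_name(nm)
  n_collapsed <- sum(duplicated(key))
  keep <- !duplicated(key)
  nm <- nm[keep]
  key <- key[keep]
  pool_key <- normalize_name(pool$species)
  idx <- match(key, pool_key)
  unmatched <- nm[is.na(idx)]
  if (length(unmatched) > 0L && strict) {
    stop("species not in the pool: ", paste(unmatched, collapse = ", "))
  }
  members <- pool$species[idx[!is.na(idx)]]
  if (length(members) == 0L) {
    stop("community is empty after resolution (site '", site, "')")
  }
  structure(
    list(species = members, site = as.character(site),
         report = list(unmatched = unmatched, n_zero_abundance = n_zero,
                       n_collapsed = n_collapsed)),
    class = "dbi_community"
  )
}

#' @export
print.dbi_community <- function(x, ...) {
  cat(sprintf("DBI community '%s': %d species\n", x$site, length(x$species)))
  cat(" ", paste(x$species, collapse = ", "), "\n")
  if (length(x$report$unmatched) > 0L) {
    cat("  unmatched (dropped):", paste(x$report$unmatched, collapse = ", "), "\n")
  }
  invisible(x)
}

# Accepts a dbi_community or a character vector of names; returns the pool
# row indices of the members (strict matching for bare name vectors).
community_indices <- function(community, pool) {
  stopifnot(inherits(pool, "dbi_pool"))
  if (inherits(community, "dbi_community")) {
    nm <- community$species
  } else if (is.character(community)) {
    nm <- community
  } else {
    stop("community must be a dbi_community or a character vector of species names")
  }
  if (length(nm) == 0L) stop("community must contain at least one species")
  idx <- match(normalize_name(nm), normalize_name(pool$species))
  if (anyNA(idx)) {
    stop("species not in the pool: ", paste(nm[is.na(idx)], collapse = ", "))
  }
  unique(idx)
}

#' Community richness
#'
#' @param community A `dbi_community` or character vector of species names.
#' @return Number of distinct member species.
#' @export
richness <- function(community) {
  if (inherits(community, "dbi_community")) length(community$species)
  else length(unique(normalize_name(community)))
}

#' Total DBI score of a community (DBI_sum)
#'
#' The sum of the total DBI scores of all member species. Member order and
#' abundance magnitudes play no role: the index is strictly
#' presence/absence based.
#'
#' @param community A [resolve_community()] result or character vector of
#'   species names present in the pool.
#' @param pool The [dbi_pool()] carrying the scores.
#' @return Non-negative integer.
#' @export
dbi_sum <- function(community, pool) {
  idx <- community_indices(community, pool)
  sum(pool$dbi[idx])
}

#' Mean DBI score of a community (DBI_mean)
#'
#' `dbi_sum / richness`, at full precision; rounding to the customary two
#' decimals is display-only and left to the caller.
#'
#' @inheritParams dbi_sum
#' @return Non-negative real in \[0, 9\].
#' @export
dbi_mean <- function(community, pool) {
  idx <- community_indices(community, pool)
  sum(pool$dbi[idx]) / length(idx)
}

#' Read a site x species community matrix from CSV
#'
#' In the default orientation each row is one site: the first column is the
#' site label, the remaining column names are species and the cells are
#' abundances (or 0/1 presence). With `orientation = "species_as_rows"` the
#' matrix is transposed: first column species names, remaining columns
#' sites.
#'
#' @param path Path to the CSV file.
#' @param orientation `"sites_as_rows"` (default) or `"species_as_rows"`.
#' @return Named list (one element per site) of named numeric abundance
#'   vectors.
#' @export
read_community_matrix <- function(path,
                                  orientation = c("sites_as_rows", "species_as_rows")) {
  orientation <- match.arg(orientation)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8",
                    check.names = FALSE, strip.white = TRUE),
    error = function(e) stop("malformed community-matrix CSV '", path, "': ",
                             conditionMessage(e))
  )
  if (nrow(df) == 0L || ncol(df) < 2L) {
    stop("community matrix '", path, "' is empty")
  }
  labels <- as.character(df[[1L]])
  cells <- df[-1L]
  bad <- !vapply(cells, is.numeric, logical(1))
  if (any(bad)) {
    stop("non-numeric abundance cells in columns: ",
         paste(names(cells)[bad], collapse = ", "))
  }
  mat <- as.matrix(cells)
  if (orientation == "species_as_rows") {
    mat <- t(mat)
    colnames(mat) <- labels        # species
    labels <- names(cells)         # sites
  }
  out <- lapply(seq_len(nrow(mat)), function(i) {
    stats::setNames(as.numeric(mat[i, ]), colnames(mat))
  })
  names(out) <- labels
  out
}
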