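#' Observed mean absolute natal-destination trait difference
#'
#' Mean over all visit records of |trait(natal) - trait(destination)|.
#' Repeat visits by the same individual count once per record, so a
#' duplicated record enters the mean twice.
#'
#' @param visits A `visit_table`.
#' @param lakes A `lake_table` resolving the visit lake ids.
#' @param trait Lake-table trait column name.
#' @return The observed mean absolute difference (trait units).
#' @export
observed_mean_difference <- function(visits, lakes, trait) {
  if (nrow(visits) == 0) stop("empty visit set", call. = FALSE)
  z <- trait_by_id(lakes, trait)
  diffs <- abs(z[visits$natal_lake_id] - z[visits$destination_lake_id])
  if (any(is.na(diffs))) {
    stop("trait '", trait, "' missing on a referenced lake", call. = FALSE)
  }
  mean(diffs)
}

trait_by_id <- function(lakes, trait) {
  z <- lakes[[trait]]
  if (is.null(z)) stop("unknown trait: ", trait, call. = FALSE)
  names(z) <- lakes$lake_id
  z
}

#' Null resampling pool of candidate destination lakes
#'
#' The suitable lakes a uniform random chooser could have visited from a
#' given natal lake: every suitable lake except the natal lake itself, and —
#' when `radius_km` is given (the spatially constrained variant) — only
#' those within that great-circle distance of the natal lake. The actually
#' visited destination stays eligible.
#'
#' @param natal_id Natal lake id.
#' @param lakes A `lake_table`.
#' @param radius_km Optional constraint radius, km.
#' @param use_flag Restrict the pool to lakes flagged suitable?
#' @return Character vector of candidate destination lake ids.
#' @export
build_resampling_pool <- function(natal_id, lakes, radius_km = NULL,
                                  use_flag = TRUE) {
  if (nrow(lakes) == 0) stop("empty lake table", call. = FALSE)
  keep <- lakes$lake_id != natal_id
  if (use_flag) keep <- keep & !is.na(lakes$suitable) & lakes$suitable
  if (!is.null(radius_km)) {
    natal_row <- match(natal_id, lakes$lake_id)
    if (is.na(natal_row)) stop("unknown natal lake: ", natal_id,
                               call. = FALSE)
    d <- haversine_km(lakes$lat[natal_row], lakes$lon[natal_row],
                      lakes$lat, lakes$lon)
    keep <- keep & d <= radius_km
  }
  pool <- lakes$lake_id[keep]
  if (length(pool) == 0) {
    stop("empty resampling pool for natal lake ", natal_id, call. = FALSE)
  }
  pool
}

#' Monte Carlo randomization test of natal-destination trait similarity
#'
#' Tests whether juveniles visit lakes more similar in a trait to their natal
#' lake than a random chooser would. In each of `n_iterations` iterations
#' every visit's destination is replaced by a uniform draw, with replacement,
#' from that visit's null pool (suitable lakes excluding the natal lake,
#' optionally restricted to `pool_radius_km` — the spatially constrained
#' null that guards against spatial autocorrelation in the trait). The
#' iteration statistic is the mean absolute trait difference across visits.
#' The p-value is lower-tail with the add-one (permutation-style) correction:
#' `p = (#\{null <= observed\} + 1) / (n_iterations + 1)`, so the smallest
#' attainable p is `1/(n_iterations + 1)`, never zero.
#'
#' `subset_radius_km` implements the alternative, observation-subsetting
#' reading of the spatial constraint: visits whose actual natal-destination
#' distance exceeds it are dropped before testing, with the null pools left
#' unconstrained unless `pool_radius_km` is also set.
#'
#' @inheritParams observed_mean_difference
#' @param n_iterations Number of Monte Carlo iterations. Default 10000.
#' @param pool_radius_km Optional radius constraining each null pool.
#' @param subset_radius_km Optional radius subsetting the observations.
#' @param seed RNG seed; `NULL` leaves the RNG state alone.
#' @param use_flag Restrict null pools to lakes flagged suitable?
#' @return A `trait_diff_result` list: `trait`, `n_obs`,
#'   `observed_mean_abs_diff`, `null_mean`, `null_q025`, `null_q975`,
#'   `null_means` (the full null distribution), `n_iterations`, `p_value`,
#'   `pool_radius_km`, `subset_radius_km`, `seed`.
#' @export
randomization_test <- function(visits, lakes, trait, n_iterations = 10000,
                               pool_radius_km = NULL, subset_radius_km = NULL,
                               seed = NULL, use_flag = TRUE) {
  stopifnot(n_iterations >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(subset_radius_km)) {
    z_lat <- stats::setNames(lakes$lat, lakes$lake_id)
    z_lon <- stats::setNames(lakes$lon, lakes$lake_id)
    d <- haversine_km(z_lat[visits$natal_lake_id],
                      z_lon[visits$natal_lake_id],
                      z_lat[visits$destination_lake_id],
                      z_lon[visits$destination_lake_id])
    visits <- visits[d <= subset_radius_km, , drop = FALSE]
  }
  if (nrow(visits) == 0) {
    stop("no visits remain after subsetting", call. = FALSE)
  }
  z <- trait_by_id(lakes, trait)
  observed <- observed_mean_difference(visits, lakes, trait)

  n_vis <- nrow(visits)
  # each visit contributes an independent stream of |diff| draws from its
  # own pool; the per-iteration statistic is their mean
  null_sum <- numeric(n_iterations)
  pools <- lapply(unique(visits$natal_lake_id), function(nid) {
    abs(z[nid] - z[build_resampling_pool(nid, lakes, pool_radius_km,
                                         use_flag = use_flag)])
  })
  names(pools) <- unique(visits$natal_lake_id)
  for (i in seq_len(n_vis)) {
    pd <- pools[[visits$natal_lake_id[i]]]
    if (anyNA(pd)) {
      stop("trait '", trait, "' missing in the null pool of lake ",
           visits$natal_lake_id[i], call. = FALSE)
    }
    null_sum <- null_sum +
      pd[sample.int(length(pd), n_iterations, replace = TRUE)]
  }
  null_means <- null_sum / n_vis
  # ties between the observed statistic and null statistics are real (the
  # actual destination stays in the pool); count them with a tolerance so
  # floating-point summation order cannot flip a tie
  tie_tol <- 1e-9 * (abs(observed) + 1)
  q <- stats::quantile(null_means, c(0.025, 0.975), names = FALSE)
  structure(list(trait = trait, n_obs = n_vis,
                 observed_mean_abs_diff = observed,
                 null_mean = mean(null_means),
                 null_q025 = q[1], null_q975 = q[2],
                 null_means = null_means,
                 n_iterations = n_iterations,
                 p_value = (sum(null_means <= observed + tie_tol) + 1) /
                   (n_iterations + 1),
                 pool_radius_km = pool_radius_km,
                 subset_radius_km = subset_radius_km,
                 seed = seed),
            class = "trait_diff_result")
}

#' @export
print.trait_diff_result <- function(x, ...) {
  cat("Randomization test of natal-destination similarity in '",
      x$trait, "'\n", sep = "")
  cat(sprintf("  n = %d visits, %d iterations%s%s\n", x$n_obs, x$n_iterations,
              if (!is.null(x$pool_radius_km))
                sprintf(", pool constrained to %g km", x$pool_radius_km)
              else "",
              if (!is.null(x$subset_radius_km))
                sprintf(", visits within %g km", x$subset_radius_km)
              else ""))
  cat(sprintf("  observed mean |diff| = %.4f; null mean %.4f [%.4f, %.4f]\n",
              x$observed_mean_abs_diff, x$null_mean, x$null_q025, x$null_q975))
  cat(sprintf("  lower-tail p = %.4g\n", x$p_value))
  invisible(x)
}

#' Run randomization tests for every lake trait
#'
#' One [randomization_test()] per trait with independent sub-seeds derived
#' from `seed`, plus Bonferroni-adjusted significance decisions at
#' `alpha_family / length(traits)` (five traits at family alpha 0.05 give a
#' per-test alpha of 0.01).
#'
#' @inheritParams randomization_test
#' @param traits Trait columns to test; default the five basic traits.
#' @param alpha_family Family-wise error rate. Default 0.05.
#' @param collapse_per_juvenile Collapse repeat records so each
#'   juvenile-destination pair counts once? Default `FALSE` (the resampling
#'   unit is the visit record).
#' @return A `trait_diff_family` list: `results` (named by trait),
#'   `alpha_family`, `alpha_per_test`, `significant` (named logical).
#' @export
run_all_traits <- function(visits, lakes, traits = basic_traits(),
                           alpha_family = 0.05, n_iterations = 10000,
                           pool_radius_km = NULL, subset_radius_km = NULL,
                           seed = NULL, collapse_per_juvenile = FALSE) {
  if (collapse_per_juvenile) {
    key <- paste(visits$juvenile_id, visits$destination_lake_id)
    visits <- visits[!duplicated(key), , drop = FALSE]
  }
  alpha_per_test <- bonferroni_alpha(alpha_family, length(traits))
  results <- vector("list", length(traits))
  names(results) <- traits
  for (k in seq_along(traits)) {
    sub_seed <- if (is.null(seed)) NULL else (seed + k) %% .Machine$integer.max
    results[[k]] <- randomization_test(
      visits, lakes, traits[k], n_iterations = n_iterations,
      pool_radius_km = pool_radius_km, subset_radius_km = subset_radius_km,
      seed = sub_seed)
  }
  significant <- vapply(results, function(r) r$p_value <= alpha_per_test,
                        logical(1))
  structure(list(results = results, alpha_family = alpha_family,
                 alpha_per_test = alpha_per_test, significant = significant),
            class = "trait_diff_family")
}

#' @export
print.trait_diff_family <- function(x, ...) {
  cat(sprintf(
    "Trait-similarity randomization tests (per-test alpha %.4g = %.2g/%d)\n",
    x$alpha_per_test, x$alpha_family, length(x$results)))
  for (r in x$results) {
    cat(sprintf("  %-12s observed %.4f  null %.4f  p = %-8.4g %s\n",
                r$trait, r$observed_mean_abs_diff, r$null_mean, r$p_value,
                if (x$significant[[r$trait]]) "*" else ""))
  }
  invisible(x)
}

#' Serialize a trait-difference result (or family) to JSON
#'
#' Includes the full null distribution for downstream plotting.
#'
#' @param x A `trait_diff_result` or `trait_diff_family`.
#' @param path Optional output path.
#' @return JSON string (invisibly when written to `path`).
#' @export
result_to_json <- function(x, path = NULL) {
  obj <- if (inherits(x, "trait_diff_family")) {
    list(alpha_family = x$alpha_family, alpha_per_test = x$alpha_per_test,
         significant = as.list(x$significant),
         results = lapply(x$results, unclass))
  } else {
    unclass(x)
  }
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
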