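#' Per-chain Cα-Cα distance vector
#'
#' Euclidean distances (Å) for every canonical pair of one chain bundle, in
#' the order of [enumerate_pairs()]. Entries where either residue is masked
#' are `NA`.
#'
#' @param chain A chain-bundle tibble (one chain; see [extract_bundle()] or
#'   [make_ideal_bundle()]).
#' @param pairs The canonical pair table from [enumerate_pairs()].
#' @return Numeric vector of length `nrow(pairs)`.
#' @export
chain_distance_vector <- function(chain, pairs) {
  xyz <- chain_matrix(chain)
  n <- nrow(xyz)
  if (max(pairs$j) > n) {
    rlang::abort("Pair table indexes beyond the chain's bundle length",
                 class = "dsa_data_error")
  }
  d <- xyz[pairs$i, , drop = FALSE] - xyz[pairs$j, , drop = FALSE]
  sqrt(rowSums(d * d))
}

# N x 3 coordinate matrix, NA rows for masked positions
chain_matrix <- function(chain) {
  stopifnot(all(c("position", "x", "y", "z", "present") %in% names(chain)))
  chain <- dplyr::arrange(chain, .data$position)
  m <- as.matrix(chain[, c("x", "y", "z")])
  m[!chain$present, ] <- NA_real_
  m
}

# split an ensemble tibble into per-chain tibbles, first-appearance order
split_chains <- function(ensemble) {
  if (!"chain" %in% names(ensemble)) {
    rlang::abort("Ensemble tibble needs a 'chain' column", class = "dsa_data_error")
  }
  split(ensemble, factor(ensemble$chain, levels = unique(ensemble$chain)))
}

# n_pairs x n_chains distance matrix for an ensemble
distance_matrix <- function(ensemble, pairs) {
  chains <- split_chains(ensemble)
  matrix(vapply(chains, chain_distance_vector, numeric(nrow(pairs)),
                pairs = pairs),
         nrow = nrow(pairs), dimnames = list(NULL, names(chains)))
}

#' Per-pair ensemble statistics and the DSA score
#'
#' For every Cα-Cα pair, computes over the chains where both residues are
#' present: the mean distance, its standard deviation, and the DSA score =
#' mean / sd, i.e. the inverse of the coefficient of variation. The score is
#' dimensionless and high when the spacing is conserved across the ensemble;
#' it is `Inf` when the spread is exactly zero (e.g. rigid copies of one
#' structure) and `NA` (undefined) when fewer than `min_chains` chains define
#' the pair.
#'
#' @param ensemble Ensemble tibble: row-bound chain bundles sharing one
#'   bundle definition (a `chain` column identifies chains).
#' @param bundle The shared `bundle_def`.
#' @param std Standard-deviation convention: `"population"` (divide by n,
#'   default) or `"sample"` (n - 1). The choice rescales all finite scores by
#'   a common factor at fixed n and so never changes a ranking at constant
#'   coverage.
#' @param min_chains Minimum chains per pair for a defined score (default 3;
#'   a coefficient of variation over fewer points is not meaningful).
#' @param zero_sd_tol Relative numerical floor below which the spread counts
#'   as exactly zero: a pair with `sd < zero_sd_tol * mean` gets an infinite
#'   score. Rigid copies of one structure rotated by different matrices
#'   differ only by floating-point round-off (~1e-13 relative), far below
#'   the default 1e-12.
#' @return Tibble with one row per canonical pair: `pair`, `i`, `j`,
#'   `label_i`, `label_j`, `class`, `group`, `n_chains`, `mean`, `sd`,
#'   `score`.
#' @examples
#' spec <- synthetic_spec(n_chains = 4, seed = 1)
#' ens <- make_ensemble(spec)
#' st <- pair_statistics(ens, synthetic_bundle(spec$helix_lengths))
#' @export
pair_statistics <- function(ensemble, bundle,
                            std = c("population", "sample"),
                            min_chains = 3L, zero_sd_tol = 1e-12) {
  std <- match.arg(std)
  chains <- split_chains(ensemble)
  if (length(chains) < 2L) {
    rlang::abort("DSA needs at least 2 chains", class = "dsa_data_error")
  }
  for (ch in chains) {
    if (nrow(ch) != bundle$total_length) {
      rlang::abort(sprintf("Chain %s has %d positions but the bundle defines %d",
                           ch$chain[1], nrow(ch), bundle$total_length),
                   class = "dsa_data_error")
    }
  }
  pairs <- enumerate_pairs(bundle)
  D <- distance_matrix(ensemble, pairs)

  n <- rowSums(!is.na(D))
  mu <- rowMeans(D, na.rm = TRUE)
  mu[n == 0L] <- NA_real_
  dev2 <- rowSums((D - mu)^2, na.rm = TRUE)
  sd <- switch(std,
               population = sqrt(dev2 / n),
               sample = sqrt(dev2 / pmax(n - 1L, 1L)))
  sd[n < 2L] <- NA_real_
  score <- ifelse(sd <= zero_sd_tol * mu, Inf, mu / sd)
  score[n < min_chains] <- NA_real_

  dplyr::mutate(pairs, n_chains = n, mean = mu, sd = sd, score = score)
}

#' Rank pairs by descending DSA score
#'
#' Pairs with defined scores sorted by descending score. Infinite scores
#' (zero spread) come first; all ties, including among infinities, are broken
#' by canonical pair order, so the ranking is deterministic and stable across
#' runs. Undefined-score pairs are excluded and their count attached as the
#' `n_undefined` attribute.
#'
#' @param stats Pair-statistics tibble from [pair_statistics()] (optionally
#'   pre-filtered, e.g. to intrahelical pairs only).
#' @return The ranked tibble with a leading `rank` column (1 = highest
#'   score). Attributes: `n_undefined`, and `group_totals` (named counts of
#'   each `group` in the *input*, undefined pairs included) used as the
#'   default cumulative-ratio denominators.
#' @export
rank_pairs <- function(stats) {
  totals <- table(stats$group)
  defined <- dplyr::filter(stats, !is.na(.data$score))
  ranked <- dplyr::arrange(defined, dplyr::desc(.data$score), .data$pair)
  ranked <- dplyr::mutate(ranked, rank = dplyr::row_number(), .before = 1)
  attr(ranked, "n_undefined") <- nrow(stats) - nrow(defined)
  attr(ranked, "group_totals") <- totals
  ranked
}

#' Cumulative-ratio curves over the top-ranked pairs
#'
#' For each pair group g and each rank r = 1..`top_n`, the fraction of
#' group g's pairs found among ranks 1..r. Curves are non-decreasing in r and
#' lie in \[0, 1\]; a group whose pairs all rank high approaches 1 quickly.
#' This is the standard way to compare, e.g., which helices dominate the
#' top-1,000 intrahelical pairs.
#'
#' @param ranked Ranked tibble from [rank_pairs()].
#' @param top_n Number of top ranks to cover (default 1000).
#' @param totals Named vector of per-group pair totals used as denominators;
#'   defaults to the `group_totals` attribute left by [rank_pairs()].
#' @param denominator `"group"` (default): each curve is normalised by its
#'   own group's total; `"grand"`: by the grand total over all groups.
#' @return Tibble with columns `rank`, `group`, `count` (cumulative), and
#'   `ratio`.
#' @export
cumulative_ratio <- function(ranked, top_n = 1000L, totals = NULL,
                             denominator = c("group", "grand")) {
  denominator <- match.arg(denominator)
  if (top_n > nrow(ranked)) {
    rlang::abort(sprintf("top_n = %d exceeds the %d ranked pairs",
                         top_n, nrow(ranked)),
                 class = "dsa_data_error")
  }
  if (is.null(totals)) totals <- attr(ranked, "group_totals")
  if (is.null(totals)) totals <- table(ranked$group)
  totals <- stats::setNames(as.numeric(totals), names(totals))
  groups <- names(totals)
  top <- ranked[seq_len(top_n), ]
  empty <- setdiff(groups, unique(top$group))
  zero_total <- groups[totals == 0]
  if (length(zero_total)) {
    rlang::warn(paste("Empty group(s) with zero pairs:",
                      paste(zero_total, collapse = ", ")))
  }
  purrr::map_dfr(groups, function(g) {
    count <- cumsum(top$group == g)
    denom <- if (denominator == "group") totals[[g]] else sum(totals)
    tibble::tibble(rank = seq_len(top_n), group = g, count = count,
                   ratio = if (denom > 0) count / denom else 0)
  })
}

#' Score-versus-distance table for plotting
#'
#' One row per defined-score pair: the mean Cα-Cα distance (Å), the DSA
#' score, and the pair class, so intrahelical and interhelical populations
#' can be distinguished (classically drawn red and blue).
#'
#' @param stats Pair-statistics tibble from [pair_statistics()].
#' @return Tibble with columns `pair`, `label_i`, `label_j`, `class`,
#'   `group`, `mean`, `score`.
#' @export
score_distance_table <- function(stats) {
  stats |>
    dplyr::filter(!is.na(.data$score)) |>
    dplyr::select("pair", "label_i", "label_j", "class", "group",
                  "mean", "score")
}

#' Remove the linear distance dependence from DSA scores
#'
#' Scores can drift with the mean pair distance (long-range pairs sometimes
#' score systematically higher), so comparisons across distance ranges may
#' warrant a baseline correction. This optional correction — never applied
#' automatically — fits `score ~ mean` by least squares over the finite
#' defined scores and replaces each such score with its residual plus the
#' grand mean score, preserving the overall level. Infinite and undefined
#' scores are left untouched.
#'
#' @param stats Pair-statistics tibble from [pair_statistics()].
#' @return The tibble with a detrended `score` column and the original
#'   preserved as `score_raw`.
#' @export
detrend_scores <- function(stats) {
  ok <- is.finite(stats$score)
  if (sum(ok) < 3L) {
    rlang::abort("Too few finite scores to fit a distance trend",
                 class = "dsa_data_error")
  }
  fit <- stats::lm(score ~ mean, data = stats[ok, ])
  out <- dplyr::mutate(stats, score_raw = .data$score)
  out$score[ok] <- stats::residuals(fit) + mean(stats$score[ok])
  out
}

#' Run distance scoring analysis on an ensemble
#'
#' The end-to-end method on an in-memory ensemble: canonical pair
#' enumeration, per-pair distance statistics, the mean/sd score, and a
#' deterministic ranking. Returns a fitted-object style result with
#' [generics::tidy()], [generics::glance()] and [ggplot2::autoplot()]
#' methods.
#'
#' @inheritParams pair_statistics
#' @return An object of class `dsa`: a list with `stats` (the pair table),
#'   `ranked`, `bundle`, `n_chains`, `std`, `min_chains`.
#' @examples
#' spec <- synthetic_spec(n_chains = 5, seed = 7)
#' fit <- dsa(make_ensemble(spec), synthetic_bundle(spec$helix_lengths))
#' glance(fit)
#' @export
dsa <- function(ensemble, bundle, std = c("population", "sample"),
                min_chains = 3L) {
  std <- match.arg(std)
  stats <- pair_statistics(ensemble, bundle, std = std,
                           min_chains = min_chains)
  structure(
    list(stats = stats, ranked = rank_pairs(stats), bundle = bundle,
         n_chains = length(unique(ensemble$chain)), std = std,
         min_chains = min_chains),
    class = "dsa")
}

#' @export
print.dsa <- function(x, ...) {
  g <- generics::glance(x)
  cat(sprintf(
    "<dsa> %d chains, %d pairs (%d intra / %d inter), std = %s\n",
    x$n_chains, g$n_pairs, g$n_intra, g$n_inter, x$std))
  cat(sprintf("  defined scores: %d (of which %d infinite), undefined: %d\n",
              g$n_defined, g$n_infinite, g$n_undefined))
  if (is.finite(g$median_score)) {
    cat(sprintf("  median finite score: %.2f\n", g$median_score))
  }
  invisible(x)
}

#' Tidy and summarise a DSA fit
#'
#' `tidy()` returns the per-pair statistics table; `glance()` a one-row
#' summary of the run.
#'
#' @param x A `dsa` object.
#' @param ... Unused.
#' @return A tibble.
#' @importFrom generics tidy glance
#' @export
tidy.dsa <- function(x, ...) x$stats

#' @rdname tidy.dsa
#' @export
glance.dsa <- function(x, ...) {
  s <- x$stats
  finite <- s$score[is.finite(s$score)]
  tibble::tibble(
    n_chains = x$n_chains,
    n_pairs = nrow(s),
    n_intra = sum(s$class == "intra"),
    n_inter = sum(s$class == "inter"),
    n_defined = sum(!is.na(s$score)),
    n_infinite = sum(is.infinite(s$score)),
    n_undefined = sum(is.na(s$score)),
    median_score = if (length(finite)) stats::median(finite) else NA_real_,
    max_finite_score = if (length(finite)) max(finite) else NA_real_
  )
}
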