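#' Least-squares rigid superposition (Kabsch)
#'
#' Closed-form optimal rigid alignment of two Cα coordinate sets via SVD of
#' the covariance matrix, with the usual reflection correction so the
#' returned rotation is proper (determinant +1). Only positions present in
#' both sets are used.
#'
#' @param mobile,target Either N x 3 coordinate matrices (rows may contain
#'   `NA` for masked positions) or chain-bundle tibbles.
#' @return List with `rotation` (3 x 3, det = +1), `translation` (length 3),
#'   `rmsd` (Å, over the common mask after superposition), and `n` (common
#'   positions used). The transform maps mobile onto target:
#'   `target ~ mobile %*% t(rotation) + translation`.
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' superpose(a, a)$rmsd  # 0
#' @export
superpose <- function(mobile, target) {
  P <- as_coord_matrix(mobile)
  Q <- as_coord_matrix(target)
  if (nrow(P) != nrow(Q)) {
    rlang::abort("Coordinate sets differ in length", class = "dsa_data_error")
  }
  ok <- stats::complete.cases(P) & stats::complete.cases(Q)
  n <- sum(ok)
  if (n < 3L) {
    rlang::abort(sprintf("Superposition needs >= 3 common positions, got %d", n),
                 class = "dsa_data_error")
  }
  P <- P[ok, , drop = FALSE]
  Q <- Q[ok, , drop = FALSE]
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (degenerate_rank(Pc) || degenerate_rank(Qc)) {
    rlang::abort("Degenerate (collinear) coordinates: superposition is ill-posed",
                 class = "dsa_data_error")
  }
  s <- svd(crossprod(Pc, Qc))     # H = t(Pc) %*% Qc = U D t(V)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Qc)^2)))
  list(rotation = R, translation = as.numeric(cq - R %*% cp),
       rmsd = rmsd, n = n)
}

as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    return(x)
  }
  chain_matrix(x)
}

# TRUE if centered coords span < 2 dimensions (points on a line)
degenerate_rank <- function(Xc) {
  sv <- svd(Xc, nu = 0, nv = 0)$d
  sv[2] < max(sv[1], 1) * 1e-10
}

#' Pairwise superposition RMSD matrix of an ensemble
#'
#' For every chain pair, the Kabsch RMSD over the positions present in both
#' chains. For around a dozen near-identical 7TM bundles this is typically
#' of order 1 Å; a couple of Å separates family members of different
#' sequence.
#'
#' @param ensemble Ensemble tibble (row-bound chain bundles).
#' @return Long tibble with one row per unordered chain pair (`chain_a`,
#'   `chain_b`, `value`, `metric = "rmsd"`); convert with
#'   [pairwise_to_matrix()].
#' @export
pairwise_rmsd <- function(ensemble) {
  pairwise_metric(ensemble, "rmsd")
}

#' Pairwise correlation matrix of chain distance vectors
#'
#' Pearson correlation between two chains' Cα-Cα distance vectors over the
#' pairs defined in both. Distances are isometry-invariant, so this metric
#' needs no superposition; near-identical bundles correlate above 0.99.
#'
#' @inheritParams pairwise_rmsd
#' @param bundle The shared `bundle_def`.
#' @return Long tibble (`chain_a`, `chain_b`, `value`,
#'   `metric = "correlation"`). Chain pairs with fewer than 2 overlapping
#'   defined distances get `NA` with a warning.
#' @export
distance_correlation <- function(ensemble, bundle) {
  pairwise_metric(ensemble, "correlation", bundle = bundle)
}

pairwise_metric <- function(ensemble, metric, bundle = NULL) {
  chains <- split_chains(ensemble)
  if (length(chains) < 2L) {
    rlang::abort("Need >= 2 chains", class = "dsa_data_error")
  }
  ids <- names(chains)
  if (metric == "correlation") {
    pairs <- enumerate_pairs(bundle)
    vecs <- lapply(chains, chain_distance_vector, pairs = pairs)
  } else {
    mats <- lapply(chains, chain_matrix)
  }
  idx <- utils::combn(length(ids), 2)
  value <- apply(idx, 2, function(k) {
    a <- k[1]; b <- k[2]
    if (metric == "rmsd") {
      tryCatch(superpose(mats[[a]], mats[[b]])$rmsd,
               error = function(e) {
                 rlang::abort(sprintf("Superposition failed for %s vs %s: %s",
                                      ids[a], ids[b], conditionMessage(e)),
                              class = "dsa_data_error")
               })
    } else {
      va <- vecs[[a]]; vb <- vecs[[b]]
      ok <- !is.na(va) & !is.na(vb)
      if (sum(ok) < 2L) {
        rlang::warn(sprintf("Fewer than 2 overlapping pairs for %s vs %s: correlation undefined",
                            ids[a], ids[b]))
        NA_real_
      } else {
        stats::cor(va[ok], vb[ok])
      }
    }
  })
  tibble::tibble(chain_a = ids[idx[1, ]], chain_b = ids[idx[2, ]],
                 value = value,
                 metric = if (metric == "rmsd") "rmsd" else "correlation")
}

#' Long pairwise table to symmetric labelled matrix
#'
#' @param tbl Tibble from [pairwise_rmsd()] or [distance_correlation()].
#' @return Symmetric matrix with chain ids as dimnames; the diagonal is 0
#'   for RMSD and 1 for correlation.
#' @export
pairwise_to_matrix <- function(tbl) {
  ids <- unique(c(tbl$chain_a, tbl$chain_b))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  diag(m) <- if (tbl$metric[1] == "rmsd") 0 else 1
  m[cbind(tbl$chain_a, tbl$chain_b)] <- tbl$value
  m[cbind(tbl$chain_b, tbl$chain_a)] <- tbl$value
  m
}
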