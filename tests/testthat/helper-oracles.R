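# Independent brute-force oracles and small builders used across tests.
# These deliberately avoid the package's vectorised code paths.

# naive O(N^2 * M) per-pair statistics via explicit loops
brute_force_stats <- function(ensemble, bundle, std = "population",
                              min_chains = 3L) {
  chains <- split(ensemble, factor(ensemble$chain, levels = unique(ensemble$chain)))
  mats <- lapply(chains, function(ch) {
    ch <- ch[order(ch$position), ]
    m <- as.matrix(ch[, c("x", "y", "z")])
    m[!ch$present, ] <- NA_real_
    m
  })
  n <- bundle$total_length
  out <- list()
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- k + 1L
      d <- vapply(mats, function(m) {
        sqrt(sum((m[i, ] - m[j, ])^2))
      }, 0)
      d <- d[!is.na(d)]
      m_ <- mean(d)
      s_ <- if (length(d) >= 2) {
        if (std == "population") sqrt(mean((d - m_)^2)) else stats::sd(d)
      } else NA_real_
      sc <- if (length(d) < min_chains || is.na(s_)) NA_real_
            else if (s_ == 0) Inf else m_ / s_
      out[[k]] <- c(i = i, j = j, n = length(d), mean = m_, sd = s_, score = sc)
    }
  }
  as.data.frame(do.call(rbind, out))
}

# rotation about an arbitrary axis by `deg` degrees (Rodrigues)
rot_about <- function(axis, deg) {
  axis <- axis / sqrt(sum(axis^2))
  a <- deg * pi / 180
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# apply one rigid motion to a chain-bundle tibble
rigid_move <- function(chain, R, t) {
  xyz <- as.matrix(chain[, c("x", "y", "z")]) %*% t(R)
  chain$x <- xyz[, 1] + t[1]
  chain$y <- xyz[, 2] + t[2]
  chain$z <- xyz[, 3] + t[3]
  chain
}

# apply independent random rigid motions to every chain of an ensemble
rigid_jitter_ensemble <- function(ensemble, seed = 99) {
  set.seed(seed)
  chains <- split(ensemble, factor(ensemble$chain, levels = unique(ensemble$chain)))
  do.call(rbind, lapply(chains, function(ch) {
    rigid_move(ch, rot_about(stats::rnorm(3), stats::runif(1, 0, 180)),
               stats::runif(3, -20, 20))
  }))
}

# hand-built chain over an arbitrary bundle: coords is an N x 3 matrix
toy_chain <- function(coords, bundle, id = "TOY", chain_id = "A",
                      present = rep(TRUE, nrow(coords))) {
  pos <- bundle_positions(bundle)
  stopifnot(nrow(coords) == nrow(pos))
  tibble::tibble(
    chain = paste(id, chain_id, sep = "."), structure_id = id,
    chain_id = chain_id, position = pos$position, helix = pos$helix,
    helix_letter = pos$helix_letter, label = pos$label,
    x = ifelse(present, coords[, 1], NA_real_),
    y = ifelse(present, coords[, 2], NA_real_),
    z = ifelse(present, coords[, 3], NA_real_),
    present = present)
}

# minimal hand-formatted PDB ATOM records for CA-only fixtures
pdb_fixture_lines <- function(resno, xyz, chain = "A", alt = "", occ = 1,
                              elety = " CA ", resid = "ALA") {
  n <- length(resno)
  alt <- rep_len(alt, n); occ <- rep_len(occ, n)
  elety <- rep_len(elety, n)
  vapply(seq_len(n), function(k) {
    sprintf("ATOM  %5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
            k, elety[k], alt[k], resid, chain, resno[k],
            xyz[k, 1], xyz[k, 2], xyz[k, 3], occ[k], 0)
  }, "")
}

write_pdb_fixture <- function(lines, path = withr::local_tempfile(fileext = ".pdb",
                                                                  .local_envir = parent.frame())) {
  # renumber atom serials (cols 7-11) so concatenated fixtures stay unique
  for (k in seq_along(lines)) {
    substr(lines[k], 7, 11) <- sprintf("%5d", k)
  }
  writeLines(c(lines, "END"), path)
  path
}
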