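#' Parameters for the synthetic 7TM bundle generator
#'
#' The generator builds idealised seven-helix Cα bundles: regular helices
#' (default rise 1.5 Å/residue, 100 deg turn/residue, 2.3 Å helix radius, so
#' consecutive Cα are ~3.8 Å apart) placed on a circle of radius
#' `bundle_radius` with alternating up/down orientation, mimicking a
#' transmembrane bundle topologically. Ensembles add isotropic Gaussian
#' per-residue noise (per-helix sigma) plus one random rigid-body motion per
#' chain. Defaults emulate a set of near-identical experimental structures:
#' helix lengths follow the 170-residue microbial rhodopsin bundle, 13
#' chains, and sigma = 0.5 Å so that two chains differ by roughly
#' `sigma * sqrt(6)` ~ 1.2 Å Cα RMSD.
#'
#' @param helix_lengths Integer vector of 7 helix lengths (default
#'   22, 24, 22, 24, 28, 25, 25).
#' @param rise Helix rise per residue, Å.
#' @param turn Helix turn per residue, degrees.
#' @param helix_radius Cα helix radius, Å.
#' @param bundle_radius Helix placement circle radius, Å.
#' @param sigma Per-residue Gaussian noise sigma, Å: a scalar or a length-7
#'   per-helix vector.
#' @param max_rotation Maximum random rigid rotation per chain, degrees.
#' @param max_translation Maximum random rigid translation per chain, Å.
#' @param n_chains Default ensemble size.
#' @param seed Default random seed.
#' @return A validated list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(helix_lengths = c(22L, 24L, 22L, 24L, 28L, 25L, 25L),
                           rise = 1.5, turn = 100, helix_radius = 2.3,
                           bundle_radius = 11, sigma = 0.5,
                           max_rotation = 15, max_translation = 3,
                           n_chains = 13L, seed = 1L) {
  spec <- list(helix_lengths = as.integer(helix_lengths), rise = rise,
               turn = turn, helix_radius = helix_radius,
               bundle_radius = bundle_radius, sigma = sigma,
               max_rotation = max_rotation, max_translation = max_translation,
               n_chains = as.integer(n_chains), seed = as.integer(seed))
  check_field <- function(ok, field, why) {
    if (!ok) rlang::abort(sprintf("Invalid synthetic spec field '%s': %s", field, why),
                          class = "dsa_config_error")
  }
  check_field(length(spec$helix_lengths) >= 1 && all(spec$helix_lengths >= 2L),
              "helix_lengths", "all lengths must be >= 2")
  check_field(spec$rise > 0, "rise", "must be > 0")
  check_field(spec$turn > 0, "turn", "must be > 0")
  check_field(spec$helix_radius > 0, "helix_radius", "must be > 0")
  check_field(spec$bundle_radius > 0, "bundle_radius", "must be > 0")
  check_field(all(spec$sigma >= 0), "sigma", "must be >= 0")
  check_field(length(spec$sigma) %in% c(1L, length(spec$helix_lengths)),
              "sigma", "scalar or one value per helix")
  check_field(spec$max_rotation >= 0, "max_rotation", "must be >= 0")
  check_field(spec$max_translation >= 0, "max_translation", "must be >= 0")
  check_field(spec$n_chains >= 2L, "n_chains", "must be >= 2")
  structure(spec, class = "synthetic_spec")
}

#' Bundle definition matching a synthetic spec
#'
#' Builds a `bundle_def` for arbitrary helix lengths, centring each helix's
#' common range on its `h.50` anchor (start = 50 - floor((L-1)/2)).
#'
#' @param helix_lengths Integer vector of helix lengths (up to 7).
#' @return A `bundle_def`.
#' @export
synthetic_bundle <- function(helix_lengths = c(22L, 24L, 22L, 24L, 28L, 25L, 25L)) {
  n <- length(helix_lengths)
  stopifnot(n >= 1, n <= 7)
  start <- 50L - (as.integer(helix_lengths) - 1L) %/% 2L
  end <- start + as.integer(helix_lengths) - 1L
  suppressWarnings(bundle_definition(
    tibble::tibble(helix = seq_len(n),
                   common_start = render_label(seq_len(n), start),
                   common_end = render_label(seq_len(n), end)),
    family = "synthetic", min_helix_length = 0L))
}

#' Generate one idealised 7TM Cα bundle
#'
#' Deterministic (noise-free) reference chain: helix k sits at angle
#' 2*pi*(k-1)/7 on the placement circle, runs along z with alternating
#' direction, and traces a regular helix with the spec's rise, turn and
#' radius. All positions are present.
#'
#' @param spec A `synthetic_spec`.
#' @param structure_id,chain_id Identifiers stamped on the chain.
#' @return A chain-bundle tibble (same shape as [extract_bundle()] output).
#' @export
make_ideal_bundle <- function(spec, structure_id = "IDEAL", chain_id = "A") {
  stopifnot(inherits(spec, "synthetic_spec"))
  bundle <- synthetic_bundle(spec$helix_lengths)
  pos <- bundle_positions(bundle)
  nh <- length(spec$helix_lengths)
  coords <- purrr::map_dfr(seq_len(nh), function(k) {
    len <- spec$helix_lengths[k]
    phi <- 2 * pi * (k - 1) / nh
    dir <- if (k %% 2 == 1) 1 else -1
    i <- seq_len(len) - 1L
    theta <- phi + pi + dir * i * spec$turn * pi / 180
    tibble::tibble(
      x = spec$bundle_radius * cos(phi) + spec$helix_radius * cos(theta),
      y = spec$bundle_radius * sin(phi) + spec$helix_radius * sin(theta),
      z = dir * (i - (len - 1) / 2) * spec$rise
    )
  })
  tibble::tibble(
    chain = paste(structure_id, chain_id, sep = "."),
    structure_id = structure_id, chain_id = chain_id,
    position = pos$position, helix = pos$helix,
    helix_letter = pos$helix_letter, label = pos$label,
    x = coords$x, y = coords$y, z = coords$z, present = TRUE
  )
}

#' Generate a perturbed synthetic ensemble
#'
#' Each chain is the ideal bundle plus independent isotropic Gaussian
#' displacement per residue (standard deviation by helix) and one random
#' rigid-body motion (rotation up to `max_rotation` degrees about a uniform
#' random axis, translation uniform in a cube of half-width
#' `max_translation`). Distance statistics are isometry-invariant, so the
#' rigid jitter exercises superposition code without affecting DSA scores.
#' Fully reproducible: the same seed and spec give bit-identical output.
#'
#' @param spec A `synthetic_spec`.
#' @param n_chains,seed Override the spec's defaults.
#' @param sigma Override the spec's per-helix noise (scalar or length-7).
#' @param declared_missing Character vector of common labels to mask in
#'   every chain (exercises partial-presence handling).
#' @return An ensemble tibble of `n_chains` chain bundles, chains named
#'   `SYN01.A`, `SYN02.A`, ...
#' @export
make_ensemble <- function(spec, n_chains = spec$n_chains, seed = spec$seed,
                          sigma = spec$sigma, declared_missing = character()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_chains < 2L) {
    rlang::abort("n_chains must be >= 2", class = "dsa_config_error")
  }
  sig <- rep_len(sigma, length(spec$helix_lengths))
  ideal <- make_ideal_bundle(spec)
  xyz0 <- as.matrix(ideal[, c("x", "y", "z")])
  sig_per_pos <- sig[ideal$helix]
  mask <- ideal$label %in% declared_missing

  set.seed(seed)
  purrr::map_dfr(seq_len(n_chains), function(c_idx) {
    n <- nrow(xyz0)
    noise <- matrix(stats::rnorm(3 * n, sd = sig_per_pos), n, 3)
    xyz <- xyz0 + noise
    R <- random_rotation(spec$max_rotation)
    t <- stats::runif(3, -spec$max_translation, spec$max_translation)
    xyz <- sweep(xyz %*% t(R), 2, t, "+")
    ch <- ideal
    ch$structure_id <- sprintf("SYN%02d", c_idx)
    ch$chain <- paste(ch$structure_id, ch$chain_id, sep = ".")
    ch$x <- xyz[, 1]; ch$y <- xyz[, 2]; ch$z <- xyz[, 3]
    if (any(mask)) {
      ch$present[mask] <- FALSE
      ch$x[mask] <- NA_real_; ch$y[mask] <- NA_real_; ch$z[mask] <- NA_real_
    }
    ch
  })
}

# proper rotation about a uniform random axis, angle uniform in [0, max_deg]
random_rotation <- function(max_deg) {
  if (max_deg == 0) return(diag(3))
  axis <- stats::rnorm(3)
  axis <- axis / sqrt(sum(axis^2))
  angle <- stats::runif(1, 0, max_deg * pi / 180)
  K <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Generate a synthetic aligned sequence set with planted conservation
#'
#' Column c of the alignment carries a designated top residue with
#' probability `levels[c]` per sequence; otherwise one of the other 19 amino
#' acids is drawn uniformly, so the expected top-residue fraction equals the
#' level exactly. Useful as a test double for conservation profiling and
#' anchor assignment.
#'
#' @param n_sequences Number of sequences.
#' @param levels Numeric vector in \[0, 1\], one conservation level per
#'   column.
#' @param seed Random seed.
#' @param top_residues Optional character vector of planted top residues
#'   (default: cycle through the 20 amino acids).
#' @return Named character vector of aligned sequences (`seq001`, ...).
#' @export
make_synthetic_msa <- function(n_sequences, levels, seed = 1L,
                               top_residues = NULL) {
  stopifnot(n_sequences >= 1, all(levels >= 0), all(levels <= 1))
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  n_col <- length(levels)
  if (is.null(top_residues)) {
    top_residues <- aa20[(seq_len(n_col) - 1L) %% 20L + 1L]
  }
  stopifnot(length(top_residues) == n_col, all(top_residues %in% aa20))
  set.seed(seed)
  mat <- matrix("", n_sequences, n_col)
  for (cc in seq_len(n_col)) {
    hit <- stats::runif(n_sequences) < levels[cc]
    others <- setdiff(aa20, top_residues[cc])
    mat[, cc] <- ifelse(hit, top_residues[cc],
                        sample(others, n_sequences, replace = TRUE))
  }
  seqs <- apply(mat, 1, paste, collapse = "")
  stats::setNames(seqs, sprintf("seq%03d", seq_len(n_sequences)))
}

#' Write aligned sequences as FASTA
#'
#' @param seqs Named character vector of aligned sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Author-numbering map for synthetic ensembles
#'
#' Assigns contiguous author residue ranges to each helix with a 10-residue
#' loop gap between helices (helix 1 starts at residue 10), producing a
#' mapping table in the same format as [read_residue_mappings()].
#'
#' @param helix_lengths Helix lengths of the synthetic bundle.
#' @param structure_ids Structure ids to map (one row set per structure).
#' @param chain_id Chain id (synthetic chains are single-chain).
#' @return A mapping tibble.
#' @export
synthetic_mapping <- function(helix_lengths, structure_ids, chain_id = "A") {
  start <- 10L + c(0L, cumsum(as.integer(helix_lengths[-length(helix_lengths)]) + 10L))
  end <- start + as.integer(helix_lengths) - 1L
  purrr::map_dfr(structure_ids, function(sid) {
    tibble::tibble(structure_id = sid, chain_id = chain_id,
                   helix = seq_along(helix_lengths),
                   author_start = start, author_end = end,
                   missing_labels = "")
  })
}

#' Write a synthetic ensemble as minimal PDB files
#'
#' One single-chain Cα-only PDB file per structure (named
#' `<structure_id>.pdb`), with author residue numbers from
#' [synthetic_mapping()], so the full file-reading path can be exercised
#' end-to-end without downloads.
#'
#' @param ensemble Ensemble tibble from [make_ensemble()].
#' @param dir Output directory (created if needed).
#' @return Tibble with `structure_id` and `path` of the written files.
#' @export
write_ensemble_pdb <- function(ensemble, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  chains <- split_chains(ensemble)
  lengths <- dplyr::count(chains[[1]], .data$helix)$n
  amap <- synthetic_mapping(lengths, structure_ids = "x")
  author_of_position <- unlist(purrr::map2(amap$author_start, amap$author_end, seq))
  purrr::map_dfr(chains, function(ch) {
    ch <- dplyr::arrange(ch, .data$position)
    keep <- ch$present
    path <- file.path(dir, paste0(ch$structure_id[1], ".pdb"))
    xyz <- as.vector(t(as.matrix(ch[keep, c("x", "y", "z")])))
    natom <- sum(keep)
    bio3d::write.pdb(file = path, xyz = xyz,
                     resno = author_of_position[keep],
                     chain = rep(ch$chain_id[1], natom),
                     resid = rep("ALA", natom), elety = rep("CA", natom),
                     o = rep(1, natom), b = rep(0, natom))
    tibble::tibble(structure_id = ch$structure_id[1], path = path)
  })
}
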