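#' Read Cα coordinates of one chain from a PDB or mmCIF file
#'
#' Parses a coordinate file (via bio3d), keeps the requested chain's Cα
#' atoms, and resolves alternate locations deterministically: the highest
#' occupancy wins, ties broken by altloc identifier order (so `'A'` beats
#' `'B'`). Residues without a Cα atom are simply absent from the result.
#' Insertion codes are not supported and raise an error (none occur in the
#' microbial rhodopsin entries this package targets).
#'
#' @param path Path to a `.pdb` or `.cif`/`.mmcif` file; the format is chosen
#'   by extension.
#' @param chain_id Chain identifier (author asym id).
#' @return Tibble with columns `resno` (author residue number, integer,
#'   strictly increasing), `x`, `y`, `z` (Å).
#' @export
read_ca_coordinates <- function(path, chain_id) {
  if (!file.exists(path)) {
    rlang::abort(paste("Structure file not found:", path),
                 class = "dsa_config_error")
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    switch(ext,
           cif = ,
           mmcif = bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE),
           bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)),
    error = function(e) {
      rlang::abort(paste0("Could not parse structure file ", path, ": ",
                          conditionMessage(e)),
                   class = "dsa_data_error")
    })
  atoms <- tibble::as_tibble(pdb$atom)
  avail <- unique(atoms$chain)
  if (!chain_id %in% avail) {
    rlang::abort(sprintf("Chain '%s' not found in %s (available: %s)",
                         chain_id, basename(path),
                         paste(avail, collapse = ", ")),
                 class = "dsa_data_error")
  }
  ca <- dplyr::filter(atoms, .data$chain == chain_id, .data$elety == "CA",
                      is.na(.data$type) | .data$type == "ATOM")
  if (any(!is.na(ca$insert) & nzchar(ca$insert))) {
    rlang::abort(sprintf("Insertion codes in %s chain %s are not supported",
                         basename(path), chain_id),
                 class = "dsa_data_error")
  }
  alt <- dplyr::coalesce(as.character(ca$alt), "")
  occ <- dplyr::coalesce(as.numeric(ca$o), 1)
  ca |>
    dplyr::mutate(.alt = alt, .occ = occ) |>
    dplyr::arrange(.data$resno, dplyr::desc(.data$.occ), .data$.alt) |>
    dplyr::distinct(.data$resno, .keep_all = TRUE) |>
    dplyr::transmute(resno = as.integer(.data$resno),
                     x = .data$x, y = .data$y, z = .data$z)
}

#' Extract a fixed-length Cα bundle from one chain
#'
#' Fills the bundle positions in helix order from a chain's Cα map using the
#' chain's residue mapping. Within each helix the author residues are
#' assigned, in increasing order, to the helix's common positions excluding
#' any declared-missing labels. Declared-missing positions and residues
#' absent from the file (missing density) are masked, not errors; undeclared
#' absences additionally emit a warning. An author range that extends beyond
#' the chain's observed residue span indicates a mapping bug, not missing
#' density, and is a hard error naming the helix and range.
#'
#' @param ca_map Tibble from [read_ca_coordinates()] (`resno`, `x`, `y`, `z`).
#' @param mapping Mapping rows for this structure/chain
#'   (see [read_residue_mappings()]).
#' @param bundle A `bundle_def`.
#' @return A chain-bundle tibble: one row per bundle position with columns
#'   `chain` (structure_id.chain_id), `structure_id`, `chain_id`, `position`,
#'   `helix`, `helix_letter`, `label`, `x`, `y`, `z`, `present`. Masked
#'   positions have `present = FALSE` and `NA` coordinates.
#' @export
extract_bundle <- function(ca_map, mapping, bundle) {
  m <- validate_mapping(mapping, bundle)
  pos <- bundle_positions(bundle)
  sid <- m$structure_id[1]; cid <- m$chain_id[1]

  rows <- purrr::pmap_dfr(
    list(m$helix, m$author_start, m$author_end, m$missing_labels,
         m$common_start, m$length),
    function(hx, a0, a1, miss, c_start, len) {
      p0 <- parse_label(c_start)$position
      labels <- render_label(hx, p0 + seq_len(len) - 1L)
      declared <- trimws(strsplit(miss, ",")[[1]])
      declared <- declared[nzchar(declared)]
      bad_lab <- setdiff(declared, labels)
      if (length(bad_lab)) {
        rlang::abort(sprintf("Declared missing label(s) %s not in helix %s",
                             paste(bad_lab, collapse = ", "),
                             helix_letter(hx)),
                     class = "dsa_config_error")
      }
      fill <- !labels %in% declared
      authors <- rep(NA_integer_, len)
      authors[fill] <- seq.int(a0, a1)
      if (a1 > max(ca_map$resno) || a0 < min(ca_map$resno)) {
        rlang::abort(sprintf(
          "Mapping for %s.%s helix %s: author range %d-%d extends beyond the chain's residues (%d-%d)",
          sid, cid, helix_letter(hx), a0, a1,
          min(ca_map$resno), max(ca_map$resno)),
          class = "dsa_config_error")
      }
      tibble::tibble(label = labels, author = authors)
    })

  rows <- dplyr::left_join(rows, ca_map, by = c(author = "resno"))
  rows$present <- !is.na(rows$x)
  undeclared <- rows$author[!is.na(rows$author) & !rows$present]
  if (length(undeclared)) {
    rlang::warn(sprintf(
      "%s.%s: %d mapped residue(s) absent from the file (masked): %s",
      sid, cid, length(undeclared), paste(undeclared, collapse = ", ")))
  }
  stopifnot(nrow(rows) == bundle$total_length, identical(rows$label, pos$label))
  tibble::tibble(
    chain = paste(sid, cid, sep = "."),
    structure_id = sid, chain_id = cid,
    position = pos$position, helix = pos$helix,
    helix_letter = pos$helix_letter, label = pos$label,
    x = rows$x, y = rows$y, z = rows$z, present = rows$present
  )
}

#' Read a full ensemble of chain bundles from structure files
#'
#' Convenience driver: for every distinct structure/chain in a mapping table,
#' reads its coordinate file from `dir` (named `<structure_id>.pdb` or
#' `.cif`) and extracts its bundle.
#'
#' @param dir Directory containing the coordinate files.
#' @param mappings Full mapping table (all chains).
#' @param bundle A `bundle_def`.
#' @return An ensemble tibble: row-bound chain bundles (see
#'   [extract_bundle()]).
#' @export
read_ensemble <- function(dir, mappings, bundle) {
  mappings <- tibble::as_tibble(mappings)
  keys <- dplyr::distinct(mappings, .data$structure_id, .data$chain_id)
  purrr::pmap_dfr(keys, function(structure_id, chain_id) {
    candidates <- file.path(dir, paste0(structure_id, c(".pdb", ".cif", ".mmcif")))
    path <- candidates[file.exists(candidates)][1]
    if (is.na(path)) {
      rlang::abort(sprintf("No coordinate file for %s in %s", structure_id, dir),
                   class = "dsa_config_error")
    }
    m <- dplyr::filter(mappings, .data$structure_id == !!structure_id,
                       .data$chain_id == !!chain_id)
    extract_bundle(read_ca_coordinates(path, chain_id), m, bundle)
  })
}

#' Write / read the per-pair statistics table
#'
#' Tab-separated, one row per pair: pair index, common labels, class, group,
#' `n_chains`, `mean` (Å), `sd` (Å), `score`. Numbers are written with full
#' precision so a write-read round trip reproduces the input to text-float
#' precision; infinite scores survive the round trip.
#'
#' @param stats Pair-statistics tibble from [pair_statistics()].
#' @param path Output TSV path.
#' @return `write_pair_table()` the path, invisibly; `read_pair_table()` the
#'   tibble.
#' @export
write_pair_table <- function(stats, path) {
  if (!nrow(stats)) {
    rlang::abort("Refusing to write an empty pair table", class = "dsa_data_error")
  }
  readr::write_tsv(stats, path)
  invisible(path)
}

#' @rdname write_pair_table
#' @export
read_pair_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    label_i = "c", label_j = "c", class = "c", group = "c",
                    .default = readr::col_guess()))
}

#' Write a labelled symmetric matrix as TSV
#'
#' @param mat Square matrix with dimnames (e.g. from [pairwise_to_matrix()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(mat, path) {
  tbl <- tibble::as_tibble(mat, rownames = "chain")
  readr::write_tsv(tbl, path)
  invisible(path)
}
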