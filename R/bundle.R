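#' Define a fixed-length 7TM helix bundle
#'
#' A bundle definition fixes, once per protein family, which common-numbered
#' positions make up the comparable helical core: seven ordered helix
#' segments, each an inclusive common-label range containing its `h.50`
#' anchor. Every structure in an ensemble is then reduced to this fixed set
#' of positions so that Cα-Cα distances are comparable pair-by-pair.
#'
#' @param helices A data frame with one row per helix and columns `helix`
#'   (1-7 or A-G), `common_start`, `common_end` (labels, e.g. `"1.34"`,
#'   `"1.55"`), and optionally `anchor_conservation` (percent, metadata only).
#' @param family Family name, e.g. `"microbial rhodopsin"`.
#' @param min_helix_length Helices shorter than this trigger a warning (the
#'   microbial-rhodopsin convention uses at least 22 residues per helix,
#'   about six turns); the definition is still accepted for other families.
#' @return An object of class `bundle_def`: a list with `family`, a `helices`
#'   tibble (`helix`, `helix_letter`, `common_start`, `common_end`, `anchor`,
#'   `length`, `anchor_conservation`, `offset`) and `total_length`.
#' @examples
#' b <- mr_bundle()
#' b$total_length             # 170
#' nrow(enumerate_pairs(b))   # 14365
#' @export
bundle_definition <- function(helices, family = "unnamed",
                              min_helix_length = 22L) {
  helices <- tibble::as_tibble(helices)
  req <- c("helix", "common_start", "common_end")
  missing_cols <- setdiff(req, names(helices))
  if (length(missing_cols)) {
    rlang::abort(paste("Bundle definition lacks column(s):",
                       paste(missing_cols, collapse = ", ")),
                 class = "dsa_config_error")
  }
  h <- helix_number(helices$helix)
  s <- parse_label(as.character(helices$common_start))
  e <- parse_label(as.character(helices$common_end))
  if (any(s$helix != h) || any(e$helix != h)) {
    rlang::abort("Common range labels must match their helix numeral",
                 class = "dsa_config_error")
  }
  if (any(e$position < s$position)) {
    rlang::abort("Helix common_end precedes common_start", class = "dsa_config_error")
  }
  if (anyDuplicated(h)) {
    rlang::abort("Duplicate helix identifiers in bundle definition",
                 class = "dsa_config_error")
  }
  if (nrow(helices) != 7L) {
    rlang::warn(sprintf("Bundle has %d helices; the 7TM convention expects 7",
                        nrow(helices)))
  }
  len <- e$position - s$position + 1L
  if (any(s$position > 50L | e$position < 50L)) {
    rlang::abort("Each helix common range must contain its h.50 anchor",
                 class = "dsa_config_error")
  }
  if (any(len < min_helix_length)) {
    rlang::warn(sprintf(
      "Helix length(s) %s below the %d-residue convention",
      paste(len[len < min_helix_length], collapse = ", "), min_helix_length))
  }
  ord <- order(h)
  tbl <- tibble::tibble(
    helix = h,
    helix_letter = LETTERS[h],
    common_start = render_label(h, s$position),
    common_end = render_label(h, e$position),
    anchor = render_label(h, 50L),
    length = len,
    anchor_conservation = if ("anchor_conservation" %in% names(helices))
      as.numeric(helices$anchor_conservation) else NA_real_
  )[ord, ]
  tbl$offset <- cumsum(c(0L, tbl$length[-nrow(tbl)]))
  structure(
    list(family = family, helices = tbl, total_length = sum(tbl$length)),
    class = "bundle_def"
  )
}

#' @export
print.bundle_def <- function(x, ...) {
  cat(sprintf("<bundle_def> %s: %d helices, %d positions, %d pairs\n",
              x$family, nrow(x$helices), x$total_length,
              x$total_length * (x$total_length - 1L) / 2L))
  print(x$helices)
  invisible(x)
}

#' The curated 170-residue microbial rhodopsin bundle
#'
#' The reference bundle definition for microbial rhodopsins: seven helices of
#' 22, 24, 22, 24, 28, 25 and 25 residues (170 positions, 14,365 Cα-Cα
#' pairs), with anchors at the most conserved position of each helix
#' (e.g. 7.50 = the retinal-binding lysine, 100% conserved; 3.50 = Arg, 98%).
#' Shipped as a plain TSV under `inst/extdata` together with the
#' bacteriorhodopsin author-numbering map ([mr_bR_mapping()]).
#'
#' @return A `bundle_def` (see [bundle_definition()]).
#' @export
mr_bundle <- function() {
  read_bundle_definition(
    system.file("extdata", "mr_bundle_definition.tsv", package = "dsa7tm",
                mustWork = TRUE),
    family = "microbial rhodopsin")
}

#' Bacteriorhodopsin residue mapping for the reference bundle
#'
#' Author-numbering ranges of the seven bundle helices in bacteriorhodopsin
#' (PDB-style serial numbers, e.g. helix G = residues 202-226 so that Lys216
#' is 7.50), as a residue-mapping tibble usable with [extract_bundle()].
#'
#' @return A tibble with one row per helix (see [read_residue_mappings()]).
#' @export
mr_bR_mapping <- function() {
  read_residue_mappings(
    system.file("extdata", "bR_mapping.tsv", package = "dsa7tm",
                mustWork = TRUE))
}

#' Per-position table of a bundle definition
#'
#' Expands a bundle definition into one row per bundle position in helix
#' order A to G: the canonical indexing every chain, distance vector and pair
#' enumeration uses.
#'
#' @param bundle A `bundle_def`.
#' @return Tibble with columns `position` (1..total_length), `helix`,
#'   `helix_letter`, `label`.
#' @export
bundle_positions <- function(bundle) {
  stopifnot(inherits(bundle, "bundle_def"))
  h <- bundle$helices
  purrr::pmap_dfr(
    list(h$helix, h$common_start, h$length),
    function(hx, start, len) {
      p0 <- parse_label(start)$position
      tibble::tibble(helix = hx, helix_letter = LETTERS[hx],
                     label = render_label(hx, p0 + seq_len(len) - 1L))
    }) |>
    dplyr::mutate(position = dplyr::row_number(), .before = 1)
}

#' Enumerate all Cα-Cα residue pairs of a bundle
#'
#' All unordered position pairs (i < j) in the canonical order: row-major
#' over bundle positions 1..N in helix order A to G, i.e. (1,2), (1,3), ...,
#' (1,N), (2,3), ... This fixed order is the tie-break used by [rank_pairs()]
#' and matches the layout of [chain_distance_vector()]. Pairs within one
#' helix are intrahelical; pairs spanning two helices are interhelical. The
#' 170-position microbial rhodopsin bundle yields 14,365 pairs: 1,992
#' intrahelical and 12,373 interhelical.
#'
#' @param bundle A `bundle_def`.
#' @return Tibble with columns `pair` (1..N(N-1)/2), `i`, `j` (positions),
#'   `label_i`, `label_j`, `class` (`"intra"`/`"inter"`) and `group` (the
#'   helix letter, e.g. `"B"`, or the helix pair, e.g. `"C-G"`).
#' @export
enumerate_pairs <- function(bundle) {
  pos <- bundle_positions(bundle)
  n <- nrow(pos)
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2:n)
  hi <- pos$helix_letter[i]
  hj <- pos$helix_letter[j]
  intra <- hi == hj
  tibble::tibble(
    pair = seq_along(i), i = i, j = j,
    label_i = pos$label[i], label_j = pos$label[j],
    class = ifelse(intra, "intra", "inter"),
    group = ifelse(intra, hi, paste(hi, hj, sep = "-"))
  )
}

#' Read and write bundle-definition files
#'
#' Plain TSV with one row per helix and columns `helix`, `common_start`,
#' `common_end`, `anchor_label`, and optionally `anchor_conservation`. The
#' `anchor_label` column is redundant (always `h.50`) but kept in the file
#' for human readers and validated on read.
#'
#' @param path Path to a TSV file.
#' @param family Family name attached to the definition.
#' @param bundle A `bundle_def` to write.
#' @return `read_bundle_definition()` a `bundle_def`;
#'   `write_bundle_definition()` the path, invisibly.
#' @export
read_bundle_definition <- function(path, family = "unnamed") {
  if (!file.exists(path)) {
    rlang::abort(paste("Bundle definition file not found:", path),
                 class = "dsa_config_error")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(
                           helix = "c", common_start = "c", common_end = "c",
                           anchor_label = "c", .default = readr::col_guess()))
  if ("anchor_label" %in% names(tbl)) {
    expect <- render_label(helix_number(tbl$helix), 50L)
    if (!all(tbl$anchor_label == expect)) {
      rlang::abort("anchor_label column disagrees with the h.50 convention",
                   class = "dsa_config_error")
    }
  }
  bundle_definition(tbl, family = family)
}

#' @rdname read_bundle_definition
#' @export
write_bundle_definition <- function(bundle, path) {
  stopifnot(inherits(bundle, "bundle_def"))
  out <- dplyr::select(bundle$helices, "helix", "common_start", "common_end",
                       anchor_label = "anchor", "anchor_conservation")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read structure-to-bundle residue mappings
#'
#' One row per structure chain per helix: `structure_id`, `chain_id`,
#' `helix`, `author_start`, `author_end`, `missing_labels` (comma-separated
#' common labels declared absent in this chain; may be empty). The author
#' range length must equal the helix length minus the number of declared
#' missing labels.
#'
#' @param path TSV file path.
#' @param mappings A mapping tibble to write.
#' @return A tibble with the columns above (`missing_labels` as a character
#'   column, `""` for none).
#' @export
read_residue_mappings <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste("Residue mapping file not found:", path),
                 class = "dsa_config_error")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE, comment = "#",
                         col_types = readr::cols(
                           structure_id = "c", chain_id = "c",
                           .default = readr::col_guess()))
  req <- c("structure_id", "chain_id", "helix", "author_start", "author_end")
  missing_cols <- setdiff(req, names(tbl))
  if (length(missing_cols)) {
    rlang::abort(paste("Residue mapping lacks column(s):",
                       paste(missing_cols, collapse = ", ")),
                 class = "dsa_config_error")
  }
  if (!"missing_labels" %in% names(tbl)) tbl$missing_labels <- ""
  tbl$missing_labels <- dplyr::coalesce(as.character(tbl$missing_labels), "")
  tbl$helix <- helix_number(tbl$helix)
  tbl$author_start <- as.integer(tbl$author_start)
  tbl$author_end <- as.integer(tbl$author_end)
  tibble::as_tibble(tbl)
}

#' @rdname read_residue_mappings
#' @export
write_residue_mappings <- function(mappings, path) {
  readr::write_tsv(tibble::as_tibble(mappings), path)
  invisible(path)
}

# validate one structure/chain's mapping rows against a bundle definition;
# returns rows joined with helix metadata, in helix order
validate_mapping <- function(mapping, bundle) {
  stopifnot(inherits(bundle, "bundle_def"))
  m <- tibble::as_tibble(mapping)
  if (!"missing_labels" %in% names(m)) m$missing_labels <- ""
  key <- unique(paste(m$structure_id, m$chain_id))
  if (length(key) != 1L) {
    rlang::abort("validate_mapping() expects rows for exactly one chain",
                 class = "dsa_config_error")
  }
  m$helix <- helix_number(m$helix)
  m <- dplyr::arrange(m, .data$helix)
  if (!identical(m$helix, bundle$helices$helix)) {
    rlang::abort(sprintf("Mapping for %s does not cover each bundle helix exactly once", key),
                 class = "dsa_config_error")
  }
  m <- dplyr::left_join(m, bundle$helices, by = "helix")
  n_missing <- vapply(strsplit(m$missing_labels, ","), function(x) {
    sum(nzchar(trimws(x)))
  }, 0L)
  span <- m$author_end - m$author_start + 1L
  bad <- span != m$length - n_missing
  if (any(bad)) {
    rlang::abort(sprintf(
      "Mapping for %s, helix %s: author range %d-%d covers %d residues but helix needs %d (declared missing: %d)",
      key, m$helix_letter[bad][1], m$author_start[bad][1], m$author_end[bad][1],
      span[bad][1], m$length[bad][1], n_missing[bad][1]),
      class = "dsa_config_error")
  }
  m
}
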