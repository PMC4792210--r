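#' Read a multiple sequence alignment
#'
#' Aligned FASTA or Clustal input (via Biostrings). Sequences are returned
#' upper-cased; `.` gap characters are normalised to `-`.
#'
#' @param path Path to the alignment file.
#' @param format `"auto"` (by extension: `.aln`/`.clustal` are Clustal,
#'   anything else FASTA), `"fasta"`, or `"clustal"`.
#' @return Named character vector of equal-length aligned sequences.
#' @export
read_msa <- function(path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    rlang::abort(paste("Alignment file not found:", path),
                 class = "dsa_config_error")
  }
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) %in% c("aln", "clustal", "clw"))
      "clustal" else "fasta"
  }
  aln <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(Biostrings::unmasked(aln))
  toupper(gsub(".", "-", seqs, fixed = TRUE))
}

#' Per-column conservation profile of an alignment
#'
#' Exact counts, per alignment column, of the 20 amino acids plus gap (`-`)
#' and unknown (`X`), and the most frequent amino-acid type with its
#' conservation percentage. Gaps are counted in the percentage denominator
#' by default (conservative percentages); set `exclude_gaps = TRUE` to
#' restrict the denominator to residues.
#'
#' @param msa Named character vector of equal-length aligned sequences (see
#'   [read_msa()]), or anything coercible via `as.character()`.
#' @param exclude_gaps Logical; drop gaps from the percentage denominator.
#' @return An object of class `conservation_profile`: a list with `counts`
#'   (long tibble: `column`, `residue`, `count`), `summary` (tibble:
#'   `column`, `top_residue`, `top_count`, `percent`), `n_sequences`,
#'   `n_columns`, `exclude_gaps`.
#' @export
build_profile <- function(msa, exclude_gaps = FALSE) {
  seqs <- toupper(as.character(msa))
  if (!length(seqs)) rlang::abort("Empty alignment", class = "dsa_data_error")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    rlang::abort("Ragged alignment: sequences differ in length",
                 class = "dsa_data_error")
  }
  aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  alphabet <- c(aa20, "-", "X")
  mat <- do.call(rbind, strsplit(gsub(".", "-", seqs, fixed = TRUE), ""))
  bad <- setdiff(unique(as.vector(mat)), alphabet)
  if (length(bad)) {
    rlang::abort(paste("Unexpected alignment character(s):",
                       paste(bad, collapse = ", ")),
                 class = "dsa_data_error")
  }
  counts <- apply(mat, 2, function(col) table(factor(col, levels = alphabet)))
  n_seq <- length(seqs)
  n_col <- ncol(mat)

  aa_counts <- counts[aa20, , drop = FALSE]
  top_idx <- apply(aa_counts, 2, which.max)
  top_count <- aa_counts[cbind(top_idx, seq_len(n_col))]
  denom <- if (exclude_gaps) n_seq - counts["-", ] else rep(n_seq, n_col)
  percent <- ifelse(denom > 0, 100 * top_count / denom, NA_real_)

  long <- tibble::tibble(
    column = rep(seq_len(n_col), each = length(alphabet)),
    residue = rep(alphabet, n_col),
    count = as.vector(counts)
  )
  structure(
    list(counts = long,
         summary = tibble::tibble(column = seq_len(n_col),
                                  top_residue = aa20[top_idx],
                                  top_count = as.integer(top_count),
                                  percent = percent),
         n_sequences = n_seq, n_columns = n_col,
         exclude_gaps = exclude_gaps),
    class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat(sprintf("<conservation_profile> %d sequences x %d columns (gaps %s)\n",
              x$n_sequences, x$n_columns,
              if (x$exclude_gaps) "excluded" else "in denominator"))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.conservation_profile <- function(x, ...) x$counts

#' Pick the anchor (most conserved) column of a helix window
#'
#' Within a window of alignment columns, selects the column whose top
#' amino-acid type has the highest conservation percentage; this column
#' becomes the helix's `h.50` anchor. Ties are broken toward the lowest
#' column index, with a warning.
#'
#' @param profile A `conservation_profile`.
#' @param window Length-2 inclusive column range.
#' @param helix Optional helix identifier (1-7 or A-G) recorded in the
#'   result.
#' @return One-row tibble: `helix`, `column`, `residue`, `percent`.
#' @export
assign_anchor <- function(profile, window, helix = NA) {
  stopifnot(inherits(profile, "conservation_profile"), length(window) == 2L)
  cols <- seq.int(window[1], window[2])
  if (!length(cols) || min(cols) < 1L || max(cols) > profile$n_columns) {
    rlang::abort("Helix window outside the alignment", class = "dsa_config_error")
  }
  s <- profile$summary[cols, ]
  if (all(s$top_count == 0L)) {
    rlang::abort("All-gap helix window: no anchor can be assigned",
                 class = "dsa_data_error")
  }
  best <- max(s$percent)
  hits <- which(s$percent == best)
  if (length(hits) > 1L) {
    rlang::warn(sprintf("Anchor tie in window %d-%d (columns %s); taking the lowest",
                        window[1], window[2],
                        paste(s$column[hits], collapse = ", ")))
  }
  k <- hits[1]
  tibble::tibble(helix = if (is.na(helix[1])) NA_integer_ else helix_number(helix),
                 column = s$column[k], residue = s$top_residue[k],
                 percent = s$percent[k])
}

#' Number a helix window around its anchor
#'
#' Assigns common labels to every column of a helix window: the anchor
#' column gets `h.50`, columns toward the amino terminus count down and
#' columns toward the carboxyl terminus count up.
#'
#' @param anchor_column Alignment column of the anchor (e.g. from
#'   [assign_anchor()]).
#' @param window Length-2 inclusive column range containing the anchor.
#' @param anchor_label The anchor's label, e.g. `"2.50"`.
#' @return Tibble with columns `column` and `label`, one row per window
#'   column: a bijection between window columns and labels.
#' @examples
#' number_helix(19, c(2, 25), "2.50")  # labels 2.33 .. 2.56
#' @export
number_helix <- function(anchor_column, window, anchor_label) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  if (anchor_column < window[1] || anchor_column > window[2]) {
    rlang::abort("Anchor column outside its helix window",
                 class = "dsa_config_error")
  }
  a <- parse_label(anchor_label)
  pos <- 50L + (seq.int(window[1], window[2]) - as.integer(anchor_column))
  if (a$position != 50L) {
    rlang::abort("Anchor label must be an h.50 label", class = "dsa_config_error")
  }
  if (min(pos) < 1L || max(pos) > 99L) {
    rlang::abort(sprintf(
      "Window too wide for the numbering convention: labels would span %d.%02d",
      a$helix, max(1L, min(pos))),
      class = "dsa_range_error")
  }
  tibble::tibble(column = seq.int(window[1], window[2]),
                 label = render_label(a$helix, pos))
}

#' Write a conservation profile and anchor report as TSV
#'
#' @param profile A `conservation_profile`.
#' @param path Output TSV path (the per-column summary; the full counts go
#'   to `<path>.counts.tsv` when `counts = TRUE`).
#' @param counts Also write the long count table.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path, counts = FALSE) {
  readr::write_tsv(profile$summary, path)
  if (counts) readr::write_tsv(profile$counts, paste0(path, ".counts.tsv"))
  invisible(path)
}
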