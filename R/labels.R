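#' Common residue labels for 7TM helices
#'
#' Family-wide residue labels of the form `"h.pp"` (e.g. `"7.50"`): `h` is the
#' helix numeral 1--7 and `pp` the position index, with the most conserved
#' position of each helix anchored at `h.50` (the *.50 convention, analogous
#' to Ballesteros--Weinstein numbering in GPCRs). Labels are stored internally
#' as `(helix, integer position)` and rendered with two digits after the dot,
#' so no floating-point label arithmetic ever occurs.
#'
#' @param label Character vector of labels such as `"3.64"`.
#' @param helix Integer helix numeral (1--7) or letter ("A"--"G").
#' @param position Integer position index within the helix numbering (e.g. 50
#'   for the anchor).
#' @return `parse_label()` returns a tibble with columns `helix` (integer) and
#'   `position` (integer); `render_label()` returns a character vector.
#'   The two functions are exact inverses.
#' @examples
#' render_label(7, 50)
#' parse_label(c("3.46", "7.60"))
#' @export
parse_label <- function(label) {
  stopifnot(is.character(label))
  ok <- grepl("^[1-7]\\.[0-9]{2}$", label)
  if (!all(ok)) {
    rlang::abort(
      paste0("Malformed common label(s): ", paste(label[!ok], collapse = ", "),
             " (expected \"h.pp\", helix 1-7, two-digit position)"),
      class = "dsa_label_error"
    )
  }
  parts <- strsplit(label, ".", fixed = TRUE)
  tibble::tibble(
    helix = as.integer(vapply(parts, `[[`, "", 1L)),
    position = as.integer(vapply(parts, `[[`, "", 2L))
  )
}

#' @rdname parse_label
#' @export
render_label <- function(helix, position) {
  helix <- helix_number(helix)
  stopifnot(all(position >= 1L), all(position <= 99L))
  sprintf("%d.%02d", helix, as.integer(position))
}

#' Convert between helix letters (A-G) and numerals (1-7)
#'
#' Microbial rhodopsin helices are conventionally lettered A-G; the common
#' numbering uses numerals 1-7 so labels do not collide with one-letter amino
#' acid codes. Both are accepted anywhere a helix identifier is expected.
#'
#' @param x Helix identifiers: integers 1-7, numerals as strings, or letters.
#' @return `helix_number()` an integer vector; `helix_letter()` a character
#'   vector.
#' @export
helix_number <- function(x) {
  if (is.numeric(x)) {
    n <- as.integer(x)
  } else {
    x <- toupper(as.character(x))
    n <- ifelse(x %in% LETTERS[1:7], match(x, LETTERS[1:7]), suppressWarnings(as.integer(x)))
  }
  if (anyNA(n) || any(n < 1L | n > 7L)) {
    rlang::abort("Helix identifiers must be 1-7 or A-G", class = "dsa_label_error")
  }
  n
}

#' @rdname helix_number
#' @export
helix_letter <- function(x) LETTERS[helix_number(x)]

#' Map an author residue number to its common-numbered label
#'
#' Within one helix, author (PDB) residue numbers and common labels are two
#' parallel inclusive ranges of equal length; the label is obtained by
#' offsetting from the range starts. For bacteriorhodopsin helix G
#' (author 202--226, common 7.36--7.60) the retinal-binding Lys216 maps
#' to "7.50".
#'
#' @param author_residue Integer author residue number(s).
#' @param author_range Length-2 integer vector, inclusive author range of the
#'   helix in the structure's own numbering.
#' @param common_range Length-2 character vector of common labels, e.g.
#'   `c("7.36", "7.60")`, spanning the same helix.
#' @return Character vector of rendered labels.
#' @examples
#' common_number(216, c(202, 226), c("7.36", "7.60"))  # "7.50"
#' common_number(96, c(78, 99), c("3.46", "3.67"))     # "3.64"
#' @seealso [author_residue()] for the inverse mapping.
#' @export
common_number <- function(author_residue, author_range, common_range) {
  rng <- check_parallel_ranges(author_range, common_range)
  bad <- author_residue < rng$a0 | author_residue > rng$a1
  if (any(bad)) {
    rlang::abort(
      sprintf("Residue(s) %s outside helix %s author range %d-%d",
              paste(author_residue[bad], collapse = ", "),
              helix_letter(rng$helix), rng$a0, rng$a1),
      class = "dsa_range_error"
    )
  }
  render_label(rng$helix, rng$c0 + (as.integer(author_residue) - rng$a0))
}

#' Map a common label back to the author residue number
#'
#' Inverse of [common_number()]: recovers the structure's own residue number
#' from a common label, given the same pair of parallel ranges.
#'
#' @param label Character vector of common labels (e.g. `"7.50"`).
#' @inheritParams common_number
#' @return Integer vector of author residue numbers.
#' @export
author_residue <- function(label, author_range, common_range) {
  rng <- check_parallel_ranges(author_range, common_range)
  p <- parse_label(label)
  bad <- p$helix != rng$helix | p$position < rng$c0 | p$position > rng$c1
  if (any(bad)) {
    rlang::abort(
      sprintf("Label(s) %s outside helix %s common range %s-%s",
              paste(label[bad], collapse = ", "), helix_letter(rng$helix),
              render_label(rng$helix, rng$c0), render_label(rng$helix, rng$c1)),
      class = "dsa_range_error"
    )
  }
  rng$a0 + (p$position - rng$c0)
}

# both ranges inclusive and of identical length; returns endpoints as integers
check_parallel_ranges <- function(author_range, common_range) {
  stopifnot(length(author_range) == 2L, length(common_range) == 2L)
  a0 <- as.integer(author_range[1]); a1 <- as.integer(author_range[2])
  cc <- parse_label(as.character(common_range))
  if (cc$helix[1] != cc$helix[2]) {
    rlang::abort("Common range endpoints must lie on one helix", class = "dsa_label_error")
  }
  if (a1 - a0 != cc$position[2] - cc$position[1] || a1 < a0) {
    rlang::abort(
      sprintf("Author range %d-%d and common range %s-%s have different lengths",
              a0, a1, common_range[1], common_range[2]),
      class = "dsa_range_error"
    )
  }
  list(helix = cc$helix[1], a0 = a0, a1 = a1, c0 = cc$position[1], c1 = cc$position[2])
}
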