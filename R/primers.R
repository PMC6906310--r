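# The elephantid-universal primer pair and the primer-binding-region panel
# of the 13 species examined for assay specificity.

L15123_SEQ <- "TACTACTRATYACYATAGCCAC"
H15240_SEQ <- "TTATCTACYGAAAAGCCTCCTC"

#' Elephantid-universal cytochrome b primer pair L15123/H15240
#'
#' Both primers are 22 nt, written 5' to 3'. The forward primer carries three
#' degenerate bases (R, Y, Y) and the reverse primer one (Y), placed away
#' from the 3' ends so that all elephantid mtDNA clades are matched without
#' penalty.
#'
#' @return A tibble with columns `name`, `direction` and `sequence`.
#' @examples
#' elephantid_primers()
#' @export
elephantid_primers <- function() {
  tibble::tibble(
    name = c("L15123", "H15240"),
    direction = c("forward", "reverse"),
    sequence = c(L15123_SEQ, H15240_SEQ)
  )
}

# Primer-binding-region states for the 13 reference species, transcribed in
# the dot notation of the source alignment: "." means identical to the primer
# base at that position, a letter is the species' own base, and "C/T"-style
# entries record within-species alternatives. Rows run 5'->3' along each
# primer (the reverse row is therefore the reverse complement of the
# template plus strand).
.primer_region_rows <- function() {
  tibble::tribble(
    ~species,          ~common_name,            ~elephantid, ~n_seqs, ~forward_row,               ~reverse_row,
    "E. maximus",      "Asian elephant",        TRUE,  4L, ".......A..C/T..C........",  "........C.............",
    "L. africana",     "African savanna elephant", TRUE, 8L, ".......A..C..C........",  "........C/T.............",
    "L. cyclotis",     "African forest elephant", TRUE, 9L, ".......A/G..C..C/T........", "........C.............",
    "M. primigenius",  "woolly mammoth",        TRUE,  9L, ".......A..C..C........",    "........C/T.............",
    "H. amphibius",    "common hippopotamus",   FALSE, 2L, ".......C.CA..C.....T..",    "..G.....G.............",
    "M. monoceros",    "narwhal",               FALSE, 3L, ".......A..A.TC........",    "........A.....C..A....",
    "P. aethiopicus",  "common warthog",        FALSE, 3L, ".......C.CTGTT.....A..",    "..G.....A..G..A..C....",
    "P. catodon",      "sperm whale",           FALSE, 3L, ".C...A.C.CAGTA........",    "........G..G..A..G....",
    "O. orca",         "killer whale",          FALSE, 2L, ".......AGCAGTT........",    "........G.....C..A....",
    "O. rosmarus",     "walrus",                FALSE, 2L, "..T....C.CT.TT........",    ".....A..T.....C..C....",
    "C. simum",        "white rhinoceros",      FALSE, 3L, ".....T.C.CTCTA........",    ".....A..G.....T.......",
    "B. taurus",       "domestic cattle",       FALSE, 3L, ".T..GT.C.CAGTA........",    "........T..G..T..G....",
    "H. sapiens",      "human",                 FALSE, 1L, ".C..G..TGCA..T.....A..",    "C.G.....T..GT........."
  )
}

#' Tokenise a dot-notation primer-region row
#'
#' Splits a row such as `".......A..C/T..C........"` into 22 per-position
#' tokens, each either `"."` (identical to the primer), a single base, or a
#' slash-separated set of within-species alternatives.
#'
#' @param row Character scalar in dot notation.
#' @return Character vector of length 22.
#' @export
primer_region_tokens <- function(row) {
  ch <- .seq_chars(row)
  out <- character(0)
  i <- 1L
  n <- length(ch)
  while (i <= n) {
    if (i + 1L <= n && ch[i + 1L] == "/") {
      out <- c(out, paste0(ch[i], "/", ch[i + 2L]))
      i <- i + 3L
    } else {
      out <- c(out, ch[i])
      i <- i + 1L
    }
  }
  out
}

#' Resolve a dot-notation row to a concrete 22-base region sequence
#'
#' Dots become the primer base (degenerate primer codes are resolved to
#' their first expansion letter, although no reference row leaves a dot
#' under a degenerate position); slash alternatives take the first listed
#' base.
#'
#' @param row Dot-notation row (see [primer_region_tokens()]).
#' @param primer Primer sequence the row is written against.
#' @return Character scalar of length-22 concrete sequence, 5'->3' along the
#'   primer.
#' @export
expand_primer_region <- function(row, primer) {
  tok <- primer_region_tokens(row)
  pch <- .seq_chars(primer)
  if (length(tok) != length(pch)) {
    stop("region row has ", length(tok), " positions; primer has ",
         length(pch), call. = FALSE)
  }
  out <- character(length(tok))
  for (i in seq_along(tok)) {
    if (tok[i] == ".") {
      out[i] <- IUPAC_EXPANSION[[pch[i]]][1L]
    } else {
      out[i] <- substr(tok[i], 1L, 1L)
    }
  }
  .chars_seq(out)
}

#' Primer-binding-region panel for the 13 reference species
#'
#' Returns the transcribed differential-nucleotide rows for both primer
#' regions together with concrete resolved region sequences
#' (`forward_region`, `reverse_region`, both 5'->3' along the primer).
#'
#' @return A tibble with one row per species.
#' @export
primer_region_panel <- function() {
  rows <- .primer_region_rows()
  rows$forward_region <- vapply(rows$forward_row, expand_primer_region,
                                character(1), primer = L15123_SEQ)
  rows$reverse_region <- vapply(rows$reverse_row, expand_primer_region,
                                character(1), primer = H15240_SEQ)
  tibble::as_tibble(rows)
}
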