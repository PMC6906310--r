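# IUPAC nucleotide ambiguity handling used by the degenerate-primer matcher.

IUPAC_EXPANSION <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# compatibility lookup: rows = primer codes, cols = template bases.
# A template N never satisfies a primer code (conservative for forensic
# prediction); it is handled as the explicit FALSE column.
.iupac_compat_matrix <- local({
  codes <- names(IUPAC_EXPANSION)
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(FALSE, nrow = length(codes), ncol = length(bases),
              dimnames = list(codes, bases))
  for (cd in codes) m[cd, IUPAC_EXPANSION[[cd]]] <- TRUE
  m[, "N"] <- FALSE
  m
})

#' Expand an IUPAC nucleotide code
#'
#' @param code Single IUPAC nucleotide character (e.g. `"R"`).
#' @return Character vector of the concrete bases the code stands for.
#' @examples
#' iupac_expand("R")
#' @export
iupac_expand <- function(code) {
  code <- toupper(as.character(code))
  if (length(code) != 1L || !code %in% names(IUPAC_EXPANSION)) {
    stop("not an IUPAC nucleotide code: '", code, "'", call. = FALSE)
  }
  IUPAC_EXPANSION[[code]]
}

#' Test template-base compatibility with a (possibly degenerate) primer code
#'
#' A template base is compatible when it belongs to the IUPAC expansion of
#' the primer code; a template `N` is always treated as incompatible.
#' Vectorised over both arguments.
#'
#' @param primer_code IUPAC code character vector (primer side).
#' @param template_base Concrete base character vector (`A`, `C`, `G`, `T`
#'   or `N`).
#' @return Logical vector.
#' @examples
#' iupac_compatible("R", "A")  # TRUE
#' iupac_compatible("R", "T")  # FALSE
#' @export
iupac_compatible <- function(primer_code, template_base) {
  primer_code <- toupper(primer_code)
  template_base <- toupper(template_base)
  bad <- !primer_code %in% rownames(.iupac_compat_matrix)
  if (any(bad)) {
    stop("not an IUPAC nucleotide code: '", primer_code[bad][1L], "'",
         call. = FALSE)
  }
  bad <- !template_base %in% colnames(.iupac_compat_matrix)
  if (any(bad)) {
    stop("template base must be one of A, C, G, T, N; got '",
         template_base[bad][1L], "'", call. = FALSE)
  }
  .iupac_compat_matrix[cbind(primer_code, template_base)]
}

# fast char-vector helpers (internal)
.seq_chars <- function(x) strsplit(toupper(x), "", fixed = TRUE)[[1L]]

.chars_seq <- function(x) paste(x, collapse = "")

COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", U = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
)

#' Reverse complement of a nucleotide sequence
#'
#' Accepts the full IUPAC alphabet plus gap characters.
#'
#' @param x Character scalar.
#' @return Character scalar.
#' @export
reverse_complement <- function(x) {
  ch <- .seq_chars(x)
  comp <- COMPLEMENT[ch]
  if (anyNA(comp)) {
    stop("cannot complement character '", ch[is.na(comp)][1L], "'",
         call. = FALSE)
  }
  .chars_seq(rev(unname(comp)))
}
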