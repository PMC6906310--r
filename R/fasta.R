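# FASTA input/output via Biostrings, normalised to the conventions used
# throughout the package (upper case, U mapped to T).

#' Read a FASTA file into a tibble
#'
#' Sequences are upper-cased and `U` is mapped to `T`. Characters outside
#' the IUPAC nucleotide alphabet (plus `-`) raise a parse error naming the
#' record and offset.
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns `id` and `sequence`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("U", "T", seqs, fixed = TRUE)
  ok <- paste0(c(names(IUPAC_EXPANSION), "-"), collapse = "")
  for (i in seq_along(seqs)) {
    bad <- regexpr(paste0("[^", ok, "]"), seqs[[i]])
    if (bad > 0L) {
      stop("invalid nucleotide character '",
           substr(seqs[[i]], bad, bad), "' in record '", ids[i],
           "' at offset ", bad, call. = FALSE)
    }
    if (nchar(seqs[[i]]) == 0L) {
      stop("empty sequence in record '", ids[i], "'", call. = FALSE)
    }
  }
  tibble::tibble(id = ids, sequence = unname(seqs))
}

#' Write sequences to a FASTA file
#'
#' @param data Tibble (or data frame) with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(data, path) {
  stopifnot(all(c("id", "sequence") %in% names(data)))
  set <- Biostrings::DNAStringSet(toupper(data$sequence))
  names(set) <- data$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# coerce the various template inputs (tibble, named vector, FASTA path)
# into the canonical tibble(id, sequence)
.as_sequence_tbl <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    return(tibble::as_tibble(x[, c("id", "sequence")]))
  }
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      (file.exists(x) || grepl("[/\\\\]|\\.fa(sta)?$", x))) {
    return(read_fasta(x))
  }
  if (is.character(x)) {
    ids <- names(x)
    if (is.null(ids)) ids <- sprintf("seq_%03d", seq_along(x))
    return(tibble::tibble(id = ids, sequence = toupper(unname(x))))
  }
  stop("cannot interpret input as sequences (need a tibble with id and ",
       "sequence, a named character vector, or a FASTA path)", call. = FALSE)
}
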