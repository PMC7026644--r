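#' Wild-type reference sequence
#'
#' A wild-type ribozyme sequence over the RNA alphabet {A, C, G, U}.
#' Positions are 1-based and inclusive throughout the package, so a
#' substitution named `G6U` mutates the G at position 6 to U. DNA input
#' (T instead of U) is converted on construction.
#'
#' @param sequence Character scalar, the reference sequence (ACGU or ACGT).
#' @param id Label for the sequence.
#' @param cleavage_site Optional 1-based position of the self-cleavage site.
#'
#' @return An object of class `wild_type`: a list with elements `id`,
#'   `sequence` (RNA alphabet), `length` and `cleavage_site`.
#' @export
#' @examples
#' wt <- wild_type("GGCGAAAGCCGAAACGGC", id = "toy")
#' wt$length
wild_type <- function(sequence, id = "wt", cleavage_site = NULL) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  seq <- toupper(gsub("\\s", "", sequence))
  seq <- chartr("T", "U", seq)
  if (grepl("[^ACGU]", seq)) {
    stop("wild-type sequence contains characters outside A/C/G/U(T)")
  }
  if (nchar(seq) < 10) {
    stop("wild-type sequence must be at least 10 nt long")
  }
  if (!is.null(cleavage_site)) {
    stopifnot(cleavage_site >= 1, cleavage_site <= nchar(seq))
  }
  structure(
    list(id = id, sequence = seq, length = nchar(seq),
         cleavage_site = cleavage_site),
    class = "wild_type"
  )
}

#' @export
print.wild_type <- function(x, ...) {
  cat("<wild_type> ", x$id, " (", x$length, " nt)\n", sep = "")
  cat(x$sequence, "\n")
  invisible(x)
}

#' Read a wild-type sequence from a FASTA file
#'
#' Reads the first record of a FASTA file (via Biostrings) and returns a
#' [wild_type()] object. T is converted to U.
#'
#' @param path Path to a FASTA file.
#' @inheritParams wild_type
#' @return A `wild_type` object.
#' @export
read_wildtype <- function(path, cleavage_site = NULL) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) stop("no sequences in ", path)
  wild_type(as.character(ss[[1]]), id = names(ss)[1],
            cleavage_site = cleavage_site)
}

#' Write a wild-type sequence to FASTA
#'
#' @param wt A `wild_type` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_wildtype <- function(wt, path) {
  writeLines(c(paste0(">", wt$id), wt$sequence), path)
  invisible(path)
}

wt_bases <- function(wt) strsplit(wt$sequence, "")[[1]]
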