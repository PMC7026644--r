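#' Read and write secondary structures
#'
#' Readers and writers for the common plain-text structure formats, all
#' returning / consuming a pair tibble (`i`, `j`, `i < j`, 1-based).
#' Dot-bracket strings may use up to four bracket layers `()`, `[]`,
#' `{}`, `<>`, so crossing (pseudoknot) pairs round-trip. CT and bpseq
#' files follow the usual column conventions. The plain pair-list TSV
#' has columns `i`, `j` and optionally a flag column (e.g. marking
#' noncanonical or tertiary reference pairs).
#'
#' @param pairs Pair tibble with columns `i`, `j`.
#' @param L Sequence length.
#' @param x A dot-bracket string, or path to a file whose last
#'   non-header line is one.
#' @param path File path.
#' @param sequence Sequence string for CT/bpseq output.
#' @param id Record identifier for CT output.
#' @name structure_io
NULL

.db_open <- c("(", "[", "{", "<")
.db_close <- c(")", "]", "}", ">")

#' @rdname structure_io
#' @return `write_dotbracket()`: a dot-bracket string.
#' @export
write_dotbracket <- function(pairs, L) {
  validate_structure(pairs, L, min_loop = 0)
  pairs <- pairs[order(pairs$i), , drop = FALSE]
  out <- rep(".", L)
  layer_pairs <- vector("list", 4)
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    placed <- FALSE
    for (l in 1:4) {
      conflict <- any(vapply(layer_pairs[[l]], function(p) {
        (p[1] < i & i < p[2] & p[2] < j) | (i < p[1] & p[1] < j & j < p[2])
      }, logical(1)))
      if (!conflict) {
        layer_pairs[[l]] <- c(layer_pairs[[l]], list(c(i, j)))
        out[i] <- .db_open[l]
        out[j] <- .db_close[l]
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("structure needs more than 4 bracket layers")
  }
  paste(out, collapse = "")
}

#' @rdname structure_io
#' @return `read_dotbracket()`: a pair tibble.
#' @export
read_dotbracket <- function(x) {
  if (file.exists(x)) {
    lines <- readLines(x)
    lines <- lines[!startsWith(lines, ">") & nzchar(lines)]
    x <- lines[grepl("^[][(){}<>.]+$", lines)][1]
    if (is.na(x)) stop("no dot-bracket line found")
  }
  chars <- strsplit(x, "")[[1]]
  res <- list()
  for (l in 1:4) {
    stack <- integer(0)
    for (p in seq_along(chars)) {
      if (chars[p] == .db_open[l]) {
        stack <- c(stack, p)
      } else if (chars[p] == .db_close[l]) {
        if (length(stack) == 0) stop("unbalanced brackets in layer ", l)
        res[[length(res) + 1]] <- c(stack[length(stack)], p)
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0) stop("unbalanced brackets in layer ", l)
  }
  if (length(res) == 0) return(tibble(i = integer(0), j = integer(0)))
  m <- do.call(rbind, res)
  dplyr::arrange(tibble(i = m[, 1], j = m[, 2]), .data$i)
}

#' @rdname structure_io
#' @export
write_ct <- function(pairs, sequence, path, id = "structure") {
  if (inherits(sequence, "wild_type")) sequence <- sequence$sequence
  L <- nchar(sequence)
  partner <- pairs_to_partner(pairs, L)
  b <- strsplit(sequence, "")[[1]]
  lines <- c(
    paste(L, id),
    sprintf("%d %s %d %d %d %d", 1:L, b, 0:(L - 1),
            c(2:L, 0), partner, 1:L)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname structure_io
#' @return `read_ct()`: a pair tibble with attribute `sequence`.
#' @export
read_ct <- function(path) {
  lines <- readLines(path)
  L <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]][1])
  body <- do.call(rbind, strsplit(trimws(lines[2:(L + 1)]), "\\s+"))
  partner <- as.integer(body[, 5])
  out <- partner_to_pairs(partner)
  attr(out, "sequence") <- paste(body[, 2], collapse = "")
  out
}

#' @rdname structure_io
#' @export
write_bpseq <- function(pairs, sequence, path) {
  if (inherits(sequence, "wild_type")) sequence <- sequence$sequence
  L <- nchar(sequence)
  partner <- pairs_to_partner(pairs, L)
  b <- strsplit(sequence, "")[[1]]
  writeLines(sprintf("%d %s %d", 1:L, b, partner), path)
  invisible(path)
}

#' @rdname structure_io
#' @return `read_bpseq()`: a pair tibble with attribute `sequence`.
#' @export
read_bpseq <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  body <- do.call(rbind, strsplit(lines, "\\s+"))
  partner <- as.integer(body[, 3])
  out <- partner_to_pairs(partner)
  attr(out, "sequence") <- paste(body[, 2], collapse = "")
  out
}

#' @rdname structure_io
#' @export
write_pairs_tsv <- function(pairs, path) {
  readr::write_tsv(as_tibble(pairs), path)
  invisible(path)
}

#' @rdname structure_io
#' @return `read_pairs_tsv()`: a pair tibble (extra columns kept).
#' @export
read_pairs_tsv <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  names(df)[1:2] <- c("i", "j")
  df$i <- as.integer(df$i)
  df$j <- as.integer(df$j)
  df
}

#' Read a reference structure in any supported format
#'
#' Dispatches on the file extension: `.ct`, `.bpseq`, `.db` /
#' `.dbn` / `.dot` (dot-bracket), anything else as pair-list TSV.
#'
#' @param path File path.
#' @return A pair tibble.
#' @export
read_reference <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         ct = read_ct(path),
         bpseq = read_bpseq(path),
         db = , dbn = , dot = read_dotbracket(path),
         read_pairs_tsv(path))
}

#' @export
print.rna_structure <- function(x, ...) {
  seq <- attr(x, "sequence")
  if (!is.null(seq)) {
    cat(seq, "\n")
    cat(write_dotbracket(x, nchar(seq)), "\n")
  }
  if (!is.null(attr(x, "energy"))) {
    cat("energy:", round(attr(x, "energy"), 3), "kcal/mol\n")
  }
  NextMethod()
}
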