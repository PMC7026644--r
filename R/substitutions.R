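#' Substitution-set encoding
#'
#' Variants are identified by their substitution set relative to the wild
#' type, encoded as a comma-separated string of `<ref><pos><alt>` tokens
#' sorted by position, e.g. `"G6U,C12A"`; the empty string denotes the
#' wild type itself. Positions are 1-based.
#'
#' `subs_parse()` expands encoded strings into a long tibble;
#' `subs_encode()` builds canonical strings from position/alternative
#' vectors.
#'
#' @param subs Character vector of encoded substitution sets.
#' @param pos,alt Integer / character vectors of equal length describing
#'   one variant's substitutions.
#' @param wt A [wild_type()] object (supplies the reference base).
#'
#' @return `subs_parse()`: a tibble with columns `variant` (index into
#'   `subs`), `ref`, `pos`, `alt`. `subs_encode()`: a character scalar.
#' @export
subs_parse <- function(subs) {
  n_tok <- ifelse(subs == "", 0L, stringr::str_count(subs, ",") + 1L)
  toks <- unlist(strsplit(subs[n_tok > 0L], ",", fixed = TRUE))
  m <- stringr::str_match(toks, "^([ACGU])(\\d+)([ACGU])$")
  if (anyNA(m[, 1])) {
    stop("malformed substitution token(s): ",
         paste(unique(toks[is.na(m[, 1])]), collapse = ", "))
  }
  tibble(
    variant = rep(which(n_tok > 0L), n_tok[n_tok > 0L]),
    ref = m[, 2],
    pos = as.integer(m[, 3]),
    alt = m[, 4]
  )
}

#' @rdname subs_parse
#' @export
subs_encode <- function(pos, alt, wt) {
  stopifnot(length(pos) == length(alt))
  if (length(pos) == 0) return("")
  o <- order(pos)
  pos <- pos[o]; alt <- alt[o]
  ref <- wt_bases(wt)[pos]
  paste0(ref, pos, alt, collapse = ",")
}

# Validate a parsed substitution table against the wild type; errors on
# out-of-range positions, duplicated positions within a variant, wrong
# reference bases or alt == ref.
subs_validate <- function(long, wt) {
  if (nrow(long) == 0) return(invisible(long))
  b <- wt_bases(wt)
  if (any(long$pos < 1 | long$pos > wt$length)) {
    stop("substitution position outside [1, ", wt$length, "]")
  }
  if (anyDuplicated(paste(long$variant, long$pos))) {
    stop("duplicated position within a substitution set")
  }
  if (any(b[long$pos] != long$ref)) {
    stop("reference base in substitution string does not match wild type")
  }
  if (any(long$alt == long$ref)) {
    stop("substitution with alt equal to the wild-type base")
  }
  invisible(long)
}

# Substitution sets of full-length reads relative to the wild type,
# vectorized over unique sequences. Returns a character vector of encoded
# sets aligned with `sequences`.
seqs_to_subs <- function(sequences, wt) {
  b <- wt_bases(wt)
  uni <- unique(sequences)
  mat <- matrix(unlist(strsplit(uni, "")), nrow = length(uni), byrow = TRUE)
  enc <- vapply(seq_along(uni), function(k) {
    d <- which(mat[k, ] != b)
    if (length(d) == 0) "" else paste0(b[d], d, mat[k, d], collapse = ",")
  }, character(1))
  enc[match(sequences, uni)]
}

# Apply substitution sets to the wild type, returning variant sequences
# as a character matrix of bases (rows = entries of the long table's
# variant index domain 1..n).
apply_subs <- function(long, wt, n) {
  b <- wt_bases(wt)
  mat <- matrix(rep(b, each = n), nrow = n)
  if (nrow(long) > 0) mat[cbind(long$variant, long$pos)] <- long$alt
  mat
}
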