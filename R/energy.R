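# Turner 2004 nearest-neighbour stacking free energies at 37 C
# (kcal/mol), indexed [outer pair, inner pair as seen from the opposite
# strand], pair order CG, GC, GU, UG, AU, UA. Entry [p1, p2] is the stack
# 5'-i k-3' / 3'-j l-5' with (i,j) of type p1 and (l,k) of type p2.
.stack_pairs <- c("CG", "GC", "GU", "UG", "AU", "UA")
.turner_stacks <- matrix(c(
  -2.40, -3.30, -2.10, -1.40, -2.10, -2.10,
  -3.30, -3.40, -2.50, -1.50, -2.20, -2.40,
  -2.10, -2.50,  1.30, -0.50, -1.40, -1.30,
  -1.40, -1.50, -0.50,  0.30, -0.60, -1.00,
  -2.10, -2.20, -1.40, -0.60, -1.10, -0.90,
  -2.10, -2.40, -1.30, -1.00, -0.90, -1.30
), nrow = 6, byrow = TRUE, dimnames = list(.stack_pairs, .stack_pairs))

#' Minimal nearest-neighbour energy model
#'
#' The folding energy of a pair set is
#' \deqn{E = \Delta G_{37,stack} + \Delta G_{37,AU\,end}
#'   + \Delta G_{lone} + \Delta G_{non\text{-}AU/GC/GU}}
#' where stacking uses the embedded Turner 2004 free energies for the two
#' adjacent canonical pairs `(i, j)` and `(i+1, j-1)`; each helix
#' terminus closed by an AU or GU pair pays the terminal penalty (0.45
#' kcal/mol; a lone pair pays it once); an isolated pair — neither
#' `(i-1, j+1)` nor `(i+1, j-1)` paired — pays the lone-pair penalty; and
#' any pair other than Watson–Crick or GU wobble pays the noncanonical
#' penalty. Lone and noncanonical penalties share a single default of 3
#' kcal/mol (results are stable over 2–5). Stacks involving a
#' noncanonical pair contribute 0 (the pair still pays its penalty).
#' Crossing (pseudoknot) pairs are permitted; stacking uses only the
#' `(i+1, j-1)` adjacency rule, which remains well-defined with
#' crossings.
#'
#' @param lone_penalty Penalty (kcal/mol) for an isolated pair.
#' @param noncanonical_penalty Penalty for a non-AU/GC/GU pair; defaults
#'   to `lone_penalty` (the single shared parameter).
#' @param au_end_penalty Terminal AU/GU penalty per qualifying helix end.
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#'
#' @return An object of class `energy_model`.
#' @export
energy_model <- function(lone_penalty = 3,
                         noncanonical_penalty = lone_penalty,
                         au_end_penalty = 0.45, min_loop = 3) {
  stopifnot(lone_penalty > 0, noncanonical_penalty > 0, min_loop >= 0)
  structure(
    list(stacks = .turner_stacks, lone_penalty = lone_penalty,
         noncanonical_penalty = noncanonical_penalty,
         au_end_penalty = au_end_penalty, min_loop = min_loop),
    class = "energy_model"
  )
}

#' @export
print.energy_model <- function(x, ...) {
  cat("<energy_model> Turner 2004 stacks; lone = ", x$lone_penalty,
      ", noncanonical = ", x$noncanonical_penalty, ", AU end = ",
      x$au_end_penalty, " kcal/mol; min loop = ", x$min_loop, "\n",
      sep = "")
  invisible(x)
}

# sequence string -> integer code A=0, C=1, G=2, U=3
seq_to_int <- function(sequence) {
  if (inherits(sequence, "wild_type")) sequence <- sequence$sequence
  s <- chartr("T", "U", toupper(sequence))
  code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "U")) - 1L
  if (anyNA(code)) stop("sequence contains characters outside A/C/G/U(T)")
  code
}

#' Base-pair sets as structures
#'
#' A structure is a set of base pairs `(i, j)`, `i < j`, at most one
#' partner per base, each enclosing at least `min_loop` unpaired bases.
#' Crossing (pseudoknot) pairs are permitted. `pairs_to_partner()` and
#' `partner_to_pairs()` convert between the pair tibble and the partner
#' vector (`0` = unpaired); `validate_structure()` checks the
#' invariants.
#'
#' @param pairs Data frame with integer columns `i`, `j`.
#' @param L Sequence length.
#' @param partner Integer vector of length `L`.
#' @param min_loop Minimum enclosed unpaired span.
#' @return `pairs_to_partner()`: integer vector; `partner_to_pairs()`:
#'   tibble with columns `i`, `j`; `validate_structure()`: the pairs,
#'   invisibly (errors if invalid).
#' @export
pairs_to_partner <- function(pairs, L) {
  validate_structure(pairs, L, min_loop = 0)
  partner <- integer(L)
  partner[pairs$i] <- pairs$j
  partner[pairs$j] <- pairs$i
  partner
}

#' @rdname pairs_to_partner
#' @export
partner_to_pairs <- function(partner) {
  i <- which(partner > seq_along(partner))
  tibble(i = i, j = partner[i])
}

#' @rdname pairs_to_partner
#' @export
validate_structure <- function(pairs, L, min_loop = 3) {
  i <- as.integer(pairs$i); j <- as.integer(pairs$j)
  if (any(i < 1 | j > L)) stop("pair position outside [1, L]")
  if (any(i >= j)) stop("pairs must satisfy i < j")
  if (anyDuplicated(c(i, j))) {
    stop("a base cannot be paired with more than a single base")
  }
  if (any(j - i - 1 < min_loop)) {
    stop("pair encloses fewer than min_loop unpaired bases")
  }
  invisible(pairs)
}

# Per-position pairing-score matrix (L x L, upper triangle) from a
# per-position tibble (i, j, ps) or a coda_scores object; NULL -> NULL.
ps_matrix <- function(ps, L) {
  if (is.null(ps)) return(NULL)
  if (inherits(ps, "coda_scores")) ps <- ps$per_position
  if (inherits(ps, "coda_fit")) ps <- ps$scores$per_position
  if (is.matrix(ps)) { stopifnot(nrow(ps) == L, ncol(ps) == L); return(ps) }
  stopifnot(all(c("i", "j") %in% names(ps)))
  val <- if ("ps" %in% names(ps)) ps$ps else ps[[3]]
  m <- matrix(0, L, L)
  m[cbind(ps$i, ps$j)] <- val
  m[cbind(ps$j, ps$i)] <- val
  m
}

# Restraint normalizer: mean of the positive per-position scores. The
# raw mean can be negative (most pairs score below zero), which would
# flip the sign of the restraint; the positive mean keeps high-Ps pairs
# attractive. Returns 0 to disable the restraint when nothing is
# positive.
ps_norm <- function(psmat) {
  if (is.null(psmat)) return(0)
  pos <- psmat[upper.tri(psmat)]
  pos <- pos[pos > 0]
  if (length(pos) == 0) 0 else mean(pos)
}

#' Folding energy of a structure
#'
#' Evaluates the [energy_model()] energy of a pair set on a sequence,
#' optionally including the mutation-derived restraint
#' `- W * Ps(i, j) / m` per pair, where `m` is the mean of the positive
#' per-position pairing scores (the restraint is disabled when `ps` is
#' absent or has no positive entry; pairs absent from `ps` contribute 0).
#'
#' @param pairs Structure as a tibble with columns `i`, `j`.
#' @param sequence Character scalar or [wild_type()].
#' @param model An [energy_model()].
#' @param ps Optional per-position pairing scores: a tibble
#'   `(i, j, ps)`, a `coda_scores`/`coda_fit`, or an `L x L` matrix.
#' @param weight Restraint weight W.
#' @return Energy in kcal/mol (the restraint term is unitless but on the
#'   same scale).
#' @export
structure_energy <- function(pairs, sequence, model = energy_model(),
                             ps = NULL, weight = 2.0) {
  code <- seq_to_int(sequence)
  L <- length(code)
  validate_structure(pairs, L, min_loop = 0)
  partner <- pairs_to_partner(pairs, L)
  psmat <- ps_matrix(ps, L)
  m <- ps_norm(psmat)
  wm <- if (m > 0) weight / m else 0
  if (is.null(psmat)) psmat <- matrix(0, L, L)
  cpp_energy(partner, code, model$stacks, model$lone_penalty,
             model$noncanonical_penalty, model$au_end_penalty,
             psmat, wm)
}
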