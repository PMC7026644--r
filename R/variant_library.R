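#' Map sequencing barcodes to variants
#'
#' Builds the projection map from barcodes to substitution sets out of
#' DNA-seq-like records. Reads whose length differs from the wild type are
#' discarded (the variant model is substitution-only), as are reads with
#' characters outside A/C/G/U/T. When several distinct sequences map to
#' one barcode, the consensus sequence is used only if its read frequency
#' exceeds 50%; barcodes without a strict majority are dropped.
#'
#' @param dna_records Data frame with columns `barcode` and `sequence`
#'   (one row per read; DNA or RNA alphabet).
#' @param wt A [wild_type()] object.
#'
#' @return A tibble with columns `barcode`, `subs` (encoded substitution
#'   set, see [subs_parse()]) and `n_reads` (reads supporting the
#'   consensus). Attributes `n_dropped_length`, `n_dropped_alphabet` and
#'   `n_dropped_ambiguous` tally discarded reads/barcodes.
#' @export
build_barcode_map <- function(dna_records, wt) {
  stopifnot(all(c("barcode", "sequence") %in% names(dna_records)))
  if (nrow(dna_records) == 0) stop("no DNA-seq records supplied")

  rec <- tibble(
    barcode = as.character(dna_records$barcode),
    sequence = chartr("T", "U", toupper(dna_records$sequence))
  )
  bad_alpha <- grepl("[^ACGU]", rec$sequence)
  bad_len <- !bad_alpha & nchar(rec$sequence) != wt$length
  if (any(bad_alpha)) {
    message(sum(bad_alpha), " read(s) skipped: non-ACGU(T) characters")
  }
  if (any(bad_len)) {
    message(sum(bad_len), " read(s) discarded: length != ", wt$length)
  }
  rec <- rec[!bad_alpha & !bad_len, ]
  if (nrow(rec) == 0) stop("no usable DNA-seq records after filtering")

  tallies <- rec |>
    dplyr::count(.data$barcode, .data$sequence, name = "n_reads") |>
    dplyr::group_by(.data$barcode) |>
    dplyr::mutate(total = sum(.data$n_reads)) |>
    dplyr::slice_max(.data$n_reads, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()

  keep <- tallies$n_reads * 2L > tallies$total  # strict majority
  n_ambig <- sum(!keep)
  if (n_ambig > 0) {
    message(n_ambig, " barcode(s) dropped: no >50% consensus sequence")
  }
  tallies <- tallies[keep, ]

  out <- tibble(
    barcode = tallies$barcode,
    subs = seqs_to_subs(tallies$sequence, wt),
    n_reads = tallies$n_reads
  )
  attr(out, "n_dropped_length") <- sum(bad_len)
  attr(out, "n_dropped_alphabet") <- sum(bad_alpha)
  attr(out, "n_dropped_ambiguous") <- n_ambig
  out
}

#' Count cleaved and uncleaved reads per variant
#'
#' Aggregates RNA-seq-like records (one row per read, with a cleaved flag)
#' into per-variant counts, summing across all barcodes that map to the
#' same substitution set. Barcodes absent from the map are tallied and
#' dropped.
#'
#' @param rna_records Data frame with columns `barcode` and `cleaved`
#'   (logical or 0/1).
#' @param barcode_map Output of [build_barcode_map()].
#'
#' @return A tibble with columns `subs`, `n_cleaved`, `n_total`, one row
#'   per variant; attribute `n_unmapped` counts dropped reads.
#' @export
count_cleavage <- function(rna_records, barcode_map) {
  stopifnot(all(c("barcode", "cleaved") %in% names(rna_records)))
  rec <- tibble(
    barcode = as.character(rna_records$barcode),
    cleaved = as.logical(as.integer(rna_records$cleaved))
  )
  rec <- dplyr::left_join(rec, barcode_map[, c("barcode", "subs")],
                          by = "barcode")
  unmapped <- is.na(rec$subs)
  if (all(unmapped) && nrow(rec) > 0) {
    warning("no RNA-seq barcode matched the barcode map")
  } else if (any(unmapped)) {
    message(sum(unmapped), " RNA-seq read(s) dropped: unknown barcode")
  }
  rec <- rec[!unmapped, ]
  out <- rec |>
    dplyr::group_by(.data$subs) |>
    dplyr::summarise(n_cleaved = sum(.data$cleaved),
                     n_total = dplyr::n(), .groups = "drop")
  attr(out, "n_unmapped") <- sum(unmapped)
  out
}

#' Relative activity from cleavage counts
#'
#' Computes the relative activity of each variant,
#' \deqn{RA(var) = \frac{N_{cleaved}(var)\, N_{total}(wt)}
#'                     {N_{total}(var)\, N_{cleaved}(wt)},}
#' so that the wild type has RA = 1 by construction and values above 1
#' (variants more active than the wild type) are possible. Variants with
#' fewer than `min_reads` total reads are omitted.
#'
#' @param variants Data frame with columns `subs`, `n_cleaved`, `n_total`
#'   (e.g. from [count_cleavage()] or [simulate_library()]).
#' @param wt A [wild_type()] object.
#' @param wt_counts Length-2 numeric `c(n_cleaved_wt, n_total_wt)`. If
#'   `NULL`, taken from the `subs == ""` row of `variants`.
#' @param min_reads Minimum total reads for a variant to be kept.
#'
#' @return A `coda_activity` tibble (see [activity_table()]) with columns
#'   `subs`, `n_mut`, `ra`, `n_total`, `provenance`.
#' @export
compute_ra <- function(variants, wt, wt_counts = NULL, min_reads = 5) {
  stopifnot(all(c("subs", "n_cleaved", "n_total") %in% names(variants)))
  if (any(variants$n_cleaved > variants$n_total)) {
    stop("n_cleaved exceeds n_total for some variant")
  }
  if (is.null(wt_counts)) {
    wt_row <- variants[variants$subs == "", ]
    if (nrow(wt_row) == 0) {
      stop("wild-type counts not supplied and no subs == \"\" row present")
    }
    wt_counts <- c(sum(wt_row$n_cleaved), sum(wt_row$n_total))
  }
  if (wt_counts[1] <= 0) stop("wild-type cleaved count is zero: RA undefined")
  if (wt_counts[2] <= 0) stop("wild-type total count is zero: RA undefined")

  kept <- variants[variants$n_total >= min_reads, ]
  long <- subs_parse(kept$subs)
  subs_validate(long, wt)
  n_mut <- integer(nrow(kept))
  if (nrow(long) > 0) {
    tab <- tabulate(long$variant, nbins = nrow(kept))
    n_mut <- tab
  }
  out <- tibble(
    subs = kept$subs,
    n_mut = n_mut,
    ra = (as.numeric(kept$n_cleaved) * as.numeric(wt_counts[2])) /
      (as.numeric(kept$n_total) * as.numeric(wt_counts[1])),
    n_total = kept$n_total,
    provenance = "measured"
  )
  activity_table(out, wt)
}

#' Activity tables
#'
#' A `coda_activity` table holds per-variant relative activities keyed by
#' substitution set, with the wild type carried as an attribute. Rows with
#' `n_mut == 2` are the direct doubles; [reduce_triples()] adds effective
#' doubles derived from triples; [merge_batches()] averages variants
#' appearing in several experimental batches.
#'
#' @param df Data frame with columns `subs`, `n_mut`, `ra`, `n_total`,
#'   `provenance`.
#' @param wt A [wild_type()] object.
#' @return A tibble of class `coda_activity` with attribute `wild_type`.
#' @export
activity_table <- function(df, wt) {
  stopifnot(all(c("subs", "n_mut", "ra") %in% names(df)))
  if (!"n_total" %in% names(df)) df$n_total <- NA_integer_
  if (!"provenance" %in% names(df)) df$provenance <- "measured"
  if (any(df$ra < 0)) stop("relative activities must be nonnegative")
  if (anyDuplicated(df$subs)) stop("duplicated substitution sets")
  out <- as_tibble(df[, c("subs", "n_mut", "ra", "n_total", "provenance")])
  attr(out, "wild_type") <- wt
  class(out) <- c("coda_activity", class(out))
  out
}

#' @export
print.coda_activity <- function(x, ...) {
  wt <- attr(x, "wild_type")
  cat("<coda_activity> ", wt$id, " (", wt$length, " nt): ",
      sum(x$n_mut == 1), " singles, ", sum(x$n_mut == 2), " doubles, ",
      sum(x$n_mut >= 3), " higher-order\n", sep = "")
  NextMethod()
}

#' Coverage of the single- and double-mutation space
#'
#' Fraction of the `3 L` possible single mutations and `9 C(L,2)` possible
#' double mutations present in an activity table.
#'
#' @param table A `coda_activity` table.
#' @return A one-row tibble with columns `singles`, `n_singles`,
#'   `doubles`, `n_doubles`, `position_pairs` (fraction of the `C(L,2)`
#'   position pairs with at least one double).
#' @export
coverage <- function(table) {
  wt <- attr(table, "wild_type")
  L <- wt$length
  n_singles <- sum(table$n_mut == 1)
  n_doubles <- sum(table$n_mut == 2)
  long <- subs_parse(table$subs[table$n_mut == 2])
  npp <- if (nrow(long) > 0) {
    pp <- matrix(long$pos, ncol = 2, byrow = TRUE)
    length(unique(paste(pmin(pp[, 1], pp[, 2]), pmax(pp[, 1], pp[, 2]))))
  } else 0L
  tibble(
    singles = n_singles / (3 * L), n_singles = n_singles,
    doubles = n_doubles / (9 * choose(L, 2)), n_doubles = n_doubles,
    position_pairs = npp / choose(L, 2)
  )
}

#' Merge activity tables from several experimental batches
#'
#' Takes the union of variants; a variant measured in more than one batch
#' receives the arithmetic mean of its batch RAs and provenance
#' `"batch_average"`. All batches must share the same wild-type sequence.
#'
#' @param tables List of `coda_activity` tables.
#' @return A merged `coda_activity` table.
#' @export
merge_batches <- function(tables) {
  if (length(tables) == 0) stop("no activity tables to merge")
  wts <- purrr::map(tables, attr, "wild_type")
  if (length(unique(purrr::map_chr(wts, "sequence"))) > 1) {
    stop("activity tables have different wild-type sequences")
  }
  merged <- dplyr::bind_rows(tables) |>
    dplyr::group_by(.data$subs) |>
    dplyr::summarise(
      n_mut = .data$n_mut[1],
      ra = mean(.data$ra),
      n_total = sum(.data$n_total),
      provenance = ifelse(dplyr::n() > 1, "batch_average",
                          .data$provenance[1]),
      .groups = "drop"
    )
  activity_table(merged, wts[[1]])
}

#' Reduce triple mutants to effective double mutants
#'
#' For a triple mutant XYZ with a qualifying third mutation Z
#' (`RA(Z) > ra_threshold`), the remaining pair is assigned
#' `RA(XY) = RA(XYZ) / RA(Z)`, assuming Z does not covary with X or Y.
#' Every qualifying choice of Z in every triple is used; multiple
#' estimates for the same double key are averaged. Effective doubles are
#' only added for position pairs with no directly measured double mutant,
#' and never overwrite a direct measurement.
#'
#' @param table A `coda_activity` table containing singles and triples.
#' @param ra_threshold Minimum single-mutant RA for Z to qualify.
#' @return The table with reduced-triple doubles appended (provenance
#'   `"reduced_triple"`).
#' @export
reduce_triples <- function(table, ra_threshold = 0.5) {
  wt <- attr(table, "wild_type")
  singles <- table[table$n_mut == 1, ]
  triples <- table[table$n_mut == 3, ]
  if (nrow(triples) == 0) return(table)
  ra_single <- setNames(singles$ra, singles$subs)

  # position pairs already covered by direct doubles
  dlong <- subs_parse(table$subs[table$n_mut == 2])
  covered <- if (nrow(dlong) > 0) {
    pp <- matrix(dlong$pos, ncol = 2, byrow = TRUE)
    unique(paste0(pmin(pp[, 1], pp[, 2]), "_", pmax(pp[, 1], pp[, 2])))
  } else character(0)

  tlong <- subs_parse(triples$subs)   # sorted by variant, then position
  tok <- paste0(tlong$ref, tlong$pos, tlong$alt)
  tokmat <- matrix(tok, nrow = 3)     # column k = triple k's three tokens
  posmat <- matrix(tlong$pos, nrow = 3)
  est <- purrr::map_dfr(1:3, function(z) {
    xy_rows <- setdiff(1:3, z)
    ra_z <- unname(ra_single[tokmat[z, ]])
    key <- paste0(posmat[xy_rows[1], ], "_", posmat[xy_rows[2], ])
    ok <- !is.na(ra_z) & ra_z > ra_threshold & !(key %in% covered)
    tibble(
      subs = paste0(tokmat[xy_rows[1], ok], ",", tokmat[xy_rows[2], ok]),
      ra = triples$ra[ok] / ra_z[ok],
      n_total = triples$n_total[ok]
    )
  })
  if (nrow(est) == 0) return(table)
  est <- est |>
    dplyr::group_by(.data$subs) |>
    dplyr::summarise(n_mut = 2L, ra = mean(.data$ra),
                     n_total = sum(.data$n_total),
                     provenance = "reduced_triple", .groups = "drop")
  est <- est[!est$subs %in% table$subs, ]
  activity_table(dplyr::bind_rows(as_tibble(table), est), wt)
}

#' Read and write activity tables
#'
#' Tab-separated with a header row: `subs  ra  provenance  n_total`.
#' The wild-type row is encoded as an empty `subs` field.
#'
#' @param table A `coda_activity` table.
#' @param path File path.
#' @param wt A [wild_type()] object (needed on read to validate
#'   substitutions).
#' @return `write_activity()` returns `path` invisibly; `read_activity()`
#'   returns a `coda_activity` table.
#' @export
write_activity <- function(table, path) {
  readr::write_tsv(as_tibble(table)[, c("subs", "ra", "provenance",
                                        "n_total", "n_mut")], path)
  invisible(path)
}

#' @rdname write_activity
#' @export
read_activity <- function(path, wt) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    subs = readr::col_character(), ra = readr::col_double(),
    provenance = readr::col_character(), n_total = readr::col_double(),
    n_mut = readr::col_integer()
  ))
  df$subs[is.na(df$subs)] <- ""
  subs_validate(subs_parse(df$subs), wt)
  activity_table(df, wt)
}
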