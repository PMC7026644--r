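#' Activity-model parameters for the synthetic benchmark
#'
#' The generative stand-in for the self-cleavage selection assay: a
#' variant's true relative activity is a product over planted pairs and
#' mutated loop positions. A planted pair contributes 1 while the
#' variant's two bases still form a canonical (Watson-Crick or GU) pair
#' — the compensatory-rescue signal — and `delta_pair` (helix pairs) or
#' `delta_tertiary` (pseudoknot / lone / noncanonical pairs, a weaker
#' penalty emulating the weaker covariation signal of tertiary contacts)
#' once disrupted. Each mutated unpaired position contributes a seeded
#' per-(position, base) factor drawn uniformly from
#' `[loop_lo, loop_hi]`. Multiplicative lognormal noise with standard
#' deviation `noise_sd` models measurement scatter.
#'
#' @param delta_pair Penalty factor for a disrupted helix pair.
#' @param delta_tertiary Penalty factor for a disrupted tertiary pair.
#' @param loop_lo,loop_hi Range of loop-mutation factors.
#' @param noise_sd Lognormal sd of multiplicative activity noise.
#' @param p_cleave_wt Wild-type cleaved fraction in the selection.
#' @return A list of class `activity_params`.
#' @export
activity_params <- function(delta_pair = 0.05, delta_tertiary = 0.2,
                            loop_lo = 0.3, loop_hi = 1.1,
                            noise_sd = 0.1, p_cleave_wt = 0.5) {
  stopifnot(delta_pair > 0, delta_pair < 1, p_cleave_wt > 0,
            p_cleave_wt < 1, loop_lo > 0, loop_hi >= loop_lo)
  structure(list(delta_pair = delta_pair, delta_tertiary = delta_tertiary,
                 loop_lo = loop_lo, loop_hi = loop_hi,
                 noise_sd = noise_sd, p_cleave_wt = p_cleave_wt),
            class = "activity_params")
}

#' Mutant-library parameters for the synthetic benchmark
#'
#' Emulates an error-prone PCR library: each position mutates
#' independently per round with a base-dependent rate — positions whose
#' wild-type base is A or U mutate `at_bias` times faster than G/C
#' positions, reproducing epPCR's poorer coverage of GC regions — and
#' the alternative base is uniform over the three others. Read depth per
#' library molecule is lognormal with median `depth`.
#'
#' The default rate and round count give a mean of about two
#' substitutions per molecule on the 50-nt default benchmark — the rate
#' that maximizes the yield of exact double mutants — and the default
#' library of 1e5 molecules yields roughly 30,000 distinct
#' single-to-triple variants there, the scale of a real ribozyme deep
#' mutational scan.
#'
#' @param n_variants Number of library molecules.
#' @param mutation_rate Per-base, per-round mutation probability at G/C
#'   positions.
#' @param n_rounds Number of mutagenic PCR rounds.
#' @param at_bias Rate multiplier at A/U positions.
#' @param depth Median total reads per molecule.
#' @param depth_dispersion Lognormal sdlog of the read depth.
#' @param barcode_collision Probability that a molecule reuses an
#'   earlier molecule's barcode (exercises the consensus rule).
#' @return A list of class `library_params`.
#' @export
library_params <- function(n_variants = 100000, mutation_rate = 0.0042,
                           n_rounds = 5, at_bias = 2.5, depth = 50,
                           depth_dispersion = 0.5,
                           barcode_collision = 0) {
  stopifnot(n_variants > 0, mutation_rate > 0, n_rounds > 0,
            at_bias > 0, depth > 0, depth_dispersion >= 0,
            barcode_collision >= 0, barcode_collision < 1)
  structure(list(n_variants = as.integer(n_variants),
                 mutation_rate = mutation_rate,
                 n_rounds = as.integer(n_rounds), at_bias = at_bias,
                 depth = depth, depth_dispersion = depth_dispersion,
                 barcode_collision = barcode_collision),
            class = "library_params")
}

# 50-nt benchmark: two nested helices (5 bp, 6 bp), a 2-bp kissing
# pseudoknot between the hairpin loop and the 3' region, and one lone
# pair crossing the pseudoknot. All planted pairs are canonical in the
# wild type. Unpaired positions are A so that no spurious canonical
# helix competes with the planted structure; the tertiary pairs sit in
# AU context, where the AT-biased mutation spectrum gives the densest
# double-mutant coverage (GC helix pairs are covered more sparsely, as
# in real epPCR libraries).
.benchmark_sequence <- paste0(
  "AGGCGAAAAG",  # 1-10:  loop A, helix1 5' (2-6), helix2 5' starts at 10
  "CGGUGAAAAU",  # 11-20: helix2 5' (10-15), hairpin loop with PK 5' (19,20)
  "AAAACACCGC",  # 21-30: hairpin loop, helix2 3' (25-30)
  "AAAAAUAAAA",  # 31-40: lone 5' (33), PK 3' (35,36)
  "AUAAUCGCCA"   # 41-50: lone 3' (42), helix1 3' (45-49)
)
.benchmark_pairs <- tibble::tibble(
  i = c(2L, 3L, 4L, 5L, 6L, 10L, 11L, 12L, 13L, 14L, 15L, 19L, 20L, 33L),
  j = c(49L, 48L, 47L, 46L, 45L, 30L, 29L, 28L, 27L, 26L, 25L, 36L, 35L,
        42L),
  tertiary = c(rep(FALSE, 11), TRUE, TRUE, TRUE)
)

#' Deterministic planted-structure benchmark
#'
#' A 50-nt synthetic ribozyme with 14 planted canonical pairs: a 5-bp
#' helix, a 6-bp helix, a 2-bp kissing-loop pseudoknot and one lone pair
#' (the pseudoknot and lone pair are flagged tertiary and carry the
#' weaker disruption penalty). The sequence and structure are fixed; the
#' seed only draws the loop-mutation activity factors.
#'
#' @param seed Integer seed for the loop-effect draws.
#' @param params An [activity_params()].
#' @return An object of class `planted_ribozyme`: list with `wild_type`,
#'   `structure` (pair tibble with `tertiary` flag), `params`,
#'   `loop_effects` (tibble `pos, alt, effect`) and `seed`.
#' @export
make_default_benchmark <- function(seed = 1, params = activity_params()) {
  wt <- wild_type(.benchmark_sequence, id = "synthetic-benchmark-50nt")
  validate_structure(.benchmark_pairs, wt$length)
  b <- wt_bases(wt)
  paired <- c(.benchmark_pairs$i, .benchmark_pairs$j)
  unpaired <- setdiff(seq_len(wt$length), paired)
  grid <- tidyr::expand_grid(pos = unpaired, alt = c("A", "C", "G", "U"))
  grid <- grid[grid$alt != b[grid$pos], ]
  effects <- withr_seed(seed, {
    runif(nrow(grid), params$loop_lo, params$loop_hi)
  })
  structure(
    list(wild_type = wt, structure = .benchmark_pairs, params = params,
         loop_effects = tibble(pos = grid$pos, alt = grid$alt,
                               effect = effects),
         seed = seed),
    class = "planted_ribozyme"
  )
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.planted_ribozyme <- function(x, ...) {
  cat("<planted_ribozyme> ", x$wild_type$id, ": ",
      nrow(x$structure), " planted pairs (",
      sum(x$structure$tertiary), " tertiary)\n", sep = "")
  cat(x$wild_type$sequence, "\n")
  cat(write_dotbracket(x$structure, x$wild_type$length), "\n")
  invisible(x)
}

#' True activity of variants under the planted model
#'
#' Deterministic part of the structure-determined activity model:
#' product over planted pairs (1 if the variant's bases still form a
#' canonical pair, else the pair's disruption penalty) times the
#' loop-effect factors of mutated unpaired positions. Optional
#' multiplicative lognormal noise.
#'
#' @param ribozyme A [make_default_benchmark()] object.
#' @param subs Character vector of encoded substitution sets.
#' @param noise If `TRUE`, multiply by lognormal noise (requires
#'   `seed`).
#' @param seed Seed for the noise draws.
#' @return Numeric vector of true relative activities.
#' @export
simulate_activity <- function(ribozyme, subs, noise = FALSE,
                              seed = NULL) {
  long <- subs_parse(subs)
  subs_validate(long, ribozyme$wild_type)
  ra <- activity_from_long(ribozyme, long, length(subs))
  if (noise) {
    stopifnot(!is.null(seed))
    ra <- ra * withr_seed(seed, {
      rlnorm(length(subs), 0, ribozyme$params$noise_sd)
    })
  }
  ra
}

# vectorized activity evaluation from a parsed substitution table
activity_from_long <- function(ribozyme, long, n) {
  b <- wt_bases(ribozyme$wild_type)
  st <- ribozyme$structure
  pp <- ribozyme$params
  ra <- rep(1, n)

  # pair factors: look up each variant's bases at the pair's positions
  for (k in seq_len(nrow(st))) {
    i <- st$i[k]; j <- st$j[k]
    rows_i <- long$pos == i
    rows_j <- long$pos == j
    if (!any(rows_i) && !any(rows_j)) next
    bi <- rep(b[i], n); bj <- rep(b[j], n)
    bi[long$variant[rows_i]] <- long$alt[rows_i]
    bj[long$variant[rows_j]] <- long$alt[rows_j]
    ok <- paste0(bi, bj) %in% c("AU", "UA", "GC", "CG", "GU", "UG")
    delta <- if (st$tertiary[k]) pp$delta_tertiary else pp$delta_pair
    ra <- ra * ifelse(ok, 1, delta)
  }

  # loop factors for mutated unpaired positions
  le <- ribozyme$loop_effects
  idx <- match(paste(long$pos, long$alt), paste(le$pos, le$alt))
  hit <- !is.na(idx)
  if (any(hit)) {
    logf <- rowsum(log(le$effect[idx[hit]]), long$variant[hit])
    who <- as.integer(rownames(logf))
    ra[who] <- ra[who] * exp(logf[, 1])
  }
  ra
}

#' Simulate a deep-mutational-scanning library
#'
#' Draws an epPCR-like mutant library from a planted ribozyme, computes
#' true activities under the structure-determined model, and samples
#' read counts: per-molecule total reads are rounded lognormal with
#' median `depth`, and cleaved reads are binomial with success
#' probability `clamp(p_cleave_wt * RA_true, 0, 0.98)`. Molecules with
#' identical substitution sets are aggregated into one variant (their
#' reads summed) before count sampling; activity noise is drawn once per
#' distinct variant.
#'
#' @param ribozyme A [make_default_benchmark()] object.
#' @param lib A [library_params()].
#' @param seed Integer seed; all sampling is reproducible from
#'   `(seed, params)`.
#' @param emit_records If `TRUE`, also return raw per-read record
#'   tables: `dna_records` (`barcode, sequence`) and `rna_records`
#'   (`barcode, cleaved`), with per-molecule barcodes (subject to
#'   `barcode_collision`) and the variant counts derived from those
#'   records. Intended for small libraries; the aggregated route is the
#'   default.
#' @return A list with `variants` (tibble `subs, n_cleaved, n_total`),
#'   `truth` (tibble `subs, n_mut, ra_true, ra_noisy`), and when
#'   requested `dna_records` / `rna_records`.
#' @export
simulate_library <- function(ribozyme, lib = library_params(), seed = 1,
                             emit_records = FALSE) {
  wt <- ribozyme$wild_type
  L <- wt$length
  b <- wt_bases(wt)
  n <- lib$n_variants
  withr_seed(seed, {
    rate <- ifelse(b %in% c("A", "U"),
                   lib$mutation_rate * lib$at_bias, lib$mutation_rate)
    p_pos <- 1 - (1 - rate)^lib$n_rounds
    mut <- matrix(runif(n * L), n, L) < rep(p_pos, each = n)
    hits <- which(mut, arr.ind = TRUE)
    others <- rbind(c("C", "G", "U"), c("A", "G", "U"),
                    c("A", "C", "U"), c("A", "C", "G"))  # rows A,C,G,U
    ref_row <- match(b[hits[, 2]], c("A", "C", "G", "U"))
    alt <- others[cbind(ref_row, sample.int(3, nrow(hits),
                                            replace = TRUE))]
    long <- tibble(variant = hits[, 1], pos = hits[, 2], alt = alt,
                   ref = b[hits[, 2]])
    long <- dplyr::arrange(long, .data$variant, .data$pos)
    tok <- paste0(long$ref, long$pos, long$alt)
    subs_mol <- character(n)
    enc <- vapply(split(tok, long$variant), paste, character(1),
                  collapse = ",")
    subs_mol[as.integer(names(enc))] <- enc

    ra_det_mol <- activity_from_long(ribozyme, long, n)
    depth_mol <- pmax(1L, as.integer(round(
      rlnorm(n, log(lib$depth), lib$depth_dispersion))))

    # aggregate molecules into distinct variants
    agg <- tibble(subs = subs_mol, ra_det = ra_det_mol,
                  n_total = depth_mol) |>
      dplyr::group_by(.data$subs) |>
      dplyr::summarise(ra_det = .data$ra_det[1],
                       n_total = sum(.data$n_total),
                       n_molecules = dplyr::n(), .groups = "drop")
    # measurement noise enters per library molecule, so variants backed
    # by many molecules (the wild type above all) see it average out
    agg$ra_noisy <- agg$ra_det *
      rlnorm(nrow(agg), 0,
             ribozyme$params$noise_sd / sqrt(agg$n_molecules))
    p_cleave <- pmin(pmax(ribozyme$params$p_cleave_wt * agg$ra_noisy,
                          0), 0.98)
    agg$n_cleaved <- rbinom(nrow(agg), agg$n_total, p_cleave)

    n_mut <- ifelse(agg$subs == "", 0L,
                    stringr::str_count(agg$subs, ",") + 1L)
    out <- list(
      variants = tibble(subs = agg$subs, n_cleaved = agg$n_cleaved,
                        n_total = agg$n_total),
      truth = tibble(subs = agg$subs, n_mut = n_mut,
                     ra_true = agg$ra_det, ra_noisy = agg$ra_noisy)
    )

    if (emit_records) {
      barcode <- sprintf("BC%07d", seq_len(n))
      if (lib$barcode_collision > 0 && n > 1) {
        reuse <- which(runif(n) < lib$barcode_collision)
        reuse <- reuse[reuse > 1]
        barcode[reuse] <- barcode[vapply(reuse, function(k) {
          sample.int(k - 1, 1)
        }, integer(1))]
      }
      seq_mat <- apply_subs(long, wt, n)
      seqs <- apply(seq_mat, 1, paste, collapse = "")
      out$dna_records <- tibble(barcode = rep(barcode, 2),
                                sequence = rep(seqs, 2))
      p_mol <- pmin(pmax(
        ribozyme$params$p_cleave_wt *
          agg$ra_noisy[match(subs_mol, agg$subs)], 0), 0.98)
      rna <- tibble(
        barcode = rep(barcode, depth_mol),
        cleaved = as.integer(runif(sum(depth_mol)) <
                               rep(p_mol, depth_mol))
      )
      out$rna_records <- rna
    }
    out
  })
}
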