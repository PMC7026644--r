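#' Annealing schedule
#'
#' Geometric cooling for the Metropolis sampler: starting at
#' `t_initial`, the (unitless) temperature is multiplied by
#' `cooling_factor` after every round of `steps_per_temperature`
#' Metropolis steps until it falls below `t_final`. The defaults (10,
#' 0.95, 0.1, 500,000 steps) are the production schedule; scaled-down
#' step counts are appropriate for short sequences.
#'
#' @param t_initial Starting temperature.
#' @param cooling_factor Multiplicative cooling per round, in (0, 1).
#' @param t_final Temperature at which cooling stops.
#' @param steps_per_temperature Metropolis steps per temperature round.
#' @return An object of class `anneal_schedule`.
#' @export
anneal_schedule <- function(t_initial = 10, cooling_factor = 0.95,
                            t_final = 0.1,
                            steps_per_temperature = 500000) {
  stopifnot(cooling_factor > 0, cooling_factor < 1,
            t_final > 0, t_final < t_initial,
            steps_per_temperature >= 1)
  structure(list(t_initial = t_initial, cooling_factor = cooling_factor,
                 t_final = t_final,
                 steps_per_temperature = as.integer(steps_per_temperature)),
            class = "anneal_schedule")
}

#' Propose a Monte Carlo move on a structure
#'
#' The sampler's move kernel, the standard insertion/deletion/shift
#' move set of RNA folding-kinetics samplers. With probability 1/3 a
#' uniformly random existing pair is proposed for removal (a no-op on
#' an empty structure); with probability 1/3 a candidate position pair
#' drawn uniformly from all loop-feasible pairs
#' (`j - i - 1 >= min_loop`) is toggled — removed if present, added if
#' both of its bases are unpaired, a no-op otherwise; with probability
#' 1/3 an existing pair keeps one endpoint and shifts the other to a
#' uniformly chosen free, loop-valid position. Any base combination may
#' be added: noncanonical pairs are penalized by the energy model, not
#' forbidden. Conditional on proposing a removal, each existing pair is
#' equally likely; conditional on an addition, each feasible new pair
#' is equally likely; a shift proposal is exactly symmetric. Because
#' the removal and toggle sub-kernels overlap, the sampler pairs them
#' with an exact Metropolis-Hastings correction, so the
#' fixed-temperature chain is Boltzmann-distributed. Uses R's RNG.
#'
#' @param pairs Current structure (tibble with columns `i`, `j`).
#' @param L Sequence length.
#' @param min_loop Minimum enclosed unpaired span.
#' @return A list with elements `type` (`"add"`, `"remove"` or
#'   `"none"`), `i`, `j` (`i`/`j` are `NA` for the empty-structure
#'   no-op).
#' @export
propose_move <- function(pairs, L, min_loop = 3) {
  partner <- pairs_to_partner(pairs, L)
  u <- stats::runif(1)
  if (u < 1 / 3) {
    if (nrow(pairs) == 0) return(list(type = "none", i = NA, j = NA))
    k <- sample.int(nrow(pairs), 1)
    return(list(type = "remove", i = pairs$i[k], j = pairs$j[k]))
  }
  if (u < 2 / 3) {
    cand <- which(outer(seq_len(L), seq_len(L),
                        function(i, j) j - i - 1 >= min_loop),
                  arr.ind = TRUE)
    k <- sample.int(nrow(cand), 1)
    i <- cand[k, 1]
    j <- cand[k, 2]
    if (partner[i] == j) {
      return(list(type = "remove", i = i, j = j))
    } else if (partner[i] == 0 && partner[j] == 0) {
      return(list(type = "add", i = i, j = j))
    }
    return(list(type = "none", i = i, j = j))
  }
  if (nrow(pairs) == 0) return(list(type = "none", i = NA, j = NA))
  k <- sample.int(nrow(pairs), 1)
  keep <- if (stats::runif(1) < 0.5) pairs$i[k] else pairs$j[k]
  free <- which(partner == 0 & abs(seq_len(L) - keep) - 1 >= min_loop)
  if (length(free) == 0) return(list(type = "none", i = NA, j = NA))
  p <- free[sample.int(length(free), 1)]
  list(type = "shift", i = min(keep, p), j = max(keep, p),
       old_i = pairs$i[k], old_j = pairs$j[k])
}

#' Predict a structure by simulated annealing
#'
#' Metropolis simulated annealing over pair sets under the
#' [energy_model()] energy, optionally restrained by CODA pairing scores
#' (`E - W * Ps / m`, with `m` the mean positive per-position score).
#' Moves insert, delete or shift a single pair (see [propose_move()]);
#' acceptance follows the Metropolis rule with the exact proposal-ratio
#' correction. The annealer is an optimizer, so it returns the
#' lowest-energy structure visited anywhere along the schedule. Fully
#' reproducible given `seed`.
#'
#' @param sequence Character scalar or [wild_type()].
#' @param model An [energy_model()].
#' @param ps Optional pairing scores (see [structure_energy()]).
#' @param weight Restraint weight W.
#' @param schedule An [anneal_schedule()].
#' @param seed Integer seed for the sampler's RNG.
#' @return A tibble of pairs (`i`, `j`) with attributes `energy`,
#'   `sequence` and class `rna_structure`.
#' @export
anneal <- function(sequence, model = energy_model(), ps = NULL,
                   weight = 2.0, schedule = anneal_schedule(), seed = 1) {
  code <- seq_to_int(sequence)
  L <- length(code)
  psmat <- ps_matrix(ps, L)
  m <- ps_norm(psmat)
  wm <- if (m > 0) weight / m else 0
  if (is.null(psmat)) psmat <- matrix(0, L, L)
  res <- cpp_anneal(code, model$stacks, model$lone_penalty,
                    model$noncanonical_penalty, model$au_end_penalty,
                    model$min_loop, psmat, wm,
                    schedule$t_initial, schedule$cooling_factor,
                    schedule$t_final, schedule$steps_per_temperature,
                    as.double(seed))
  out <- partner_to_pairs(res$partner)
  attr(out, "energy") <- res$energy
  attr(out, "sequence") <- paste(c("A", "C", "G", "U")[code + 1],
                                 collapse = "")
  class(out) <- c("rna_structure", class(out))
  out
}

#' Sample structures at a fixed temperature
#'
#' Long-run Metropolis sampling at constant temperature, returning the
#' marginal occupancy frequency of every pair. Used to check that the
#' sampler equilibrates to the Boltzmann distribution.
#'
#' @inheritParams anneal
#' @param temperature Fixed (unitless) temperature.
#' @param n_steps Total Metropolis steps after burn-in.
#' @param burn_in Discarded initial steps.
#' @param thin Record occupancy every `thin` steps.
#' @return A tibble `i, j, freq` over pairs observed at least once.
#' @export
mc_sample <- function(sequence, model = energy_model(), ps = NULL,
                      weight = 2.0, temperature = 1, n_steps = 1e6,
                      burn_in = 1e5, thin = 10, seed = 1) {
  code <- seq_to_int(sequence)
  L <- length(code)
  psmat <- ps_matrix(ps, L)
  m <- ps_norm(psmat)
  wm <- if (m > 0) weight / m else 0
  if (is.null(psmat)) psmat <- matrix(0, L, L)
  res <- cpp_mc_sample(code, model$stacks, model$lone_penalty,
                       model$noncanonical_penalty, model$au_end_penalty,
                       model$min_loop, psmat, wm, temperature,
                       as.integer(n_steps), as.integer(burn_in),
                       as.integer(thin), as.double(seed))
  idx <- which(res$counts > 0, arr.ind = TRUE)
  tibble(i = idx[, 1], j = idx[, 2],
         freq = res$counts[idx] / res$n_samples)
}

#' Fold an ensemble of annealing runs
#'
#' Repeats [anneal()] with distinct derived seeds and aggregates the
#' per-pair occupancy over runs into pair frequencies (contact
#' probabilities). The consensus structure is extracted greedily: pairs
#' sorted by frequency (ties by `(i, j)` lexicographic order) are
#' accepted while their frequency is at least `consensus_threshold` and
#' both bases are still unpaired.
#'
#' @inheritParams anneal
#' @param n_runs Number of independent annealing runs.
#' @param consensus_threshold Minimum pair frequency for the consensus.
#' @return An object of class `coda_fold`: list with `pair_freq`
#'   (tibble `i, j, freq`), `consensus` (`rna_structure` pairs tibble),
#'   `n_runs`, `energies` and `sequence`.
#' @export
fold_ensemble <- function(sequence, model = energy_model(), ps = NULL,
                          weight = 2.0, schedule = anneal_schedule(),
                          n_runs = 100, seed = 1,
                          consensus_threshold = 0.5) {
  stopifnot(n_runs >= 1)
  run_seeds <- (as.double(seed) + 7919 * (seq_len(n_runs) - 1)) %% 2147483647
  runs <- purrr::map(run_seeds, function(s) {
    anneal(sequence, model = model, ps = ps, weight = weight,
           schedule = schedule, seed = s)
  })
  freq <- dplyr::bind_rows(runs) |>
    dplyr::count(.data$i, .data$j, name = "n") |>
    dplyr::mutate(freq = .data$n / n_runs) |>
    dplyr::select("i", "j", "freq") |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$i, .data$j)
  class(freq) <- c("tbl_df", "tbl", "data.frame")
  attr(freq, "sequence") <- NULL
  attr(freq, "energy") <- NULL

  L <- nchar(attr(runs[[1]], "sequence"))
  consensus <- consensus_structure(freq, L,
                                   threshold = consensus_threshold)
  attr(consensus, "sequence") <- attr(runs[[1]], "sequence")
  structure(
    list(pair_freq = freq, consensus = consensus, n_runs = n_runs,
         energies = purrr::map_dbl(runs, attr, "energy"),
         sequence = attr(runs[[1]], "sequence")),
    class = "coda_fold"
  )
}

#' Greedy consensus from pair frequencies
#'
#' Pairs sorted by frequency (descending; ties by `(i, j)` lexicographic
#' order) are accepted while their frequency is at least `threshold` and
#' both bases are still unpaired, so the consensus never pairs a base
#' twice.
#'
#' @param pair_freq Tibble `i, j, freq`.
#' @param L Sequence length.
#' @param threshold Minimum frequency.
#' @return An `rna_structure` pair tibble (with `freq` retained).
#' @export
consensus_structure <- function(pair_freq, L, threshold = 0.5) {
  freq <- dplyr::arrange(pair_freq, dplyr::desc(.data$freq), .data$i,
                         .data$j)
  taken <- logical(L)
  keep <- logical(nrow(freq))
  for (k in seq_len(nrow(freq))) {
    if (freq$freq[k] >= threshold &&
        !taken[freq$i[k]] && !taken[freq$j[k]]) {
      keep[k] <- TRUE
      taken[freq$i[k]] <- TRUE
      taken[freq$j[k]] <- TRUE
    }
  }
  out <- dplyr::arrange(freq[keep, ], .data$i)
  class(out) <- unique(c("rna_structure", class(out)))
  out
}

#' @export
print.coda_fold <- function(x, ...) {
  cat("<coda_fold> ", x$n_runs, " annealing runs, ",
      nrow(x$consensus), " consensus pairs\n", sep = "")
  cat(x$sequence, "\n")
  cat(write_dotbracket(x$consensus, nchar(x$sequence)), "\n")
  invisible(x)
}

#' @export
tidy.coda_fold <- function(x, ...) x$pair_freq

#' @export
glance.coda_fold <- function(x, ...) {
  tibble(n_runs = x$n_runs, n_consensus_pairs = nrow(x$consensus),
         min_energy = min(x$energies), mean_energy = mean(x$energies))
}
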