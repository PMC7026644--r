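test_that("energy worked examples match the embedded Turner terms", {
  # empty structure
  expect_equal(structure_energy(tibble::tibble(i = integer(0),
                                               j = integer(0)),
                                "GGGAAAACCC"), 0)
  # GC-closed hairpin: two GG/CC stacks, no penalties
  hp <- tibble::tibble(i = 1:3, j = 10:8)
  expect_equal(structure_energy(hp, "GGGAAAACCC"), 2 * -3.30)
  # single isolated AU pair: lone penalty + one terminal AU penalty
  au <- tibble::tibble(i = 1L, j = 10L)
  expect_equal(structure_energy(au, "AGGAAAACCU"), 3 + 0.45)
  # isolated GC pair: lone penalty only
  expect_equal(structure_energy(au, "GGGAAAACCC"), 3)
  # isolated noncanonical pair: lone + noncanonical, no AU-end term
  expect_equal(structure_energy(au, "AGGAAAACCA"), 3 + 3)
})

test_that("energy is additive against an independent per-term recount", {
  set.seed(41)
  for (k in 1:25) {
    L <- sample(15:40, 1)
    seq <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                 collapse = "")
    pairs <- random_pairs(L, sample(2:6, 1), min_loop = 3)
    ps <- NULL
    w <- 2
    if (k %% 3 == 0) {
      ps <- dplyr::mutate(random_pairs(L, 4, min_loop = 3),
                          ps = runif(4, -2, 6))
      w <- runif(1, 0, 5)
    }
    expect_equal(structure_energy(pairs, seq, ps = ps, weight = w),
                 naive_energy(pairs, seq, ps = ps, weight = w),
                 tolerance = 1e-10)
  }
})

test_that("structures enforce one partner per base and the loop span", {
  expect_error(validate_structure(tibble::tibble(i = c(1, 2), j = c(8, 8)),
                                  10), "more than a single base")
  expect_error(validate_structure(tibble::tibble(i = 5, j = 7), 10,
                                  min_loop = 3), "min_loop")
  expect_error(validate_structure(tibble::tibble(i = 0, j = 5), 10),
               "outside")
  # crossing pairs are permitted
  expect_silent(validate_structure(tibble::tibble(i = c(1, 3),
                                                  j = c(6, 10)), 10))
  partner <- pairs_to_partner(tibble::tibble(i = c(1, 3), j = c(6, 10)), 10)
  expect_equal(partner[partner[1]], 1)  # involution
  expect_equal(partner_to_pairs(partner),
               tibble::tibble(i = c(1L, 3L), j = c(6L, 10L)))
})

test_that("move proposals are feasible and uniform where they should be", {
  set.seed(91)
  empty <- tibble::tibble(i = integer(0), j = integer(0))
  moves <- purrr::map(1:500, ~ propose_move(empty, 12))
  types <- purrr::map_chr(moves, "type")
  expect_false(any(types == "remove"))  # nothing to remove
  expect_gt(mean(types == "add"), 0.3)
  adds <- purrr::keep(moves, ~ .x$type == "add")
  spans <- purrr::map_int(adds, ~ .x$j - .x$i - 1L)
  expect_true(all(spans >= 3))

  hp <- tibble::tibble(i = 1:3, j = 10:8)
  res <- purrr::map(1:4000, ~ propose_move(hp, 10))
  rem <- purrr::keep(res, ~ .x$type == "remove")
  tab <- table(purrr::map_chr(rem, ~ paste(.x$i, .x$j)))
  expect_setequal(names(tab), c("1 10", "2 9", "3 8"))
  # each existing pair picked ~uniformly among removals
  expect_true(all(abs(tab / length(rem) - 1 / 3) < 0.09))
})

test_that("annealing is deterministic given the seed", {
  sched <- anneal_schedule(steps_per_temperature = 2000)
  s1 <- anneal("GGGCAAAAGCCC", schedule = sched, seed = 7)
  s2 <- anneal("GGGCAAAAGCCC", schedule = sched, seed = 7)
  expect_equal(as.data.frame(s1), as.data.frame(s2))
  expect_equal(attr(s1, "energy"), attr(s2, "energy"))
})

test_that("annealing reaches the enumerated minimum on short sequences", {
  set.seed(17)
  sched <- anneal_schedule(steps_per_temperature = 10000)
  for (k in 1:4) {
    L <- sample(14:17, 1)
    seq <- paste(sample(c("A", "C", "G", "U"), L, replace = TRUE,
                        prob = c(0.3, 0.25, 0.25, 0.2)), collapse = "")
    emin <- enumerate_min_energy(seq)
    hits <- purrr::map_dbl(1:3, function(r) {
      attr(anneal(seq, schedule = sched, seed = 100 * k + r), "energy")
    })
    expect_equal(min(hits), emin, tolerance = 1e-9)
    expect_gte(min(hits), emin - 1e-9)  # never below the true minimum
  }
})

test_that("ensemble frequencies and greedy consensus behave as specified", {
  sched <- anneal_schedule(steps_per_temperature = 5000)
  f1 <- fold_ensemble("GGGCAAAAGCCC", schedule = sched, n_runs = 1,
                      seed = 3)
  expect_true(all(f1$pair_freq$freq %in% c(0, 1)))
  run1 <- anneal("GGGCAAAAGCCC", schedule = sched, seed = 3)
  expect_equal(f1$consensus[, c("i", "j")], run1[, c("i", "j")],
               ignore_attr = TRUE)

  # a GC-rich stem is found in essentially every run
  f <- fold_ensemble("GGGGCAAAAGCCCC",
                     schedule = anneal_schedule(
                       steps_per_temperature = 10000),
                     n_runs = 20, seed = 11)
  stem <- dplyr::semi_join(
    f$pair_freq, tibble::tibble(i = 1:5, j = 14:10), by = c("i", "j"))
  expect_equal(nrow(stem), 5)
  expect_true(all(stem$freq >= 0.95))

  # greedy conflict resolution keeps the more frequent of two clashing pairs
  pf <- tibble::tibble(i = c(2L, 2L, 5L), j = c(9L, 8L, 9L),
                       freq = c(0.9, 0.6, 0.6))
  cons <- consensus_structure(pf, 12)
  expect_equal(cons$i, 2L)
  expect_equal(cons$j, 9L)
  # sub-threshold pairs never enter
  pf2 <- tibble::tibble(i = c(2L, 5L), j = c(9L, 10L), freq = c(0.49, 0.8))
  expect_equal(consensus_structure(pf2, 12)$i, 5L)
})

test_that("without restraints no consensus contains lone or noncanonical pairs", {
  set.seed(23)
  sched <- anneal_schedule(steps_per_temperature = 5000)
  canon <- c("CG", "GC", "GU", "UG", "AU", "UA")
  for (k in 1:3) {
    seq <- paste(sample(c("A", "C", "G", "U"), 30, replace = TRUE),
                 collapse = "")
    b <- strsplit(seq, "")[[1]]
    f <- fold_ensemble(seq, schedule = sched, n_runs = 10, seed = k)
    cons <- f$consensus
    if (nrow(cons) == 0) next
    partner <- pairs_to_partner(cons, 30)
    for (r in seq_len(nrow(cons))) {
      i <- cons$i[r]; j <- cons$j[r]
      expect_true(paste0(b[i], b[j]) %in% canon)
      lone <- !(i > 1 && j < 30 && partner[i - 1] == j + 1) &&
        !(partner[i + 1] == j - 1)
      expect_false(lone)
    }
  }
})

test_that("fixed-temperature sampling reproduces exact Boltzmann marginals", {
  seq12 <- "GGCAAAAAAGCC"
  exact <- boltzmann_pair_marginals(seq12, temp = 1.5)
  samp <- mc_sample(seq12, temperature = 1.5, n_steps = 6e5,
                    burn_in = 5e4, thin = 5, seed = 99)
  est <- matrix(0, 12, 12)
  est[cbind(samp$i, samp$j)] <- samp$freq
  idx <- which(exact > 0.005, arr.ind = TRUE)
  expect_gt(nrow(idx), 2)
  expect_true(all(abs(est[idx] - exact[idx]) < 0.02))
  # and nothing appreciable appears that the exact distribution excludes
  expect_true(all(est[exact < 1e-4] < 0.01))
})

test_that("a pairing-score restraint pulls a restrained pair into the fold", {
  # strong restraint on a pseudoknot-like pair that stacking alone rejects
  seq <- "GGGCAAAAGCCCAAUAAA"  # A6-U15 crosses the 1-12 stem's loop
  ps <- tibble::tibble(i = c(6L), j = c(15L), ps = 5)
  sched <- anneal_schedule(steps_per_temperature = 5000)
  f0 <- fold_ensemble(seq, schedule = sched, n_runs = 10, seed = 2)
  expect_false(any(f0$consensus$i == 6 & f0$consensus$j == 15))
  f1 <- fold_ensemble(seq, ps = ps, weight = 4, schedule = sched,
                      n_runs = 10, seed = 2)
  expect_true(any(f1$consensus$i == 6 & f1$consensus$j == 15))
})
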