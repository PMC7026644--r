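# Shared fixtures and independent oracles for the test suite.

toy_wt <- function(seq = "GGCGAAAGCCGAAACGGC") wild_type(seq, id = "toy")

# A small noiseless activity table following the multiplicative
# independence model exactly, with optional planted compensatory pairs
# whose rescue doubles get RA 1 (the CODA signal). Singles cover every
# (pos, alt); doubles cover `n_doubles` random position pairs.
toy_activity <- function(wt = toy_wt(), n_doubles = 200, seed = 42,
                         planted = NULL) {
  set.seed(seed)
  L <- wt$length
  b <- strsplit(wt$sequence, "")[[1]]
  alts <- c("A", "C", "G", "U")
  singles <- tidyr::expand_grid(pos = seq_len(L), alt = alts)
  singles <- singles[singles$alt != b[singles$pos], ]
  singles$ra <- runif(nrow(singles), 0.05, 1.2)
  stab <- tibble::tibble(
    subs = paste0(b[singles$pos], singles$pos, singles$alt),
    n_mut = 1L, ra = singles$ra, n_total = 100L, provenance = "measured"
  )
  key <- function(pos, alt) paste0(pos, alt)
  ra1 <- stats::setNames(singles$ra, key(singles$pos, singles$alt))

  dd <- singles[sample.int(nrow(singles), 2 * n_doubles, replace = TRUE), ]
  a <- dd[seq_len(n_doubles), ]
  c2 <- dd[n_doubles + seq_len(n_doubles), ]
  ok <- a$pos != c2$pos
  a <- a[ok, ]; c2 <- c2[ok, ]
  swap <- a$pos > c2$pos
  tmp <- a[swap, ]; a[swap, ] <- c2[swap, ]; c2[swap, ] <- tmp
  dtab <- tibble::tibble(
    subs = paste0(b[a$pos], a$pos, a$alt, ",", b[c2$pos], c2$pos, c2$alt),
    n_mut = 2L,
    ra = ra1[key(a$pos, a$alt)] * ra1[key(c2$pos, c2$alt)],
    n_total = 100L, provenance = "measured"
  )
  dtab <- dtab[!duplicated(dtab$subs), ]
  if (!is.null(planted)) {
    for (k in seq_len(nrow(planted))) {
      i <- planted$i[k]; j <- planted$j[k]
      hit <- grepl(paste0("^[ACGU]", i, "[ACGU],[ACGU]", j, "[ACGU]$"),
                   dtab$subs)
      dtab$ra[hit] <- 1
    }
  }
  activity_table(dplyr::bind_rows(
    tibble::tibble(subs = "", n_mut = 0L, ra = 1, n_total = 10000L,
                   provenance = "measured"),
    stab, dtab), wt)
}

# Independent recount of the folding energy: straightforward loops over
# the pair set, written separately from the package's evaluation path.
naive_energy <- function(pairs, sequence, lone = 3, noncan = lone,
                         auend = 0.45, ps = NULL, weight = 2) {
  b <- strsplit(chartr("T", "U", toupper(sequence)), "")[[1]]
  L <- length(b)
  canon <- c("CG", "GC", "GU", "UG", "AU", "UA")
  stacks <- codarna:::.turner_stacks  # the embedded constants are data
  partner <- integer(L)
  for (k in seq_len(nrow(pairs))) {
    partner[pairs$i[k]] <- pairs$j[k]
    partner[pairs$j[k]] <- pairs$i[k]
  }
  has_pair <- function(i, j) {
    i >= 1 && j <= L && i < j && partner[i] == j
  }
  m <- if (is.null(ps)) 0 else {
    v <- ps$ps[ps$ps > 0]
    if (length(v) == 0) 0 else mean(v)
  }
  e <- 0
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    pt <- paste0(b[i], b[j])
    outer_nb <- has_pair(i - 1, j + 1)
    inner_nb <- has_pair(i + 1, j - 1)
    if (!outer_nb && !inner_nb) e <- e + lone
    if (!pt %in% canon) {
      e <- e + noncan
    } else if (pt %in% c("GU", "UG", "AU", "UA")) {
      n_end <- (!outer_nb) + (!inner_nb)
      if (n_end == 2) n_end <- 1
      e <- e + n_end * auend
    }
    if (inner_nb) {
      pt2 <- paste0(b[j - 1], b[i + 1])  # inner pair from opposite strand
      if (pt %in% canon && paste0(b[i + 1], b[j - 1]) %in% canon) {
        e <- e + stacks[pt, pt2]
      }
    }
    if (m > 0) {
      hit <- ps$i == i & ps$j == j
      if (any(hit)) e <- e - weight * ps$ps[hit][1] / m
    }
  }
  e
}

# Exhaustive minimum energy over all canonical-pair structures (crossing
# pairs allowed, loop constraint enforced). Noncanonical pairs never
# lower the energy (they add their penalty and stack nothing), so the
# canonical-only minimum is the global minimum.
enumerate_min_energy <- function(sequence, model = energy_model(),
                                 ps = NULL, weight = 2) {
  code <- codarna:::seq_to_int(sequence)
  L <- length(code)
  canon <- matrix(FALSE, 4, 4)
  for (p in list(c(2, 3), c(3, 2), c(3, 4), c(4, 3), c(1, 4), c(4, 1))) {
    canon[p[1], p[2]] <- TRUE
  }
  cand <- list()
  for (i in seq_len(L - 1)) {
    for (j in seq_len(L)) {
      if (j - i - 1 >= model$min_loop && canon[code[i] + 1, code[j] + 1]) {
        cand[[length(cand) + 1]] <- c(i, j)
      }
    }
  }
  psmat <- codarna:::ps_matrix(ps, L)
  m <- codarna:::ps_norm(psmat)
  wm <- if (m > 0) weight / m else 0
  if (is.null(psmat)) psmat <- matrix(0, L, L)
  partner <- integer(L)
  best <- 0  # empty structure
  n_cand <- length(cand)
  rec <- function(k) {
    if (k > n_cand) {
      e <- codarna:::cpp_energy(partner, code, model$stacks,
                                model$lone_penalty,
                                model$noncanonical_penalty,
                                model$au_end_penalty, psmat, wm)
      if (e < best) best <<- e
      return(invisible())
    }
    rec(k + 1)
    i <- cand[[k]][1]; j <- cand[[k]][2]
    if (partner[i] == 0 && partner[j] == 0) {
      partner[i] <<- j; partner[j] <<- i
      rec(k + 1)
      partner[i] <<- 0; partner[j] <<- 0
    }
    invisible()
  }
  rec(1)
  best
}

# Enumerate every structure (any base combination) with Boltzmann
# weights at temperature `temp`; returns exact pair marginals.
boltzmann_pair_marginals <- function(sequence, model = energy_model(),
                                     temp = 1) {
  code <- codarna:::seq_to_int(sequence)
  L <- length(code)
  cand <- list()
  for (i in seq_len(L - 1)) {
    for (j in seq_len(L)) {
      if (j - i - 1 >= model$min_loop) {
        cand[[length(cand) + 1]] <- c(i, j)
      }
    }
  }
  psmat <- matrix(0, L, L)
  partner <- integer(L)
  Z <- 0
  wsum <- matrix(0, L, L)
  rec <- function(k) {
    if (k > length(cand)) {
      e <- codarna:::cpp_energy(partner, code, model$stacks,
                                model$lone_penalty,
                                model$noncanonical_penalty,
                                model$au_end_penalty, psmat, 0)
      w <- exp(-e / temp)
      Z <<- Z + w
      idx <- which(partner > seq_len(L))
      for (i in idx) wsum[i, partner[i]] <<- wsum[i, partner[i]] + w
      return(invisible())
    }
    rec(k + 1)
    i <- cand[[k]][1]; j <- cand[[k]][2]
    if (partner[i] == 0 && partner[j] == 0) {
      partner[i] <<- j; partner[j] <<- i
      rec(k + 1)
      partner[i] <<- 0; partner[j] <<- 0
    }
    invisible()
  }
  rec(1)
  wsum / Z
}

# Naive per-threshold PR / max-MCC sweep recomputing the confusion table
# from scratch at every distinct score value.
naive_sweep <- function(position_scores, reference, L) {
  val <- position_scores$ps
  ref_key <- paste(reference$i, reference$j)
  all_key <- paste(position_scores$i, position_scores$j)
  ths <- sort(unique(val), decreasing = TRUE)
  P <- nrow(reference)
  n_univ <- choose(L, 2)
  rows <- lapply(ths, function(th) {
    pred <- all_key[val >= th]
    tp <- sum(pred %in% ref_key)
    fp <- length(pred) - tp
    fn <- P - tp
    tn <- n_univ - tp - fp - fn
    mcc_num <- tp * tn - fp * fn
    mcc_den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    data.frame(threshold = th, recall = tp / P, precision = tp / (tp + fp),
               mcc = if (mcc_den == 0) 0 else mcc_num / mcc_den)
  })
  do.call(rbind, rows)
}

naive_auc <- function(sweep) {
  r <- c(0, sweep$recall)
  p <- c(sweep$precision[1], sweep$precision)
  sum(diff(r) * (head(p, -1) + p[-1]) / 2)
}

# One full synthetic benchmark run (simulate -> activities -> CODA fit),
# computed once and reused across test files.
benchmark_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rz <- make_default_benchmark(seed = 12)
      sim <- simulate_library(rz, library_params(), seed = 24)
      act <- reduce_triples(compute_ra(sim$variants, rz$wild_type))
      fit <- coda_fit(act)
      cache <<- list(rz = rz, sim = sim, act = act, fit = fit)
    }
    cache
  }
})

random_pairs <- function(L, n, min_loop = 0) {
  pool <- which(outer(seq_len(L), seq_len(L),
                      function(i, j) j - i - 1 >= min_loop),
                arr.ind = TRUE)
  taken <- logical(L)
  out <- list()
  for (k in sample.int(nrow(pool), nrow(pool))) {
    i <- pool[k, 1]; j <- pool[k, 2]
    if (!taken[i] && !taken[j]) {
      out[[length(out) + 1]] <- c(i, j)
      taken[i] <- TRUE; taken[j] <- TRUE
      if (length(out) >= n) break
    }
  }
  m <- do.call(rbind, out)
  tibble::tibble(i = m[, 1], j = m[, 2])
}
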