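#' Fit the independent-mutation model
#'
#' Fits an unsupervised support-vector regression (RBF kernel) of the
#' observed double-mutant relative activity against the two constituent
#' single-mutant activities. Under the independence assumption the model
#' predicts the activity of any double mutant; compensatory base-pair
#' rescues then appear as outliers above the prediction. All double
#' entries are used, functional and nonfunctional alike — no activity
#' filtering — and no structural information enters the fit.
#'
#' The regressor is trained on both argument orders of each
#' `(ra_i, ra_j)` feature pair, and [predict_double()] averages the two
#' orders, so predictions are symmetric by construction.
#'
#' @param table A `coda_activity` table with full single coverage of the
#'   positions touched by its doubles (entries with a missing constituent
#'   single are skipped with a warning).
#' @param C Regularization (box-constraint) parameter of the SVR.
#' @param gamma RBF kernel width.
#' @param epsilon Width of the SVR epsilon-insensitive tube. The default
#'   matches the reference implementation's tooling; training residuals
#'   are bounded by roughly this value, so tighten it if predictions
#'   must track the independence surface more closely.
#'
#' @return An object of class `coda_svr`: the fitted regressor plus the
#'   training table (`doubles`, with `ra_i`, `ra_j`, `ra_obs`).
#' @export
fit_independent_model <- function(table, C = 2000, gamma = 2.0,
                                  epsilon = 0.1) {
  d <- double_features(table)
  if (nrow(d$missing) > 0) {
    warning(nrow(d$missing),
            " double entr(ies) skipped: constituent single mutant missing")
  }
  doubles <- d$doubles
  if (nrow(doubles) < 50) {
    stop("only ", nrow(doubles),
         " usable double entries; at least 50 are required")
  }
  x <- rbind(cbind(doubles$ra_i, doubles$ra_j),
             cbind(doubles$ra_j, doubles$ra_i))
  y <- c(doubles$ra_obs, doubles$ra_obs)
  fit <- e1071::svm(x = x, y = y, type = "eps-regression",
                    kernel = "radial", cost = C, gamma = gamma,
                    epsilon = epsilon, scale = FALSE)
  structure(
    list(svm = fit, C = C, gamma = gamma, doubles = doubles,
         n_skipped = nrow(d$missing)),
    class = "coda_svr"
  )
}

# Doubles of an activity table joined with their single-mutant RAs.
# Returns list(doubles = tibble(i, alt_i, j, alt_j, ra_i, ra_j, ra_obs,
# provenance), missing = rows lacking a single).
double_features <- function(table) {
  dd <- table[table$n_mut == 2, ]
  singles <- table[table$n_mut == 1, ]
  ra_single <- setNames(singles$ra, singles$subs)
  long <- subs_parse(dd$subs)
  stopifnot(nrow(long) == 2 * nrow(dd))
  tok <- paste0(long$ref, long$pos, long$alt)
  # subs strings are position-sorted, so odd rows are i (< j)
  i_rows <- seq(1, nrow(long), by = 2)
  j_rows <- i_rows + 1
  out <- tibble(
    i = long$pos[i_rows], alt_i = long$alt[i_rows],
    j = long$pos[j_rows], alt_j = long$alt[j_rows],
    ra_i = unname(ra_single[tok[i_rows]]),
    ra_j = unname(ra_single[tok[j_rows]]),
    ra_obs = dd$ra,
    provenance = dd$provenance
  )
  miss <- is.na(out$ra_i) | is.na(out$ra_j)
  list(doubles = out[!miss, ], missing = out[miss, ])
}

#' @export
print.coda_svr <- function(x, ...) {
  cat("<coda_svr> independent-mutation model: ", nrow(x$doubles),
      " doubles, C = ", x$C, ", gamma = ", x$gamma, "\n", sep = "")
  invisible(x)
}

#' Predict double-mutant activity under mutation independence
#'
#' @param model A `coda_svr` from [fit_independent_model()].
#' @param ra_i,ra_j Single-mutant relative activities (vectorized).
#' @return Predicted double-mutant RA, symmetric in `ra_i`/`ra_j`.
#' @export
predict_double <- function(model, ra_i, ra_j) {
  stopifnot(length(ra_i) == length(ra_j), all(ra_i >= 0), all(ra_j >= 0))
  p1 <- predict(model$svm, cbind(ra_i, ra_j))
  p2 <- predict(model$svm, cbind(ra_j, ra_i))
  pmax(unname((p1 + p2) / 2), 0)  # relative activity is nonnegative
}

#' Covariation-induced deviation of activity
#'
#' \deqn{CODA = \frac{RA_{obs} - RA_{pred}}{RA_{pred} + s}}
#' with shift `s` (default 0.2) guarding against small predicted
#' activities. Results are insensitive to the shift over roughly
#' \[0.1, 0.5\].
#'
#' @param ra_obs Observed double-mutant RA.
#' @param ra_pred Predicted RA from [predict_double()].
#' @param shift Denominator shift.
#' @return Numeric vector of CODA scores.
#' @export
coda_score <- function(ra_obs, ra_pred, shift = 0.2) {
  stopifnot(all(ra_pred >= 0))
  (ra_obs - ra_pred) / (ra_pred + shift)
}

#' De-mix the CODA score distribution
#'
#' The pooled CODA scores are modelled as a two-Gaussian mixture: a
#' dominant component centred near 0 (independent double mutations) and a
#' minor component at higher scores (likely base pairs). Because the
#' unpaired class dominates, the de-mixing is a one-pass empirical rule:
#' the unpaired component's mean `a1` and standard deviation `sd1` are
#' taken from all scores; the subset with score `> a1 + k_sd * sd1`
#' provides the paired component's `a2` and `sd2`, and its relative size
#' is the overall base-pair prior `p_paired`. The outcome is insensitive
#' to `k_sd` over roughly 1–7.
#'
#' @param scores Numeric vector of CODA scores (at least 100).
#' @param k_sd Outlier cutoff multiplier.
#' @return An object of class `coda_mixture` with fields `a1`, `sd1`,
#'   `a2`, `sd2`, `p_paired`, `k_sd`, `n`, `n_outliers`.
#' @export
fit_mixture <- function(scores, k_sd = 3) {
  scores <- scores[is.finite(scores)]
  if (length(scores) < 100) stop("need at least 100 CODA scores")
  a1 <- mean(scores)
  sd1 <- sd(scores)
  if (sd1 == 0) stop("degenerate CODA scores: zero variance")
  S <- scores[scores > a1 + k_sd * sd1]
  if (length(S) < 2) stop("no covariation signal detected")
  structure(
    list(a1 = a1, sd1 = sd1, a2 = mean(S), sd2 = sd(S),
         p_paired = length(S) / length(scores),
         k_sd = k_sd, n = length(scores), n_outliers = length(S)),
    class = "coda_mixture"
  )
}

#' @export
print.coda_mixture <- function(x, ...) {
  cat(sprintf(paste0(
    "<coda_mixture> unpaired N(%.3f, %.3f^2), paired N(%.3f, %.3f^2), ",
    "P(paired) = %.4f (%d / %d scores)\n"),
    x$a1, x$sd1, x$a2, x$sd2, x$p_paired, x$n_outliers, x$n))
  invisible(x)
}

#' @export
tidy.coda_mixture <- function(x, ...) {
  tibble(component = c("unpaired", "paired"),
         mean = c(x$a1, x$a2), sd = c(x$sd1, x$sd2),
         weight = c(1 - x$p_paired, x$p_paired))
}

#' @export
glance.coda_mixture <- function(x, ...) {
  tibble(a1 = x$a1, sd1 = x$sd1, a2 = x$a2, sd2 = x$sd2,
         p_paired = x$p_paired, k_sd = x$k_sd, n = x$n,
         n_outliers = x$n_outliers)
}

#' Naive-Bayes pairing score
#'
#' Log-Bayes score that a CODA value arose from the paired component:
#' \deqn{Ps = \log \frac{p(CODA \mid paired)}{p(CODA)}}
#' with `p(CODA) = p(CODA|paired) p(paired) +
#' p(CODA|unpaired) (1 - p(paired))` and Gaussian class densities from
#' the fitted mixture. Natural logarithm.
#'
#' @param coda Numeric vector of CODA scores.
#' @param mixture A `coda_mixture` from [fit_mixture()].
#' @return Numeric vector of pairing scores.
#' @export
pairing_score <- function(coda, mixture) {
  dp <- dnorm(coda, mixture$a2, mixture$sd2)
  du <- dnorm(coda, mixture$a1, mixture$sd1)
  p <- mixture$p_paired
  log(dp) - log(dp * p + du * (1 - p))
}

#' Score every double mutation and position pair
#'
#' Computes CODA and pairing scores for each double entry of an activity
#' table (direct and reduced-triple doubles alike), then aggregates to
#' position pairs: the per-position score of `(i, j)` is the maximum (or
#' mean) pairing score over the mutation combinations observed there.
#' Position pairs with no double data are absent.
#'
#' @param table A `coda_activity` table.
#' @param model A `coda_svr` from [fit_independent_model()].
#' @param mixture A `coda_mixture` from [fit_mixture()].
#' @param shift CODA denominator shift, see [coda_score()].
#' @param aggregate `"max"` (default) or `"mean"` over mutation
#'   combinations at a position pair.
#'
#' @return An object of class `coda_scores`: list with `per_mutation`
#'   (tibble `i, j, alt_i, alt_j, ra_obs, ra_pred, coda, ps, provenance`)
#'   and `per_position` (tibble `i, j, ps, n_mutants`).
#' @export
score_all <- function(table, model, mixture, shift = 0.2,
                      aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  d <- double_features(table)$doubles
  d$ra_pred <- predict_double(model, d$ra_i, d$ra_j)
  d$coda <- coda_score(d$ra_obs, d$ra_pred, shift = shift)
  d$ps <- pairing_score(d$coda, mixture)
  per_mutation <- d[, c("i", "j", "alt_i", "alt_j", "ra_obs", "ra_pred",
                        "coda", "ps", "provenance")]
  agg_fun <- if (aggregate == "max") max else mean
  per_position <- per_mutation |>
    dplyr::group_by(.data$i, .data$j) |>
    dplyr::summarise(ps = agg_fun(.data$ps), n_mutants = dplyr::n(),
                     .groups = "drop")
  structure(
    list(per_mutation = per_mutation, per_position = per_position,
         wild_type = attr(table, "wild_type"),
         shift = shift, aggregate = aggregate),
    class = "coda_scores"
  )
}

#' @export
print.coda_scores <- function(x, ...) {
  cat("<coda_scores> ", nrow(x$per_mutation), " double mutations over ",
      nrow(x$per_position), " position pairs\n", sep = "")
  invisible(x)
}

#' @export
tidy.coda_scores <- function(x, ...) x$per_position

#' Fit the full CODA model in one call
#'
#' Convenience wrapper chaining [fit_independent_model()],
#' [coda_score()], [fit_mixture()], [pairing_score()] and [score_all()].
#'
#' @inheritParams fit_independent_model
#' @inheritParams fit_mixture
#' @inheritParams score_all
#' @return An object of class `coda_fit` bundling `model`, `mixture` and
#'   `scores` (a `coda_scores`).
#' @export
coda_fit <- function(table, C = 2000, gamma = 2.0, epsilon = 0.1,
                     shift = 0.2, k_sd = 3,
                     aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  model <- fit_independent_model(table, C = C, gamma = gamma,
                                 epsilon = epsilon)
  d <- model$doubles
  cs <- coda_score(d$ra_obs, predict_double(model, d$ra_i, d$ra_j),
                   shift = shift)
  mixture <- fit_mixture(cs, k_sd = k_sd)
  scores <- score_all(table, model, mixture, shift = shift,
                      aggregate = aggregate)
  structure(list(model = model, mixture = mixture, scores = scores),
            class = "coda_fit")
}

#' @export
print.coda_fit <- function(x, ...) {
  print(x$model); print(x$mixture); print(x$scores)
  invisible(x)
}

#' @export
tidy.coda_fit <- function(x, ...) tidy(x$mixture)

#' @export
glance.coda_fit <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$mixture),
    tibble(C = x$model$C, gamma = x$model$gamma,
           n_doubles = nrow(x$model$doubles),
           n_position_pairs = nrow(x$scores$per_position))
  )
}

#' Write per-mutation and per-position score tables
#'
#' @param scores A `coda_scores` object.
#' @param path Output TSV for per-mutation scores (`i j alt_i alt_j
#'   ra_obs ra_pred coda ps`).
#' @param position_path Optional output TSV for per-position scores
#'   (`i j ps n_mutants`).
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path, position_path = NULL) {
  readr::write_tsv(scores$per_mutation, path)
  if (!is.null(position_path)) {
    readr::write_tsv(scores$per_position, position_path)
  }
  invisible(path)
}
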