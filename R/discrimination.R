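# Ideal-observer discrimination: ROC/AUC, permutation null, pooling.

#' Area under the ROC curve
#'
#' Probability that a random draw from `b` exceeds a random draw from `a`,
#' ties counted 1/2 — the Mann-Whitney rank-statistic formulation of the
#' two-alternative forced-choice ideal observer. By convention `b` is the
#' coarser (larger mean particle diameter) condition, so values above 0.5
#' mean the coarser texture evokes larger responses.
#'
#' @param a,b Nonempty numeric sample vectors.
#' @return AUC in `[0, 1]`; `auc(a, b) + auc(b, a) == 1`.
#' @examples
#' auc(c(1, 2, 3), c(2, 3, 4))   # 7/9
#' @export
auc <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    wp_abort("both sample groups must be nonempty")
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  (sum(r[(na + 1L):(na + nb)]) - nb * (nb + 1) / 2) / (na * nb)
}

#' ROC curve coordinates
#'
#' Hit and false-alarm probabilities over all threshold placements at the
#' observed sample values (criterion: response > threshold is a "b" call).
#'
#' @inheritParams auc
#' @return data.frame with columns `threshold`, `fa`, `hit`, running from
#'   (1, 1) to (0, 0).
#' @export
roc_curve <- function(a, b) {
  thr <- c(-Inf, sort(unique(c(a, b))))
  data.frame(threshold = thr,
             fa = vapply(thr, function(th) mean(a > th), numeric(1)),
             hit = vapply(thr, function(th) mean(b > th), numeric(1)))
}

# Order condition labels from fine to coarse by mean particle diameter.
order_conditions <- function(conditions, diameters = NULL) {
  conditions <- as.character(conditions)
  if (is.null(diameters)) {
    tab <- texture_grades()
    d <- tab$diameter_um[match(conditions, tab$grade)]
    if (anyNA(d)) return(sort(conditions))        # unknown labels: lexical
    diameters <- stats::setNames(d, conditions)
  }
  conditions[order(diameters[conditions])]
}

#' Mean pairwise AUC across texture conditions
#'
#' Computes the AUC for every unordered pair of conditions on one feature
#' and reports the unweighted mean. Pairs are oriented fine -> coarse by
#' mean particle diameter (the generator makes coarser textures evoke
#' larger features, so AUC >= 0.5 in expectation); set `fold = TRUE` to
#' report `max(AUC, 1 - AUC)` for data of unknown direction.
#'
#' @param value Numeric feature values, one per trial.
#' @param condition Condition label per trial (>= 2 conditions, >= 2 trials
#'   each).
#' @param diameters Optional named vector mapping condition to mean particle
#'   diameter (um); known P-grades are resolved automatically.
#' @param fold Fold AUCs about 0.5.
#' @return A `discrimination_result`: list with `pairs` (data.frame
#'   `cond_a`, `cond_b`, `auc`, `n_a`, `n_b`), `mean_auc`, `n_pairs`.
#' @export
pairwise_mean_auc <- function(value, condition, diameters = NULL,
                              fold = FALSE) {
  condition <- as.character(condition)
  conds <- order_conditions(unique(condition), diameters)
  if (length(conds) < 2L) wp_abort("need at least 2 conditions")
  cnt <- table(condition)
  if (any(cnt < 2L))
    wp_abort(sprintf("condition(s) with fewer than 2 trials: %s",
                     paste(names(cnt)[cnt < 2L], collapse = ", ")))
  prs <- utils::combn(length(conds), 2L)
  rows <- lapply(seq_len(ncol(prs)), function(j) {
    ca <- conds[prs[1L, j]]; cb <- conds[prs[2L, j]]   # ca finer than cb
    va <- value[condition == ca]; vb <- value[condition == cb]
    x <- auc(va, vb)
    if (fold) x <- max(x, 1 - x)
    data.frame(cond_a = ca, cond_b = cb, auc = x,
               n_a = length(va), n_b = length(vb), stringsAsFactors = FALSE)
  })
  pairs <- do.call(rbind, rows)
  structure(list(pairs = pairs, mean_auc = mean(pairs$auc),
                 n_pairs = nrow(pairs)),
            class = "discrimination_result")
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf("<discrimination_result: mean AUC %.3f over %d pairs>\n",
              x$mean_auc, x$n_pairs))
  invisible(x)
}

#' Permutation null distribution of the pairwise AUC
#'
#' Shuffles the trials across the different stimuli: for each shuffle the
#' condition labels are permuted over the pooled trial list and all pairwise
#' AUCs recomputed; samples are pooled over shuffles and pairs, and the
#' significance threshold is the stated percentile of the pooled null.
#'
#' @inheritParams pairwise_mean_auc
#' @param n_shuffles Number of label shuffles (>= 1), default 500.
#' @param percentile Threshold percentile of the pooled null, default 90.
#' @param seed Optional seed.
#' @return A `null_distribution`: list with `samples`, `n_shuffles`,
#'   `percentile`, `threshold`.
#' @export
permutation_null <- function(value, condition, n_shuffles = 500,
                             percentile = 90, seed = NULL, diameters = NULL) {
  if (n_shuffles < 1L) wp_abort("n_shuffles must be >= 1")
  condition <- as.character(condition)
  conds <- order_conditions(unique(condition), diameters)
  if (length(conds) < 2L) wp_abort("need at least 2 conditions")
  idx <- lapply(conds, function(cc) which(condition == cc))
  ns <- lengths(idx)
  if (any(ns < 2L)) wp_abort("every condition needs at least 2 trials")
  prs <- utils::combn(length(conds), 2L)
  n <- length(value)
  with_seed_opt(seed, {
    samples <- matrix(NA_real_, nrow = ncol(prs), ncol = n_shuffles)
    for (s in seq_len(n_shuffles)) {
      vperm <- value[sample.int(n)]
      for (j in seq_len(ncol(prs))) {
        samples[j, s] <- auc(vperm[idx[[prs[1L, j]]]],
                             vperm[idx[[prs[2L, j]]]])
      }
    }
    null_distribution(as.numeric(samples), n_shuffles, percentile)
  })
}

#' Assemble a null distribution from pooled samples
#'
#' @param samples Null AUC samples.
#' @param n_shuffles Number of shuffles that produced them.
#' @param percentile Threshold percentile.
#' @return A `null_distribution`.
#' @export
null_distribution <- function(samples, n_shuffles, percentile = 90) {
  structure(list(samples = samples, n_shuffles = n_shuffles,
                 percentile = percentile,
                 threshold = stats::quantile(samples, percentile / 100,
                                             names = FALSE)),
            class = "null_distribution")
}

#' Pool null distributions across units
#'
#' Pools the shuffled-AUC samples of several units (uniform weighting) and
#' recomputes the percentile threshold on the ensemble.
#'
#' @param nulls List of `null_distribution` objects.
#' @param percentile Threshold percentile; defaults to the first element's.
#' @return A pooled `null_distribution`.
#' @export
pool_nulls <- function(nulls, percentile = NULL) {
  if (length(nulls) == 0L) wp_abort("no null distributions to pool")
  percentile <- percentile %||% nulls[[1L]]$percentile
  null_distribution(unlist(lapply(nulls, `[[`, "samples")),
                    n_shuffles = nulls[[1L]]$n_shuffles, percentile)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution: %d samples (%d shuffles), %g%% threshold = %.4f>\n",
    length(x$samples), x$n_shuffles, x$percentile, x$threshold))
  invisible(x)
}

#' Closed-form permutation-null AUC threshold
#'
#' Normal approximation of the Mann-Whitney null: the shuffled AUC has mean
#' 1/2 and `SD = sqrt((n1 + n2 + 1) / (12 n1 n2))`; the threshold is the
#' corresponding normal percentile. Used as the analytic cross-check of
#' [permutation_null()].
#'
#' @param n1,n2 Trials per condition.
#' @param percentile Threshold percentile.
#' @return The approximate threshold.
#' @export
null_threshold_normal <- function(n1, n2, percentile = 90) {
  0.5 + stats::qnorm(percentile / 100) * sqrt((n1 + n2 + 1) / (12 * n1 * n2))
}

#' Pool trials across whiskers
#'
#' Trial-wise arithmetic mean of feature values across a whisker set,
#' condition by condition; with unequal trial counts the set is trimmed to
#' the shortest. Optionally permute trial order within each whisker first
#' (trial order within a texture is arbitrary).
#'
#' @param trials Long data.frame with columns `whisker`, `condition`,
#'   `value`.
#' @param whiskers Whisker names to pool; default all present (must be
#'   nonempty).
#' @param shuffle_pairing Seed for random within-condition trial pairing;
#'   `NULL` keeps recording order.
#' @return data.frame `condition`, `trial`, `value` of pooled trials.
#' @export
combine_whiskers <- function(trials, whiskers = NULL, shuffle_pairing = NULL) {
  whiskers <- whiskers %||% unique(trials$whisker)
  if (length(whiskers) == 0L) wp_abort("whisker set must be nonempty")
  sub <- trials[trials$whisker %in% whiskers, , drop = FALSE]
  out <- list()
  for (cc in unique(sub$condition)) {
    per <- lapply(whiskers, function(w)
      sub$value[sub$whisker == w & sub$condition == cc])
    m <- min(lengths(per))
    if (m == 0L) next
    per <- if (is.null(shuffle_pairing))
      lapply(per, function(v) v[seq_len(m)])
    else
      with_seed_opt(shuffle_pairing,
                    lapply(per, function(v) v[sample.int(length(v))[seq_len(m)]]))
    pooled <- Reduce(`+`, per) / length(per)
    out[[length(out) + 1L]] <- data.frame(condition = cc, trial = seq_len(m),
                                          value = pooled,
                                          stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Linearity-of-summation index
#'
#' Ratio between the mean pairwise AUC of the whisker-averaged trials and
#' the average of the single-whisker mean pairwise AUCs. Values above 1
#' indicate supralinear summation: pooling is better than the average
#' channel.
#'
#' @inheritParams combine_whiskers
#' @param diameters Optional condition -> diameter map for pair orientation.
#' @return List with `index`, `combined_auc`, `single_aucs` (named).
#' @export
linearity_index <- function(trials, whiskers = NULL, diameters = NULL,
                            shuffle_pairing = NULL) {
  whiskers <- whiskers %||% unique(trials$whisker)
  if (length(whiskers) < 2L) wp_abort("need at least 2 whiskers")
  pooled <- combine_whiskers(trials, whiskers, shuffle_pairing)
  num <- pairwise_mean_auc(pooled$value, pooled$condition, diameters)$mean_auc
  singles <- vapply(whiskers, function(w) {
    sub <- trials[trials$whisker == w, , drop = FALSE]
    pairwise_mean_auc(sub$value, sub$condition, diameters)$mean_auc
  }, numeric(1))
  den <- mean(singles)
  if (!is.finite(den) || den == 0) wp_abort("undefined single-whisker AUC")
  list(index = num / den, combined_auc = num,
       single_aucs = stats::setNames(singles, whiskers))
}

#' Texture-versus-edge discrimination AUC
#'
#' AUC between edge-window firing rates (T = 10 ms) and fine-grained
#' texture-window firing rates (T = 50 ms): the ideal observer telling a
#' collision from texture-evoked activity.
#'
#' @param edge_rates Edge-window rates (Hz).
#' @param texture_rates Fine-grained texture-window rates (Hz).
#' @return AUC (edge as the "signal" group `b`).
#' @export
texture_edge_auc <- function(edge_rates, texture_rates) {
  if (length(edge_rates) == 0L || length(texture_rates) == 0L)
    wp_abort("both epoch types must be present")
  auc(texture_rates, edge_rates)
}
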