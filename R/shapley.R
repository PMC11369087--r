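set_value_fn <- function(model_fn, x, background) {
  # v(S): fix features in S at x's values, average model output over the
  # background rows for the remaining features (interventional expectation)
  background <- as.matrix(background)
  x <- unlist(x)
  function(members) {
    z <- background
    if (length(members)) z[, members] <- rep(x[members], each = nrow(z))
    mean(model_fn(z))
  }
}

#' Exact Shapley-value explanation by subset enumeration
#'
#' Attributes a model prediction `f(x)` to its features with the classical
#' combinatorial weights: contribution of feature i is the average, over
#' all subsets S of the other features, of
#' `w(S) * (v(S + i) - v(S))` with `w(S) = |S|! (d - |S| - 1)! / d!`.
#' The coalition value `v(S)` fixes the features in S at `x` and averages
#' the model over an explicit background sample for the rest
#' (interventional marginalization). The base value is `v(empty) =`
#' mean background prediction, and local accuracy holds:
#' `base + sum(phi) = f(x)` up to floating point.
#'
#' Enumeration costs `2^d` coalition evaluations; use
#' [sampled_shapley()] beyond `max_features`.
#'
#' @param model_fn function mapping a numeric matrix of instances (rows)
#'   to a numeric score vector.
#' @param x named numeric vector, the instance to explain.
#' @param background matrix/data.frame of background instances with the
#'   same columns.
#' @param max_features refuse enumeration beyond this many features
#'   (default 16).
#' @param instance_id identifier stored in the explanation.
#' @return a `shapley_explanation`: list with `base_value`,
#'   `contributions` (named vector), `prediction`, `feature_values`,
#'   `instance_id`, `method`.
#' @export
exact_shapley <- function(model_fn, x, background, max_features = 16L,
                          instance_id = NA_character_) {
  x <- unlist(x)
  d <- length(x)
  if (d > max_features)
    stop(d, " features exceed max_features = ", max_features,
         "; use sampled_shapley() for high-dimensional instances",
         call. = FALSE)
  v <- set_value_fn(model_fn, x, background)
  # value of every coalition, indexed by bitmask + 1
  vals <- numeric(2^d)
  for (mask in 0:(2^d - 1))
    vals[mask + 1] <- v(which(bitwAnd(mask, bitwShiftL(1L, 0:(d - 1))) > 0))
  sizes <- vapply(0:(2^d - 1), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(d - 1))) > 0), numeric(1))
  lw <- lfactorial(0:d) + lfactorial(d - (0:d) - 1) - lfactorial(d)  # log w by |S|
  phi <- numeric(d)
  for (i in seq_len(d)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(2^d - 1), bit) == 0L)  # masks not containing i
    s <- sizes[without]
    phi[i] <- sum(exp(lw[s + 1]) * (vals[without + bit] - vals[without]))
  }
  names(phi) <- names(x)
  new_shapley_explanation(base_value = vals[1], contributions = phi,
                          prediction = vals[2^d], feature_values = x,
                          instance_id = instance_id, method = "exact")
}

new_shapley_explanation <- function(base_value, contributions, prediction,
                                    feature_values, instance_id, method) {
  structure(list(base_value = base_value, contributions = contributions,
                 prediction = prediction, feature_values = feature_values,
                 instance_id = instance_id, method = method),
            class = "shapley_explanation")
}

#' @export
print.shapley_explanation <- function(x, ...) {
  cat("<shapley_explanation>", x$method, "- base", signif(x$base_value, 4),
      "-> prediction", signif(x$prediction, 4), "\n")
  top <- sort(abs(x$contributions), decreasing = TRUE)
  print(round(x$contributions[names(top)[seq_len(min(8, length(top)))]], 4))
  invisible(x)
}

#' Permutation-sampling Shapley estimate
#'
#' Monte-Carlo estimator for high-dimensional instances: for each sampled
#' feature ordering, features are added one by one and each feature is
#' credited its marginal change in the coalition value. The average over
#' orderings estimates the exact Shapley value. The small Monte-Carlo
#' residual `f(x) - base - sum(phi)` is spread uniformly across features so
#' local accuracy holds exactly (residual magnitude kept in attribute
#' `residual`).
#'
#' @inheritParams exact_shapley
#' @param n_permutations sampled orderings.
#' @param seed RNG seed.
#' @return a `shapley_explanation` (method `"sampled"`).
#' @export
sampled_shapley <- function(model_fn, x, background, n_permutations = 100L,
                            seed = 1L, instance_id = NA_character_) {
  stopifnot(n_permutations >= 1L)
  x <- unlist(x)
  d <- length(x)
  v <- set_value_fn(model_fn, x, background)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)
  base <- v(integer(0))
  pred <- v(seq_len(d))
  phi <- numeric(d)
  for (p in seq_len(n_permutations)) {
    ord <- sample.int(d)
    prev <- base
    for (pos in seq_len(d)) {
      cur <- if (pos == d) pred else v(ord[seq_len(pos)])
      phi[ord[pos]] <- phi[ord[pos]] + (cur - prev)
      prev <- cur
    }
  }
  phi <- phi / n_permutations
  residual <- pred - base - sum(phi)
  phi <- phi + residual / d
  names(phi) <- names(x)
  out <- new_shapley_explanation(base_value = base, contributions = phi,
                                 prediction = pred, feature_values = x,
                                 instance_id = instance_id, method = "sampled")
  attr(out, "residual") <- residual
  out
}

#' Explain a set of instances
#'
#' Convenience wrapper: explains each row of `x` with [exact_shapley()]
#' when the feature count permits, [sampled_shapley()] otherwise. The
#' background is capped at `background_cap` rows by seeded subsampling.
#'
#' @param model_fn scoring function over instance matrices.
#' @param x matrix/data.frame of instances to explain.
#' @param background background sample (typically the training split).
#' @param exact_limit dimension threshold for exact enumeration.
#' @param n_permutations orderings for the sampler.
#' @param background_cap maximum background rows retained.
#' @param seed RNG seed.
#' @return list of `shapley_explanation`s.
#' @export
explain_instances <- function(model_fn, x, background, exact_limit = 12L,
                              n_permutations = 50L, background_cap = 100L,
                              seed = 1L) {
  x <- as.matrix(x)
  background <- as.matrix(background)
  if (nrow(background) > background_cap) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    set.seed(seed)
    background <- background[sample.int(nrow(background), background_cap), , drop = FALSE]
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)
  }
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  lapply(seq_len(nrow(x)), function(i) {
    xi <- x[i, ]
    if (ncol(x) <= exact_limit)
      exact_shapley(model_fn, xi, background, instance_id = ids[i])
    else
      sampled_shapley(model_fn, xi, background, n_permutations = n_permutations,
                      seed = seed + i, instance_id = ids[i])
  })
}

#' Global feature importance from local explanations
#'
#' Mean absolute contribution per feature over a set of explanations.
#'
#' @param explanations list of `shapley_explanation`s sharing a feature
#'   set.
#' @return named numeric vector, sorted decreasing.
#' @export
global_importance <- function(explanations) {
  if (!length(explanations)) stop("no explanations supplied", call. = FALSE)
  phi <- do.call(rbind, lapply(explanations, `[[`, "contributions"))
  sort(colMeans(abs(phi)), decreasing = TRUE)
}

#' Export explanations as waterfall and scatter tables
#'
#' The waterfall table lists, per instance, features sorted by decreasing
#' `|phi|` with the cumulative sum running from the base value to the
#' prediction. The scatter table pairs each feature's value with its
#' contribution across instances, for trend inspection.
#'
#' @param explanations list of `shapley_explanation`s.
#' @return list with data.frames `waterfall` and `scatter`.
#' @export
export_explanations <- function(explanations) {
  if (!length(explanations))
    return(list(waterfall = data.frame(), scatter = data.frame()))
  wf <- do.call(rbind, lapply(explanations, function(e) {
    ord <- order(abs(e$contributions), decreasing = TRUE)
    data.frame(instance_id = e$instance_id,
               feature = names(e$contributions)[ord],
               feature_value = unname(e$feature_values[ord]),
               phi = unname(e$contributions[ord]),
               cumulative = e$base_value + cumsum(unname(e$contributions[ord])),
               base_value = e$base_value,
               prediction = e$prediction,
               stringsAsFactors = FALSE)
  }))
  sc <- do.call(rbind, lapply(explanations, function(e)
    data.frame(instance_id = e$instance_id,
               feature = names(e$contributions),
               feature_value = unname(e$feature_values),
               phi = unname(e$contributions),
               stringsAsFactors = FALSE)))
  rownames(wf) <- rownames(sc) <- NULL
  list(waterfall = wf, scatter = sc)
}
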