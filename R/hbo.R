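# Wrapper feature selection: honey badger algorithm with stochastic
# variance-reduced gradient Langevin dynamics (SVGL) exploration.
#
# Agents are continuous positions in [bLow, bHigh]^d; a feature is
# selected when its coordinate exceeds 0.5.  The fitness of a mask is
# the cross-validated accuracy of a cheap deterministic probe
# (z-scored nearest centroid).  Exploration follows Langevin dynamics
# with an SPSA surrogate gradient of the probe's smooth loss on
# position-weighted features, variance-reduced against a periodically
# refreshed snapshot; exploitation is the greedy honey phase moving
# toward/away from the best position (prey) under a time-adaptive
# density factor.

#' Configuration of the feature-selection optimizer
#'
#' @param nPop population size (default 30).
#' @param iterations optimizer iterations (default 100).
#' @param bLow,bHigh per-dimension position bounds (defaults 0 and 1).
#' @param stepSize Langevin step size, decayed by `1/sqrt(iteration)`
#'   (default 0.05).
#' @param theta density-factor constant (default 2).
#' @param exploreProb per-agent probability of an exploration move
#'   (default 0.5).
#' @param snapshotEvery iterations between variance-reduction snapshot
#'   refreshes (default 10).
#' @param noise include the Langevin Gaussian noise term (default TRUE;
#'   diagnostics switch it off).
#' @param sizePenalty optional fitness penalty per selected-feature
#'   fraction (default 0 — fitness is accuracy exactly).
#' @param folds cross-validation folds of the probe (default 3).
#' @param seed RNG seed; determines the whole run.
#' @return a list of class `"HBOConfig"`.
#' @export
hboConfig <- function(nPop = 30L, iterations = 100L, bLow = 0, bHigh = 1,
                      stepSize = 0.05, theta = 2, exploreProb = 0.5,
                      snapshotEvery = 10L, noise = TRUE, sizePenalty = 0,
                      folds = 3L, seed = 1L) {
  if (nPop < 2L) stop("population must have at least 2 agents")
  if (any(bLow >= bHigh)) stop("bLow must be < bHigh elementwise")
  structure(list(nPop = as.integer(nPop), iterations = as.integer(iterations),
                 bLow = bLow, bHigh = bHigh, stepSize = stepSize,
                 theta = theta, exploreProb = exploreProb,
                 snapshotEvery = as.integer(snapshotEvery), noise = noise,
                 sizePenalty = sizePenalty, folds = as.integer(folds),
                 seed = as.integer(seed)),
            class = "HBOConfig")
}

# Deterministic fold assignment.
.cvFolds <- function(n, folds, seed = 1L) {
  withSeed(seed, sample(rep_len(seq_len(folds), n)))
}

# Nearest-centroid probe accuracy on (possibly masked/weighted) features.
.probeAccuracy <- function(X, y, folds = 3L, seed = 1L) {
  n <- nrow(X)
  fold <- .cvFolds(n, folds, seed)
  correct <- 0L
  classes <- sort(unique(y))
  for (f in seq_len(folds)) {
    tr <- fold != f
    mu <- colMeans(X[tr, , drop = FALSE])
    sg <- apply(X[tr, , drop = FALSE], 2, sd)
    sg[sg < 1e-12] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    Zte <- sweep(sweep(X[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    cent <- matrix(vapply(classes, function(cl)
      colMeans(Ztr[y[tr] == cl, , drop = FALSE]), numeric(ncol(X))),
      nrow = ncol(X))
    d2 <- matrix(vapply(seq_along(classes), function(k)
      rowSums(sweep(Zte, 2, cent[, k])^2), numeric(nrow(Zte))),
      nrow = nrow(Zte))
    pred <- classes[max.col(-d2, ties.method = "first")]
    correct <- correct + sum(pred == y[!tr])
  }
  correct / n
}

# Smooth probe loss on position-weighted features (for SPSA gradients):
# softmax over negative squared centroid distances, cross-entropy.
.probeLoss <- function(q, X, y, folds = 3L, seed = 1L) {
  Xq <- sweep(X, 2, q, "*")
  n <- nrow(Xq)
  fold <- .cvFolds(n, folds, seed)
  classes <- sort(unique(y))
  loss <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f
    cent <- matrix(vapply(classes, function(cl)
      colMeans(Xq[tr & y == cl, , drop = FALSE]), numeric(ncol(Xq))),
      nrow = ncol(Xq))
    Zte <- Xq[!tr, , drop = FALSE]
    d2 <- matrix(vapply(seq_along(classes), function(k)
      rowSums(sweep(Zte, 2, cent[, k])^2), numeric(nrow(Zte))),
      nrow = nrow(Zte))
    z <- -d2 / 2
    z <- z - apply(z, 1, max)
    p <- exp(z) / rowSums(exp(z))
    ti <- match(y[!tr], classes)
    loss <- loss + sum(-log(pmax(p[cbind(seq_len(nrow(p)), ti)], 1e-300)))
  }
  loss / n
}

#' Wrapper fitness of a feature mask
#'
#' Mean `folds`-fold cross-validated accuracy of the probe classifier on
#' the masked features, minus the optional size penalty.  An empty mask
#' scores 0 and never raises.
#'
#' @param mask logical vector over features.
#' @param features samples x features matrix.
#' @param labels class vector.
#' @param config an [hboConfig()] (folds, seed, sizePenalty).
#' @return fitness in `[0, 1]`.
#' @export
hboFitness <- function(mask, features, labels, config = hboConfig()) {
  mask <- as.logical(mask)
  if (!any(mask)) return(0)
  acc <- .probeAccuracy(features[, mask, drop = FALSE], labels,
                        config$folds, config$seed)
  acc - config$sizePenalty * sum(mask) / length(mask)
}

.positionMask <- function(q) q > 0.5

# Honey-phase direction flag and time-adaptive density factor.
.hboMu <- function(x2) if (x2 <= 0.5) 1 else -1
.hboDensity <- function(theta, iter, total) theta * iter / total

# SPSA two-point gradient estimate of fn at q with perturbation delta.
.spsa <- function(fn, q, delta, c = 0.05) {
  (fn(q + c * delta) - fn(q - c * delta)) / (2 * c) * delta
}

#' Initialize the optimizer state
#'
#' Positions are drawn uniformly inside the bounds (per-dimension draws),
#' fitness evaluated, the best agent becomes the prey, and the variance-
#' reduction snapshot is taken.
#'
#' @param features samples x features matrix (ignored when `fitnessFn`
#'   is supplied).
#' @param labels class vector.
#' @param config an [hboConfig()].
#' @param fitnessFn optional `function(position) -> fitness` overriding
#'   the probe-based default (diagnostics/toy objectives).
#' @param gradFn optional `function(position, state) -> gradient`
#'   overriding the SPSA/variance-reduced default.
#' @return a list of class `"HBOState"`.
#' @export
hboInit <- function(features, labels, config = hboConfig(),
                    fitnessFn = NULL, gradFn = NULL) {
  d <- if (!is.null(features)) ncol(features) else
    stop("features required (or supply fitnessFn with a positions matrix)")
  if (d < 1L) stop("need at least one feature dimension")
  if (is.null(fitnessFn))
    fitnessFn <- function(q) hboFitness(.positionMask(q), features, labels,
                                        config)
  lossFn <- if (!is.null(features) && is.null(gradFn))
    function(q) .probeLoss(q, features, labels, config$folds, config$seed)
  state <- withSeed(config$seed, {
    pos <- matrix(config$bLow + runif(config$nPop * d) *
                    (config$bHigh - config$bLow), config$nPop, d)
    fit <- apply(pos, 1, fitnessFn)
    bi <- which.max(fit)
    list(positions = pos, fitness = fit,
         best = pos[bi, ], bestFitness = fit[bi],
         iter = 0L, total = config$iterations,
         trace = data.frame(iteration = integer(0), bestFitness = numeric(0),
                            meanFitness = numeric(0)),
         snapshot = pos, snapshotGrad = matrix(0, config$nPop, d),
         fitnessFn = fitnessFn, lossFn = lossFn, gradFn = gradFn,
         rngState = get(".Random.seed", envir = globalenv()))
  })
  class(state) <- "HBOState"
  if (!is.null(state$lossFn))
    state <- .withStateRNG(state, .hboRefreshSnapshot(state))
  state
}

# Refresh snapshots and their cached (averaged-SPSA) full gradients.
# Draws from the active RNG stream; callers manage the state's stream.
.hboRefreshSnapshot <- function(state) {
  d <- ncol(state$positions)
  state$snapshot <- state$positions
  for (i in seq_len(nrow(state$positions))) {
    g <- numeric(d)
    for (r in 1:3) {
      delta <- sample(c(-1, 1), d, replace = TRUE)
      g <- g + .spsa(state$lossFn, state$snapshot[i, ], delta)
    }
    state$snapshotGrad[i, ] <- g / 3
  }
  state
}

# Run expr under the state's stored RNG stream, then store it back.
.withStateRNG <- function(state, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  assign(".Random.seed", state$rngState, envir = globalenv())
  res <- expr
  res$rngState <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv())
  res
}

#' One exploration (Langevin) iteration
#'
#' Per-agent update `q - w * g + sqrt(2 w) * h` where `g` is the
#' variance-reduced surrogate gradient (shared-perturbation SPSA at the
#' position and its snapshot plus the cached snapshot gradient), `h` a
#' standard-normal draw, and `w` the decayed step size.  Positions are
#' clipped to the bounds; fitness and the prey are updated.
#'
#' @param state an [hboInit()] state.
#' @param config the matching [hboConfig()].
#' @return the updated state.
#' @export
explorationStep <- function(state, config) {
  stopifnot(inherits(state, "HBOState"))
  state$iter <- state$iter + 1L
  d <- ncol(state$positions)
  w <- config$stepSize / sqrt(state$iter)
  state <- .withStateRNG(state, {
    if (!is.null(state$lossFn) &&
        state$iter %% config$snapshotEvery == 0L) {
      state <- .hboRefreshSnapshot(state)
    }
    for (i in seq_len(nrow(state$positions))) {
      q <- state$positions[i, ]
      g <- if (!is.null(state$gradFn)) {
        state$gradFn(q, state)
      } else {
        delta <- sample(c(-1, 1), d, replace = TRUE)
        .spsa(state$lossFn, q, delta) -
          .spsa(state$lossFn, state$snapshot[i, ], delta) +
          state$snapshotGrad[i, ]
      }
      h <- if (config$noise) rnorm(d) else numeric(d)
      qn <- q - w * g + sqrt(2 * w) * h
      qn <- pmin(pmax(qn, config$bLow), config$bHigh)
      state$positions[i, ] <- qn
      state$fitness[i] <- state$fitnessFn(qn)
      if (state$fitness[i] > state$bestFitness) {
        state$bestFitness <- state$fitness[i]
        state$best <- qn
      }
    }
    state
  })
  state
}

#' One exploitation (honey-phase) iteration
#'
#' Each agent proposes `prey + mu * x2 * density * distance`, with
#' `mu = +1` when the uniform draw `x2 <= 0.5` and `-1` otherwise,
#' density factor `theta * iter/total`, and elementwise distance
#' `|prey - position|`.  The move is accepted only if it improves the
#' agent's fitness (greedy acceptance), after clipping to the bounds.
#'
#' @inheritParams explorationStep
#' @return the updated state.
#' @export
exploitationStep <- function(state, config) {
  stopifnot(inherits(state, "HBOState"))
  state$iter <- state$iter + 1L
  dens <- .hboDensity(config$theta, state$iter, state$total)
  state <- .withStateRNG(state, {
    for (i in seq_len(nrow(state$positions))) {
      q <- state$positions[i, ]
      x2 <- runif(1)
      mu <- .hboMu(x2)
      phi <- abs(state$best - q)
      qn <- state$best + mu * x2 * dens * phi
      qn <- pmin(pmax(qn, config$bLow), config$bHigh)
      fn <- state$fitnessFn(qn)
      if (fn > state$fitness[i]) {
        state$positions[i, ] <- qn
        state$fitness[i] <- fn
        if (fn > state$bestFitness) {
          state$bestFitness <- fn
          state$best <- qn
        }
      }
    }
    state
  })
  state
}

#' Run the full feature-selection search
#'
#' Alternates exploration and exploitation (per-iteration seeded coin
#' flip with probability `exploreProb`) for the configured number of
#' iterations and returns the selected feature indices (best position
#' coordinates above 0.5; at least one feature is always returned).
#'
#' @param features samples x features numeric matrix.
#' @param labels class vector.
#' @param config an [hboConfig()].
#' @return list with `selected` (integer indices), `best` (position),
#'   `bestFitness`, `trace` (iteration, bestFitness, meanFitness) and
#'   the final `state`.
#' @export
hboSelect <- function(features, labels, config = hboConfig()) {
  if (is.null(features) || ncol(features) < 1L)
    stop("need at least one feature")
  state <- hboInit(features, labels, config)
  phase <- withSeed(config$seed + 7L,
                    runif(config$iterations) < config$exploreProb)
  for (it in seq_len(config$iterations)) {
    state <- if (phase[it]) explorationStep(state, config)
             else exploitationStep(state, config)
    state$trace <- rbind(state$trace,
                         data.frame(iteration = it,
                                    bestFitness = state$bestFitness,
                                    meanFitness = mean(state$fitness)))
  }
  sel <- which(.positionMask(state$best))
  if (!length(sel)) sel <- which.max(state$best)
  list(selected = sel, best = state$best, bestFitness = state$bestFitness,
       trace = state$trace, state = state)
}

#' Exhaustive-search reference over all feature masks
#'
#' Evaluates [hboFitness()] for every non-empty mask (feasible for
#' d <= ~15); the independent optimum the optimizer is compared against.
#'
#' @inheritParams hboSelect
#' @return list with `bestFitness` and `bestMask`.
#' @export
hboExhaustive <- function(features, labels, config = hboConfig()) {
  d <- ncol(features)
  if (d > 20L) stop("exhaustive search limited to d <= 20")
  bestF <- -Inf
  bestM <- NULL
  for (m in seq_len(2^d - 1L)) {
    mask <- as.logical(bitwAnd(m, 2^(seq_len(d) - 1L)))
    f <- hboFitness(mask, features, labels, config)
    if (f > bestF) {
      bestF <- f
      bestM <- mask
    }
  }
  list(bestFitness = bestF, bestMask = bestM)
}
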