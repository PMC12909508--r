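# Bell-elliptic fuzzy logic system (BE-FLS): seizure activity index.
#
# Three crisp inputs — relative alpha power, relative delta power,
# normalized spectral entropy — are fuzzified through generalized-bell
# memberships (one Low/Medium/High triple per variable), combined by a
# Mamdani min-conjunction rule base, and defuzzified by the weighted
# average of the consequent crisp values.  The resulting index is a
# signal-derived relative tier, explicitly not a clinical severity score.

.FUZZY_VARS <- c("alpha", "delta", "entropy")
.FUZZY_LEVELS <- c("Low", "Medium", "High")

#' Generalized bell membership degree
#'
#' \deqn{1 / (1 + (|v - \lambda| / \beta)^{2\gamma})}
#' Equals 1 at the center, 0.5 at distance `beta` for any `gamma`, and
#' decays monotonically to 0 in the tails.
#'
#' @param v crisp value (vectorized).
#' @param lambda bell center.
#' @param beta bell width (> 0).
#' @param gamma bell slope (> 0).
#' @return membership degree(s) in `(0, 1]`.
#' @export
bellMembership <- function(v, lambda, beta, gamma) {
  if (beta <= 0 || gamma <= 0) stop("beta and gamma must be positive")
  1 / (1 + (abs(v - lambda) / beta)^(2 * gamma))
}

#' The canonical four-rule seizure-activity rule base
#'
#' Antecedents over (alpha, delta, entropy) levels and the consequent
#' stage: (L,L,L) -> Low, (M,M,M) -> Medium, (L,H,H) -> Low,
#' (M,M,L) -> High.  Membership centers default to an equispaced grid on
#' `[0, 1]` (0.2 / 0.5 / 0.8 per variable, width half the center gap,
#' slope 2) and are normally refitted to training data with
#' [fitMemberships()].
#'
#' @param consequents named crisp stage values (default 0.25/0.50/0.75).
#' @param gamma bell slope (default 2).
#' @return a [FuzzyRuleBase-class].
#' @export
defaultRuleBase <- function(consequents = c(Low = 0.25, Medium = 0.50,
                                            High = 0.75),
                            gamma = 2) {
  rules <- data.frame(
    alpha   = c("Low", "Medium", "Low", "Medium"),
    delta   = c("Low", "Medium", "High", "Medium"),
    entropy = c("Low", "Medium", "High", "Low"),
    stage   = c("Low", "Medium", "Low", "High"),
    stringsAsFactors = FALSE)
  centers <- c(Low = 0.2, Medium = 0.5, High = 0.8)
  widths <- c(Low = 0.15, Medium = 0.15, High = 0.15)
  memb <- lapply(.FUZZY_VARS, function(v)
    list(center = centers, width = widths, gamma = gamma))
  names(memb) <- .FUZZY_VARS
  new("FuzzyRuleBase", rules = rules, memberships = memb,
      consequents = consequents[.FUZZY_LEVELS])
}

#' Fit membership parameters from training features
#'
#' Level centers are set to the tertile midpoints of each variable's
#' training distribution (midpoints of the [0, q33], [q33, q66],
#' [q66, max] bands), widths to half the inter-tertile distance, slope to
#' `gamma`.  Degenerate (constant) variables fall back to the default
#' grid.
#'
#' @param featureMatrix samples x 3 matrix with columns alpha, delta,
#'   entropy (as from [segmentFuzzyFeatures()]).
#' @param ruleBase rule base to refit (default [defaultRuleBase()]).
#' @param gamma bell slope (default 2).
#' @return the refitted [FuzzyRuleBase-class].
#' @export
fitMemberships <- function(featureMatrix, ruleBase = defaultRuleBase(),
                           gamma = 2) {
  stopifnot(ncol(featureMatrix) == 3L)
  colnames(featureMatrix) <- .FUZZY_VARS
  memb <- ruleBase@memberships
  for (v in .FUZZY_VARS) {
    x <- featureMatrix[, v]
    qs <- quantile(x, c(0, 1 / 3, 2 / 3, 1), names = FALSE)
    if (diff(range(qs)) < 1e-12) next
    centers <- c(Low = mean(qs[1:2]), Medium = mean(qs[2:3]),
                 High = mean(qs[3:4]))
    gap <- unname(diff(centers))
    widths <- c(Low = gap[1] / 2, Medium = mean(gap) / 2, High = gap[2] / 2)
    widths <- pmax(widths, 1e-6)
    memb[[v]] <- list(center = centers, width = widths, gamma = gamma)
  }
  initialize(ruleBase, memberships = memb)
}

#' Fuzzify crisp inputs
#'
#' Evaluates the generalized-bell membership of each input variable at
#' each linguistic level.
#'
#' @param inputs named numeric vector `c(alpha, delta, entropy)`.
#' @param ruleBase a [FuzzyRuleBase-class].
#' @return 3 x 3 matrix of degrees (rows = variables, cols = levels).
#' @export
fuzzify <- function(inputs, ruleBase) {
  stopifnot(is(ruleBase, "FuzzyRuleBase"))
  if (is.null(names(inputs))) names(inputs) <- .FUZZY_VARS
  deg <- matrix(0, 3, 3, dimnames = list(.FUZZY_VARS, .FUZZY_LEVELS))
  for (v in .FUZZY_VARS) {
    m <- ruleBase@memberships[[v]]
    for (lv in .FUZZY_LEVELS)
      deg[v, lv] <- bellMembership(inputs[[v]], m$center[[lv]],
                                   m$width[[lv]], m$gamma)
  }
  deg
}

#' Infer the seizure activity index
#'
#' Mamdani inference: each rule fires with strength `min` over its
#' antecedent degrees; the defuzzified output is the firing-strength-
#' weighted average of the consequent crisp values,
#' \deqn{DF = \sum_r R_r c_r / \sum_r R_r,} and the stage is the nearest
#' consequent.  When every strength is (numerically) zero the rule with
#' maximum strength decides (fallback), unless `fallback = FALSE`, in
#' which case an error is raised.
#'
#' @param degrees 3 x 3 degree matrix from [fuzzify()], or a named crisp
#'   input vector (fuzzified on the fly).
#' @param ruleBase a [FuzzyRuleBase-class].
#' @param fallback use the maximum-strength rule when no rule fires
#'   (default TRUE).
#' @return list with `DF` (defuzzified value), `stage` (Low/Medium/High)
#'   and `strengths` (per-rule firing strength).
#' @export
inferIndex <- function(degrees, ruleBase, fallback = TRUE) {
  stopifnot(is(ruleBase, "FuzzyRuleBase"))
  if (is.null(dim(degrees))) degrees <- fuzzify(degrees, ruleBase)
  rules <- ruleBase@rules
  strengths <- vapply(seq_len(nrow(rules)), function(r)
    min(degrees["alpha", rules$alpha[r]],
        degrees["delta", rules$delta[r]],
        degrees["entropy", rules$entropy[r]]), numeric(1))
  cons <- ruleBase@consequents[rules$stage]
  tot <- sum(strengths)
  if (tot < 1e-12) {
    if (!fallback) stop("no rule fires for the given inputs")
    DF <- unname(cons[which.max(strengths)])
  } else {
    DF <- unname(sum(strengths * cons) / tot)
  }
  stage <- .FUZZY_LEVELS[which.min(abs(ruleBase@consequents - DF))]
  list(DF = DF, stage = stage, strengths = strengths)
}

#' Seizure activity index for every segment
#'
#' Convenience wrapper: computes [segmentFuzzyFeatures()] per segment
#' and runs [inferIndex()].
#'
#' @param segmentSet a [SegmentSet-class].
#' @param ruleBase a fitted [FuzzyRuleBase-class].
#' @return data.frame with columns `DF` and `stage`.
#' @export
segmentActivityIndex <- function(segmentSet, ruleBase) {
  fs <- segmentSet@samplingRate
  res <- lapply(segments(segmentSet), function(seg) {
    r <- inferIndex(segmentFuzzyFeatures(seg, fs), ruleBase)
    data.frame(DF = r$DF, stage = r$stage, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Load a rule base from a YAML file
#'
#' The file mirrors the [FuzzyRuleBase-class] structure: a `rules` list
#' of `{alpha, delta, entropy, stage}` entries, per-variable
#' `memberships` (`center`/`width` maps and `gamma`), and `consequents`.
#'
#' @param path YAML file path.
#' @return a [FuzzyRuleBase-class].
#' @export
ruleBaseFromYAML <- function(path) {
  y <- yaml::read_yaml(path)
  rules <- do.call(rbind, lapply(y$rules, function(r)
    data.frame(alpha = r$alpha, delta = r$delta, entropy = r$entropy,
               stage = r$stage, stringsAsFactors = FALSE)))
  memb <- lapply(y$memberships, function(m)
    list(center = unlist(m$center)[.FUZZY_LEVELS],
         width = unlist(m$width)[.FUZZY_LEVELS],
         gamma = m$gamma))
  new("FuzzyRuleBase", rules = rules, memberships = memb[.FUZZY_VARS],
      consequents = unlist(y$consequents)[.FUZZY_LEVELS])
}
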