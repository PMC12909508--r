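#' EEGRecording: multichannel EEG with annotations
#'
#' Container for a channels x samples signal matrix (microvolts) with its
#' sampling rate, 10-20-system channel names and interval annotations.
#' Annotations are a `data.frame` with columns `onset`, `offset` (seconds),
#' `label`, and optionally `lobe` and `level` for seizure events.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot samplingRate sampling rate in Hz (> 0).
#' @slot channelNames character vector, one name per channel.
#' @slot annotations data.frame of labeled intervals.
#'
#' @exportClass EEGRecording
setClass("EEGRecording",
  representation(data = "matrix", samplingRate = "numeric",
                 channelNames = "character", annotations = "data.frame"),
  prototype(annotations = data.frame(onset = numeric(0), offset = numeric(0),
                                     label = character(0),
                                     stringsAsFactors = FALSE)))

setValidity("EEGRecording", function(object) {
  msg <- character(0)
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (nrow(object@data) != length(object@channelNames))
    msg <- c(msg, "one channel name per data row required")
  if (nrow(object@annotations)) {
    dur <- ncol(object@data) / object@samplingRate
    a <- object@annotations
    if (!all(c("onset", "offset") %in% names(a)))
      msg <- c(msg, "annotations need onset and offset columns")
    else if (any(a$onset < 0) || any(a$offset > dur + 1e-9) ||
             any(a$onset >= a$offset))
      msg <- c(msg, "annotation intervals must satisfy 0 <= onset < offset <= duration")
  }
  if (length(msg)) msg else TRUE
})

#' SegmentSet: windowed EEG segments with labels
#'
#' Result of sliding-window segmentation.  Each segment is a channels x
#' window-samples matrix.  `labels` holds the per-segment class
#' (`"seizure"`, `"non-seizure"`, `"excluded"`, or `"unlabeled"`), `lobes`
#' the seizure lobe (or `NA`), `starts` the start sample (0-based).
#'
#' @slot segments list of channels x window matrices.
#' @slot windowSec window length in seconds.
#' @slot overlap overlap fraction in `[0, 1)`.
#' @slot samplingRate sampling rate in Hz.
#' @slot labels character vector, one per segment.
#' @slot lobes character vector, one per segment (NA when not a seizure).
#' @slot starts integer vector of 0-based start samples.
#' @slot subject subject identifier of the source recording.
#' @slot channelNames channel names carried from the recording.
#'
#' @exportClass SegmentSet
setClass("SegmentSet",
  representation(segments = "list", windowSec = "numeric", overlap = "numeric",
                 samplingRate = "numeric", labels = "character",
                 lobes = "character", starts = "integer", subject = "character",
                 channelNames = "character"))

setValidity("SegmentSet", function(object) {
  n <- length(object@segments)
  if (length(object@labels) != n || length(object@lobes) != n ||
      length(object@starts) != n)
    return("labels, lobes and starts must have one entry per segment")
  ok <- object@labels %in% c("seizure", "non-seizure", "excluded", "unlabeled")
  if (!all(ok)) return("invalid segment label")
  TRUE
})

#' FuzzyRuleBase: generalized-bell Mamdani rule base
#'
#' Holds the linguistic rules mapping (alpha power, delta power, spectral
#' entropy) levels to a seizure-activity stage, the generalized-bell
#' membership parameters per variable and level, and the consequent crisp
#' values used for weighted-average defuzzification.
#'
#' @slot rules data.frame with columns `alpha`, `delta`, `entropy`, `stage`
#'   (levels `"Low"`, `"Medium"`, `"High"`).
#' @slot memberships named list (alpha, delta, entropy), each a list with
#'   numeric vectors `center`, `width` (names Low/Medium/High) and scalar
#'   `gamma`.
#' @slot consequents named numeric vector of crisp stage values,
#'   strictly increasing Low < Medium < High.
#'
#' @exportClass FuzzyRuleBase
setClass("FuzzyRuleBase",
  representation(rules = "data.frame", memberships = "list",
                 consequents = "numeric"))

setValidity("FuzzyRuleBase", function(object) {
  msg <- character(0)
  if (!all(c("alpha", "delta", "entropy", "stage") %in% names(object@rules)))
    msg <- c(msg, "rules need alpha, delta, entropy, stage columns")
  lv <- c("Low", "Medium", "High")
  if (!all(unlist(object@rules[c("alpha", "delta", "entropy", "stage")]) %in% lv))
    msg <- c(msg, "rule levels must be Low/Medium/High")
  cq <- object@consequents
  if (length(cq) != 3L || is.null(names(cq)) || !all(lv %in% names(cq)))
    msg <- c(msg, "consequents must be named Low/Medium/High")
  else if (!(cq["Low"] < cq["Medium"] && cq["Medium"] < cq["High"]))
    msg <- c(msg, "consequents must be strictly ordered Low < Medium < High")
  for (v in c("alpha", "delta", "entropy")) {
    m <- object@memberships[[v]]
    if (is.null(m) || !all(lv %in% names(m$center)) || !all(lv %in% names(m$width)))
      msg <- c(msg, sprintf("missing membership parameters for %s", v))
    else if (any(m$width <= 0) || m$gamma <= 0)
      msg <- c(msg, sprintf("width and gamma must be positive for %s", v))
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
  cat("  channels:", paste(head(object@channelNames, 8), collapse = ", "),
      if (length(object@channelNames) > 8) "..." else "", "\n")
  cat(sprintf("  annotations: %d\n", nrow(object@annotations)))
})

setMethod("show", "SegmentSet", function(object) {
  tab <- table(factor(object@labels,
                      levels = c("seizure", "non-seizure", "excluded", "unlabeled")))
  cat(sprintf("SegmentSet: %d segments of %g s (overlap %g%%) @ %g Hz\n",
              length(object@segments), object@windowSec, 100 * object@overlap,
              object@samplingRate))
  cat(sprintf("  seizure %d | non-seizure %d | excluded %d | unlabeled %d\n",
              tab[1], tab[2], tab[3], tab[4]))
})

setMethod("show", "FuzzyRuleBase", function(object) {
  cat("FuzzyRuleBase (generalized bell, gamma =",
      object@memberships$alpha$gamma, ")\n")
  cat("  consequents:",
      paste(sprintf("%s=%.2f", names(object@consequents), object@consequents),
            collapse = " "), "\n")
  r <- object@rules
  for (i in seq_len(nrow(r)))
    cat(sprintf("  R%d: alpha %-6s & delta %-6s & entropy %-6s -> %s\n",
                i, r$alpha[i], r$delta[i], r$entropy[i], r$stage[i]))
})
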