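.maskMatrix <- function(m) {
  if (is(m, "BinaryMask")) return(m@values)
  if (is.matrix(m) && all(m %in% c(0, 1))) return(m)
  stop("expected a BinaryMask or 0/1 matrix")
}

#' Confusion counts of a predicted mask against a ground truth
#'
#' Standard pixel counts between ground truth `sg` and prediction `st`:
#' TP = foreground in both, FP = predicted-only, FN = ground-truth-only,
#' TN = background in both.
#'
#' @param sg ground-truth [BinaryMask-class] (or 0/1 matrix).
#' @param st predicted mask, same shape.
#' @return A [ConfusionCounts-class].
#' @export
confusionCounts <- function(sg, st) {
  g <- .maskMatrix(sg); t <- .maskMatrix(st)
  if (!identical(dim(g), dim(t))) stop("mask shapes differ")
  new("ConfusionCounts",
      tp = sum(g == 1L & t == 1L), fp = sum(g == 0L & t == 1L),
      fn = sum(g == 1L & t == 0L), tn = sum(g == 0L & t == 0L))
}

.asCounts <- function(counts) {
  if (is(counts, "ConfusionCounts")) return(counts)
  if (is.numeric(counts) && all(c("tp", "fp", "fn") %in% names(counts)))
    return(new("ConfusionCounts", tp = counts[["tp"]], fp = counts[["fp"]],
               fn = counts[["fn"]],
               tn = if ("tn" %in% names(counts)) counts[["tn"]] else 0))
  stop("expected ConfusionCounts or a named vector with tp/fp/fn")
}

#' Volumetric Dice similarity coefficient
#'
#' Overlap metric \eqn{2|S_g^1 \cap S_t^1| / (|S_g^1| + |S_t^1|)
#' = 2TP/(2TP + FP + FN)}: 1 for perfect overlap, 0 for disjoint masks.
#' Two empty masks agree vacuously and score 1 (with a warning).
#'
#' @param sg,st ground-truth and predicted masks ([BinaryMask-class] or 0/1
#'   matrices of equal shape).
#' @return Value in \eqn{[0, 1]}.
#' @export
volumetricDice <- function(sg, st) {
  cc <- confusionCounts(sg, st)
  den <- 2 * cc@tp + cc@fp + cc@fn
  if (den == 0) {
    warning("both masks empty: Volumetric Dice defined as 1 (vacuous agreement)")
    return(1)
  }
  2 * cc@tp / den
}

#' Jaccard index
#'
#' Intersection over union of the two foregrounds,
#' \eqn{TP/(TP + FP + FN)}; related to Volumetric Dice by
#' \eqn{JAC = DICE/(2 - DICE)}.
#'
#' @inheritParams volumetricDice
#' @return Value in \eqn{[0, 1]}.
#' @export
jaccard <- function(sg, st) {
  cc <- confusionCounts(sg, st)
  den <- cc@tp + cc@fp + cc@fn
  if (den == 0) {
    warning("both masks empty: Jaccard defined as 1 (vacuous agreement)")
    return(1)
  }
  cc@tp / den
}

# Boundary pixels of a mask: foreground pixels 4-adjacent to background or to
# the frame edge.
.maskBoundary <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  # neighbor values, with the frame treated as background (0)
  shift <- function(dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  nbmin <- pmin(shift(1, 0), shift(-1, 0), shift(0, 1), shift(0, -1))
  m == 1L & nbmin == 0L
}

#' Surface Dice similarity coefficient
#'
#' Dice-type overlap between the tolerance-\eqn{\tau} border regions of the
#' two masks: \eqn{B_i(\tau)} is the set of pixels whose Euclidean distance
#' to the boundary \eqn{\partial S_i} is at most \eqn{\tau} (boundary =
#' foreground pixels 4-adjacent to background or to the frame edge; distances
#' from an exact Euclidean distance transform), and
#' \deqn{R_{g,t}(\tau) = \frac{2|B_g(\tau) \cap B_t(\tau)|}
#'   {|B_g(\tau)| + |B_t(\tau)|}.}
#' A score of 1 means the two boundaries coincide within tolerance; larger
#' \eqn{\tau} makes the metric more tolerant (it is nondecreasing in
#' \eqn{\tau}).
#'
#' @inheritParams volumetricDice
#' @param tau boundary tolerance in pixel-length units (> 0).
#' @return Value in \eqn{[0, 1]}.
#' @export
surfaceDice <- function(sg, st, tau = 1) {
  if (tau <= 0) stop("'tau' must be positive")
  g <- .maskMatrix(sg); t <- .maskMatrix(st)
  if (!identical(dim(g), dim(t))) stop("mask shapes differ")
  border <- function(m) {
    if (all(m == 0L) || all(m == 1L))
      stop("mask has an empty boundary (all-background or all-foreground)")
    b <- .maskBoundary(m)
    # distance of every pixel to the nearest boundary pixel
    d <- distmap(1 - b)
    matrix(as.numeric(d) <= tau, nrow(m), ncol(m))
  }
  bg <- border(g); bt <- border(t)
  2 * sum(bg & bt) / (sum(bg) + sum(bt))
}

#' Precision and sensitivity
#'
#' Positive predictive value \eqn{PPV = TP/(TP+FP)} and true positive rate
#' \eqn{TPR = TP/(TP+FN)}. A zero denominator yields 0 with a warning.
#'
#' @param counts a [ConfusionCounts-class] (or named vector with
#'   `tp`, `fp`, `fn`).
#' @return Named numeric `c(ppv = ..., tpr = ...)`.
#' @export
precisionSensitivity <- function(counts) {
  cc <- .asCounts(counts)
  ppv <- if (cc@tp + cc@fp == 0) {
    warning("no predicted foreground: precision defined as 0"); 0
  } else cc@tp / (cc@tp + cc@fp)
  tpr <- if (cc@tp + cc@fn == 0) {
    warning("no ground-truth foreground: sensitivity defined as 0"); 0
  } else cc@tp / (cc@tp + cc@fn)
  c(ppv = ppv, tpr = tpr)
}

#' F-beta measure
#'
#' Precision/sensitivity trade-off metric, computed in the count form that
#' avoids 0/0: \deqn{F_\beta = \frac{(\beta^2+1)\,TP}
#' {(\beta^2+1)\,TP + \beta^2 FN + FP}.}
#' \eqn{\beta = 1} recovers the Volumetric Dice coefficient exactly;
#' \eqn{\beta \to \infty} recovers the sensitivity. When TP = FP = FN = 0 the
#' masks agree vacuously and the value is 1 with a warning.
#'
#' @inheritParams precisionSensitivity
#' @param beta trade-off weight (> 0): \eqn{\beta < 1} penalizes false
#'   positives, \eqn{\beta > 1} false negatives.
#' @return Value in \eqn{[0, 1]}.
#' @examples
#' fBeta(c(tp = 3170, fp = 134, fn = 347), beta = 0.25)
#' @export
fBeta <- function(counts, beta = 1) {
  if (beta <= 0) stop("'beta' must be positive")
  cc <- .asCounts(counts)
  b2 <- beta^2
  num <- (b2 + 1) * cc@tp
  den <- (b2 + 1) * cc@tp + b2 * cc@fn + cc@fp
  if (den == 0) {
    warning("TP = FP = FN = 0: F-beta defined as 1 (vacuous agreement)")
    return(1)
  }
  num / den
}

#' Convert between Dice and Jaccard
#'
#' The exact algebraic relationship \eqn{JAC = DICE/(2 - DICE)} and its
#' inverse \eqn{DICE = 2\,JAC/(1 + JAC)}; the two maps are mutual inverses
#' on \eqn{[0, 1]}.
#'
#' @param value metric value(s) in \eqn{[0, 1]}.
#' @param to `"jaccard"` (input is Dice) or `"dice"` (input is Jaccard).
#' @return Converted value(s).
#' @export
diceJaccardConvert <- function(value, to = c("jaccard", "dice")) {
  to <- match.arg(to)
  if (any(value < 0) || any(value > 1)) stop("'value' must lie in [0, 1]")
  if (to == "jaccard") value / (2 - value) else 2 * value / (1 + value)
}

#' Dice vs Jaccard approximation bounds
#'
#' Brute-force sweep of the Dice-Jaccard gap over a dense grid of Dice
#' values in \eqn{(0, 1]}: returns the maximum absolute gap
#' \eqn{\max |DICE - JAC|} (analytically \eqn{3 - 2\sqrt 2}, attained at
#' \eqn{DICE = 2 - \sqrt 2}) and the supremum of the relative approximation
#' error (\eqn{\max(D/J, J/D) - 1}, which tends to 1 as \eqn{DICE \to 0}).
#'
#' @param step grid spacing of the sweep (default `1e-4`).
#' @return List with `maxAbsolute`, `argmaxDice`, `maxRelative`.
#' @export
diceJaccardApproximationBounds <- function(step = 1e-4) {
  d <- seq(step, 1, by = step)
  j <- diceJaccardConvert(d, "jaccard")
  gap <- d - j
  rel <- pmax(d / j, j / d) - 1
  list(maxAbsolute = max(gap), argmaxDice = d[which.max(gap)],
       maxRelative = max(rel))
}

#' Loss of a similarity metric
#'
#' `1 - metric`: 0 for perfect agreement, 1 for complete mismatch.
#'
#' @param metric metric value(s).
#' @return `1 - metric`.
#' @export
metricLoss <- function(metric) 1 - metric

#' Evaluate a predicted mask against a ground truth
#'
#' Computes the confusion counts and the full metric suite, and the loss of
#' the selected metric.
#'
#' @param sg,st ground-truth and predicted masks.
#' @param metric which metric drives the reported loss: one of
#'   `"surf_dice"`, `"vol_dice"`, `"jaccard"`, `"fbeta"`.
#' @param tau Surface Dice tolerance in pixel units.
#' @param beta F-beta trade-off weight.
#' @return A [MetricReport-class].
#' @export
evaluateMask <- function(sg, st,
                         metric = c("surf_dice", "vol_dice", "jaccard", "fbeta"),
                         tau = 1, beta = 1) {
  metric <- match.arg(metric)
  cc <- confusionCounts(sg, st)
  vd <- volumetricDice(sg, st)
  jc <- jaccard(sg, st)
  sd <- tryCatch(surfaceDice(sg, st, tau), error = function(e) NA_real_)
  fb <- fBeta(cc, beta)
  ps <- suppressWarnings(precisionSensitivity(cc))
  vals <- c(vol_dice = vd, surf_dice = sd, jaccard = jc, fbeta = fb,
            ppv = unname(ps["ppv"]), tpr = unname(ps["tpr"]))
  sel <- vals[[metric]]
  new("MetricReport", counts = cc, metrics = vals,
      loss = metricLoss(sel),
      config = list(metric = metric, tau = tau, beta = beta))
}

#' Serialize a metric report to JSON
#'
#' @param report a [MetricReport-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeMetricReport <- function(report, path) {
  stopifnot(is(report, "MetricReport"))
  cc <- report@counts
  jsonlite::write_json(
    list(counts = list(tp = cc@tp, fp = cc@fp, fn = cc@fn, tn = cc@tn),
         metrics = as.list(report@metrics),
         loss = report@loss,
         config = report@config),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g FP=%g FN=%g TN=%g\n",
              object@tp, object@fp, object@fn, object@tn))
})

setMethod("show", "MetricReport", function(object) {
  cat("MetricReport (loss metric:", object@config$metric, ")\n")
  print(round(object@metrics, 4))
  cat(sprintf("loss = %.4f\n", object@loss))
})
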