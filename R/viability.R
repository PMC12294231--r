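#' @title Live/dead quantification and IG50 dose-response fitting
#' @name viability
NULL

#' Segment and count live/dead objects
#'
#' Each channel is thresholded at a fixed intensity and objects are connected
#' components of the combined stain mask (>= `minSize` voxels). By default an
#' object is live iff it carries live-channel signal and no dead-channel
#' signal (PI marks compromised nuclei, so doubly stained objects count as
#' dead); `strictPaper = TRUE` restores the literal mask-intersection rule
#' under which doubly stained objects count as live.
#'
#' @param image 2-channel [VoxelImage-class] (channels `"live"`, `"dead"`)
#'   or list of two arrays.
#' @param liveThreshold,deadThreshold fixed intensity thresholds.
#' @param minSize minimum object size in voxels.
#' @param strictPaper logical; see above.
#' @return list with `n_live`, `n_dead`, `live_fraction` and the component
#'   label array.
#' @export
segmentLiveDead <- function(image, liveThreshold = 0.5, deadThreshold = 0.5,
                            minSize = 5, strictPaper = FALSE) {
  if (is(image, "VoxelImage")) {
    live <- imgData(getChannel(image, "live"))
    dead <- imgData(getChannel(image, "dead"))
  } else {
    live <- image[[1L]]; dead <- image[[2L]]
  }
  liveM <- live >= liveThreshold
  deadM <- dead >= deadThreshold
  any_ <- liveM | deadM
  if (!any(any_)) stop("both channels empty: nothing to segment")
  lab <- .cc_label3d(any_, dim(any_), 26L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minSize)
  nLive <- 0L; nDead <- 0L
  for (k in keep) {
    obj <- lab == k
    hasLive <- any(liveM[obj]); hasDead <- any(deadM[obj])
    isLive <- if (strictPaper) hasLive else (hasLive && !hasDead)
    if (isLive) nLive <- nLive + 1L else nDead <- nDead + 1L
  }
  n <- nLive + nDead
  list(n_live = nLive, n_dead = nDead,
       live_fraction = if (n > 0) nLive / n else NA_real_,
       labels = lab)
}

#' Relative viability of a treated versus control condition
#'
#' Ratio of live object counts, treated / control.
#'
#' @param treated,control [segmentLiveDead()] results (or lists with
#'   `n_live`).
#' @return numeric ratio.
#' @export
relativeViability <- function(treated, control) {
  if (is.null(control$n_live) || control$n_live <= 0)
    stop("control has no live objects")
  treated$n_live / control$n_live
}

#' Fit a four-parameter-logistic dose-response (IG50)
#'
#' Fits `viability = bottom + (top - bottom) / (1 + (dose/ig50)^hill)` on a
#' log10 dose axis with [minpack.lm::nlsLM()], deterministic initialization
#' from the data: plateaus from the extreme-dose means (dose 0 anchors the
#' top plateau) and IG50 from the doses bracketing half-maximum. Requires at
#' least four non-zero doses; a response with no transition is rejected, and
#' non-monotone data are fitted but flagged via the residual.
#'
#' @param doses dose vector (uM; may include 0 = control).
#' @param viabilities viability percentages, same length.
#' @param highResidual RMS threshold (percentage points) above which the
#'   `"high_residual"` flag is set.
#' @return a [DoseResponseFit-class].
#' @export
fitIG50 <- function(doses, viabilities, highResidual = 10) {
  stopifnot(length(doses) == length(viabilities))
  nz <- doses > 0
  if (sum(nz) < 4) stop("need >= 4 non-zero doses")
  d <- doses[nz]; v <- viabilities[nz]
  ord <- order(d); d <- d[ord]; v <- v[ord]
  top0 <- if (any(doses == 0)) mean(viabilities[doses == 0]) else max(v)
  bot0 <- min(v)
  if (abs(top0 - bot0) < 1e-6 * max(abs(top0), 1) ||
      diff(range(v)) < 0.02 * max(abs(v), 1))
    stop("flat response: no transition to fit")
  half <- (top0 + bot0) / 2
  below <- which(v <= half)
  ig0 <- if (length(below) && min(below) > 1)
    sqrt(d[min(below)] * d[min(below) - 1L]) else stats::median(d)
  df <- data.frame(ld = log10(d), v = v)
  fit <- minpack.lm::nlsLM(
    v ~ bottom + (top - bottom) / (1 + 10^((ld - lig) * hill)),
    data = df,
    start = list(top = top0, bottom = bot0, lig = log10(ig0), hill = 1),
    lower = c(top = -Inf, bottom = -Inf, lig = log10(min(d)) - 3, hill = 0.05),
    upper = c(top = Inf, bottom = Inf, lig = log10(max(d)) + 3, hill = 20),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  resid <- sqrt(mean(stats::residuals(fit)^2))
  flags <- character(0)
  if (resid > highResidual) flags <- c(flags, "high_residual")
  if (cf[["bottom"]] > cf[["top"]]) flags <- c(flags, "inverted")
  new("DoseResponseFit", ig50 = 10^cf[["lig"]], hill = cf[["hill"]],
      top = cf[["top"]], bottom = cf[["bottom"]], residual = resid,
      flags = flags,
      data = data.frame(dose_uM = doses, viability_pct = viabilities))
}

setMethod("show", "DoseResponseFit", function(object) {
  cat("DoseResponseFit (4PL)\n",
      "  IG50  : ", signif(object@ig50, 4), " uM\n",
      "  hill  : ", signif(object@hill, 4), "\n",
      "  top   : ", signif(object@top, 4), " %, bottom: ",
      signif(object@bottom, 4), " %\n",
      "  RMS residual: ", signif(object@residual, 3), sep = "")
  if (length(object@flags)) cat("  [", paste(object@flags, collapse = ", "),
                                "]", sep = "")
  cat("\n")
})

#' Predicted viability of a fitted dose-response
#' @param object a [DoseResponseFit-class].
#' @param newdata optional data.frame with `dose_uM`.
#' @param ... unused.
#' @export
setMethod("predict", "DoseResponseFit", function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object@data$dose_uM else newdata$dose_uM
  ifelse(d == 0, object@top,
         object@bottom + (object@top - object@bottom) /
           (1 + (d / object@ig50)^object@hill))
})
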