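## Biphasic melting model: evaluation, normalization, nonlinear fitting and
## mono- vs biphasic model selection.

#' Evaluate the double-sigmoid melting model
#'
#' \code{f(x) = a / (1 + exp(-(x - x0)/b)) + c / (1 + exp(-(x - x2)/d))}.
#' The first transition (midpoint \code{x0}) corresponds to release of the
#' Hoogsteen-bound third strand, the second (\code{x2}) to Watson-Crick
#' duplex melting.
#'
#' @param params Named numeric vector or list with \code{a, x0, b, c, x2,
#'   d}; slopes \code{b, d} must be positive (for a monophasic model set
#'   \code{c = 0}; \code{d} is then inert but must still be positive).
#' @param temperature Numeric vector of temperatures (degrees C).
#' @return Model values at \code{temperature}.
#' @examples
#' p <- c(a = 0.5, x0 = 50, b = 3, c = 0.5, x2 = 80, d = 3)
#' evalMeltingModel(p, 50)  # 0.25 + small second-transition tail
#' @export
evalMeltingModel <- function(params, temperature) {
  p <- as.list(params)
  for (nm in c("a", "x0", "b", "c", "x2", "d"))
    if (is.null(p[[nm]])) stop("missing parameter '", nm, "'")
  if (p$b <= 0 || p$d <= 0) stop("slope parameters b, d must be positive")
  p$a / (1 + exp(-(temperature - p$x0) / p$b)) +
    p$c / (1 + exp(-(temperature - p$x2) / p$d))
}

#' Normalize raw ellipticity to the unit interval
#'
#' Min-max scales a raw ellipticity series to [0, 1], flipping its sign
#' first if the signal decreases with temperature on average, so that the
#' normalized melting signal is non-decreasing overall. Affine transforms
#' of the input (including sign flips) yield identical output.
#'
#' @param raw Numeric vector of raw ellipticity values (>= 2 distinct
#'   values required).
#' @param temperatures Optional temperatures used to orient the signal;
#'   defaults to the point index (equivalent for an ordered series).
#' @return Normalized values in [0, 1].
#' @examples
#' normalizeEllipticity(c(0, 0.5, 1))   # unchanged
#' normalizeEllipticity(c(1, 0.5, 0))   # flipped
#' @export
normalizeEllipticity <- function(raw, temperatures = seq_along(raw)) {
  if (diff(range(raw)) == 0)
    stop("cannot normalize a constant signal")
  if (stats::cor(raw, temperatures) < 0) raw <- -raw
  (raw - min(raw)) / (max(raw) - min(raw))
}

## Corrected information criterion (small-sample AIC) from a least-squares
## fit: k counts the model parameters plus the error variance.
.aicc <- function(sse, n, npar) {
  k <- npar + 1
  n * log(sse / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit the melting model to a curve
#'
#' Least-squares fit of the double-sigmoid melting model (or its
#' single-sigmoid restriction with \code{c = 0}) by Levenberg-Marquardt,
#' started from a coarse deterministic grid: candidate midpoints every
#' 5 degrees C across the measured range (midpoint pairs with
#' \code{x0 < x2} for the biphasic model), amplitudes splitting the
#' observed signal range, slopes starting at 3 degrees C. The best
#' converged start by residual sum of squares wins; for biphasic fits the
#' two transitions are reordered so that \code{x0 < x2} (tm1 < tm2).
#'
#' @param curve A \code{\linkS4class{MeltingCurve}} with at least 12 points
#'   spanning at least 30 degrees C.
#' @param model \code{"biphasic"} (default) or \code{"monophasic"}.
#' @param nStarts Number of top grid starts refined by the optimizer
#'   (default 5).
#' @return A \code{\linkS4class{BiphasicFit}}.
#' @examples
#' cv <- makeMeltingCurve(a = 0.5, x0 = 50, b = 3, c = 0.5, x2 = 80, d = 3)
#' meltingTemperatures(fitMelting(cv))
#' @export
fitMelting <- function(curve, model = c("biphasic", "monophasic"),
                       nStarts = 5L) {
  model <- match.arg(model)
  stopifnot(is(curve, "MeltingCurve"))
  x <- curve@temperatures
  y <- curve@values
  n <- length(x)
  if (n < 12L)
    stop("fitting requires at least 12 points (got ", n, ")")
  if (diff(range(x)) < 30)
    stop("fitting requires a temperature span of at least 30 degC")
  r <- diff(range(y))
  if (r < 1e-8)
    stop("degenerate curve: constant signal, no melting transition to fit")

  mids <- seq(min(x) + 2, max(x) - 2, by = 5)
  df <- data.frame(x = x, y = y)

  if (model == "monophasic") {
    sse0 <- vapply(mids, function(m)
      sum((y - evalMeltingModel(
        c(a = r, x0 = m, b = 3, c = 0, x2 = m, d = 3), x))^2), numeric(1))
    starts <- lapply(mids[order(sse0)][seq_len(min(3L, length(mids)))],
                     function(m) list(a = r, x0 = m, b = 3))
    fits <- lapply(starts, function(s) tryCatch(
      minpack.lm::nlsLM(y ~ a / (1 + exp(-(x - x0) / b)), data = df,
                        start = s,
                        lower = c(a = 0, x0 = min(x) - 10, b = 1e-2),
                        upper = c(a = Inf, x0 = max(x) + 10, b = 30),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL))
  } else {
    grid <- expand.grid(x0 = mids, x2 = mids)
    grid <- grid[grid$x0 < grid$x2, , drop = FALSE]
    if (!nrow(grid))
      stop("temperature range too narrow for a biphasic start grid")
    sse0 <- vapply(seq_len(nrow(grid)), function(i)
      sum((y - evalMeltingModel(
        c(a = r / 2, x0 = grid$x0[i], b = 3, c = r / 2, x2 = grid$x2[i],
          d = 3), x))^2), numeric(1))
    top <- order(sse0)[seq_len(min(nStarts, nrow(grid)))]
    starts <- lapply(top, function(i)
      list(a = r / 2, x0 = grid$x0[i], b = 3, c = r / 2, x2 = grid$x2[i],
           d = 3))
    fits <- lapply(starts, function(s) tryCatch(
      minpack.lm::nlsLM(
        y ~ a / (1 + exp(-(x - x0) / b)) + c / (1 + exp(-(x - x2) / d)),
        data = df, start = s,
        lower = c(a = 0, x0 = min(x) - 10, b = 1e-2, c = 0,
                  x2 = min(x) - 10, d = 1e-2),
        upper = c(a = Inf, x0 = max(x) + 10, b = 30, c = Inf,
                  x2 = max(x) + 10, d = 30),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL))
  }

  fits <- Filter(Negate(is.null), fits)
  if (!length(fits))
    stop("melting fit failed to converge from any grid start (model = ",
         model, ", n = ", n, ", signal range = ", signif(r, 3), ")")
  sses <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  best <- fits[[which.min(sses)]]

  cf <- coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, length(cf)),
                                              names(cf)))
  if (model == "monophasic") {
    params <- c(a = unname(cf[["a"]]), x0 = unname(cf[["x0"]]),
                b = unname(cf[["b"]]), c = 0, x2 = NA_real_, d = NA_real_)
    stderr <- c(a = unname(se[["a"]]), x0 = unname(se[["x0"]]),
                b = unname(se[["b"]]), c = NA_real_, x2 = NA_real_,
                d = NA_real_)
  } else {
    params <- cf[c("a", "x0", "b", "c", "x2", "d")]
    stderr <- se[c("a", "x0", "b", "c", "x2", "d")]
    if (params[["x0"]] > params[["x2"]]) {   # canonical ordering tm1 < tm2
      params <- params[c("c", "x2", "d", "a", "x0", "b")]
      stderr <- stderr[c("c", "x2", "d", "a", "x0", "b")]
      names(params) <- names(stderr) <- c("a", "x0", "b", "c", "x2", "d")
    }
  }
  new("BiphasicFit", params = params, stderr = stderr,
      residualSSE = min(sses), model = model, selectionStat = NA_real_,
      nPoints = as.integer(n), curveId = curve@curveId)
}

#' Classify a melting curve as monophasic or biphasic
#'
#' Fits both the single- and double-sigmoid models (after normalizing the
#' signal, so the decision is invariant to affine transforms of the raw
#' ellipticity) and selects the biphasic model only when it improves the
#' corrected information criterion by more than \code{margin} AND the
#' fitted midpoints are separated by more than \code{minSeparation}
#' degrees C. A biphasic melting transition is the spectroscopic signature
#' of triplex formation (Hoogsteen release, then Watson-Crick melting);
#' the conservative margin guards against over-fitting broad single
#' transitions.
#'
#' @param curve A \code{\linkS4class{MeltingCurve}}.
#' @param margin Required corrected information-criterion improvement
#'   (default 10).
#' @param minSeparation Required midpoint separation in degrees C
#'   (default 5).
#' @param minAmplitudeFraction Each transition must carry at least this
#'   fraction of the total amplitude \code{a + c} (default 0.1); this stops
#'   a near-zero-amplitude second sigmoid from acting as a baseline
#'   correction and being mistaken for a melting phase.
#' @param normalize Normalize the signal first (default \code{TRUE}).
#' @return A list with \code{model} (\code{"monophasic"} or
#'   \code{"biphasic"}), the two fits (\code{monophasic},
#'   \code{biphasic}), and the decision trace (\code{aiccMono},
#'   \code{aiccBiphasic}, \code{deltaAICc}, \code{separation}).
#' @examples
#' cv <- makeMeltingCurve(a = 0.5, x0 = 45, b = 3, c = 0.5, x2 = 80, d = 3)
#' classifyTransition(cv)$model  # "biphasic"
#' @export
classifyTransition <- function(curve, margin = 10, minSeparation = 5,
                               minAmplitudeFraction = 0.1,
                               normalize = TRUE) {
  stopifnot(is(curve, "MeltingCurve"))
  work <- if (normalize)
    MeltingCurve(curve@temperatures,
                 normalizeEllipticity(curve@values, curve@temperatures),
                 curve@curveId)
  else curve

  fitMono <- fitMelting(work, "monophasic")
  fitBi <- tryCatch(fitMelting(work, "biphasic"), error = function(e) NULL)

  n <- length(work@temperatures)
  aiccMono <- .aicc(max(fitMono@residualSSE, 1e-300), n, 3L)
  if (is.null(fitBi)) {
    return(list(model = "monophasic", monophasic = fitMono,
                biphasic = NULL, aiccMono = aiccMono,
                aiccBiphasic = NA_real_, deltaAICc = NA_real_,
                separation = NA_real_))
  }
  aiccBi <- .aicc(max(fitBi@residualSSE, 1e-300), n, 6L)
  delta <- aiccMono - aiccBi
  sep <- abs(fitBi@params[["x2"]] - fitBi@params[["x0"]])
  ampFrac <- min(fitBi@params[["a"]], fitBi@params[["c"]]) /
    (fitBi@params[["a"]] + fitBi@params[["c"]])

  ## parsimony guard: a numerically perfect monophasic fit needs no second
  ## transition (information criteria are meaningless at SSE ~ 0)
  monoPerfect <- fitMono@residualSSE / n < 1e-12
  model <- if (!monoPerfect && delta > margin && sep > minSeparation &&
               ampFrac >= minAmplitudeFraction)
    "biphasic" else "monophasic"

  fitBi@selectionStat <- delta
  fitMono@selectionStat <- delta
  list(model = model, monophasic = fitMono, biphasic = fitBi,
       aiccMono = aiccMono, aiccBiphasic = aiccBi, deltaAICc = delta,
       separation = unname(sep))
}
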