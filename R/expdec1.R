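#' Fit a one-phase exponential decay (ExpDec1) to an inhibition curve
#'
#' Unweighted nonlinear least squares of
#' \eqn{y = y_0 + A_1 \exp(-x / t_1)} — the "ExpDec1" parameterization of
#' Origin — to relative-activity points over isoform:FLp53 ratios, via the
#' Levenberg-Marquardt algorithm. Starting values are
#' \code{y0 = min(y)}, \code{a1 = y(min(x)) - y0},
#' \code{t1 = (max(x) - min(x)) / 3}; \code{t1} is constrained positive.
#' When y has essentially no variance the decay is non-identifiable and a
#' flagged flat fit (\code{a1 = 0}, \code{t1 = Inf}) is returned with a
#' warning.
#'
#' @param x non-negative, distinct ratios (>= 4 points).
#' @param y relative activities.
#' @return an \linkS4class{ExpDec1Fit}.
#' @examples
#' x <- c(0, 1, 5, 10)
#' y <- 0.2 + 0.8 * exp(-x / 2)
#' coef(fitExpDec1(x, y))
#' @export
fitExpDec1 <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 4L)
    stop("at least 4 points are required to fit ExpDec1, got ", length(x))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (any(x < 0)) stop("ratios must be non-negative")
  if (anyDuplicated(x)) stop("ratios must be distinct")
  if (sd(y) < 1e-10 * (abs(mean(y)) + 1)) {
    warning("y is essentially constant; decay parameters are not ",
            "identifiable (returning flat fit)")
    return(new("ExpDec1Fit", y0 = mean(y), a1 = 0, t1 = Inf,
               rss = sum((y - mean(y))^2), converged = FALSE,
               nonIdentifiable = TRUE))
  }
  y0 <- min(y)
  a1 <- y[which.min(x)] - y0
  if (a1 == 0) a1 <- max(y) - y0
  spread <- max(x) - min(x)
  resFun <- function(p) y - (p[1] + p[2] * exp(-x / p[3]))
  best <- NULL
  # Levenberg-Marquardt from a short ladder of decay-constant starts;
  # t1 kept positive by a box constraint
  for (t1 in spread / c(3, 10, 1, 30)) {
    out <- tryCatch(
      minpack.lm::nls.lm(par = c(y0 = y0, a1 = a1, t1 = t1),
                         fn = resFun,
                         lower = c(-Inf, -Inf, 1e-9),
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500)),
      error = function(e) NULL)
    if (is.null(out)) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best))
    return(new("ExpDec1Fit", y0 = y0, a1 = a1, t1 = spread / 3,
               rss = NA_real_, converged = FALSE,
               nonIdentifiable = FALSE))
  cf <- best$par
  conv <- best$info %in% 1:4   # nls.lm convergence codes
  new("ExpDec1Fit", y0 = unname(cf["y0"]), a1 = unname(cf["a1"]),
      t1 = unname(cf["t1"]), rss = best$deviance, converged = conv,
      nonIdentifiable = FALSE)
}
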