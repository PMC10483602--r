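#' Natural cubic spline basis with analytic derivatives and integrals
#'
#' Constructs a natural cubic spline basis of a given number of degrees of
#' freedom, with interior knots placed at equally spaced quantiles of the
#' supplied times and boundary knots at their range (or as supplied). The
#' basis is built from the truncated-power natural-spline construction, so it
#' is exactly linear beyond the boundary knots and its derivative and
#' antiderivative are available in closed form -- which the slope and
#' scaled-area association forms of the joint model require.
#'
#' The basis excludes the intercept: `df = 1` gives a single (scaled) linear
#' column; `df = d` adds `d - 1` curvature columns from `d - 1` interior
#' knots. Time is internally rescaled to the unit interval spanned by the
#' boundary knots, so all basis columns are O(1) regardless of the time unit.
#'
#' @param times numeric vector of observation times (days) used to place
#'   interior knots.
#' @param df degrees of freedom (number of basis columns), `>= 1`.
#' @param boundary optional length-2 numeric vector of boundary knots;
#'   defaults to `range(times)`.
#' @return an object of class `ctmon_ncs` with elements `df`, `boundary`,
#'   `knots` (interior knots on the original scale).
#' @examples
#' b <- ncs_basis(seq(0, 365, by = 28), df = 3)
#' X <- ncs_eval(b, c(0, 100, 200))
#' @export
ncs_basis <- function(times, df, boundary = NULL) {
  times <- as.numeric(times)
  if (df < 1) stop("df must be >= 1")
  if (is.null(boundary)) boundary <- range(times)
  boundary <- as.numeric(boundary)
  if (length(boundary) != 2 || boundary[2] <= boundary[1])
    stop("degenerate time range: boundary knots must be distinct")
  interior <- numeric(0)
  if (df >= 2) {
    probs <- seq_len(df - 1) / df
    interior <- unname(quantile(times, probs = probs, type = 7))
    interior <- interior[interior > boundary[1] & interior < boundary[2]]
    interior <- unique(interior)
    if (length(interior) != df - 1)
      stop("could not place ", df - 1, " distinct interior knots; ",
           "observation times are too degenerate")
  }
  structure(list(df = as.integer(df), boundary = boundary, knots = interior),
            class = "ctmon_ncs")
}

#' Evaluate a natural cubic spline basis
#'
#' @param basis a `ctmon_ncs` object from [ncs_basis()].
#' @param t times at which to evaluate.
#' @param deriv 0 for the basis itself, 1 for its first derivative with
#'   respect to time (per day).
#' @param integral if `TRUE`, return the running antiderivative
#'   \eqn{\int_0^t N_k(s)\,ds} of each column instead (days x basis units).
#' @return numeric matrix, `length(t)` rows by `df` columns.
#' @export
ncs_eval <- function(basis, t, deriv = 0, integral = FALSE) {
  stopifnot(inherits(basis, "ctmon_ncs"))
  t <- as.numeric(t)
  a <- basis$boundary[1]; b <- basis$boundary[2]
  h <- b - a
  u <- (t - a) / h                       # scaled time
  xi <- c(0, (basis$knots - a) / h, 1)   # all knots on the unit scale
  K <- length(xi)
  out <- matrix(0, length(t), basis$df)
  # column 1: linear term
  if (integral) {
    u0 <- -a / h  # scaled value of t = 0, the lower integration limit
    out[, 1] <- h * (u^2 - u0^2) / 2
  } else if (deriv == 0) {
    out[, 1] <- u
  } else {
    out[, 1] <- rep(1 / h, length(t))
  }
  if (basis$df >= 2) {
    tp3 <- function(x) ifelse(x > 0, x^3, 0)      # truncated cube
    tp2 <- function(x) ifelse(x > 0, x^2, 0)
    tp4 <- function(x) ifelse(x > 0, x^4, 0)
    dfun <- function(k, v) (tp3(v - xi[k]) - tp3(v - xi[K])) / (xi[K] - xi[k])
    dfun1 <- function(k, v) 3 * (tp2(v - xi[k]) - tp2(v - xi[K])) / (xi[K] - xi[k])
    dfunI <- function(k, v) (tp4(v - xi[k]) - tp4(v - xi[K])) / (4 * (xi[K] - xi[k]))
    for (k in seq_len(K - 2)) {
      if (integral) {
        u0 <- -a / h
        val <- (dfunI(k, u) - dfunI(K - 1, u)) -
               (dfunI(k, u0) - dfunI(K - 1, u0))
        out[, k + 1] <- h * val
      } else if (deriv == 0) {
        out[, k + 1] <- dfun(k, u) - dfun(K - 1, u)
      } else {
        out[, k + 1] <- (dfun1(k, u) - dfun1(K - 1, u)) / h
      }
    }
  }
  colnames(out) <- paste0("ncs", seq_len(basis$df))
  out
}
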