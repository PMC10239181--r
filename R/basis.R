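#' Spline specification for regional effect curves
#'
#' @param df basis dimension per curve (default 10). `df = 1` requests the
#'   degenerate constant basis (one column of ones, zero penalty), used for
#'   reductions to ordinary logistic regression.
#' @param degree polynomial degree of the B-spline pieces (default cubic).
#' @param penalty_order order of the difference penalty on adjacent basis
#'   coefficients (default 2: null space of constants and linear trends).
#' @return list of class `spline_spec`.
#' @export
spline_spec <- function(df = 10L, degree = 3L, penalty_order = 2L) {
  stopifnot(df >= 1L, degree >= 0L, penalty_order >= 1L)
  if (df > 1L && df < 3L) stop("basis dimension must be 1 (constant) or >= 3")
  if (df > 1L && df <= degree) stop("df must exceed the spline degree")
  structure(list(df = as.integer(df), degree = as.integer(degree),
                 penalty_order = as.integer(penalty_order)),
            class = "spline_spec")
}

#' Evaluate a penalized B-spline basis at CpG positions
#'
#' Cubic B-splines (by default) are placed on the bp coordinate axis with
#' interior knots at quantiles of the CpG positions, so knot density
#' follows CpG density. The basis columns form a partition of unity
#' (each row sums to 1). The roughness penalty is the squared
#' `penalty_order`-th difference of adjacent basis coefficients, a positive
#' semi-definite matrix whose null space (dimension `penalty_order`)
#' contains the polynomial trends left unpenalized.
#'
#' @param cpg_positions strictly increasing bp coordinates.
#' @param spec a [spline_spec()].
#' @return list of class `region_basis` with `B` (n x df basis matrix),
#'   `P` (df x df penalty), `positions`, and the spec fields.
#' @export
build_basis <- function(cpg_positions, spec = spline_spec()) {
  pos <- as.numeric(cpg_positions)
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must be strictly increasing")
  n <- length(pos)
  if (spec$df == 1L) {
    return(structure(list(B = matrix(1, n, 1L), P = matrix(0, 1L, 1L),
                          positions = pos, df = 1L, degree = 0L,
                          penalty_order = spec$penalty_order),
                     class = "region_basis"))
  }
  if (spec$df >= n)
    stop("too few CpGs (", n, ") for basis dimension ", spec$df)
  n_inner <- spec$df - spec$degree - 1L
  inner <- if (n_inner > 0L)
    stats::quantile(pos, probs = seq_len(n_inner) / (n_inner + 1L),
                    names = FALSE, type = 7)
  else numeric(0)
  knots <- c(rep(min(pos), spec$degree + 1L), inner,
             rep(max(pos), spec$degree + 1L))
  B <- splines::splineDesign(knots, pos, ord = spec$degree + 1L,
                             outer.ok = FALSE)
  D <- diff(diag(spec$df), differences = spec$penalty_order)
  P <- crossprod(D)
  structure(list(B = B, P = P, positions = pos, df = spec$df,
                 degree = spec$degree, penalty_order = spec$penalty_order),
            class = "region_basis")
}
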