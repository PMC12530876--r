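#' Define a feasible parameter space
#'
#' A parameter space is an axis-aligned box of physically reasonable
#' force-field parameter values.  The canonical use case is the
#' four-dimensional Lennard-Jones space (`sigma_C`, `sigma_H` in nm;
#' `eps_C`, `eps_H` in kJ/mol), but any dimensionality `d >= 1` is
#' supported.
#'
#' @param names character vector of parameter identifiers, in order.
#' @param lower,upper numeric vectors of per-parameter bounds;
#'   `lower[i] < upper[i]` is required for every dimension.
#' @return An object of class `parameter_space` with fields `names`,
#'   `lower` and `upper`.
#' @seealso [feasible_space()] for the default Lennard-Jones box,
#'   [make_grid()], [make_sobol()], [space_contains()].
#' @export
#' @examples
#' parameter_space(c("sigma_C", "eps_C"), lower = c(0.05, 0.15),
#'                 upper = c(0.35, 1.15))
parameter_space <- function(names, lower, upper) {
  names <- as.character(names)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(names) < 1L)
    stop("a parameter space needs at least one dimension", call. = FALSE)
  if (length(lower) != length(names) || length(upper) != length(names))
    stop("'names', 'lower' and 'upper' must have equal length", call. = FALSE)
  if (anyDuplicated(names))
    stop("parameter names must be unique", call. = FALSE)
  if (!all(is.finite(lower)) || !all(is.finite(upper)))
    stop("bounds must be finite", call. = FALSE)
  if (any(lower >= upper))
    stop("every lower bound must be strictly below its upper bound",
         call. = FALSE)
  structure(list(names = names, lower = lower, upper = upper),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("<parameter_space> ", length(x$names), " dimensions\n", sep = "")
  for (i in seq_along(x$names))
    cat(sprintf("  %-10s [%g, %g]\n", x$names[i], x$lower[i], x$upper[i]))
  invisible(x)
}

#' Default Lennard-Jones feasible space
#'
#' The box searched during data acquisition for the n-octane density
#' target: `sigma_C` in \[0.05, 0.35\] nm, `sigma_H` in \[0.045, 0.35\] nm,
#' `eps_C` in \[0.15, 1.15\] kJ/mol, `eps_H` in \[0.01, 0.15\] kJ/mol.
#'
#' @return A [parameter_space()] of dimension 4.
#' @export
feasible_space <- function() {
  parameter_space(names = c("sigma_C", "sigma_H", "eps_C", "eps_H"),
                  lower = c(0.0500, 0.0450, 0.1500, 0.0100),
                  upper = c(0.3500, 0.3500, 1.1500, 0.1500))
}

#' Construct a Lennard-Jones parameter set
#'
#' @param sigma_C,sigma_H carbon and hydrogen zero-crossing distances, nm.
#' @param eps_C,eps_H carbon and hydrogen well depths, kJ/mol.
#' @return A named numeric vector of class `lj_params`.
#' @export
#' @examples
#' lj_params(0.3286, 0.2606, 0.6730, 0.1194)
lj_params <- function(sigma_C, sigma_H, eps_C, eps_H) {
  p <- c(sigma_C = as.numeric(sigma_C), sigma_H = as.numeric(sigma_H),
         eps_C = as.numeric(eps_C), eps_H = as.numeric(eps_H))
  if (!all(is.finite(p)) || any(p <= 0))
    stop("all Lennard-Jones parameters must be finite and strictly positive",
         call. = FALSE)
  class(p) <- "lj_params"
  p
}

#' @export
print.lj_params <- function(x, ...) {
  cat(sprintf(
    "<lj_params> sigma_C=%g nm  sigma_H=%g nm  eps_C=%g kJ/mol  eps_H=%g kJ/mol\n",
    x[["sigma_C"]], x[["sigma_H"]], x[["eps_C"]], x[["eps_H"]]))
  invisible(x)
}

# coerce a point argument (lj_params, named vector, one-row data frame) to a
# plain numeric vector ordered like `names`
as_param_vector <- function(p, names) {
  if (is.data.frame(p)) {
    if (nrow(p) != 1L)
      stop("expected a single parameter point", call. = FALSE)
    p <- unlist(p[1L, , drop = TRUE])
  }
  p <- unclass(p)
  if (!is.null(names(p))) {
    missing <- setdiff(names, names(p))
    if (length(missing))
      stop("point is missing parameter(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    p <- p[names]
  } else if (length(p) != length(names)) {
    stop("point dimensionality (", length(p), ") does not match the space (",
         length(names), ")", call. = FALSE)
  }
  as.numeric(p)
}

#' Specify a rectangular sampling grid
#'
#' Each dimension is an inclusive arithmetic sequence `min, min + step, ...`
#' up to `max`.  The per-dimension point count is
#' `floor((max - min) / step) + 1`, with the endpoint included when
#' `max - min` is an integer multiple of `step` within a relative
#' tolerance of 1e-9.
#'
#' @param min,step,max numeric vectors (recycled to a common length) of
#'   per-dimension sequence parameters; `step > 0`, `min <= max`.
#' @param names optional parameter identifiers; defaults to the
#'   Lennard-Jones names when the dimension is 4.
#' @return An object of class `grid_spec`.
#' @seealso [make_grid()]
#' @export
#' @examples
#' # 6 values per dimension, 6^4 = 1296 points in total
#' grid_spec(min  = c(0.0750, 0.0683, 0.2465, 0.0300),
#'           step = c(0.0500, 0.0455, 0.1643, 0.0200),
#'           max  = c(0.3250, 0.2958, 1.0680, 0.1300))
grid_spec <- function(min, step, max, names = NULL) {
  d <- base::max(length(min), length(step), length(max))
  min <- rep_len(as.numeric(min), d)
  step <- rep_len(as.numeric(step), d)
  max <- rep_len(as.numeric(max), d)
  if (is.null(names)) {
    names <- if (d == 4L) c("sigma_C", "sigma_H", "eps_C", "eps_H")
             else paste0("x", seq_len(d))
  }
  if (any(step <= 0))
    stop("grid step sizes must be strictly positive", call. = FALSE)
  if (any(min > max))
    stop("grid minima must not exceed the maxima", call. = FALSE)
  structure(list(names = as.character(names), min = min, step = step,
                 max = max),
            class = "grid_spec")
}

# inclusive arithmetic sequence with relative endpoint tolerance
grid_axis <- function(min, step, max, rel_tol = 1e-9) {
  span <- max - min
  k <- floor(span / step + rel_tol * base::max(1, abs(span / step)))
  min + step * (0:k)
}

#' Generate a full-factorial grid of parameter sets
#'
#' Returns the Cartesian product of the per-dimension arithmetic sequences
#' of a [grid_spec()].  Ordering is lexicographic over the dimensions in
#' declared order (the first parameter varies slowest).
#'
#' @param spec a [grid_spec()].
#' @return A data frame with one column per parameter and
#'   `prod(points per dimension)` rows; the originating space is attached
#'   as attribute `"space"`.
#' @export
#' @examples
#' nrow(make_grid(grid_spec(min = c(0, 0), step = c(1, 1), max = c(1, 2))))
make_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  axes <- Map(grid_axis, spec$min, spec$step, spec$max)
  names(axes) <- spec$names
  # expand.grid varies the first factor fastest; reverse for lexicographic
  # order with the first declared dimension most significant
  grid <- expand.grid(rev(axes), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(axes)), drop = FALSE]
  rownames(grid) <- NULL
  attr(grid, "space") <- parameter_space(
    spec$names, spec$min,
    # degenerate axes (min == max) still need a valid box
    pmax(vapply(axes, base::max, numeric(1)), spec$min + 1e-12))
  grid
}

# --- Sobol sequence ---------------------------------------------------------
#
# Base-2 digital sequence built from the standard primitive-polynomial /
# direction-number table (Joe & Kuo) for the leading dimensions, generated
# in Gray-code order with 30-bit precision.  The first point of the
# unscrambled sequence is the origin.  No installed R package provides a
# Sobol generator, so the (small) construction lives here; it reproduces
# the reference unscrambled sequence bit-for-bit.

.sobol_polys <- list(
  list(s = 1L, a = 0L, m = c(1L)),
  list(s = 2L, a = 1L, m = c(1L, 3L)),
  list(s = 3L, a = 1L, m = c(1L, 3L, 1L)),
  list(s = 3L, a = 2L, m = c(1L, 1L, 1L)),
  list(s = 4L, a = 1L, m = c(1L, 1L, 3L, 3L)),
  list(s = 4L, a = 4L, m = c(1L, 3L, 5L, 13L)),
  list(s = 5L, a = 2L, m = c(1L, 1L, 5L, 5L, 17L))
)

.sobol_bits <- 30L

# direction integers, one column per dimension
sobol_directions <- function(d, bits = .sobol_bits) {
  if (d > length(.sobol_polys) + 1L)
    stop("Sobol generator supports at most ", length(.sobol_polys) + 1L,
         " dimensions", call. = FALSE)
  V <- matrix(0L, nrow = bits, ncol = d)
  V[, 1L] <- as.integer(2^(bits - seq_len(bits)))  # van der Corput dimension
  if (d > 1L) for (j in 2L:d) {
    tb <- .sobol_polys[[j - 1L]]
    s <- tb$s; a <- tb$a; m <- tb$m
    if (bits > s) {
      m <- c(m, integer(bits - s))
      for (k in (s + 1L):bits) {
        mk <- bitwXor(m[k - s], bitwShiftL(m[k - s], s))
        if (s > 1L) for (i in 1L:(s - 1L)) {
          if (bitwAnd(bitwShiftR(a, s - 1L - i), 1L) == 1L)
            mk <- bitwXor(mk, bitwShiftL(m[k - i], i))
        }
        m[k] <- mk
      }
    }
    V[, j] <- as.integer(m[seq_len(bits)] * 2^(bits - seq_len(bits)))
  }
  V
}

# n points of the d-dimensional sequence on [0,1)^d, Gray-code order.
# scramble_seed applies a seeded per-dimension digital (XOR) shift.
sobol_unit <- function(n, d, scramble_seed = NULL) {
  bits <- .sobol_bits
  V <- sobol_directions(d, bits)
  shift <- integer(d)
  if (!is.null(scramble_seed)) {
    shift <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(as.integer(scramble_seed))
      as.integer(sample.int(2^bits, d, replace = TRUE) - 1L)
    })
  }
  X <- matrix(0, n, d)
  state <- integer(d)
  if (n >= 1L) X[1L, ] <- bitwXor(state, shift) / 2^bits
  if (n >= 2L) for (i in 2L:n) {
    k <- i - 1L
    c_idx <- 1L
    while (bitwAnd(k, 1L) == 0L) {
      k <- bitwShiftR(k, 1L)
      c_idx <- c_idx + 1L
    }
    state <- bitwXor(state, V[c_idx, ])
    X[i, ] <- bitwXor(state, shift) / 2^bits
  }
  X
}

#' Generate a Sobol low-discrepancy sample of parameter sets
#'
#' Draws the first `2^m` points of a base-2 Sobol sequence and scales them
#' affinely into the bounds of `space`.  The unscrambled sequence (the
#' default) is fully deterministic and starts at the lower-bound corner;
#' each one-dimensional projection of `2^m` points places exactly one point
#' in each of the `2^m` equal subintervals of its range.  Supplying
#' `scramble_seed` applies a seeded digital (XOR) shift to decorrelate
#' repeated designs while preserving the net's balance.
#'
#' @param space a [parameter_space()].
#' @param m non-negative integer; `2^m` points are generated.
#' @param scramble_seed optional integer seed for digital-shift scrambling;
#'   `NULL` (default) yields the plain sequence.
#' @return A data frame of `2^m` rows with the space attached as
#'   attribute `"space"`; points are in sequence order.
#' @export
#' @examples
#' pts <- make_sobol(feasible_space(), m = 4)
#' nrow(pts)  # 16
make_sobol <- function(space, m, scramble_seed = NULL) {
  stopifnot(inherits(space, "parameter_space"))
  if (length(m) != 1L || is.na(m) || m < 0 || m != floor(m))
    stop("'m' must be a single non-negative integer", call. = FALSE)
  d <- length(space$names)
  n <- as.integer(2^m)
  U <- sobol_unit(n, d, scramble_seed = scramble_seed)
  X <- sweep(sweep(U, 2L, space$upper - space$lower, `*`), 2L, space$lower, `+`)
  out <- as.data.frame(X)
  names(out) <- space$names
  attr(out, "space") <- space
  out
}

#' Test membership of points in a parameter space
#'
#' Bounds are inclusive on both sides.
#'
#' @param space a [parameter_space()].
#' @param p a single point ([lj_params()], named numeric vector) or a data
#'   frame of points with one column per parameter.
#' @return Logical vector, one element per point.
#' @export
space_contains <- function(space, p) {
  stopifnot(inherits(space, "parameter_space"))
  if (is.data.frame(p)) {
    missing <- setdiff(space$names, names(p))
    if (length(missing))
      stop("points are missing parameter(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    X <- as.matrix(p[, space$names, drop = FALSE])
    ok <- rep(TRUE, nrow(X))
    for (i in seq_along(space$names))
      ok <- ok & X[, i] >= space$lower[i] & X[, i] <= space$upper[i]
    return(unname(ok))
  }
  v <- as_param_vector(p, space$names)
  all(v >= space$lower & v <= space$upper)
}

# map a point to [0,1]^d box coordinates and back (used by the optimizer)
to_unit <- function(space, v) (v - space$lower) / (space$upper - space$lower)
from_unit <- function(space, u) space$lower + u * (space$upper - space$lower)
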