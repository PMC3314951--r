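#' Diffusion gradient direction scheme
#'
#' A set of unit gradient directions plus a count of low-b ("unweighted")
#' measurements. Directions must be unit norm and, for schemes of up to 64
#' directions, separated by more than 5 degrees modulo antipodal symmetry
#' (g and -g encode the same measurement).
#'
#' @param vectors Numeric matrix, one row per direction, 3 columns.
#' @param n_lowb Number of low-b measurements associated with the scheme.
#' @return An object of class `direction_scheme`.
#' @export
direction_scheme <- function(vectors, n_lowb = 0L) {
  vectors <- as.matrix(vectors)
  if (ncol(vectors) != 3) stop("vectors must have 3 columns")
  nrm <- sqrt(rowSums(vectors^2))
  if (any(abs(nrm - 1) > 1e-9))
    stop("direction vectors must be unit norm (max deviation ",
         signif(max(abs(nrm - 1)), 3), ")")
  n <- nrow(vectors)
  if (n <= 64 && n >= 2) {
    ang <- min_pairwise_angle(vectors)
    if (ang <= 5)
      stop("minimum pairwise angle ", signif(ang, 3),
           " deg <= 5 deg (antipodally folded): directions too clustered")
  }
  if (n_lowb < 0) stop("n_lowb must be >= 0")
  structure(list(vectors = vectors, n_lowb = as.integer(n_lowb)),
            class = "direction_scheme")
}

#' @export
print.direction_scheme <- function(x, ...) {
  cat(sprintf("Direction scheme: %d directions + %d low-b volumes\n",
              nrow(x$vectors), x$n_lowb))
  invisible(x)
}

#' Minimum pairwise angle of a direction set (antipodally folded)
#'
#' @param vectors Matrix of unit row vectors.
#' @return Smallest angle between any two directions, degrees, treating g
#'   and -g as identical.
#' @export
min_pairwise_angle <- function(vectors) {
  dots <- abs(tcrossprod(vectors))
  diag(dots) <- 0
  acos(pmin(max(dots), 1)) * 180 / pi
}

# electrostatic energy and gradient for antipodal point sets; x is an
# n x 3 matrix of (not necessarily unit) coordinates
.repulsion_energy <- function(par, n) {
  u <- matrix(par, n, 3)
  nr <- sqrt(rowSums(u^2))
  x <- u / nr
  e <- 0
  for (i in seq_len(n - 1)) {
    dif <- x[(i + 1):n, , drop = FALSE]
    d1 <- sqrt(rowSums(sweep(dif, 2, x[i, ], "-")^2))
    d2 <- sqrt(rowSums(sweep(dif, 2, x[i, ], "+")^2))
    e <- e + sum(1 / d1 + 1 / d2)
  }
  e
}

.repulsion_grad <- function(par, n) {
  u <- matrix(par, n, 3)
  nr <- sqrt(rowSums(u^2))
  x <- u / nr
  gx <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    oth <- x[-i, , drop = FALSE]
    dm <- sweep(-oth, 2, x[i, ], "+")          # x_i - x_j
    dp <- sweep(oth, 2, x[i, ], "+")           # x_i + x_j
    r1 <- sqrt(rowSums(dm^2)); r2 <- sqrt(rowSums(dp^2))
    gx[i, ] <- -colSums(dm / r1^3) - colSums(dp / r2^3)
  }
  # chain rule through normalization: du = (I - x x^T)/|u| dx
  g <- (gx - x * rowSums(gx * x)) / nr
  as.numeric(g)
}

#' Generate isotropically distributed gradient directions
#'
#' Electrostatic-repulsion optimization of `n` antipodal point pairs on the
#' sphere: minimises the Coulomb energy `sum 1/|xi - xj| + 1/|xi + xj|` by
#' quasi-Newton descent from a seeded random start. Deterministic given the
#' seed. For `n = 6` this recovers the icosahedral arrangement (minimum
#' pairwise angle above 60 degrees).
#'
#' @param n Number of directions (>= 6).
#' @param seed Integer seed for the random initialisation.
#' @param n_lowb Low-b volume count stored in the scheme.
#' @param restarts Number of seeded restarts; the lowest-energy solution is
#'   returned.
#' @return A [direction_scheme()] with attribute `energy`.
#' @examples
#' sch <- generate_directions(6, seed = 1)
#' min_pairwise_angle(sch$vectors)    # > 60 degrees
#' @export
generate_directions <- function(n, seed = 1L, n_lowb = 0L, restarts = 1L) {
  if (n < 6) stop("n must be >= 6 for a usable diffusion scheme")
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(seed + r - 1L)
    u0 <- matrix(stats::rnorm(3 * n), n, 3)
    opt <- stats::optim(as.numeric(u0), .repulsion_energy, .repulsion_grad,
                        n = n, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  x <- matrix(best$par, n, 3)
  x <- x / sqrt(rowSums(x^2))
  # canonical hemisphere (z >= 0, ties by y then x) for reproducibility
  flip <- x[, 3] < 0 | (x[, 3] == 0 & x[, 2] < 0)
  x[flip, ] <- -x[flip, ]
  structure(direction_scheme(x, n_lowb = n_lowb), energy = best$value)
}

#' Read gradient tables in the bvec/bval dialect
#'
#' `bvec` files hold one whitespace-separated row per coordinate (3 rows,
#' one column per volume); `bval` files hold a single row of b-values.
#' Volumes whose b-value is below `lowb_threshold` are treated as low-b
#' volumes and removed from the direction set.
#'
#' @param bvec_path,bval_path File paths.
#' @param lowb_threshold b-values at or below this are low-b, s/mm^2.
#' @return A list with `scheme` ([direction_scheme()]), `bvals` (all
#'   b-values in file order) and `lowb_index`.
#' @seealso [write_bvec_bval()]
#' @export
read_bvec_bval <- function(bvec_path, bval_path, lowb_threshold = 100) {
  bvec <- as.matrix(utils::read.table(bvec_path))
  if (nrow(bvec) != 3) stop("bvec file must have exactly 3 rows")
  bval <- as.numeric(utils::read.table(bval_path)[1, ])
  if (length(bval) != ncol(bvec))
    stop("bvec (", ncol(bvec), " volumes) and bval (", length(bval),
         ") disagree")
  low <- bval <= lowb_threshold
  vec <- t(bvec[, !low, drop = FALSE])
  vec <- vec / sqrt(rowSums(vec^2))
  list(scheme = direction_scheme(vec, n_lowb = sum(low)),
       bvals = bval, lowb_index = which(low))
}

#' Write gradient tables in the bvec/bval dialect
#'
#' Low-b volumes are written first with direction (0, 0, 0) and b-value
#' `lowb`, followed by the diffusion-weighted directions at b-value `b`.
#'
#' @param scheme A [direction_scheme()].
#' @param bvec_path,bval_path Output paths.
#' @param b Nominal b-value of the weighted volumes, s/mm^2.
#' @param lowb b-value recorded for the low-b volumes.
#' @return Invisibly, a list of the two paths.
#' @export
write_bvec_bval <- function(scheme, bvec_path, bval_path, b = 4500,
                            lowb = 0) {
  stopifnot(inherits(scheme, "direction_scheme"))
  nl <- scheme$n_lowb
  vec <- rbind(matrix(0, nl, 3), scheme$vectors)
  bval <- c(rep(lowb, nl), rep(b, nrow(scheme$vectors)))
  lines <- apply(t(vec), 1, function(row)
    paste(format(row, digits = 10, trim = TRUE), collapse = " "))
  writeLines(lines, bvec_path)
  writeLines(paste(format(bval, trim = TRUE), collapse = " "), bval_path)
  invisible(list(bvec = bvec_path, bval = bval_path))
}
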