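#' Solver specification for abundance estimation
#'
#' Selects the algorithm used to express a measured spectrum as a
#' combination of library end-members: `"lstsq"` (unconstrained normal
#' equations with clip-and-renormalize), `"nnls"` (nonnegative least
#' squares, Lawson--Hanson active set), `"fcls"` (fully constrained: both
#' nonnegativity and sum-to-one enforced jointly), or `"nmf"`
#' (multiplicative-update factorization with the spectra matrix held fixed).
#'
#' @param name One of `"lstsq"`, `"nnls"`, `"fcls"`, `"nmf"`.
#' @param tol Convergence / clipping tolerance.
#' @param max_iter Iteration cap for the iterative solvers.
#' @param seed RNG seed, used by `"nmf"` initialisation only.
#' @return An object of class `solver_spec`.
#' @export
solver_spec <- function(name = c("lstsq", "nnls", "fcls", "nmf"),
                        tol = 1e-10, max_iter = 500L, seed = 1L) {
  name <- match.arg(name)
  structure(list(name = name, tol = tol, max_iter = as.integer(max_iter),
                 seed = as.integer(seed)),
            class = "solver_spec")
}

# Lawson-Hanson active-set nonnegative least squares: min ||Ax - b||, x >= 0
nnls_lh <- function(A, b, tol = 1e-10, max_iter = 10L * ncol(A)) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      Ap <- A[, passive, drop = FALSE]
      z[passive] <- qr.coef(qr(Ap), b)
      z[is.na(z)] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > tol
      x[!passive] <- 0
      if (!any(passive)) { x <- numeric(n); break }
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}

# fully constrained least squares via the augmented-row NNLS trick:
# append delta * 1^T to A and delta to b so the sum-to-one constraint is
# enforced (in the large-delta limit) jointly with nonnegativity
fcls_solve <- function(A, b, tol = 1e-10) {
  # abundances are scale-invariant; solving on the unit-sum spectrum keeps
  # the sum-to-one row commensurate with the data rows
  if (sum(b) > 0) b <- b / sum(b)
  delta <- 1e3 * max(abs(A))
  Aa <- rbind(A, delta)
  ba <- c(b, delta)
  x <- nnls_lh(Aa, ba, tol = tol)
  s <- sum(x)
  if (s > 0) x / s else x
}

# multiplicative-update NMF with the spectra matrix fixed: only the
# abundance vector is updated, x <- x * (A^T b) / (A^T A x). With the
# spectra held fixed the subproblem is a nonnegative least-squares program,
# whose zero components decay only as O(1/k) under multiplicative updates;
# the iteration therefore identifies the support and an exact active-set
# polish (refit on the support, then Kuhn-Tucker completion re-admitting
# any pruned component with positive gradient) finishes convergence.
nmf_solve <- function(A, b, tol = 1e-10, max_iter = 500L) {
  n <- ncol(A)
  x <- rep(sum(b) / max(n, 1), n)
  if (sum(b) == 0) return(numeric(n))
  AtA <- crossprod(A)
  Atb <- crossprod(A, b)
  for (k in seq_len(max_iter)) {
    denom <- AtA %*% x
    xn <- x * as.vector(Atb) / pmax(as.vector(denom), 1e-300)
    if (max(abs(xn - x)) < tol * max(1, max(x))) { x <- xn; break }
    x <- xn
  }
  supp <- x > 1e-4 * sum(x)
  refit <- function(supp) {
    xp <- numeric(n)
    if (any(supp))
      xp[supp] <- nnls_lh(A[, supp, drop = FALSE], b, tol = tol)
    xp
  }
  x <- refit(supp)
  for (k in seq_len(n)) {
    w <- as.vector(Atb - AtA %*% x)
    viol <- !supp & w > max(tol, 1e-9 * max(abs(Atb)))
    if (!any(viol)) break
    supp[which.max(ifelse(viol, w, -Inf))] <- TRUE
    x <- refit(supp)
  }
  x
}

# vectorised unweighted normal-equation solve for many spectra at once:
# S is n-by-c (rows = spectra), returns n-by-i raw (unclipped) coefficients
lstsq_batch <- function(S, lib) {
  A <- lib$spectra                      # i x c
  G <- tcrossprod(A)                    # i x i normal matrix
  if (nrow(A) > 1L) {
    k <- kappa(G, exact = FALSE)
    if (!is.finite(k) || k > 1e12)
      stop(sprintf("rank-deficient library (condition number %.3g)", k))
  }
  rhs <- A %*% t(S)                     # i x n
  t(solve(G, rhs))                      # n x i
}

# clip negatives to zero and renormalize rows to sum 1; all-zero rows kept
clip_renorm <- function(R) {
  R[R < 0] <- 0
  s <- rowSums(R)
  pos <- s > 0
  R[pos, ] <- R[pos, , drop = FALSE] / s[pos]
  R
}

#' Solve end-member abundance ratios for one spectrum
#'
#' Expresses a measured spectrum as a linear combination of the library's
#' end-member spectra and returns the abundance ratios `R_i`, which sum to 1
#' where the spectrum carries signal. The model assumes identical weights
#' for all end-members and low additive noise; `"lstsq"` solves the
#' unweighted normal equations and then clips negative components to zero
#' and renormalizes, the constrained solvers enforce nonnegativity (and for
#' `"fcls"` the sum-to-one constraint) during the fit.
#'
#' @param spectrum Numeric length-`c` vector of intensities (DL).
#' @param lib A normalized [spectral_library()].
#' @param solver A [solver_spec()].
#' @return Numeric length-`i` vector of ratios (named by end-member). An
#'   all-zero spectrum (or one whose fit clips to nothing) returns all
#'   zeros with attribute `flagged = TRUE`.
#' @examples
#' lib <- default_library()
#' r <- solve_ratios(0.3 * lib$spectra[1, ] + 0.7 * lib$spectra[2, ], lib)
#' round(r, 6)
#' @export
solve_ratios <- function(spectrum, lib, solver = solver_spec("lstsq")) {
  stopifnot(inherits(lib, "spectral_library"))
  if (!lib$normalized) stop("library must be normalized; see normalize_library()")
  if (length(spectrum) != ncol(lib$spectra))
    stop("axis mismatch: spectrum length != library channels")
  A <- t(lib$spectra)                  # c x i
  x <- switch(solver$name,
    lstsq = as.vector(lstsq_batch(matrix(spectrum, nrow = 1), lib)),
    nnls  = nnls_lh(A, spectrum, tol = solver$tol),
    fcls  = fcls_solve(A, spectrum, tol = solver$tol),
    nmf   = nmf_solve(A, spectrum, tol = solver$tol,
                      max_iter = solver$max_iter)
  )
  x[x < 0] <- 0
  s <- sum(x)
  flagged <- s <= 0
  if (!flagged) x <- x / s
  names(x) <- lib$names
  if (flagged) attr(x, "flagged") <- TRUE
  x
}

# internal: ratios for an n-by-c matrix of spectra; lstsq is fully
# vectorised, the constrained solvers loop (they are reference
# implementations used at bin scale or in tests)
solve_ratios_matrix <- function(S, lib, solver = solver_spec("lstsq")) {
  nz <- rowSums(S) > 0
  R <- matrix(0, nrow(S), nrow(lib$spectra),
              dimnames = list(NULL, lib$names))
  if (!any(nz)) return(R)
  if (solver$name == "lstsq") {
    R[nz, ] <- clip_renorm(lstsq_batch(S[nz, , drop = FALSE], lib))
  } else {
    A <- t(lib$spectra)
    fn <- switch(solver$name,
      nnls = function(b) nnls_lh(A, b, tol = solver$tol),
      fcls = function(b) fcls_solve(A, b, tol = solver$tol),
      nmf  = function(b) nmf_solve(A, b, tol = solver$tol,
                                   max_iter = solver$max_iter))
    idx <- which(nz)
    out <- t(vapply(idx, function(r) fn(S[r, ]), numeric(nrow(lib$spectra))))
    R[idx, ] <- clip_renorm(out)
  }
  R
}
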