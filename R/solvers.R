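#' Solver parameters for the axial inverse problem
#'
#' The per-pixel problem is `min 0.5 ||A f - b||^2 + mu ||f||_1` subject to
#' `f >= 0`. `mu` is specified relative to `||A' b||_inf` so one value works
#' across brightness scales; `mu = 0` gives plain non-negative least
#' squares. Internally the columns of `A` are l2-normalized (compensated on
#' output), which improves conditioning and means `mu` acts on the
#' normalized-column scale.
#'
#' @param mu l1 weight relative to `||A' b||_inf` (>= 0); used when
#'   `mu_mode = "relative"`.
#' @param mu_mode `"relative"` (mu scales with the data) or `"sigma"`
#'   (noise-calibrated universal threshold `sigma sqrt(2 log M)` per pixel,
#'   with sigma the additive-noise sd; requires a sigma estimate at solve
#'   time and falls back to `"relative"` without one). The sigma mode
#'   suppresses spurious deep-bin mass on dim pixels without hand tuning.
#' @param rho initial ADMM penalty (> 0); adapted by residual balancing.
#' @param max_iter iteration cap.
#' @param tol relative primal/dual residual tolerance.
#' @param solver `"admm"` (default), `"grad"` (projected accelerated
#'   gradient) or `"nnls"` (active-set non-negative least squares; ignores
#'   `mu`).
#' @return An object of class `solver_params`.
#' @export
solver_params <- function(mu = 0.01, rho = 1, max_iter = 500, tol = 1e-6,
                          solver = c("admm", "grad", "nnls"),
                          mu_mode = c("relative", "sigma")) {
  solver <- match.arg(solver)
  mu_mode <- match.arg(mu_mode)
  stopifnot(mu >= 0, rho > 0, tol > 0, max_iter >= 1)
  structure(list(mu = mu, rho = rho, max_iter = max_iter, tol = tol,
                 solver = solver, mu_mode = mu_mode),
            class = "solver_params")
}

# l2-normalize columns; returns list(an, scale)
.normalize_columns <- function(a) {
  s <- sqrt(colSums(a^2))
  s[s == 0] <- 1
  list(an = sweep(a, 2, s, "/"), scale = s)
}

# Batched ADMM for min 0.5||An f - b||^2 + mu |f|_1, f >= 0, over P columns
# of B (K x P). mu_abs is a length-P vector of absolute l1 weights on the
# normalized scale. Per-column penalty adaptation and convergence so each
# column's trajectory is independent of the others.
.admm_core <- function(an, b, mu_abs, rho0, max_iter, tol, alpha = 1.8) {
  m <- ncol(an)
  p <- ncol(b)
  ata <- crossprod(an)
  atb <- crossprod(an, b)                    # M x P
  f <- g <- u <- matrix(0, m, p)
  rho <- rep(rho0, p)
  iters <- integer(p)
  converged <- rep(FALSE, p)
  chol_cache <- new.env(parent = emptyenv())
  chol_for <- function(r) {
    key <- format(r, digits = 17)
    if (is.null(chol_cache[[key]]))
      chol_cache[[key]] <- chol(ata + diag(r, m))
    chol_cache[[key]]
  }
  active <- seq_len(p)
  for (it in seq_len(max_iter)) {
    if (!length(active)) break
    rhs <- atb[, active, drop = FALSE] +
      sweep(g[, active, drop = FALSE] - u[, active, drop = FALSE],
            2, rho[active], "*")
    fa <- matrix(0, m, length(active))
    for (r in unique(rho[active])) {
      cols <- which(rho[active] == r)
      ch <- chol_for(r)
      fa[, cols] <- backsolve(ch, forwardsolve(t(ch),
                                               rhs[, cols, drop = FALSE]))
    }
    f[, active] <- fa
    gprev <- g[, active, drop = FALSE]
    # over-relaxation accelerates the splitting on ill-conditioned systems
    fr <- alpha * fa + (1 - alpha) * gprev
    thr <- sweep(matrix(1, m, length(active)), 2,
                 mu_abs[active] / rho[active], "*")
    ga <- pmax(fr + u[, active, drop = FALSE] - thr, 0)
    g[, active] <- ga
    u[, active] <- u[, active, drop = FALSE] + fr - ga
    # per-column scaled residuals
    rnorm <- sqrt(colSums((fa - ga)^2))
    rden <- pmax(sqrt(colSums(fa^2)), sqrt(colSums(ga^2)), 1e-12)
    snorm <- rho[active] * sqrt(colSums((ga - gprev)^2))
    sden <- pmax(rho[active] * sqrt(colSums(u[, active, drop = FALSE]^2)),
                 1e-12)
    rs <- rnorm / rden
    ss <- snorm / sden
    iters[active] <- it
    done <- rs < tol & ss < tol
    # residual balancing (only for columns that continue)
    up <- !done & rs > 10 * ss & rho[active] < 1e4
    dn <- !done & ss > 10 * rs & rho[active] > 1e-4
    if (any(up)) {
      cols <- active[up]
      rho[cols] <- rho[cols] * 2
      u[, cols] <- u[, cols, drop = FALSE] / 2
    }
    if (any(dn)) {
      cols <- active[dn]
      rho[cols] <- rho[cols] / 2
      u[, cols] <- u[, cols, drop = FALSE] * 2
    }
    converged[active[done]] <- TRUE
    active <- active[!done]
  }
  # the non-negative, thresholded copy is the returned solution
  list(f = g, iterations = iters, converged = converged)
}

.axial_profile <- function(f, an, scale, b, mu_abs, iterations, converged) {
  res <- sqrt(sum((an %*% f - b)^2))
  structure(list(f = as.numeric(f / scale), residual_norm = res,
                 objective = 0.5 * res^2 + mu_abs * sum(abs(f)),
                 iterations = iterations, converged = converged),
            class = "axial_profile")
}

#' Solve the axial profile of one pixel
#'
#' Inverts the per-pixel multi-angle intensity decay `b` against the
#' angle-by-depth system matrix: non-negative, l1-regularized least squares.
#' The default solver is ADMM with the splitting `f = g`, `g >= 0`
#' soft-thresholded, and residual-balanced penalty adaptation.
#'
#' @param b length-K vector of background-subtracted intensities, one per
#'   incidence angle. Small negative entries are clamped to zero.
#' @param a a `system_matrix` (or plain K x M matrix).
#' @param params a [solver_params()].
#' @param sigma additive-noise sd of the entries of `b`, used by
#'   `mu_mode = "sigma"` (see [solver_params()]); ignored otherwise.
#' @return An object of class `axial_profile`: `f` (length-M non-negative
#'   weights on the axial grid), `residual_norm`, `objective`,
#'   `iterations`, `converged`.
#' @export
solve_pixel <- function(b, a, params = solver_params(), sigma = NULL) {
  amat <- if (inherits(a, "system_matrix")) a$a else a
  b <- as.numeric(b)
  if (any(!is.finite(b))) stop("non-finite entries in b")
  if (length(b) != nrow(amat))
    stop("length(b) must equal the number of angles (rows of A)")
  b <- pmax(b, 0)
  m <- ncol(amat)
  if (all(b == 0))
    return(structure(list(f = numeric(m), residual_norm = 0, objective = 0,
                          iterations = 0L, converged = TRUE),
                     class = "axial_profile"))
  nc <- .normalize_columns(amat)
  mu_abs <- if (identical(params$mu_mode, "sigma") && !is.null(sigma) &&
                is.finite(sigma))
    sigma * sqrt(2 * log(m))
  else params$mu * max(abs(crossprod(nc$an, b)))
  if (params$solver == "admm") {
    out <- .admm_core(nc$an, matrix(b), mu_abs, params$rho,
                      params$max_iter, params$tol)
    .axial_profile(out$f[, 1], nc$an, nc$scale, b, mu_abs,
                   out$iterations[1], out$converged[1])
  } else if (params$solver == "grad") {
    solve_gradient_descent(b, a, params)
  } else {
    f <- pracma::lsqnonneg(nc$an, b)$x
    .axial_profile(f, nc$an, nc$scale, b, 0, NA_integer_, TRUE)
  }
}

#' Projected accelerated gradient solver (comparison solver)
#'
#' Solves the same non-negative l1-regularized least-squares objective as
#' [solve_pixel()] by accelerated projected gradient descent (FISTA with
#' restart on objective increase). On the non-negative orthant the l1 term
#' is linear, so the objective is smooth there and a fixed `1/L` step with
#' projection converges; persistent objective increase triggers step
#' halving and, past a floor, an error.
#'
#' @param b length-K data vector.
#' @param a a `system_matrix` or K x M matrix.
#' @param params a [solver_params()]; `max_iter` is interpreted more
#'   generously (first-order method), capped at `50 * max_iter`.
#' @return An `axial_profile`.
#' @export
solve_gradient_descent <- function(b, a, params = solver_params()) {
  amat <- if (inherits(a, "system_matrix")) a$a else a
  b <- pmax(as.numeric(b), 0)
  if (any(!is.finite(b))) stop("non-finite entries in b")
  m <- ncol(amat)
  if (all(b == 0))
    return(structure(list(f = numeric(m), residual_norm = 0, objective = 0,
                          iterations = 0L, converged = TRUE),
                     class = "axial_profile"))
  nc <- .normalize_columns(amat)
  an <- nc$an
  atb <- as.numeric(crossprod(an, b))
  mu_abs <- params$mu * max(abs(atb))
  ata <- crossprod(an)
  step <- 1 / max(eigen(ata, symmetric = TRUE, only.values = TRUE)$values)
  obj <- function(f) {
    r <- an %*% f - b
    0.5 * sum(r^2) + mu_abs * sum(f)
  }
  f <- numeric(m); y <- f; t_acc <- 1
  o_prev <- obj(f)
  bad <- 0L
  max_iter <- 50L * params$max_iter
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    grad <- as.numeric(ata %*% y) - atb + mu_abs
    f_new <- pmax(y - step * grad, 0)
    o <- obj(f_new)
    if (o > o_prev + 1e-15) {
      bad <- bad + 1L
      if (bad >= 10L) {
        step <- step / 2
        if (step < 1e-16) stop("gradient descent diverged")
        bad <- 0L
      }
      # restart acceleration
      t_acc <- 1; y <- f
      next
    }
    bad <- 0L
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    y <- f_new + ((t_acc - 1) / t_new) * (f_new - f)
    if (sqrt(sum((f_new - f)^2)) <=
        params$tol * max(sqrt(sum(f_new^2)), 1e-12) &&
        abs(o_prev - o) <= params$tol * max(o, 1e-15)) {
      f <- f_new
      converged <- TRUE
      break
    }
    f <- f_new; t_acc <- t_new; o_prev <- o
  }
  if (!converged)
    warning("gradient solver did not converge within ", max_iter,
            " iterations")
  .axial_profile(f, an, nc$scale, b, mu_abs, it, converged)
}
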