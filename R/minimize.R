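# Gradient minimizers: steepest descent with golden-section line search
# and Polak-Ribiere conjugate gradients. Both operate on an abstract
# "system" (objective + gradient + optional per-term breakdown), which
# keeps them testable on analytic functions and reusable for the
# molecular energy model. Minimization is fully deterministic.

GOLD <- (sqrt(5) - 1) / 2  # 0.618...

#' Golden-section search for a scalar minimum
#'
#' Narrows a valid bracket (a, b, c) with f(b) < f(a) and f(b) < f(c)
#' until its width is below \code{tol} and returns the abscissa of the
#' best point.
#'
#' @param f Scalar function.
#' @param bracket Numeric vector (a, b, c), a < b < c.
#' @param tol Absolute tolerance on the argument.
#' @return Approximate argmin.
#' @export
golden_section_search <- function(f, bracket, tol = 1e-6) {
  a <- bracket[1]; b <- bracket[2]; cc <- bracket[3]
  if (!(a < b && b < cc))
    stop("invalid bracket: need a < b < c", call. = FALSE)
  fa <- f(a); fb <- f(b); fc <- f(cc)
  if (!(fb < fa && fb < fc))
    stop("invalid bracket: f(b) must be below f(a) and f(c)",
         call. = FALSE)
  # seed the two interior points from the wider side
  repeat {
    if (cc - a < tol) break
    if (b - a > cc - b) {
      x <- b - (1 - GOLD) * (b - a)
      fx <- f(x)
      if (fx < fb) { cc <- b; fc <- fb; b <- x; fb <- fx }
      else { a <- x; fa <- fx }
    } else {
      x <- b + (1 - GOLD) * (cc - b)
      fx <- f(x)
      if (fx < fb) { a <- b; fa <- fb; b <- x; fb <- fx }
      else { cc <- x; fc <- fx }
    }
  }
  # centered parabolic refinement: golden-section alone can only locate a
  # smooth minimum to ~sqrt(machine eps) by value comparisons; one
  # three-point parabola at a wider, noise-robust spacing recovers nearly
  # full precision (exact for quadratics)
  h <- .Machine$double.eps^0.25 * max(abs(b), 1e-3)
  fm <- f(b - h); fp <- f(b + h)
  den <- fm - 2 * fb + fp
  if (is.finite(den) && den > 0) {
    xp <- b + 0.5 * h * (fm - fp) / den
    if (is.finite(xp) && abs(xp - b) <= h) return(xp)
  }
  b
}

# bracket a minimum of f along t >= 0 starting from f(0); returns NULL if
# no decrease can be found down to the smallest trial step, or a capped
# step when the cap is reached while still descending
bracket_minimum <- function(f1d, f0, step0 = 1e-4, growth = 2, cap = 1.0) {
  t <- step0
  ft <- f1d(t)
  while (!is.finite(ft) || ft >= f0) {
    t <- t / 2
    if (t < 1e-12) return(NULL)
    ft <- f1d(t)
  }
  a <- 0
  b <- t; fb <- ft
  repeat {
    if (b >= cap * (1 - 1e-12))
      return(list(cap_hit = TRUE, t = b))
    cc <- min(b * growth, cap)
    fc <- f1d(cc)
    if (!is.finite(fc) || fc >= fb)
      return(list(a = a, b = b, c = cc))
    a <- b
    b <- cc; fb <- fc
  }
}

line_search <- function(f1d, f0, cfg) {
  br <- bracket_minimum(f1d, f0, growth = cfg$bracket_growth,
                        cap = cfg$ls_cap)
  if (is.null(br)) return(0)
  if (isTRUE(br$cap_hit)) return(br$t)
  golden_section_search(f1d, c(br$a, br$b, br$c), tol = cfg$gs_tol)
}

rms_grad <- function(g) sqrt(mean(g^2))

run_minimizer <- function(system, config, method) {
  cfg <- merge_config(config)
  x <- as.numeric(system$x0)
  f <- system$f; gr <- system$g
  breakdown <- if (!is.null(system$breakdown)) system$breakdown
               else function(x) c(total = f(x))
  trace <- list(breakdown(x))
  fx <- sum(trace[[1]][length(trace[[1]])])
  if (!is.finite(fx)) stop("non-finite energy at iteration 0",
                           call. = FALSE)
  g <- gr(x)
  termination <- "max_steps"
  iter <- 0L
  d_old <- NULL; g_old <- NULL
  dim_n <- length(x)
  since_restart <- 0L
  for (it in seq_len(cfg$max_steps)) {
    gn <- rms_grad(g)
    if (gn <= cfg$grad_tol) { termination <- "converged"; break }
    if (method == "sd" || is.null(d_old) || since_restart >= dim_n) {
      d <- -g
      since_restart <- 0L
    } else {
      beta <- max(0, sum(g * (g - g_old)) / sum(g_old * g_old))
      d <- -g + beta * d_old
      if (sum(d * g) >= 0) { d <- -g; since_restart <- 0L }  # restart
    }
    since_restart <- since_restart + 1L
    dn <- sqrt(sum(d * d))
    if (dn == 0) { termination <- "converged"; break }
    du <- d / dn
    f1d <- function(t) f(x + t * du)
    alpha <- line_search(f1d, fx, cfg)
    if (alpha == 0) { termination <- "converged"; break }
    x_new <- x + alpha * du
    fx_new <- f(x_new)
    if (!is.finite(fx_new))
      stop("divergence: non-finite energy at iteration ", it,
           call. = FALSE)
    if (fx_new > fx + 1e-8) { termination <- "converged"; break }
    x <- x_new; fx <- fx_new
    g_old <- g; d_old <- d
    g <- gr(x)
    iter <- it
    trace[[length(trace) + 1L]] <- breakdown(x)
  }
  tr <- do.call(rbind, trace)
  res <- list(x = x, trace = tr, termination = termination,
              iterations = iter, grad_norm = rms_grad(g),
              energy = fx)
  class(res) <- "minimization_result"
  res
}

#' Steepest-descent minimization with golden-section line search
#'
#' Moves along the negative gradient; the step length is found by growing
#' a bracket geometrically from a small trial step (capped at 1 Angstrom)
#' and refining it by golden-section search. The energy trace is
#' non-increasing; iteration stops when the RMS gradient drops below
#' \code{grad_tol} or after \code{max_steps}.
#'
#' @param system List with \code{f} (objective), \code{g} (gradient),
#'   \code{x0} (start) and optional \code{breakdown} (per-term energies
#'   for the trace).
#' @param config Configuration (see \code{\link{default_config}}); only
#'   the minimizer keys are used.
#' @return A \code{minimization_result}: final \code{x}, per-iteration
#'   \code{trace}, \code{termination} ("converged" or "max_steps") and
#'   \code{iterations}.
#' @export
minimize_sd <- function(system, config = list()) {
  run_minimizer(system, config, "sd")
}

#' Polak-Ribiere conjugate-gradient minimization
#'
#' Conjugate directions with the Polak-Ribiere beta clamped at zero
#' (restarting on negative beta); the direction is also reset to steepest
#' descent whenever it is not a descent direction or every \code{dim}
#' iterations. Same line search and termination contract as
#' \code{\link{minimize_sd}}.
#'
#' @inheritParams minimize_sd
#' @return A \code{minimization_result}.
#' @export
minimize_prcg <- function(system, config = list()) {
  run_minimizer(system, config, "prcg")
}

#' @export
print.minimization_result <- function(x, ...) {
  cat("Minimization: ", x$iterations, " iterations, ", x$termination,
      "\n", sep = "")
  cat("  final energy: ", format(x$energy), "  RMS gradient: ",
      format(x$grad_norm), "\n", sep = "")
  invisible(x)
}
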