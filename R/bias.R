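#' Metadynamics bias potentials as Gaussian kernel sums
#'
#' A bias potential is an ordered list of deposited Gaussian kernels over
#' the (1- or 2-D) information-bottleneck coordinates:
#' `V(s) = sum_k h_k exp(-sum_d (s_d - c_kd)^2 / (2 sigma_kd^2))`, energies
#' in kBT.  The kernel list is the exact representation (so serialization
#' round-trips bit-exactly); a grid cache is used only inside the dynamics
#' engine for per-step forces.  Once `freeze()`d, the kernel list is
#' immutable and the bias can be reused as a static Hamiltonian term.
#'
#' @param centers Kernel centers, matrix (kernels in rows) with `ds`
#'   columns.
#' @param sigmas Kernel widths, same shape as `centers` (all > 0).
#' @param heights Kernel heights in kBT (all >= 0).
#' @param times Optional deposit step indices.
#' @param walker Optional depositing-walker ids.
#' @param bias_factor Well-tempered bias factor gamma (> 1).
#' @param frozen Is the bias immutable?
#' @param ds Dimension of the biased coordinates (inferred from `centers`
#'   when kernels are present).
#' @return A `bias_potential` object.
#' @export
bias_potential <- function(centers = NULL, sigmas = NULL, heights = NULL,
                           times = NULL, walker = NULL, bias_factor = 10,
                           frozen = FALSE, ds = NULL) {
  if (is.null(centers)) {
    if (is.null(ds)) stop("empty bias needs explicit ds")
    centers <- matrix(numeric(0), 0, ds)
    sigmas <- matrix(numeric(0), 0, ds)
    heights <- numeric(0)
  }
  centers <- as.matrix(centers)
  sigmas <- as.matrix(sigmas)
  heights <- as.numeric(heights)
  if (is.null(ds)) ds <- ncol(centers)
  stopifnot(ncol(centers) == ds, ncol(sigmas) == ds,
            nrow(centers) == length(heights), nrow(sigmas) == length(heights))
  if (any(sigmas <= 0)) stop("kernel widths must be > 0")
  if (any(heights < 0)) stop("kernel heights must be >= 0")
  structure(list(centers = centers, sigmas = sigmas, heights = heights,
                 times = times, walker = walker, bias_factor = bias_factor,
                 frozen = isTRUE(frozen), ds = ds),
            class = "bias_potential")
}

#' Evaluate a bias potential
#'
#' Exact Gaussian kernel sum (no truncation) at one or many points; an
#' empty bias evaluates to 0 everywhere.
#'
#' @param bias A [bias_potential()].
#' @param s Point (length-`ds` vector) or matrix of points (rows).
#' @return Numeric vector of bias energies in kBT.
#' @export
evaluate_bias <- function(bias, s) {
  stopifnot(inherits(bias, "bias_potential"))
  if (is.null(dim(s))) {
    s <- if (length(s) == bias$ds) matrix(s, nrow = 1)
         else if (bias$ds == 1L) matrix(s, ncol = 1)
         else stop("s must be a length-", bias$ds, " vector or a matrix")
  }
  s <- as.matrix(s)
  stopifnot(ncol(s) == bias$ds, all(is.finite(s)))
  if (length(bias$heights) == 0L) return(numeric(nrow(s)))
  cpp_eval_bias(bias$centers, bias$sigmas, bias$heights, s)
}

#' Deposit a well-tempered Gaussian kernel
#'
#' Appends one kernel at `s` with the well-tempered height
#' `w0 * exp(-V(s) / ((gamma - 1) kBT))`, so heights decay as the local
#' bias accumulates and the total bias stays bounded.
#'
#' @param bias A non-frozen [bias_potential()].
#' @param s Deposit location (length-`ds`).
#' @param w0 Initial Gaussian height in kBT.
#' @param sigma Kernel widths (length-`ds`).
#' @param gamma Bias factor (> 1); default the bias's own.
#' @param kBT Thermal energy (default 1).
#' @param time Optional step index recorded with the kernel.
#' @return The updated `bias_potential`.
#' @export
deposit <- function(bias, s, w0, sigma, gamma = bias$bias_factor, kBT = 1,
                    time = NA_real_) {
  stopifnot(inherits(bias, "bias_potential"))
  if (bias$frozen) stop("frozen-bias: cannot deposit on a frozen bias")
  stopifnot(gamma > 1, length(s) == bias$ds, length(sigma) == bias$ds)
  h <- w0 * exp(-evaluate_bias(bias, s) / ((gamma - 1) * kBT))
  bias_potential(centers = rbind(bias$centers, as.numeric(s)),
                 sigmas = rbind(bias$sigmas, as.numeric(sigma)),
                 heights = c(bias$heights, h),
                 times = c(bias$times, time),
                 walker = c(bias$walker, NA_integer_),
                 bias_factor = gamma, frozen = FALSE, ds = bias$ds)
}

#' Freeze a bias potential for static reuse
#'
#' Marks the kernel list immutable.  A frozen bias is a fixed Hamiltonian
#' term: dynamics run under it sample `exp(-(U + V))`, and unbiased
#' statistics are recovered with importance weights `exp(+V/kBT)` (see
#' [compute_weights()]).
#'
#' @param bias A [bias_potential()].
#' @return The same bias with `frozen = TRUE`.
#' @export
freeze <- function(bias) {
  stopifnot(inherits(bias, "bias_potential"))
  bias$frozen <- TRUE
  bias
}

#' First index at which a stop rule is satisfied
#'
#' The stop rule used for metadynamics walkers: halt at the first position
#' where the state label has equalled `target` for `window` consecutive
#' entries (the toy analogue of "stable for 1 ns").
#'
#' @param states Vector of state labels.
#' @param target Target label.
#' @param window Required consecutive run length (>= 1).
#' @return The 1-based index where the rule first holds, or `NA_integer_`.
#' @export
stop_index <- function(states, target, window) {
  stopifnot(window >= 1)
  run <- 0L
  for (i in seq_along(states)) {
    run <- if (identical(states[i], target) ||
               (!is.na(states[i]) && states[i] == target)) run + 1L else 0L
    if (run >= window) return(i)
  }
  NA_integer_
}

#' @export
print.bias_potential <- function(x, ...) {
  cat("bias potential: ", length(x$heights), " kernels over ", x$ds,
      "-D coordinates, gamma = ", x$bias_factor,
      if (x$frozen) " [frozen]" else "", "\n", sep = "")
  invisible(x)
}
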