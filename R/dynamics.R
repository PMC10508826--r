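#' Langevin (BAOAB) dynamics on a toy potential
#'
#' Unit-mass Langevin dynamics integrated with the BAOAB splitting scheme.
#' `run_baoab` is the unbiased engine used to generate seed trajectories;
#' the biased engine ([run_metad()]) uses the same scheme with the bias
#' force added.
#'
#' @param friction Friction coefficient (1/time, > 0).
#' @param temperature Thermal energy kBT (default 1; 0 gives gradient
#'   descent with inertia).
#' @param dt Integration step (> 0).
#' @param n_steps Number of steps.
#' @param stride Record every `stride` steps.
#' @param seed RNG seed (`NULL` leaves the RNG state alone).
#' @param guard Divergence guard: an error is raised if any coordinate
#'   exceeds this magnitude.
#' @return `langevin_config` returns the config list.
#' @export
langevin_config <- function(friction = 1, temperature = 1, dt = 0.01,
                            n_steps = 10000L, stride = 10L, seed = NULL,
                            guard = 1e4) {
  stopifnot(friction > 0, dt > 0, temperature >= 0, stride >= 1)
  structure(list(friction = friction, temperature = temperature, dt = dt,
                 n_steps = as.integer(n_steps), stride = as.integer(stride),
                 seed = seed, guard = guard),
            class = "langevin_config")
}

#' @rdname langevin_config
#' @param potential A [make_potential()] object.
#' @param cfg A `langevin_config`.
#' @param x0 Initial coordinates (length `potential$dim`).
#' @return `run_baoab` returns a data.frame with columns `step`, the
#'   coordinates, matching velocity columns, and `energy` (kBT).
#' @export
run_baoab <- function(potential, cfg = langevin_config(), x0) {
  stopifnot(inherits(potential, "toy_potential"),
            length(x0) == potential$dim, all(is.finite(x0)))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- cpp_baoab(potential$code, potential$par, as.numeric(x0),
                   cfg$dt, cfg$friction, cfg$temperature,
                   cfg$n_steps, cfg$stride, cfg$guard)
  cn <- coord_names(potential)
  out <- data.frame(step = res$steps)
  for (d in seq_len(potential$dim)) out[[cn[d]]] <- res$x[, d]
  for (d in seq_len(potential$dim)) out[[paste0("v_", cn[d])]] <- res$v[, d]
  out$energy <- res$energy
  out
}

coord_names <- function(potential) {
  if (potential$classifier == 2L) c("d1", "d2")
  else if (potential$dim == 1L) "x"
  else c("x", "y")
}

state_label_map <- function(potential) {
  if (potential$classifier == 1L) c("A", "B")
  else if (potential$classifier == 2L) dfg_states()
  else character(0)
}

# map C++ state codes (0-based; -1 = unclassified) to labels
decode_states <- function(codes, potential) {
  labs <- state_label_map(potential)
  if (length(labs) == 0L) return(factor(rep(NA_character_, length(codes))))
  factor(labs[codes + 1L], levels = labs)
}

#' Identity order-parameter model over a potential's coordinates
#'
#' Wraps the raw toy coordinates as a (trivial) linear IB model so the bias
#' engine can be driven either by a learned encoder or directly in
#' coordinate space.
#'
#' @param potential A `toy_potential`.
#' @return An `ib_model` whose encoder is the identity.
#' @export
identity_ib_model <- function(potential) {
  d <- potential$dim
  m <- list(W = diag(d), b = numeric(d), U = NULL, c = NULL,
            cv_names = coord_names(potential), n_states = NA_integer_,
            classes = state_label_map(potential), state_labels = NULL,
            history = NULL, lag = NA_integer_, cfg = NULL)
  class(m) <- "ib_model"
  m
}

#' Well-tempered metadynamics configuration
#'
#' Gaussian widths, initial height, pace and bias factor are unstated in
#' the protocol this package operationalizes; the defaults here (w0 = 1.2
#' kBT, pace = 500 steps, gamma = 10, widths 5% of the biased-coordinate
#' range) are package choices, logged with every run and overridable.
#'
#' @param w0 Initial Gaussian height (kBT).
#' @param sigma Kernel widths per biased dimension (`NULL`: 5% of the grid
#'   extent).
#' @param pace Steps between deposits.
#' @param bias_factor Well-tempered gamma (> 1).
#' @param n_walkers Number of walkers sharing the bias (default 5).
#' @param dt,friction,stride,guard Integrator settings (see
#'   [langevin_config()]).
#' @param max_steps Hard cap on biased run length.
#' @param window Stop-condition stability window in steps (toy analogue of
#'   "stable for 1 ns").
#' @param grid_bins Nodes per dimension of the bias grid cache used for
#'   per-step forces (interpolation tolerance shrinks with the node
#'   spacing; kernels are kept exact for serialization and reweighting).
#' @return A `metad_config` list.
#' @export
metad_config <- function(w0 = 1.2, sigma = NULL, pace = 500L,
                         bias_factor = 10, n_walkers = 5L, dt = 0.01,
                         friction = 1, stride = 10L, max_steps = 200000L,
                         window = 2000L, grid_bins = 501L, guard = 1e4) {
  stopifnot(bias_factor > 1, pace >= 1, w0 >= 0, window >= 1)
  structure(list(w0 = w0, sigma = sigma, pace = as.integer(pace),
                 bias_factor = bias_factor, n_walkers = as.integer(n_walkers),
                 dt = dt, friction = friction, stride = as.integer(stride),
                 max_steps = as.integer(max_steps), window = as.integer(window),
                 grid_bins = as.integer(grid_bins), guard = guard),
            class = "metad_config")
}

# bias-grid box in s-space: project the potential box through the encoder
# and pad, so deposits stay on-grid
s_grid_box <- function(potential, model, pad = 0.15) {
  box <- matrix(potential$box, nrow = 2)  # (lo,hi) x dim
  corners <- as.matrix(expand.grid(lapply(seq_len(ncol(box)), function(d)
    box[, d])))
  colnames(corners) <- model$cv_names
  s <- project(model, corners)
  lo <- apply(s, 2, min)
  hi <- apply(s, 2, max)
  span <- hi - lo
  list(lo = lo - pad * span, hi = hi + pad * span)
}

# per-walker stop targets: opposite main state, "either" (-2) when starting
# outside the two main states, -1 (no rule) for unclassified systems
auto_targets <- function(potential, x0) {
  if (potential$classifier == 0L) return(rep(-1L, nrow(x0)))
  st <- if (potential$classifier == 1L) {
    ifelse(x0[, 1] < 0, 0L, 1L)
  } else {
    as.integer(classify_dfg(x0[, 1], x0[, 2])) - 1L
  }
  ifelse(st == 0L, 1L, ifelse(st == 1L, 0L, -2L))
}

run_walkers_internal <- function(potential, model, x0, cfg, bias, frozen,
                                 targets, seed, halt_on_stop = TRUE) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(model, "ib_model"), inherits(cfg, "metad_config"))
  x0 <- as.matrix(x0)
  stopifnot(ncol(x0) == potential$dim, all(is.finite(x0)),
            all(is.finite(model$W)), all(is.finite(model$b)))
  ds <- nrow(model$W)
  grid <- s_grid_box(potential, model)
  sigma <- cfg$sigma
  if (is.null(sigma)) sigma <- 0.05 * (grid$hi - grid$lo)
  stopifnot(length(sigma) == ds)
  if (is.null(bias)) bias <- bias_potential(ds = ds,
                                            bias_factor = cfg$bias_factor)
  stopifnot(bias$ds == ds)
  if (frozen && !bias$frozen)
    stop("static runs require a frozen bias")
  if (!frozen && bias$frozen)
    stop("frozen-bias: cannot deposit on a frozen bias")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_run_walkers(potential$code, potential$par, x0,
                         model$W, model$b, frozen,
                         cfg$w0, sigma, cfg$pace, cfg$bias_factor,
                         bias$centers, bias$sigmas, bias$heights,
                         grid$lo, grid$hi,
                         rep(cfg$grid_bins, ds),
                         cfg$dt, cfg$friction, cfg$max_steps, cfg$stride,
                         potential$classifier, as.integer(targets),
                         cfg$window, cfg$guard, halt_on_stop)
  cn <- coord_names(potential)
  walkers <- lapply(res$traj, function(M) {
    df <- data.frame(step = M[, 1])
    for (d in seq_len(potential$dim)) df[[cn[d]]] <- M[, 1 + d]
    for (d in seq_len(ds)) df[[paste0("s", d)]] <- M[, 1 + potential$dim + d]
    df$bias <- M[, 2 + potential$dim + ds]
    df$state <- decode_states(as.integer(M[, 3 + potential$dim + ds]),
                              potential)
    df
  })
  n_old <- length(bias$heights)
  new_bias <- bias_potential(centers = res$centers, sigmas = res$sigmas,
                             heights = res$heights,
                             times = res$times, walker = res$walker,
                             bias_factor = cfg$bias_factor,
                             frozen = frozen, ds = ds)
  stop_steps <- ifelse(res$stop_step < 0, NA_integer_, res$stop_step)
  structure(list(walkers = walkers, bias = new_bias,
                 stop_steps = stop_steps,
                 converged = !is.na(stop_steps),
                 n_deposits = length(res$heights) - n_old,
                 targets = targets, cfg = cfg, frozen = frozen,
                 potential = potential$name, sigma = sigma, grid = grid),
            class = "walker_run")
}

#' Run well-tempered metadynamics walkers on the IB coordinates
#'
#' Multiple walkers share a single kernel list (deposits from every walker
#' repel all of them).  Each walker halts when its stop rule holds: having
#' started in one main metastable state it must reach the other and stay
#' there for `cfg$window` consecutive steps; walkers starting outside the
#' two main states must reach either one stably.  Walkers that exhaust
#' `cfg$max_steps` are flagged unconverged, not an error.
#'
#' @param potential A [make_potential()] object.
#' @param model Linear `ib_model` mapping coordinates to the biased s-space
#'   (default: identity).
#' @param x0 Matrix of start coordinates, one row per walker (default: the
#'   potential's basin minima, recycled over `cfg$n_walkers`).
#' @param cfg A [metad_config()].
#' @param bias Starting [bias_potential()] (default empty).  Passing a
#'   frozen bias turns the run into static-bias dynamics: the kernel list
#'   is used for forces but nothing is ever deposited.
#' @param targets Integer stop targets per walker (internal coding;
#'   default derived from each walker's start state).
#' @param seed RNG seed.
#' @return A `walker_run`: per-walker trajectories (coordinates, IB
#'   coordinates, bias at visit time, state), the shared bias, stop steps
#'   and convergence flags.
#' @export
run_metad <- function(potential, model = identity_ib_model(potential),
                      x0 = NULL, cfg = metad_config(), bias = NULL,
                      targets = NULL, seed = NULL) {
  if (is.null(x0)) {
    b <- potential$basins
    if (potential$classifier == 2L) b <- b[c("IN", "OUT"), , drop = FALSE]
    idx <- rep(seq_len(nrow(b)), length.out = cfg$n_walkers)
    x0 <- b[idx, , drop = FALSE]
  }
  x0 <- as.matrix(x0)
  if (is.null(targets)) targets <- auto_targets(potential, x0)
  if (length(targets) == 1L) targets <- rep(targets, nrow(x0))
  # a frozen bias turns the run into static-bias dynamics: no deposits
  frozen <- !is.null(bias) && isTRUE(bias$frozen)
  run_walkers_internal(potential, model, x0, cfg, bias, frozen = frozen,
                       targets = targets, seed = seed)
}

#' Transfer a frozen static bias to a (possibly perturbed) system
#'
#' Launches independent walkers under the same frozen bias from both main
#' basins of `potential` (e.g. a mutant analogue of the system the bias
#' was learned on) and runs each until it is stable in the basin it was
#' not initialized in, or the step cap.  The returned trajectories are the
#' input for static-bias reweighting.
#'
#' @param static_bias A frozen [bias_potential()].
#' @param potential Target system (same coordinate space as the bias).
#' @param model Linear IB model used when learning the bias.
#' @param cfg A [metad_config()] (deposit settings are ignored).
#' @param n_per_basin Walkers per starting basin.
#' @param seed RNG seed.
#' @param halt_on_stop Halt each walker once its stop rule holds
#'   (`TRUE`), or keep sampling to `cfg$max_steps` with the rule only
#'   recorded as the convergence flag (`FALSE`, the usual choice when the
#'   trajectories feed reweighting and more overlap is welcome).
#' @return A `walker_run` (no deposits; `bias` is the input bias).
#' @export
static_bias_transfer <- function(static_bias, potential,
                                 model = identity_ib_model(potential),
                                 cfg = metad_config(), n_per_basin = 3L,
                                 seed = NULL, halt_on_stop = FALSE) {
  stopifnot(inherits(static_bias, "bias_potential"))
  if (!static_bias$frozen) stop("static bias must be frozen")
  b <- potential$basins
  if (potential$classifier == 2L) b <- b[c("IN", "OUT"), , drop = FALSE]
  x0 <- b[rep(seq_len(nrow(b)), each = n_per_basin), , drop = FALSE]
  targets <- auto_targets(potential, x0)
  run_walkers_internal(potential, model, x0, cfg, static_bias, frozen = TRUE,
                       targets = targets, seed = seed,
                       halt_on_stop = halt_on_stop)
}

#' Well-tempered free-energy estimator
#'
#' Under well-tempered metadynamics the accumulated bias converges (up to
#' an additive constant) to `-(1 - 1/gamma) F(s)`, so the free energy is
#' estimated as `F_hat(s) = -(gamma/(gamma-1)) V(s)`.
#'
#' @param bias A [bias_potential()].
#' @param s Points at which to estimate (vector or matrix).
#' @param gamma Bias factor (default the bias's own).
#' @return Numeric vector `F_hat(s)` in kBT (additive constant arbitrary).
#' @export
wt_free_energy <- function(bias, s, gamma = bias$bias_factor) {
  stopifnot(gamma > 1)
  -(gamma / (gamma - 1)) * evaluate_bias(bias, s)
}

#' @export
print.walker_run <- function(x, ...) {
  cat("walker run on '", x$potential, "': ", length(x$walkers), " walker(s), ",
      sum(x$converged), " converged, ", x$n_deposits, " deposits",
      if (x$frozen) " [static bias]" else "", "\n", sep = "")
  invisible(x)
}
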