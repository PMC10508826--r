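#' Importance weights for static-bias trajectories
#'
#' A trajectory sampled under a frozen bias V(s) samples
#' `exp(-(U + V)/kBT)`; unbiased Boltzmann statistics are recovered with
#' per-frame weights `w_t = exp(+V(s_t)/kBT)`.  The maximum bias is
#' subtracted before exponentiation (a pure normalization shift, guarding
#' overflow) and weights are normalized to mean 1.  The effective sample
#' size `ESS = (sum w)^2 / sum w^2` is recorded.
#'
#' @param traj One walker trajectory (a data.frame from a [run_metad()]
#'   result
#'   with `s*` columns, or a matrix of IB coordinates).
#' @param bias The frozen [bias_potential()] the trajectory ran under.
#' @param kBT Thermal energy (default 1).
#' @param frames Optional matrix of frame coordinates carried along for
#'   histogramming/classification; defaults to the trajectory's coordinate
#'   columns when `traj` is a walker data.frame.
#' @return A `weighted_traj`: `frames`, `s`, `weights` (mean 1), `ess`,
#'   `kBT`.
#' @export
compute_weights <- function(traj, bias, kBT = 1, frames = NULL) {
  stopifnot(inherits(bias, "bias_potential"))
  if (!bias$frozen) stop("reweighting requires a frozen bias")
  if (is.data.frame(traj)) {
    scols <- grep("^s[0-9]+$", names(traj), value = TRUE)
    if (length(scols) != bias$ds)
      stop("trajectory has ", length(scols), " IB columns, bias has ds = ",
           bias$ds)
    s <- as.matrix(traj[, scols, drop = FALSE])
    if (is.null(frames)) {
      drop_cols <- c("step", scols, "bias", "state",
                     grep("^v_", names(traj), value = TRUE), "energy")
      frames <- as.matrix(traj[, setdiff(names(traj), drop_cols),
                               drop = FALSE])
    }
  } else {
    s <- as.matrix(traj)
    if (is.null(frames)) frames <- s
  }
  v <- evaluate_bias(bias, s)
  w <- exp((v - max(v)) / kBT)
  w <- w / mean(w)
  structure(list(frames = as.matrix(frames), s = s, weights = w,
                 ess = sum(w)^2 / sum(w^2), kBT = kBT),
            class = "weighted_traj")
}

#' Potential of mean force on the Dunbrack plane
#'
#' Weighted 2-D histogram of the frame coordinates converted to free
#' energies: `F_bin = -kBT log(sum of weights in bin)`, shifted so the
#' minimum over sampled bins is 0.  Bins with zero weight are `NA`
#' (unsampled), never zero energy.
#'
#' @param wtraj A [compute_weights()] result (or a list of them, pooled).
#' @param xbreaks,ybreaks Bin edges; default 0.25-Angstrom bins over
#'   6--20 Angstrom on each Dunbrack axis.
#' @param cols Which two frame columns to histogram (default 1:2).
#' @return A `pmf_grid`: bin edges, midpoints, `F` matrix (kBT, `NA` where
#'   unsampled), and the raw weight sums.
#' @export
pmf_2d <- function(wtraj, xbreaks = seq(6, 20, by = 0.25),
                   ybreaks = seq(6, 20, by = 0.25), cols = 1:2) {
  if (inherits(wtraj, "weighted_traj")) wtraj <- list(wtraj)
  kBT <- wtraj[[1]]$kBT
  wsum <- matrix(0, length(xbreaks) - 1L, length(ybreaks) - 1L)
  for (wt in wtraj) {
    x <- wt$frames[, cols[1]]
    y <- wt$frames[, cols[2]]
    ix <- findInterval(x, xbreaks, rightmost.closed = TRUE)
    iy <- findInterval(y, ybreaks, rightmost.closed = TRUE)
    ok <- ix >= 1 & ix <= nrow(wsum) & iy >= 1 & iy <= ncol(wsum)
    for (i in which(ok)) wsum[ix[i], iy[i]] <- wsum[ix[i], iy[i]] + wt$weights[i]
  }
  if (all(wsum == 0)) stop("no samples fall inside the PMF grid")
  f <- -kBT * log(wsum)
  f[!is.finite(f)] <- NA
  f <- f - min(f, na.rm = TRUE)
  structure(list(xbreaks = xbreaks, ybreaks = ybreaks,
                 xmid = (head(xbreaks, -1) + tail(xbreaks, -1)) / 2,
                 ymid = (head(ybreaks, -1) + tail(ybreaks, -1)) / 2,
                 F = f, weight = wsum, kBT = kBT),
            class = "pmf_grid")
}

#' @rdname pmf_2d
#' @param pmf A `pmf_grid`.
#' @param file Output TSV path (`d1  d2  F` rows; unsampled bins written
#'   as `NA`).
#' @export
write_pmf <- function(pmf, file) {
  stopifnot(inherits(pmf, "pmf_grid"))
  grid <- expand.grid(d1 = pmf$xmid, d2 = pmf$ymid)
  grid$F <- as.vector(pmf$F)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines("#! FIELDS d1 d2 F", con)
  write.table(grid, con, quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  invisible(file)
}

#' Free-energy difference between two PMF regions
#'
#' Integrates `exp(-F/kBT)` over the bins belonging to each of two states
#' (by classifying bin midpoints) and returns
#' `Delta G = -kBT log(P_a / P_b)`; used as the self-consistency check
#' against [state_thermo()].
#'
#' @param pmf A `pmf_grid` over the Dunbrack plane.
#' @param state_a,state_b State labels (default `IN` vs `OUT`).
#' @return `Delta G` in kBT.
#' @export
delta_g_from_pmf <- function(pmf, state_a = "IN", state_b = "OUT") {
  stopifnot(inherits(pmf, "pmf_grid"))
  lab <- classify_dfg(rep(pmf$xmid, times = length(pmf$ymid)),
                      rep(pmf$ymid, each = length(pmf$xmid)))
  f <- as.vector(pmf$F)  # column-major: x fastest, matching lab above
  p <- ifelse(is.na(f), 0, exp(-f / pmf$kBT))
  pa <- sum(p[lab == state_a])
  pb <- sum(p[lab == state_b])
  if (pa == 0 || pb == 0) stop("a state region is unsampled")
  -pmf$kBT * log(pa / pb)
}

#' Reweighted state thermodynamics with multi-trajectory spread
#'
#' Classifies every frame of each independently reweighted trajectory into
#' a discrete state, integrates the weights per state, and reports the
#' free-energy difference `Delta G = G(state_a) - G(state_b) =
#' -kBT log(P_a / P_b)` as mean +/- sample sd over trajectories.  With the
#' default Dunbrack classifier and `IN`/`OUT` states, the sign convention
#' makes a system whose DFG-out state is more stable come out positive.
#' `GAP`-labelled frames are excluded from the state normalization and
#' reported as a separate mass.  Trajectories in which either state is
#' unsampled are flagged one-sided and excluded with a warning.
#'
#' @param wtrajs List of [compute_weights()] results (one per independent
#'   trajectory).
#' @param state_fun Function mapping a frame-coordinate matrix to state
#'   labels; default applies [classify_dfg()] to the first two columns.
#' @param state_a,state_b The two states compared (defaults `IN`, `OUT`).
#' @param kBT Thermal energy.
#' @return A `state_thermo`: per-trajectory and mean state probabilities,
#'   separate GAP mass, per-trajectory `delta_g`, `delta_g_mean`,
#'   `delta_g_sd` (n-1 denominator), `n_traj`, and indices of excluded
#'   one-sided trajectories.
#' @export
state_thermo <- function(wtrajs, state_fun = NULL, state_a = "IN",
                         state_b = "OUT", kBT = 1) {
  if (inherits(wtrajs, "weighted_traj")) wtrajs <- list(wtrajs)
  if (is.null(state_fun))
    state_fun <- function(fr) classify_dfg(fr[, 1], fr[, 2])
  states <- lapply(wtrajs, function(wt) as.character(state_fun(wt$frames)))
  all_lev <- sort(unique(unlist(states)))
  lev <- setdiff(all_lev, "GAP")
  p <- matrix(0, length(wtrajs), length(lev), dimnames = list(NULL, lev))
  gap_mass <- numeric(length(wtrajs))
  dg <- rep(NA_real_, length(wtrajs))
  for (i in seq_along(wtrajs)) {
    w <- wtrajs[[i]]$weights
    st <- states[[i]]
    gap_mass[i] <- sum(w[st == "GAP"]) / sum(w)
    keep <- st != "GAP"
    tot <- sum(w[keep])
    for (l in lev) p[i, l] <- sum(w[keep & st == l]) / tot
    pa <- if (state_a %in% lev) p[i, state_a] else 0
    pb <- if (state_b %in% lev) p[i, state_b] else 0
    if (pa > 0 && pb > 0) dg[i] <- -kBT * log(pa / pb)
  }
  excluded <- which(is.na(dg))
  if (length(excluded) > 0)
    warning("one-sided trajectories excluded from Delta G: ",
            paste(excluded, collapse = ", "))
  ok <- dg[!is.na(dg)]
  structure(list(p = p, p_mean = colMeans(p), gap_mass = gap_mass,
                 delta_g = dg,
                 delta_g_mean = if (length(ok)) mean(ok) else NA_real_,
                 delta_g_sd = if (length(ok) > 1) sd(ok) else NA_real_,
                 n_traj = length(ok), excluded = excluded,
                 state_a = state_a, state_b = state_b, kBT = kBT),
            class = "state_thermo")
}

#' @export
print.state_thermo <- function(x, ...) {
  cat("state thermodynamics over ", x$n_traj, " trajectories:\n", sep = "")
  cat("  P(mean): ", paste(sprintf("%s=%.3f", names(x$p_mean), x$p_mean),
                           collapse = ", "), "\n", sep = "")
  cat(sprintf("  Delta G (%s - %s) = %.3f +/- %.3f kBT\n", x$state_a,
              x$state_b, x$delta_g_mean,
              ifelse(is.na(x$delta_g_sd), 0, x$delta_g_sd)))
  invisible(x)
}
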