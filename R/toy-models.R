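#' Analytic toy potentials with known thermodynamics
#'
#' Desk-scale stand-ins for the protein Hamiltonian: every potential is an
#' analytic energy function (kBT units) whose state free energies are
#' computed by numerical quadrature at construction, so downstream
#' estimators can be validated against exact references.
#'
#' Available potentials:
#' \describe{
#'   \item{`double_well_1d`}{`U = h (x^2 - 1)^2`; `params$barrier` (= h,
#'     default 8) is the barrier height at x = 0 relative to the minima.
#'     Two states: `A` (x < 0), `B` (x >= 0).}
#'   \item{`tilted_double_well_1d`}{Adds `params$tilt * x`; alternatively
#'     give `params$target_dg` (the desired `G_A - G_B` in kBT) and the
#'     tilt is solved by root finding against the quadrature.}
#'   \item{`kinase_mimic_2d`}{A Gaussian-mixture free-energy surface over
#'     the Dunbrack plane (d1, d2) with basins at the DFG-in, DFG-out and
#'     DFG-inter reference positions (defaults (9.5, 15.5), (13, 10),
#'     (9.5, 9.5) Angstrom; artifact choices placed inside the printed
#'     rule regions).  `params$target_dg` (default +0.5 kBT) is the
#'     desired `G_IN - G_OUT`; the IN-basin depth is solved numerically.}
#'   \item{`mueller_like_2d`}{The Mueller-Brown surface scaled by
#'     `params$scale` (default 0.05) into the kBT range.}
#'   \item{`harmonic_1d`}{`U = k (x - x0)^2 / 2` with `params$k`,
#'     `params$x0`.}
#' }
#'
#' @param name Potential name (see Details).
#' @param params Named list of parameters.
#' @return A `toy_potential`: energy code/parameters, dimension, discrete
#'   state classifier, basin minima, recommended coordinate box, and `fe`,
#'   the quadrature thermodynamics (state probabilities, free energies and
#'   the headline free-energy difference, all in kBT).
#' @export
make_potential <- function(name, params = list()) {
  p <- params
  if (name == "double_well_1d" || name == "tilted_double_well_1d") {
    h <- if (is.null(p$barrier)) 8 else p$barrier
    tilt <- if (is.null(p$tilt)) 0 else p$tilt
    if (name == "tilted_double_well_1d" && !is.null(p$target_dg)) {
      tilt <- uniroot(function(tl) {
        quad_delta_g_1d(1, c(h, tl)) - p$target_dg
      }, c(-4 * h, 4 * h), tol = 1e-10)$root
    }
    pot <- list(name = name, code = 1L, par = c(h, tilt), dim = 1L,
                classifier = 1L, state_labels = c("A", "B"),
                basins = rbind(A = -1, B = 1),
                box = c(-2.5, 2.5), params = list(barrier = h, tilt = tilt))
  } else if (name == "harmonic_1d") {
    k <- if (is.null(p$k)) 1 else p$k
    x0 <- if (is.null(p$x0)) 0 else p$x0
    pot <- list(name = name, code = 4L, par = c(k, x0), dim = 1L,
                classifier = 0L, state_labels = character(0),
                basins = rbind(min = x0),
                box = x0 + c(-1, 1) * 6 / sqrt(k), params = list(k = k, x0 = x0))
  } else if (name == "mueller_like_2d") {
    scl <- if (is.null(p$scale)) 0.05 else p$scale
    pot <- list(name = name, code = 3L, par = scl, dim = 2L,
                classifier = 0L, state_labels = character(0),
                basins = rbind(a = c(-0.558, 1.442), b = c(0.623, 0.028)),
                box = c(-1.8, 1.2, -0.5, 2.2), params = list(scale = scl))
  } else if (name == "kinase_mimic_2d") {
    centers <- if (is.null(p$centers))
      rbind(IN = c(9.5, 15.5), OUT = c(13, 10), INTER = c(9.5, 9.5))
    else p$centers
    sigmas <- if (is.null(p$sigmas)) c(IN = 1.2, OUT = 1.2, INTER = 1.0)
    else p$sigmas
    amps <- if (is.null(p$amps)) c(IN = NA, OUT = 1, INTER = 0.08) else p$amps
    target <- if (is.null(p$target_dg)) 0.5 else p$target_dg
    mk_par <- function(a_in) {
      a <- amps
      a["IN"] <- a_in
      ord <- rownames(centers)
      c(nrow(centers), a[ord], centers[, 1], centers[, 2], sigmas[ord],
        sigmas[ord])
    }
    if (is.na(amps["IN"])) {
      la <- uniroot(function(la) {
        fe <- quad_fe_2d(2L, mk_par(exp(la)))
        fe$delta_g - target
      }, c(-8, 8), tol = 1e-8)$root
      amps["IN"] <- exp(la)
    }
    pot <- list(name = name, code = 2L, par = unname(mk_par(amps["IN"])),
                dim = 2L, classifier = 2L, state_labels = dfg_states(),
                basins = centers, box = c(4, 22, 4, 22),
                params = list(centers = centers, sigmas = sigmas, amps = amps,
                              target_dg = target))
  } else {
    stop("unknown potential: ", name)
  }
  class(pot) <- "toy_potential"
  pot$fe <- quad_free_energies(pot)
  pot
}

#' Evaluate a toy potential
#'
#' @param pot A `toy_potential`.
#' @param x Vector (one point, or many points for 1-D) or matrix of points.
#' @return Energies in kBT.
#' @export
potential_energy <- function(pot, x) {
  stopifnot(inherits(pot, "toy_potential"))
  if (is.null(dim(x))) {
    x <- if (pot$dim == 1L) matrix(x, ncol = 1) else matrix(x, nrow = 1)
  }
  cpp_pot_energy(pot$code, pot$par, as.matrix(x))
}

# quadrature Delta G (G_A - G_B) for the 1-D two-state potentials
quad_delta_g_1d <- function(code, par, box = c(-5, 5), n = 20001L) {
  x <- seq(box[1], box[2], length.out = n)
  u <- cpp_pot_energy(code, par, matrix(x, ncol = 1))
  p <- exp(-(u - min(u)))
  pa <- sum(p[x < 0]) + 0.5 * sum(p[x == 0])
  pb <- sum(p[x > 0]) + 0.5 * sum(p[x == 0])
  -log(pa / pb)
}

# quadrature thermodynamics over the Dunbrack regions for 2-D mixtures
quad_fe_2d <- function(code, par, box = c(4, 22, 4, 22), n = 351L) {
  gx <- seq(box[1], box[2], length.out = n)
  gy <- seq(box[3], box[4], length.out = n)
  X <- cbind(rep(gx, times = n), rep(gy, each = n))
  u <- cpp_pot_energy(code, par, X)
  p <- exp(-(u - min(u)))
  lab <- classify_dfg(X[, 1], X[, 2])
  mass <- tapply(p, lab, sum, default = 0)
  mass <- mass / sum(mass)
  g <- -log(mass)
  list(p_states = mass, g_states = g,
       delta_g = unname(g["IN"] - g["OUT"]))
}

# full quadrature record attached to a toy_potential
quad_free_energies <- function(pot) {
  if (pot$classifier == 1L) {
    dg <- quad_delta_g_1d(pot$code, pot$par)
    pa <- 1 / (1 + exp(dg))
    list(states = c(A = -log(pa), B = -log(1 - pa)),
         p_states = c(A = pa, B = 1 - pa), delta_g = dg,
         convention = "delta_g = G_A - G_B")
  } else if (pot$classifier == 2L) {
    fe <- quad_fe_2d(pot$code, pot$par, box = pot$box)
    fe$convention <- "delta_g = G_IN - G_OUT"
    fe
  } else {
    NULL
  }
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("toy potential '", x$name, "' (", x$dim, "-D)", sep = "")
  if (!is.null(x$fe)) cat(", delta G = ", signif(x$fe$delta_g, 4), " kBT (",
                          x$fe$convention, ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Configuration for the synthetic structural ensemble generator
#'
#' Emulates the *shape* of a reduced-MSA structure-prediction ensemble as CV
#' vectors drawn from a mixture over the DFG-in / DFG-out / DFG-inter
#' reference geometries, with a configurable fraction of injected
#' broken-backbone frames.  The default ensemble size of 1280 mirrors the
#' protocol's per-kinase ensemble (2 MSA depths x 128 seeds x 5 structures).
#' No claim is made that the statistics match a real predictor's; the
#' generator exists to exercise filtering, classification, clustering and
#' seeding, and it exports its ground truth (mode labels, injected defects)
#' so downstream checks are closed-loop.
#'
#' @param n Number of structures (default 1280).
#' @param weights Mixture weights over `IN`, `OUT`, `INTER` (sum to 1).
#' @param centers 3 x 2 matrix of per-mode (d1, d2) reference centers
#'   (Angstrom).
#' @param sigma Per-mode isotropic sd of (d1, d2) around the center.
#' @param n_aux Number of auxiliary (uninformative) distance CVs.
#' @param aux_mean,aux_sd Auxiliary CV distribution.
#' @param unphysical_fraction Fraction of frames given a broken backbone.
#' @param chain_length Residue count of the synthetic backbone trace.
#' @param seed RNG seed.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(n = 1280L, weights = c(IN = 0.45, OUT = 0.35,
                                                   INTER = 0.2),
                            centers = rbind(IN = c(9.5, 15.5),
                                            OUT = c(13, 10),
                                            INTER = c(9.5, 9.5)),
                            sigma = c(IN = 0.45, OUT = 0.45, INTER = 0.45),
                            n_aux = 8L, aux_mean = 10, aux_sd = 0.5,
                            unphysical_fraction = 0, chain_length = 20L,
                            seed = 1L) {
  stopifnot(abs(sum(weights) - 1) < 1e-8, all(weights >= 0),
            unphysical_fraction >= 0, unphysical_fraction < 1)
  structure(list(n = as.integer(n), weights = weights, centers = centers,
                 sigma = sigma, n_aux = as.integer(n_aux),
                 aux_mean = aux_mean, aux_sd = aux_sd,
                 unphysical_fraction = unphysical_fraction,
                 chain_length = as.integer(chain_length),
                 seed = as.integer(seed)),
            class = "ensemble_config")
}

#' Draw a synthetic structural ensemble
#'
#' @param cfg An [ensemble_config()].
#' @return A `synthetic_ensemble` list: `cv` (matrix with columns `d1`,
#'   `d2`, `aux*`), `labels` (ground-truth mode per frame), `ca_dist`
#'   (consecutive Calpha distances per frame, with injected breaks),
#'   `unphysical` (logical ground truth), and the config.
#' @export
synth_ensemble <- function(cfg = ensemble_config()) {
  stopifnot(inherits(cfg, "ensemble_config"))
  set.seed(cfg$seed)
  modes <- c("IN", "OUT", "INTER")
  comp <- sample(modes, cfg$n, replace = TRUE, prob = cfg$weights[modes])
  d12 <- t(vapply(comp, function(m)
    cfg$centers[m, ] + rnorm(2, sd = cfg$sigma[m]), numeric(2)))
  aux <- matrix(rnorm(cfg$n * cfg$n_aux, cfg$aux_mean, cfg$aux_sd), cfg$n)
  cv <- cbind(d12, aux)
  colnames(cv) <- c("d1", "d2",
                    if (cfg$n_aux > 0) paste0("aux", seq_len(cfg$n_aux)))
  rownames(cv) <- NULL
  nb <- cfg$chain_length - 1L
  ca <- matrix(3.8, cfg$n, nb)
  nbad <- floor(cfg$n * cfg$unphysical_fraction)
  unphysical <- rep(FALSE, cfg$n)
  if (nbad > 0) {
    bad <- sample.int(cfg$n, nbad)
    unphysical[bad] <- TRUE
    ca[cbind(bad, sample.int(nb, nbad, replace = TRUE))] <- 9.0
  }
  structure(list(cv = cv, labels = factor(comp, levels = modes),
                 ca_dist = ca, unphysical = unphysical, config = cfg),
            class = "synthetic_ensemble")
}

#' Write a minimal fixture PDB from prescribed coordinates
#'
#' Builds a small, valid PDB file from an explicit atom table so that CV
#' extraction can be tested against coordinates that are known exactly.
#' PDB coordinate fields carry three decimals, so distances round-trip to
#' about 1e-3 Angstrom.
#'
#' @param spec `data.frame` with columns `resno`, `resname`, `elety`, `x`,
#'   `y`, `z` (one row per atom).
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
write_fixture_pdb <- function(spec, file) {
  spec <- as.data.frame(spec)
  need <- c("resno", "resname", "elety", "x", "y", "z")
  if (!all(need %in% names(spec)))
    stop("fixture spec needs columns: ", paste(need, collapse = ", "))
  xyz <- as.matrix(spec[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("fixture spec has non-finite coordinates")
  bio3d::write.pdb(file = file,
                   xyz = as.numeric(t(xyz)),
                   type = rep("ATOM", nrow(spec)),
                   resno = spec$resno,
                   resid = spec$resname,
                   eleno = seq_len(nrow(spec)),
                   elety = spec$elety,
                   chain = rep("A", nrow(spec)))
  invisible(file)
}

#' Random fixture structure with exact ground-truth coordinates
#'
#' Generates an `n_res`-residue chain with N/CA/CB (CA-only for glycine)
#' atoms at randomized but recorded coordinates, for round-trip tests of
#' PDB writing and CV extraction.
#'
#' @param n_res Number of residues.
#' @param seed RNG seed.
#' @param glycine_at Residue indices to make glycine (no CB).
#' @return List with `spec` (atom table for [write_fixture_pdb()]).
#' @export
make_fixture_structure <- function(n_res = 10L, seed = 1L,
                                   glycine_at = integer(0)) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n_res)) {
    base <- c(4 * i, 0, 0) + rnorm(3, sd = 0.5)
    resname <- if (i %in% glycine_at) "GLY" else "ALA"
    atoms <- c("N", "CA", if (resname != "GLY") "CB")
    for (a in atoms) {
      rows[[length(rows) + 1L]] <- data.frame(
        resno = i, resname = resname, elety = a,
        x = round(base[1] + rnorm(1, sd = 0.8), 3),
        y = round(base[2] + rnorm(1, sd = 0.8), 3),
        z = round(base[3] + rnorm(1, sd = 0.8), 3))
    }
  }
  list(spec = do.call(rbind, rows))
}
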