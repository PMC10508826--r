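#' Configuration for state-predictive information-bottleneck learning
#'
#' The order parameter is learned by a time-lagged state-predictive model:
#' a linear encoder compresses each CV frame at time t into a 2-D latent,
#' and a softmax decoder predicts the discrete state label of the frame at
#' t + lag from that latent.  State labels are themselves iteratively
#' relearned between training phases (frames are reassigned to the state
#' the decoder predicts for them), so states can merge but never split.
#' Around the fit sits a feature-refinement loop: the model is trained
#' `prune_rounds` times, each time discarding CVs whose encoder weight
#' falls below `prune_fraction` of the maximum weight.
#'
#' The linear encoder is the default (and only biasable) mode: the learned
#' coordinate is a plain linear combination of standardized CVs and can be
#' exported as a PLUMED COMBINE-style input for real MD engines.  During
#' training a small seeded Gaussian noise on the latent acts as the
#' stochastic-encoder regularizer; inference always uses the deterministic
#' mean encoder.
#'
#' @param lag Time lag in trajectory steps (Delta t >= 1).
#' @param latent_dim Latent dimension (2, the biasable order parameter).
#' @param epochs Full-batch training epochs per relabeling iteration.
#' @param lr Adam learning rate.
#' @param l2 L2 penalty on encoder and decoder weights.
#' @param noise_sd Latent noise scale during training (0 disables).
#' @param relabel_max Maximum relabeling iterations.
#' @param relabel_tol Stop when fewer than this fraction of frames change
#'   label (default 0.01).
#' @param prune_fraction Importance threshold relative to the maximum
#'   (default 0.25).
#' @param prune_rounds Refinement rounds (default 3).
#' @param seed RNG seed for initialization and latent noise.
#' @return A `spib_config` list.
#' @export
spib_config <- function(lag = 10L, latent_dim = 2L, epochs = 200L, lr = 0.05,
                        l2 = 1e-4, noise_sd = 0.05, relabel_max = 10L,
                        relabel_tol = 0.01, prune_fraction = 0.25,
                        prune_rounds = 3L, seed = 1L) {
  stopifnot(lag >= 1L, prune_fraction > 0, prune_fraction < 1,
            prune_rounds >= 1L, latent_dim >= 1L)
  structure(list(lag = as.integer(lag), latent_dim = as.integer(latent_dim),
                 epochs = as.integer(epochs), lr = lr, l2 = l2,
                 noise_sd = noise_sd, relabel_max = as.integer(relabel_max),
                 relabel_tol = relabel_tol, prune_fraction = prune_fraction,
                 prune_rounds = as.integer(prune_rounds),
                 seed = as.integer(seed)),
            class = "spib_config")
}

softmax_rows <- function(l) {
  l <- l - apply(l, 1, max)
  e <- exp(l)
  e / rowSums(e)
}

# one Adam-trained phase of the encoder/decoder on given (input, target) pairs
spib_train_phase <- function(xp, y, K, par, cfg) {
  n <- nrow(xp)
  Y <- matrix(0, n, K)
  Y[cbind(seq_len(n), y)] <- 1
  m <- lapply(par, function(p) p * 0)
  v <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (ep in seq_len(cfg$epochs)) {
    Z <- xp %*% t(par$W) + matrix(par$b, n, cfg$latent_dim, byrow = TRUE)
    if (cfg$noise_sd > 0)
      Z <- Z + matrix(rnorm(n * cfg$latent_dim, sd = cfg$noise_sd), n)
    P <- softmax_rows(Z %*% t(par$U) + matrix(par$c, n, K, byrow = TRUE))
    D <- (P - Y) / n
    dZ <- D %*% par$U
    g <- list(W = t(dZ) %*% xp + 2 * cfg$l2 * par$W,
              b = colSums(dZ),
              U = t(D) %*% Z + 2 * cfg$l2 * par$U,
              c = colSums(D))
    for (nm in names(par)) {
      m[[nm]] <- b1 * m[[nm]] + (1 - b1) * g[[nm]]
      v[[nm]] <- b2 * v[[nm]] + (1 - b2) * g[[nm]]^2
      mh <- m[[nm]] / (1 - b1^ep)
      vh <- v[[nm]] / (1 - b2^ep)
      par[[nm]] <- par[[nm]] - cfg$lr * mh / (sqrt(vh) + eps)
    }
  }
  par
}

#' Fit a state-predictive information-bottleneck model
#'
#' @param x Numeric CV matrix (frames in rows, standardized columns with
#'   names), or a list of such matrices (independent trajectory segments;
#'   time-lagged pairs never cross segment boundaries).
#' @param labels Initial per-frame state labels (factor, character or
#'   integer).  `NA` labels (e.g. Dunbrack GAP frames) are allowed: such
#'   frames are excluded as prediction targets until the first relabeling
#'   assigns them a state.
#' @param cfg A [spib_config()].
#' @return An `ib_model`: encoder (`W`, `b`), decoder (`U`, `c`), the CV
#'   names, final per-frame `state_labels`, and a relabeling `history`
#'   (fraction changed and occupied-state count per iteration).
#' @export
spib_fit <- function(x, labels, cfg = spib_config()) {
  if (is.list(x) && !is.data.frame(x)) {
    seg_len <- vapply(x, nrow, integer(1))
    x <- do.call(rbind, x)
    if (is.list(labels)) labels <- unlist(lapply(labels, as.character))
  } else {
    x <- as.matrix(x)
    seg_len <- nrow(x)
  }
  n <- nrow(x)
  if (all(seg_len <= cfg$lag)) stop("trajectory shorter than the time lag")
  seg_id <- rep(seq_along(seg_len), seg_len)
  labels <- factor(labels)
  if (nlevels(labels) < 2L || length(unique(labels[!is.na(labels)])) < 2L)
    stop("degenerate-labels: need at least two initial states")
  K <- nlevels(labels)
  lev <- levels(labels)
  d <- ncol(x)
  set.seed(cfg$seed)
  par <- list(W = matrix(rnorm(cfg$latent_dim * d, sd = 0.1), cfg$latent_dim, d),
              b = numeric(cfg$latent_dim),
              U = matrix(rnorm(K * cfg$latent_dim, sd = 0.1), K, cfg$latent_dim),
              c = numeric(K))
  cur <- as.integer(labels)
  hist_changed <- numeric(0)
  hist_occ <- integer(0)
  starts <- seq_len(n - cfg$lag)
  starts <- starts[seg_id[starts] == seg_id[starts + cfg$lag]]
  for (it in seq_len(cfg$relabel_max)) {
    tt <- starts
    tgt <- cur[tt + cfg$lag]
    ok <- !is.na(tgt)
    if (!any(ok)) stop("no usable time-lagged training pairs")
    par <- spib_train_phase(x[tt[ok], , drop = FALSE], tgt[ok], K, par, cfg)
    # relabel every frame with its predicted-future state, restricted to
    # currently occupied states so states can merge but never split
    Z <- x %*% t(par$W) + matrix(par$b, n, cfg$latent_dim, byrow = TRUE)
    P <- softmax_rows(Z %*% t(par$U) + matrix(par$c, n, K, byrow = TRUE))
    occ <- sort(unique(cur[!is.na(cur)]))
    newlab <- occ[max.col(P[, occ, drop = FALSE], ties.method = "first")]
    was <- !is.na(cur)
    changed <- mean(newlab[was] != cur[was])
    hist_changed <- c(hist_changed, changed)
    hist_occ <- c(hist_occ, length(unique(newlab)))
    conv <- changed < cfg$relabel_tol && all(was)
    cur <- newlab
    if (length(unique(cur)) < 2L) {
      warning("state labels collapsed to a single state")
      break
    }
    if (conv) break
  }
  out <- list(W = par$W, b = par$b, U = par$U, c = par$c,
              cv_names = colnames(x), n_states = K, classes = lev,
              state_labels = factor(lev[cur], levels = lev),
              history = data.frame(iteration = seq_along(hist_changed),
                                   changed = hist_changed,
                                   occupied = hist_occ),
              lag = cfg$lag, cfg = cfg)
  class(out) <- "ib_model"
  out
}

#' Project frames onto the learned information-bottleneck coordinates
#'
#' Deterministic mean-encoder projection (no latent sampling at inference):
#' `z = W x + b`.
#'
#' @param model An `ib_model`.
#' @param frames Frame vector or matrix conforming to the model's CV set.
#' @return Matrix of IB coordinates, one row per frame.
#' @export
project <- function(model, frames) {
  stopifnot(inherits(model, "ib_model"))
  if (is.null(dim(frames))) frames <- matrix(frames, nrow = 1,
                                             dimnames = list(NULL, names(frames)))
  frames <- as.matrix(frames)
  if (ncol(frames) != ncol(model$W))
    stop("CV-set mismatch: model expects ", ncol(model$W), " CVs, got ",
         ncol(frames))
  if (!is.null(colnames(frames)) && !is.null(model$cv_names) &&
      !identical(colnames(frames), model$cv_names))
    stop("CV-set mismatch: column names differ from the model's CV names")
  sweep(frames %*% t(model$W), 2, model$b, "+")
}

#' Per-CV encoder importances and the pruning rule
#'
#' Importance of CV i is the maximum over the latent dimensions of the
#' absolute encoder weight on (standardized) CV i.  `prune_features`
#' retains CV i iff its importance is at least `fraction` times the
#' maximum importance; the maximum itself always survives, so the retained
#' set is never empty.
#'
#' @param model An `ib_model`.
#' @param fraction Relative threshold (default the model config's
#'   `prune_fraction`, i.e. 0.25).
#' @return `feature_importance`: named numeric vector.  `prune_features`:
#'   integer indices (into the model's CV set) of retained CVs.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "ib_model"))
  imp <- apply(abs(model$W), 2, max)
  names(imp) <- model$cv_names
  imp
}

#' @rdname feature_importance
#' @export
prune_features <- function(model, fraction = NULL) {
  if (is.null(fraction)) fraction <- model$cfg$prune_fraction
  imp <- feature_importance(model)
  which(imp >= fraction * max(imp))
}

#' Iterative SPIB refinement with feature pruning
#'
#' Runs [spib_fit()] `prune_rounds` times; after each fit the CV basis is
#' pruned by the relative-importance rule, and the next round is trained on
#' the surviving CVs with the previous round's refined state labels.
#'
#' @inheritParams spib_fit
#' @return List with `model` (the last fit), `retained` (indices into the
#'   original CV columns surviving the final prune), and `rounds`
#'   (per-round retained counts).
#' @export
spib_refine_loop <- function(x, labels, cfg = spib_config()) {
  is_list <- is.list(x) && !is.data.frame(x)
  if (!is_list) x <- as.matrix(x)
  ncv <- if (is_list) ncol(x[[1]]) else ncol(x)
  retained <- seq_len(ncv)
  lab <- labels
  model <- NULL
  counts <- integer(0)
  for (r in seq_len(cfg$prune_rounds)) {
    xr <- if (is_list) lapply(x, function(m) m[, retained, drop = FALSE])
          else x[, retained, drop = FALSE]
    model <- spib_fit(xr, lab, cfg)
    keep <- prune_features(model)
    retained <- retained[keep]
    lab <- model$state_labels
    counts <- c(counts, length(retained))
  }
  list(model = model, retained = retained, rounds = counts)
}

#' Best-permutation label agreement
#'
#' State identities are arbitrary, so predicted labels are compared with
#' reference labels under the best one-to-one mapping of label sets
#' (exhaustive over permutations for small state counts, greedy otherwise).
#'
#' @param pred,truth Label vectors of equal length.
#' @return Fraction of frames agreeing under the best mapping.
#' @export
label_accuracy <- function(pred, truth) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  stopifnot(length(pred) == length(truth))
  tab <- table(pred, truth)
  k <- max(dim(tab))
  M <- matrix(0, k, k)
  M[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  if (k <= 7L) {
    perms <- function(v) {
      if (length(v) <= 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
      out
    }
    best <- max(vapply(perms(seq_len(k)),
                       function(p) sum(M[cbind(seq_len(k), p)]), numeric(1)))
  } else {
    # greedy: repeatedly take the largest remaining cell
    best <- 0
    repeat {
      if (all(M < 0)) break
      ij <- which(M == max(M), arr.ind = TRUE)[1, ]
      best <- best + M[ij[1], ij[2]]
      M[ij[1], ] <- -1
      M[, ij[2]] <- -1
    }
  }
  best / length(pred)
}

#' Fisher discriminant ratio of a 1-D coordinate
#'
#' Between-class separation over pooled within-class variance for a
#' two-state labelling; used to compare the learned latent against raw CVs.
#'
#' @param v Numeric vector.
#' @param labels Two-level labelling of the same length.
#' @return The Fisher ratio.
#' @export
fisher_ratio <- function(v, labels) {
  labels <- factor(labels)
  stopifnot(nlevels(labels) == 2L)
  sp <- split(v, labels)
  (mean(sp[[1]]) - mean(sp[[2]]))^2 /
    (stats::var(sp[[1]]) + stats::var(sp[[2]]))
}

#' Export the learned order parameter as a PLUMED input snippet
#'
#' Writes the linear IB coordinates as PLUMED `COMBINE` actions over the
#' named CVs so the learned order parameter can be biased in a real MD
#' engine.
#'
#' @param model An `ib_model`.
#' @param file Output path.
#' @return The file path, invisibly.
#' @export
export_plumed <- function(model, file) {
  stopifnot(inherits(model, "ib_model"))
  nms <- model$cv_names
  if (is.null(nms)) nms <- paste0("cv", seq_len(ncol(model$W)))
  lines <- character(0)
  for (d in seq_len(nrow(model$W))) {
    lines <- c(lines, sprintf(
      "sigma%d: COMBINE ARG=%s COEFFICIENTS=%s PARAMETERS=%s PERIODIC=NO",
      d, paste(nms, collapse = ","),
      paste(format(model$W[d, ], digits = 10), collapse = ","),
      paste(rep("0", length(nms)), collapse = ",")))
  }
  writeLines(c("# learned information-bottleneck order parameter", lines), file)
  invisible(file)
}

#' @export
print.ib_model <- function(x, ...) {
  cat("information-bottleneck model: ", ncol(x$W), " CVs -> ", nrow(x$W),
      "-D latent, ", length(unique(x$state_labels)), "/", x$n_states,
      " states occupied, lag = ", x$lag, "\n", sep = "")
  invisible(x)
}

#' Serialize / restore an IB model as JSON
#'
#' Stores encoder and decoder weights at full precision together with the
#' CV names, state classes and (optionally) the standardization transform,
#' so a learned order parameter can be moved between runs and machines as
#' plain text.
#'
#' @param model An `ib_model`.
#' @param file JSON path.
#' @param scaler Optional [standardize()] transform to store alongside.
#' @return `read_ib_model` returns a list with `model` and `scaler` (NULL
#'   if none was stored).
#' @export
write_ib_model <- function(model, file, scaler = NULL) {
  stopifnot(inherits(model, "ib_model"))
  obj <- list(W = model$W, b = model$b, U = model$U, c = model$c,
              cv_names = model$cv_names, classes = model$classes,
              n_states = model$n_states, lag = model$lag)
  if (!is.null(scaler))
    obj$scaler <- list(center = as.list(scaler$center),
                       scale = as.list(scaler$scale))
  jsonlite::write_json(obj, file, digits = NA, auto_unbox = TRUE)
  invisible(file)
}

#' @rdname write_ib_model
#' @export
read_ib_model <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  m <- list(W = as.matrix(obj$W), b = as.numeric(obj$b),
            U = if (is.null(obj$U)) NULL else as.matrix(obj$U),
            c = if (is.null(obj$c)) NULL else as.numeric(obj$c),
            cv_names = obj$cv_names, classes = obj$classes,
            n_states = obj$n_states, state_labels = NULL, history = NULL,
            lag = obj$lag, cfg = NULL)
  class(m) <- "ib_model"
  scaler <- NULL
  if (!is.null(obj$scaler)) {
    scaler <- list(values = NULL,
                   center = unlist(obj$scaler$center),
                   scale = unlist(obj$scaler$scale))
    class(scaler) <- "cv_standardizer"
  }
  list(model = m, scaler = scaler)
}

#' Restrict a standardized-input IB model to raw coordinates
#'
#' A model trained on standardized CVs defines `s = W_std (x - m)/sd + b`.
#' For biasing a dynamics engine that only exposes a subset of the CVs as
#' raw coordinates (here the Dunbrack distances), the encoder is rewritten
#' on those raw coordinates; CVs outside the subset are held at their
#' standardized mean (0), which is exact when pruning has removed them and
#' an approximation otherwise.
#'
#' @param model An `ib_model` trained on standardized CVs.
#' @param scaler The [standardize()] transform used in training.
#' @param coords Names of the raw coordinates to keep (e.g. `c("d1","d2")`).
#' @return An `ib_model` acting on the raw `coords`.
#' @export
model_on_coords <- function(model, scaler, coords) {
  stopifnot(inherits(model, "ib_model"), all(coords %in% model$cv_names))
  j <- match(coords, model$cv_names)
  dropped <- setdiff(model$cv_names, coords)
  if (length(dropped) > 0) {
    imp <- feature_importance(model)
    if (any(imp[dropped] > 0.25 * max(imp)))
      warning("dropping CVs with non-negligible weight: ",
              paste(dropped[imp[dropped] > 0.25 * max(imp)], collapse = ", "))
  }
  sdv <- scaler$scale[coords]
  mn <- scaler$center[coords]
  W_raw <- sweep(model$W[, j, drop = FALSE], 2, sdv, "/")
  b_raw <- model$b - as.numeric(model$W[, j, drop = FALSE] %*% (mn / sdv))
  m <- list(W = W_raw, b = b_raw, U = model$U, c = model$c,
            cv_names = coords, n_states = model$n_states,
            classes = model$classes, state_labels = NULL, history = NULL,
            lag = model$lag, cfg = model$cfg)
  class(m) <- "ib_model"
  m
}
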