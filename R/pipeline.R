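#' Configure the end-to-end seeding/learning/biasing/reweighting protocol
#'
#' One config drives the whole pipeline on the toy kinase-mimic systems:
#' generate a synthetic structural ensemble, filter broken frames, cluster
#' and seed, run unbiased Langevin trajectories, learn the IB order
#' parameter with pruning, run shared-bias well-tempered metadynamics on
#' the "wild-type" system, freeze the bias, transfer it statically to the
#' wild type and a "mutant" variant, and reweight to DFG-state
#' thermodynamics.  Every stage draws its RNG stream from a per-stage seed
#' derived from `seed`, so a resumed run reproduces an uninterrupted one.
#'
#' @param run_dir Directory for stage artifacts (created if needed).
#' @param seed Global seed.
#' @param wt_dg,mut_dg Target `G_IN - G_OUT` (kBT) of the wild-type-like
#'   and mutant-like toy potentials.
#' @param ensemble An [ensemble_config()] (its `seed` is overridden).
#' @param dmin Regular-space clustering minimum distance in standardized
#'   CV space.  The pipeline default (4) is scaled to its 10-CV basis; the
#'   module-level default of 9 presumes the much larger CV basis of a real
#'   kinase run.
#' @param n_seed_traj Maximum number of seeds launched as unbiased
#'   trajectories.
#' @param unbiased_steps,unbiased_stride Unbiased run length and stride.
#' @param spib A [spib_config()].
#' @param metad A [metad_config()] for bias learning.
#' @param transfer_steps Static-bias sampling length per walker.
#' @param n_per_basin Static walkers per starting basin (2 basins, so the
#'   default 3 yields 6 independent trajectories per system for the
#'   multi-trajectory spread).
#' @param stages Character vector of stages to run, in order.
#' @return A `protocol_config`.
#' @export
protocol_config <- function(run_dir = tempfile("ibmetad_run_"), seed = 1L,
                            wt_dg = 0.5, mut_dg = -0.4,
                            ensemble = ensemble_config(n = 640L,
                              unphysical_fraction = 0.05),
                            dmin = 4, n_seed_traj = 6L,
                            unbiased_steps = 20000L, unbiased_stride = 10L,
                            spib = spib_config(lag = 5L, epochs = 120L,
                                               relabel_max = 6L),
                            metad = metad_config(n_walkers = 5L,
                              sigma = c(0.4, 0.4), pace = 200L,
                              max_steps = 150000L, window = 2000L,
                              stride = 20L),
                            transfer_steps = 150000L, n_per_basin = 3L,
                            stages = c("ensemble", "filter", "cluster",
                                       "unbiased", "spib", "metad",
                                       "transfer", "reweight")) {
  structure(list(run_dir = run_dir, seed = as.integer(seed), wt_dg = wt_dg,
                 mut_dg = mut_dg, ensemble = ensemble, dmin = dmin,
                 n_seed_traj = as.integer(n_seed_traj),
                 unbiased_steps = as.integer(unbiased_steps),
                 unbiased_stride = as.integer(unbiased_stride),
                 spib = spib, metad = metad,
                 transfer_steps = as.integer(transfer_steps),
                 n_per_basin = as.integer(n_per_basin), stages = stages),
            class = "protocol_config")
}

log_event <- function(run_dir, stage, ...) {
  entry <- c(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                  stage = stage), list(...))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE, digits = NA), "\n",
      file = file.path(run_dir, "run.log.jsonl"), append = TRUE)
}

manifest_add <- function(run_dir, stage, seed, files) {
  files <- normalizePath(files)
  sums <- tools::md5sum(files)
  entry <- list(stage = stage, seed = seed,
                artifacts = as.list(setNames(unname(sums), basename(files))))
  cat(jsonlite::toJSON(entry, auto_unbox = TRUE), "\n",
      file = file.path(run_dir, "manifest.jsonl"), append = TRUE)
}

stage_done <- function(run_dir, stage, files) {
  mf <- file.path(run_dir, "manifest.jsonl")
  if (!file.exists(mf)) return(FALSE)
  stages <- vapply(readLines(mf), function(l)
    jsonlite::fromJSON(l)$stage, character(1), USE.NAMES = FALSE)
  stage %in% stages && all(file.exists(files))
}

#' Run the full protocol
#'
#' Executes the enabled stages in order, writing every artifact under
#' `cfg$run_dir` together with a manifest (md5 checksums, per-stage seeds)
#' and a JSON-lines event log.  A failed stage halts with its name; because
#' completed stages are recorded in the manifest, re-running with
#' `resume = TRUE` skips them and reproduces the uninterrupted result
#' (per-stage seeding makes stages independent of one another's RNG
#' state).
#'
#' @param cfg A [protocol_config()].
#' @param resume Skip stages whose artifacts already exist.
#' @return A report list: per-stage artifact paths and, after the final
#'   stage, `thermo_wt` / `thermo_mut` ([state_thermo()] objects).
#' @export
run_protocol <- function(cfg = protocol_config(), resume = FALSE) {
  stopifnot(inherits(cfg, "protocol_config"))
  rd <- cfg$run_dir
  dir.create(rd, showWarnings = FALSE, recursive = TRUE)
  report <- list(run_dir = rd)
  paths <- list(
    ensemble = file.path(rd, "ensemble.colvar"),
    truth = file.path(rd, "ensemble_truth.json"),
    retained = file.path(rd, "retained.json"),
    seeds = file.path(rd, "seeds.json"),
    seeds_colvar = file.path(rd, "seeds.colvar"),
    spib = file.path(rd, "spib_model.json"),
    plumed = file.path(rd, "plumed_op.dat"),
    hills = file.path(rd, "HILLS"),
    thermo = file.path(rd, "thermo.json"),
    pmf_wt = file.path(rd, "pmf_wt.tsv"),
    pmf_mut = file.path(rd, "pmf_mut.tsv"))

  wt <- make_potential("kinase_mimic_2d", list(target_dg = cfg$wt_dg))
  mut <- make_potential("kinase_mimic_2d", list(target_dg = cfg$mut_dg))

  run_stage <- function(stage, files, fun) {
    if (!(stage %in% cfg$stages)) return(invisible(NULL))
    sseed <- derive_seed(cfg$seed, stage)
    if (resume && stage_done(rd, stage, files)) {
      log_event(rd, stage, event = "skipped (resume)")
      return(invisible(NULL))
    }
    ok <- tryCatch({
      fun(sseed)
      TRUE
    }, error = function(e) {
      log_event(rd, stage, event = "failed", error = conditionMessage(e))
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           " (completed stages are resumable from ", rd, ")", call. = FALSE)
    })
    manifest_add(rd, stage, sseed, files)
    log_event(rd, stage, event = "completed", seed = sseed,
              artifacts = basename(files))
    invisible(NULL)
  }

  run_stage("ensemble", c(paths$ensemble, paths$truth), function(sseed) {
    ecfg <- cfg$ensemble
    ecfg$seed <- sseed
    ens <- synth_ensemble(ecfg)
    write_colvar(ens$cv, paths$ensemble)
    jsonlite::write_json(list(labels = as.character(ens$labels),
                              unphysical = ens$unphysical,
                              ca_dist = ens$ca_dist),
                         paths$truth, digits = NA, auto_unbox = FALSE)
  })

  read_ens <- function() {
    cv <- read_colvar(paths$ensemble)$values
    tr <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
    list(cv = cv, labels = tr$labels, ca_dist = as.matrix(tr$ca_dist))
  }

  run_stage("filter", paths$retained, function(sseed) {
    ens <- read_ens()
    flt <- filter_unphysical(ens$ca_dist)
    jsonlite::write_json(list(keep = flt$keep,
                              rejections = flt$rejections),
                         paths$retained, digits = NA)
    log_event(rd, "filter", event = "rejected",
              n = sum(!flt$keep))
  })

  run_stage("cluster", c(paths$seeds, paths$seeds_colvar), function(sseed) {
    ens <- read_ens()
    keep <- jsonlite::read_json(paths$retained, simplifyVector = TRUE)$keep
    cv <- ens$cv[keep, , drop = FALSE]
    std <- standardize(cv)
    cl <- regular_space_cluster(std$values, dmin = cfg$dmin)
    seeds <- select_seeds(cl, cv)
    jsonlite::write_json(list(indices = seeds$indices,
                              states = as.character(seeds$states),
                              dmin = cfg$dmin,
                              scaler = list(center = std$center,
                                            scale = std$scale)),
                         paths$seeds, digits = NA)
    write_colvar(seeds$frames, paths$seeds_colvar)
    log_event(rd, "cluster", event = "centers", n = length(seeds$indices),
              states = as.character(unique(seeds$states)))
  })

  unbiased_files <- function() {
    sj <- jsonlite::read_json(paths$seeds, simplifyVector = TRUE)
    n <- min(cfg$n_seed_traj, length(sj$indices))
    file.path(rd, sprintf("unbiased_%02d.colvar", seq_len(n)))
  }

  run_stage("unbiased", if (file.exists(paths$seeds)) unbiased_files()
            else character(0), function(sseed) {
    seeds <- read_colvar(paths$seeds_colvar)$values
    n <- min(cfg$n_seed_traj, nrow(seeds))
    ecfg <- cfg$ensemble
    for (i in seq_len(n)) {
      lcfg <- langevin_config(n_steps = cfg$unbiased_steps,
                              stride = cfg$unbiased_stride,
                              seed = derive_seed(sseed, i))
      tr <- run_baoab(wt, lcfg, x0 = seeds[i, c("d1", "d2")])
      # decorate with the same auxiliary CV noise model the ensemble uses,
      # so order-parameter learning sees the full CV basis
      naux <- ecfg$n_aux
      aux <- matrix(rnorm(nrow(tr) * naux, ecfg$aux_mean, ecfg$aux_sd),
                    nrow(tr))
      cv <- cbind(d1 = tr$d1, d2 = tr$d2, aux)
      colnames(cv) <- c("d1", "d2", paste0("aux", seq_len(naux)))
      write_colvar(cv, file.path(rd, sprintf("unbiased_%02d.colvar", i)),
                   time = tr$step)
    }
  })

  run_stage("spib", c(paths$spib, paths$plumed), function(sseed) {
    files <- unbiased_files()
    trajs <- lapply(files, function(f) read_colvar(f)$values)
    allcv <- do.call(rbind, trajs)
    std <- standardize(allcv)
    seg_of <- rep(seq_along(trajs), vapply(trajs, nrow, integer(1)))
    segs <- lapply(seq_along(trajs), function(i)
      std$values[seg_of == i, , drop = FALSE])
    labels <- lapply(trajs, function(m) {
      l <- as.character(classify_dfg(m[, "d1"], m[, "d2"]))
      l[l == "GAP"] <- NA
      l
    })
    scfg <- cfg$spib
    scfg$seed <- derive_seed(sseed, "fit")
    loop <- spib_refine_loop(lapply(segs, as.matrix), labels, scfg)
    model <- loop$model
    write_ib_model(model, paths$spib, scaler = std)
    export_plumed(model, paths$plumed)
    log_event(rd, "spib", event = "refined",
              retained = model$cv_names,
              occupied = length(unique(model$state_labels)))
  })

  run_stage("metad", paths$hills, function(sseed) {
    ms <- read_ib_model(paths$spib)
    dyn_model <- model_on_coords(ms$model, ms$scaler, c("d1", "d2"))
    run <- run_metad(wt, model = dyn_model, cfg = cfg$metad, seed = sseed)
    write_hills(freeze(run$bias), paths$hills)
    log_event(rd, "metad", event = "bias learned",
              deposits = run$n_deposits,
              converged = sum(run$converged), walkers = length(run$walkers))
  })

  transfer_files <- function() {
    n <- 2L * cfg$n_per_basin
    c(file.path(rd, sprintf("transfer_wt_%02d.colvar", seq_len(n))),
      file.path(rd, sprintf("transfer_mut_%02d.colvar", seq_len(n))))
  }

  run_stage("transfer", transfer_files(), function(sseed) {
    ms <- read_ib_model(paths$spib)
    dyn_model <- model_on_coords(ms$model, ms$scaler, c("d1", "d2"))
    sb <- read_hills(paths$hills)
    scfg <- cfg$metad
    scfg$max_steps <- cfg$transfer_steps
    for (sys in c("wt", "mut")) {
      pot <- if (sys == "wt") wt else mut
      run <- static_bias_transfer(sb, pot, model = dyn_model, cfg = scfg,
                                  n_per_basin = cfg$n_per_basin,
                                  seed = derive_seed(sseed, sys),
                                  halt_on_stop = FALSE)
      for (i in seq_along(run$walkers)) {
        w <- run$walkers[[i]]
        cv <- as.matrix(w[, c("d1", "d2", "s1", "s2", "bias")])
        write_colvar(cv, file.path(rd, sprintf("transfer_%s_%02d.colvar",
                                               sys, i)), time = w$step)
      }
      log_event(rd, "transfer", event = paste0(sys, " sampled"),
                converged = sum(run$converged),
                deposits = run$n_deposits)
    }
  })

  run_stage("reweight", c(paths$thermo, paths$pmf_wt, paths$pmf_mut),
            function(sseed) {
    sb <- read_hills(paths$hills)
    th <- list()
    for (sys in c("wt", "mut")) {
      files <- Sys.glob(file.path(rd, sprintf("transfer_%s_*.colvar", sys)))
      wts <- lapply(files, function(f) {
        v <- read_colvar(f)$values
        compute_weights(v[, c("s1", "s2")], sb,
                        frames = v[, c("d1", "d2")])
      })
      th[[sys]] <- state_thermo(wts)
      pmf <- pmf_2d(wts)
      write_pmf(pmf, if (sys == "wt") paths$pmf_wt else paths$pmf_mut)
    }
    jsonlite::write_json(list(
      wt = list(delta_g = th$wt$delta_g_mean, sd = th$wt$delta_g_sd,
                n_traj = th$wt$n_traj, p = as.list(th$wt$p_mean),
                truth = wt$fe$delta_g),
      mut = list(delta_g = th$mut$delta_g_mean, sd = th$mut$delta_g_sd,
                 n_traj = th$mut$n_traj, p = as.list(th$mut$p_mean),
                 truth = mut$fe$delta_g)),
      paths$thermo, digits = NA, auto_unbox = TRUE)
  })

  report$paths <- paths
  if (file.exists(paths$thermo)) {
    report$thermo <- jsonlite::read_json(paths$thermo, simplifyVector = TRUE)
  }
  report
}
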