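# shared fixtures, all generated in code at test time

# double-well Langevin trajectory dressed as a CV matrix:
# `n_info` noisy copies of the coordinate plus `n_noise` pure-noise CVs
two_state_cv_traj <- function(seed, n_steps = 40000L, n_info = 3L,
                              n_noise = 17L, info_sd = 0.4, barrier = 3) {
  dw <- make_potential("double_well_1d", list(barrier = barrier))
  tr <- run_baoab(dw, langevin_config(n_steps = n_steps, stride = 10L,
                                      seed = seed), x0 = -1)
  x <- tr$x
  n <- length(x)
  set.seed(seed + 1)
  info <- vapply(seq_len(n_info), function(i) x + rnorm(n, sd = info_sd),
                 numeric(n))
  noise <- matrix(rnorm(n * n_noise), n)
  cv <- cbind(info, noise)
  colnames(cv) <- c(paste0("inf", seq_len(n_info)),
                    paste0("nz", seq_len(n_noise)))
  list(cv = standardize(cv)$values,
       truth = factor(ifelse(x < 0, "A", "B")), x = x)
}

# minimal schema with the two mandatory Dunbrack entries
dunbrack_schema <- function() {
  cv_schema(data.frame(
    name = c("d1", "d2"),
    res_a = c(5, 5), atom_a = c("CB", "CB"),
    res_b = c(9, 12), atom_b = c("CB", "CB")))
}

# place single atoms at explicit positions and wrap as a bio3d-like object
point_pdb <- function(coords, resno, elety, resname = "ALA") {
  spec <- data.frame(resno = resno, resname = resname, elety = elety,
                     x = coords[, 1], y = coords[, 2], z = coords[, 3])
  f <- tempfile(fileext = ".pdb")
  write_fixture_pdb(spec, f)
  bio3d::read.pdb(f, verbose = FALSE)
}
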