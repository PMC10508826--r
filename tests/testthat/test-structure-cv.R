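test_that("extract_cvs computes Euclidean distances in schema order", {
  pdb <- point_pdb(rbind(c(0, 0, 0), c(3, 4, 0)), resno = c(1, 2),
                   elety = c("CA", "CA"))
  sch <- cv_schema(data.frame(name = "d", res_a = 1, atom_a = "CA",
                              res_b = 2, atom_b = "CA"))
  expect_equal(unname(extract_cvs(pdb, sch)), 5.0, tolerance = 1e-3)

  # symmetry in atom order
  sch_rev <- cv_schema(data.frame(name = "d", res_a = 2, atom_a = "CA",
                                  res_b = 1, atom_b = "CA"))
  expect_equal(extract_cvs(pdb, sch), extract_cvs(pdb, sch_rev))
})

test_that("an atom paired with itself violates the frame invariant", {
  pdb <- point_pdb(rbind(c(1, 2, 3)), resno = 1, elety = "CA")
  sch <- cv_schema(data.frame(name = "self", res_a = 1, atom_a = "CA",
                              res_b = 1, atom_b = "CA"))
  expect_error(extract_cvs(pdb, sch), "finite and > 0")
})

test_that("missing residues/atoms raise schema-unresolvable errors", {
  pdb <- point_pdb(rbind(c(0, 0, 0)), resno = 1, elety = "CA")
  sch <- cv_schema(data.frame(name = "miss", res_a = 1, atom_a = "CA",
                              res_b = 7, atom_b = "CB"))
  expect_error(extract_cvs(pdb, sch), "schema-unresolvable.*miss")
})

test_that("fixture PDB distances match generator ground truth", {
  fx <- make_fixture_structure(10, seed = 4, glycine_at = c(3, 7))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(fx$spec, f)
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  set.seed(9)
  pairs <- t(replicate(8, sample.int(10, 2)))
  sch <- cv_schema(data.frame(name = paste0("cv", 1:8),
                              res_a = pairs[, 1], atom_a = "CA",
                              res_b = pairs[, 2], atom_b = "CA"))
  got <- extract_cvs(pdb, sch)
  coord <- function(r) unlist(fx$spec[fx$spec$resno == r &
                                      fx$spec$elety == "CA", c("x", "y", "z")])
  truth <- apply(pairs, 1, function(p) sqrt(sum((coord(p[1]) - coord(p[2]))^2)))
  expect_equal(unname(got), truth, tolerance = 1e-6)
})

test_that("glycine CB requests fall back to CA", {
  fx <- make_fixture_structure(4, seed = 1, glycine_at = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(fx$spec, f)
  pdb <- bio3d::read.pdb(f, verbose = FALSE)
  sch <- cv_schema(data.frame(name = "g", res_a = 1, atom_a = "CA",
                              res_b = 2, atom_b = "CB"))
  expect_message(v <- extract_cvs(pdb, sch), "glycine")
  ca2 <- unlist(fx$spec[fx$spec$resno == 2 & fx$spec$elety == "CA",
                        c("x", "y", "z")])
  ca1 <- unlist(fx$spec[fx$spec$resno == 1 & fx$spec$elety == "CA",
                        c("x", "y", "z")])
  expect_equal(unname(v), sqrt(sum((ca1 - ca2)^2)), tolerance = 1e-3)
})

test_that("extract_cvs is invariant under rigid-body motion", {
  fx <- make_fixture_structure(6, seed = 11)
  sch <- cv_schema(data.frame(name = c("a", "b"), res_a = c(1, 2),
                              atom_a = "CB", res_b = c(5, 6), atom_b = "CB"))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_fixture_pdb(fx$spec, f)
  v0 <- extract_cvs(bio3d::read.pdb(f, verbose = FALSE), sch)
  set.seed(21)
  for (i in 1:3) {
    th <- runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
                c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
    Rot <- Rx %*% Rz
    sp <- fx$spec
    xyz <- as.matrix(sp[, c("x", "y", "z")]) %*% t(Rot)
    sp$x <- xyz[, 1] + 10 * i
    sp$y <- xyz[, 2] - 3
    sp$z <- xyz[, 3] + 0.5
    f2 <- tempfile(fileext = ".pdb")
    write_fixture_pdb(sp, f2)
    v <- extract_cvs(bio3d::read.pdb(f2, verbose = FALSE), sch)
    expect_equal(v, v0, tolerance = 2e-3)
  }
})

test_that("dunbrack_distances extracts by name and errors when absent", {
  fr <- c(d1 = 10.2, d2 = 15.1, other = 3)
  expect_equal(dunbrack_distances(fr), c(d1 = 10.2, d2 = 15.1))
  expect_error(dunbrack_distances(c(d1 = 10, other = 3)),
               "dunbrack-entries-missing")
})

test_that("classify_dfg reproduces the printed rule and is total", {
  expect_equal(as.character(classify_dfg(10, 15)), "IN")
  expect_equal(as.character(classify_dfg(12, 13)), "OUT")
  expect_equal(as.character(classify_dfg(10, 12.5)), "GAP")
  expect_equal(as.character(classify_dfg(10, 10)), "INTER")
  expect_equal(as.character(classify_dfg(12, 15)), "UNASSIGNED")

  # exhaustive grid against a straight-line transcription of the rule
  g <- expand.grid(d1 = seq(9, 16, by = 0.5), d2 = seq(9, 16, by = 0.5))
  got <- as.character(classify_dfg(g$d1, g$d2))
  ref <- mapply(function(d1, d2) {
    if (d1 < 11 && d2 > 14) "IN"
    else if (d1 > 11 && d2 < 14) "OUT"
    else if (d1 < 11 && d2 < 11) "INTER"
    else if (d1 > 11 && d2 > 14) "UNASSIGNED"
    else "GAP"
  }, g$d1, g$d2)
  expect_equal(got, unname(ref))
  expect_true(all(!is.na(got)))  # exactly one label per point
})

test_that("filter_unphysical rejects broken backbones with reasons", {
  ca <- rbind(rep(3.8, 9), c(rep(3.8, 4), 9, rep(3.8, 4)))
  flt <- filter_unphysical(ca)
  expect_equal(flt$keep, c(TRUE, FALSE))
  expect_match(flt$rejections$reason, "broken bond at 5")
  expect_warning(filter_unphysical(matrix(numeric(0), 0, 3)), "no frames")

  # injected breaks are found exactly
  ens <- synth_ensemble(ensemble_config(n = 400, unphysical_fraction = 0.05,
                                        seed = 3))
  flt2 <- filter_unphysical(ens$ca_dist)
  expect_equal(!flt2$keep, ens$unphysical)
  expect_equal(sum(!flt2$keep), floor(400 * 0.05))
})

test_that("standardize gives zero-mean unit-sd columns and round-trips", {
  expect_equal(standardize(matrix(c(1, 3), ncol = 1))$values[, 1], c(-1, 1))
  set.seed(2)
  x <- matrix(rnorm(100 * 20, 5, 3), 100)
  colnames(x) <- paste0("cv", 1:20)
  st <- standardize(x)
  expect_true(all(abs(colMeans(st$values)) < 1e-10))
  psd <- apply(st$values, 2, function(v) sqrt(mean((v - mean(v))^2)))
  expect_true(all(abs(psd - 1) < 1e-10))
  # idempotence and inverse
  expect_equal(standardize(st$values)$values, st$values, tolerance = 1e-12)
  expect_equal(destandardize(st, st$values), x, tolerance = 1e-10)
  expect_equal(apply_standardizer(st, x), st$values)
  # constant column is an error naming the column
  xc <- cbind(x, konst = 1)
  expect_error(standardize(xc), "constant-cv.*konst")
})

test_that("COLVAR and schema files round-trip", {
  x <- matrix(runif(20), 5, dimnames = list(NULL, paste0("cv", 1:4)))
  f <- withr::local_tempfile(fileext = ".colvar")
  write_colvar(x, f, time = 0:4)
  back <- read_colvar(f)
  expect_equal(back$values, x, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(colnames(back$values), colnames(x))
  expect_equal(back$time, 0:4)

  sch <- dunbrack_schema()
  fy <- withr::local_tempfile(fileext = ".yaml")
  write_cv_schema(sch, fy)
  expect_equal(read_cv_schema(fy), sch, ignore_attr = TRUE)
})
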