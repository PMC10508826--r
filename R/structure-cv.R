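#' Define a collective-variable schema of inter-residue distances
#'
#' The CV basis set is a fixed, ordered list of inter-residue atom-pair
#' distances (in Angstrom).  Every frame of a run carries its values in
#' schema order, so the schema is the contract between structure parsing,
#' clustering, order-parameter learning and biasing.  The two Dunbrack
#' distances used for DFG classification must be present under the
#' mandatory names `d1` (salt-bridge Lys CB to alpha-C-helix Glu CB) and
#' `d2` (salt-bridge Lys CB to DFG-Asp CB); the remainder of the basis is
#' user-supplied and protein-specific.
#'
#' @param entries `data.frame` with columns `name`, `res_a`, `atom_a`,
#'   `res_b`, `atom_b`.  Residue ids are 1-based.
#' @return A `cv_schema` object (validated data.frame).
#' @export
cv_schema <- function(entries) {
  entries <- as.data.frame(entries, stringsAsFactors = FALSE)
  need <- c("name", "res_a", "atom_a", "res_b", "atom_b")
  if (!all(need %in% names(entries)))
    stop("schema needs columns: ", paste(need, collapse = ", "))
  entries <- entries[, need]
  if (anyDuplicated(entries$name))
    stop("duplicate CV names: ",
         paste(unique(entries$name[duplicated(entries$name)]), collapse = ", "))
  if (any(entries$res_a < 1L) || any(entries$res_b < 1L))
    stop("residue ids must be >= 1 (1-based numbering)")
  class(entries) <- c("cv_schema", "data.frame")
  entries
}

#' @rdname cv_schema
#' @param file YAML file with a top-level `cvs:` list of entries.
#' @export
read_cv_schema <- function(file) {
  y <- yaml::read_yaml(file)
  if (is.null(y$cvs)) stop("schema YAML must have a top-level 'cvs' list")
  cv_schema(do.call(rbind, lapply(y$cvs, as.data.frame)))
}

#' @rdname cv_schema
#' @param schema A `cv_schema`.
#' @export
write_cv_schema <- function(schema, file) {
  stopifnot(inherits(schema, "cv_schema"))
  yaml::write_yaml(list(cvs = lapply(seq_len(nrow(schema)), function(i)
    as.list(schema[i, ]))), file)
  invisible(file)
}

# resolve one (residue, atom) request to an atom-table row index;
# Cbeta requests on glycine fall back to Calpha (logged via message)
atom_index <- function(pdb, resno, elety, entry_name, quiet = FALSE) {
  at <- pdb$atom
  hit <- which(at$resno == resno & at$elety == elety)
  if (length(hit) == 0L && identical(elety, "CB")) {
    res_rows <- which(at$resno == resno)
    if (length(res_rows) > 0L && any(at$resid[res_rows] == "GLY")) {
      hit <- which(at$resno == resno & at$elety == "CA")
      if (length(hit) > 0L && !quiet)
        message("schema entry '", entry_name, "': glycine ", resno,
                " has no CB, using CA")
    }
  }
  if (length(hit) == 0L)
    stop("schema-unresolvable: entry '", entry_name, "' needs residue ",
         resno, " atom ", elety)
  hit[1L]
}

#' Extract CV values from a parsed structure
#'
#' Computes the schema's inter-residue atom-pair distances (Angstrom) from a
#' `bio3d` PDB object.  Multi-model PDB files (as produced when a structure
#' predictor emits an ensemble) are handled by `extract_cvs_ensemble`, which
#' evaluates the schema against every model.
#'
#' @param pdb A `bio3d::read.pdb()` object (use `multi = TRUE` for
#'   ensembles).
#' @param schema A [cv_schema()].
#' @param model Model number to evaluate (for `extract_cvs`).
#' @return `extract_cvs`: named numeric vector of distances in schema
#'   order.  `extract_cvs_ensemble`: numeric matrix, one row per model.
#' @details Distances of zero (an atom paired with itself) violate the
#'   frame invariant (all values finite and positive) and raise an error.
#' @export
extract_cvs <- function(pdb, schema, model = 1L) {
  stopifnot(inherits(schema, "cv_schema"))
  xyz <- if (is.matrix(pdb$xyz)) pdb$xyz[model, ] else as.numeric(pdb$xyz)
  ia <- mapply(atom_index, schema$res_a, schema$atom_a, schema$name,
               MoreArgs = list(pdb = pdb))
  ib <- mapply(atom_index, schema$res_b, schema$atom_b, schema$name,
               MoreArgs = list(pdb = pdb))
  ca <- matrix(xyz[as.vector(t(cbind(ia * 3 - 2, ia * 3 - 1, ia * 3)))],
               ncol = 3, byrow = TRUE)
  cb <- matrix(xyz[as.vector(t(cbind(ib * 3 - 2, ib * 3 - 1, ib * 3)))],
               ncol = 3, byrow = TRUE)
  d <- sqrt(rowSums((ca - cb)^2))
  names(d) <- schema$name
  if (any(!is.finite(d)) || any(d <= 0))
    stop("invalid CV frame: distances must be finite and > 0 (offending: ",
         paste(schema$name[!is.finite(d) | d <= 0], collapse = ", "), ")")
  d
}

#' @rdname extract_cvs
#' @export
extract_cvs_ensemble <- function(pdb, schema) {
  nm <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  out <- do.call(rbind, lapply(seq_len(nm), function(m)
    extract_cvs(pdb, schema, model = m)))
  colnames(out) <- schema$name
  rownames(out) <- NULL
  out
}

#' Dunbrack distances of a frame
#'
#' Pulls the two classification distances `d1` and `d2` out of a CV frame by
#' name.
#'
#' @param frame Named numeric vector (one frame) or matrix with named
#'   columns.
#' @param schema Optional [cv_schema()]; if given, the mandatory entries are
#'   checked against it.
#' @return For a vector: `c(d1 = , d2 = )`.  For a matrix: a two-column
#'   matrix.
#' @export
dunbrack_distances <- function(frame, schema = NULL) {
  nms <- if (is.matrix(frame)) colnames(frame) else names(frame)
  if (!is.null(schema)) nms <- intersect(nms, schema$name)
  if (!all(c("d1", "d2") %in% nms))
    stop("dunbrack-entries-missing: schema/frame must contain CVs named 'd1' and 'd2'")
  if (is.matrix(frame)) frame[, c("d1", "d2"), drop = FALSE]
  else c(d1 = unname(frame["d1"]), d2 = unname(frame["d2"]))
}

#' Classify DFG state from the Dunbrack distances
#'
#' Applies the three-threshold Dunbrack rule on the (d1, d2) plane
#' (Angstrom): `IN` if d1 < 11 and d2 > 14; `OUT` if d1 > 11 and d2 < 14;
#' `INTER` if d1 < 11 and d2 < 11; `UNASSIGNED` if d1 > 11 and d2 > 14.
#' The rule leaves the strip d1 < 11, 11 <= d2 <= 14 uncovered; those
#' points, and any boundary equality, are labelled `GAP` explicitly rather
#' than silently merged into a neighbouring state, so the partition is
#' total and auditable.
#'
#' @param d1,d2 Numeric vectors of distances (Angstrom), or `d1` may be a
#'   two-column matrix as returned by [dunbrack_distances()].
#' @param thresholds The two cut-offs, default `c(11, 14)` Angstrom.
#' @return Factor with levels [dfg_states()].
#' @export
classify_dfg <- function(d1, d2 = NULL, thresholds = c(11, 14)) {
  if (is.matrix(d1) || is.data.frame(d1)) {
    d2 <- d1[, 2]
    d1 <- d1[, 1]
  }
  stopifnot(length(d1) == length(d2))
  if (any(d1 <= 0 | d2 <= 0, na.rm = TRUE)) stop("distances must be > 0")
  t1 <- thresholds[1]
  t2 <- thresholds[2]
  lab <- rep("GAP", length(d1))
  lab[d1 < t1 & d2 > t2] <- "IN"
  lab[d1 > t1 & d2 < t2] <- "OUT"
  lab[d1 < t1 & d2 < t1] <- "INTER"
  lab[d1 > t1 & d2 > t2] <- "UNASSIGNED"
  factor(lab, levels = dfg_states())
}

#' Filter structurally broken frames
#'
#' Rejects frames whose backbone trace is unphysical: any consecutive
#' Calpha-Calpha distance outside the window (default 2.5--4.5 Angstrom,
#' bracketing the 3.8 Angstrom trans spacing) marks a broken bond.
#'
#' @param ca_dist Matrix of consecutive Calpha distances (frames in rows)
#'   or a list of numeric vectors, one per frame.
#' @param window Acceptance window in Angstrom.
#' @return List with `keep` (logical vector) and `rejections` (data.frame
#'   with columns `frame`, `bond`, `reason`).
#' @export
filter_unphysical <- function(ca_dist, window = c(2.5, 4.5)) {
  if (is.list(ca_dist) && !is.data.frame(ca_dist))
    ca_dist <- do.call(rbind, ca_dist)
  ca_dist <- as.matrix(ca_dist)
  if (nrow(ca_dist) == 0L) {
    warning("no frames to filter")
    return(list(keep = logical(0),
                rejections = data.frame(frame = integer(0), bond = integer(0),
                                        reason = character(0))))
  }
  bad <- ca_dist < window[1] | ca_dist > window[2]
  keep <- !apply(bad, 1, any)
  rej <- which(bad, arr.ind = TRUE)
  rejections <- if (nrow(rej) > 0) {
    rej <- rej[order(rej[, 1], rej[, 2]), , drop = FALSE]
    data.frame(frame = unname(rej[, 1]), bond = unname(rej[, 2]),
               reason = sprintf("broken bond at %d (%.2f A)", rej[, 2],
                                ca_dist[rej]))
  } else {
    data.frame(frame = integer(0), bond = integer(0), reason = character(0))
  }
  list(keep = keep, rejections = rejections)
}

#' Standardize a CV matrix
#'
#' Z-scores each CV column with the population (1/N) standard deviation and
#' keeps the transform so it can be reapplied to other data (e.g. a mutant
#' ensemble standardized with the wild-type transform) or inverted.
#'
#' @param x Numeric CV matrix, frames in rows, named columns; at least two
#'   frames.
#' @return A list of class `cv_standardizer` with elements `values`
#'   (standardized matrix), `center` and `scale` (named vectors).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("standardization needs >= 2 frames")
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  if (any(scl == 0)) {
    nm <- colnames(x)[scl == 0]
    if (is.null(nm)) nm <- which(scl == 0)
    stop("constant-cv: zero-variance column(s): ", paste(nm, collapse = ", "))
  }
  out <- list(values = sweep(sweep(x, 2, ctr), 2, scl, "/"),
              center = ctr, scale = scl)
  class(out) <- "cv_standardizer"
  out
}

#' @rdname standardize
#' @param scaler A `cv_standardizer`.
#' @export
apply_standardizer <- function(scaler, x) {
  stopifnot(inherits(scaler, "cv_standardizer"))
  sweep(sweep(as.matrix(x), 2, scaler$center), 2, scaler$scale, "/")
}

#' @rdname standardize
#' @param z Standardized matrix to map back to original units.
#' @export
destandardize <- function(scaler, z) {
  stopifnot(inherits(scaler, "cv_standardizer"))
  sweep(sweep(as.matrix(z), 2, scaler$scale, "*"), 2, scaler$center, "+")
}
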