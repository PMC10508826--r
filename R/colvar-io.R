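#' Read and write PLUMED-style COLVAR tables
#'
#' CV time series are exchanged as whitespace-separated tables headed by a
#' `#! FIELDS time <cv names>` line, the dialect written by PLUMED's `PRINT`
#' action, so that real MD output can be dropped in for the toy engine's.
#'
#' @param x Numeric matrix of CV values (frames in rows) with column names.
#' @param file Path to write to / read from.
#' @param time Optional numeric vector of time stamps (default `0:(n-1)`).
#' @return `read_colvar` returns a list with `time` (numeric vector) and
#'   `values` (numeric matrix with the CV names as column names).
#' @export
write_colvar <- function(x, file, time = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) stop("CV matrix must carry column names")
  if (is.null(time)) time <- seq_len(nrow(x)) - 1
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS time", paste(colnames(x), collapse = " ")), con)
  write.table(cbind(format(time, trim = TRUE), format(x, digits = 12, trim = TRUE)),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_colvar
#' @export
read_colvar <- function(file) {
  header <- readLines(file, n = 1L)
  if (!startsWith(header, "#! FIELDS"))
    stop("not a COLVAR file (missing '#! FIELDS' header): ", file)
  fields <- strsplit(sub("^#! FIELDS\\s+", "", header), "\\s+")[[1]]
  dat <- read.table(file, comment.char = "#")
  colnames(dat) <- fields
  vals <- as.matrix(dat[, setdiff(fields, "time"), drop = FALSE])
  list(time = dat$time, values = vals)
}

#' Read and write metadynamics HILLS tables
#'
#' Deposited Gaussian kernels are serialized in the PLUMED HILLS dialect:
#' `#! FIELDS time <centers> <sigma_...> height biasf`, one kernel per row.
#' Reading a HILLS file reconstructs a [bias_potential()] (frozen by
#' default, since a file on disk is a finished bias).
#'
#' @param bias A `bias_potential` object.
#' @param file File path.
#' @param cv_names Names of the biased coordinates (default `s1`, `s2`, ...).
#' @param frozen Should the bias read from file be frozen? Default `TRUE`.
#' @return `read_hills` returns a [bias_potential()].
#' @export
write_hills <- function(bias, file, cv_names = NULL) {
  stopifnot(inherits(bias, "bias_potential"))
  ds <- bias$ds
  if (is.null(cv_names)) cv_names <- paste0("s", seq_len(ds))
  hdr <- paste("#! FIELDS time", paste(cv_names, collapse = " "),
               paste(paste0("sigma_", cv_names), collapse = " "), "height biasf")
  n <- length(bias$heights)
  tm <- if (is.null(bias$times)) seq_len(n) - 1 else bias$times
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  if (n > 0) {
    tab <- cbind(tm, bias$centers, bias$sigmas, bias$heights,
                 rep(bias$bias_factor, n))
    write.table(format(tab, digits = 17, trim = TRUE), con, quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_hills
#' @export
read_hills <- function(file, frozen = TRUE) {
  header <- readLines(file, n = 1L)
  if (!startsWith(header, "#! FIELDS"))
    stop("not a HILLS file (missing '#! FIELDS' header): ", file)
  fields <- strsplit(sub("^#! FIELDS\\s+", "", header), "\\s+")[[1]]
  sig <- grep("^sigma_", fields)
  cvn <- setdiff(fields[2:(sig[1] - 1)], character(0))
  ds <- length(cvn)
  first <- readLines(file, n = 2L)
  if (length(first) < 2L || !nzchar(trimws(first[2]))) {
    return(bias_potential(ds = ds, bias_factor = NA_real_, frozen = frozen))
  }
  dat <- read.table(file, comment.char = "#")
  colnames(dat) <- fields
  bias_potential(
    centers = as.matrix(dat[, cvn, drop = FALSE]),
    sigmas = as.matrix(dat[, paste0("sigma_", cvn), drop = FALSE]),
    heights = dat$height,
    times = dat$time,
    bias_factor = dat$biasf[1],
    frozen = frozen
  )
}
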