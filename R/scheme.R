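#' b-value acquisition scheme
#'
#' An ordered table of diffusion weightings (b-values), the number of scan
#' averages (NSA) acquired at each, and the number of orthogonal diffusion
#' directions averaged by the scanner. The first b-value must be 0 (the
#' unweighted reference used for normalization).
#'
#' @param b_values strictly increasing numeric vector of b-values (s/mm^2),
#'   starting at 0.
#' @param nsa integer vector of scan-average counts, same length, all >= 1.
#' @param n_directions number of orthogonal directions averaged (>= 1).
#' @return An object of class `bvalue_scheme`.
#' @seealso [default_bvalue_scheme()] for the 17-b-value brain protocol.
#' @export
bvalue_scheme <- function(b_values, nsa = rep(1L, length(b_values)),
                          n_directions = 3L) {
  b_values <- as.numeric(b_values)
  nsa <- as.integer(nsa)
  if (length(b_values) < 2L)
    stop("a scheme needs at least two b-values")
  if (length(nsa) != length(b_values))
    stop("b_values and nsa must have the same length")
  if (b_values[1L] != 0)
    stop("the first b-value must be 0")
  if (any(diff(b_values) <= 0))
    stop("b_values must be strictly increasing")
  if (any(nsa < 1L))
    stop("all NSA counts must be >= 1")
  n_directions <- as.integer(n_directions)
  if (n_directions < 1L) stop("n_directions must be >= 1")
  structure(list(b_values = b_values, nsa = nsa,
                 n_directions = n_directions),
            class = "bvalue_scheme")
}

#' The default 17-b-value acquisition scheme
#'
#' b = 0, 10, 20, 30, 50, 70, 100, 150, 200, 300, 500, 700, 1000, 2000,
#' 3000, 5000 and 8000 s/mm^2 with NSAs 1, 3, 3, 3, 3, 3, 3, 3, 3, 3, 3,
#' 5, 5, 5, 5, 9 and 12, three orthogonal directions averaged. The first
#' 16 b-values are used for fitting; b = 8000 is held out for prediction.
#'
#' @return A [bvalue_scheme()].
#' @export
default_bvalue_scheme <- function() {
  bvalue_scheme(
    b_values = c(0, 10, 20, 30, 50, 70, 100, 150, 200, 300, 500, 700,
                 1000, 2000, 3000, 5000, 8000),
    nsa = c(1L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 3L, 5L, 5L, 5L, 5L,
            9L, 12L),
    n_directions = 3L)
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("b-value scheme:", length(x$b_values), "b-values,",
      x$n_directions, "directions\n")
  print(data.frame(b = x$b_values, nsa = x$nsa))
  invisible(x)
}

#' Read / write a b-value table sidecar
#'
#' The sidecar is a plain-text two-column table (b-value, NSA). A
#' single-line FSL-style `.bval` file (b-values only) is also accepted, in
#' which case every NSA defaults to 1.
#'
#' @param path file path.
#' @param n_directions direction count to attach (not stored in the file).
#' @return [read_bvalue_table()] returns a [bvalue_scheme()];
#'   [write_bvalue_table()] returns `path` invisibly.
#' @export
read_bvalue_table <- function(path, n_directions = 3L) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t,]+")
  if (length(fields) == 1L) {           # FSL-style .bval: one row of b-values
    b <- as.numeric(fields[[1L]])
    return(bvalue_scheme(b, rep(1L, length(b)), n_directions))
  }
  mat <- do.call(rbind, lapply(fields, function(f) as.numeric(f[1:2])))
  bvalue_scheme(mat[, 1L], mat[, 2L], n_directions)
}

#' @rdname read_bvalue_table
#' @param scheme a [bvalue_scheme()] to write.
#' @export
write_bvalue_table <- function(scheme, path) {
  writeLines(paste(format(scheme$b_values, trim = TRUE, scientific = FALSE),
                   scheme$nsa), path)
  invisible(path)
}
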