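#' @importFrom stats integrate uniroot setNames runif rnorm
#' @importFrom utils write.table read.table modifyList packageVersion
NULL

## Gauss-Legendre nodes/weights on [a, b]; reference nodes cached per order
.gl_cache <- new.env(parent = emptyenv())

gauss_legendre <- function(n, a, b) {
  key <- as.character(n)
  ref <- .gl_cache[[key]]
  if (is.null(ref)) {
    ref <- pracma::gaussLegendre(n, -1, 1)
    .gl_cache[[key]] <- ref
  }
  list(x = (a + b) / 2 + (b - a) / 2 * ref$x, w = (b - a) / 2 * ref$w)
}

## Composite Simpson weights for n (odd) equispaced points with spacing h
simpson_weights <- function(n, h) {
  stopifnot(n >= 3L, n %% 2L == 1L)
  h / 3 * c(1, rep(c(4, 2), (n - 1L) / 2 - 1L), 4, 1)
}

## Odd-length equispaced grid covering [a, b] with spacing <= by
simpson_grid <- function(a, b, by) {
  n <- max(3L, ceiling((b - a) / by) + 1L)
  if (n %% 2L == 0L) n <- n + 1L
  x <- seq(a, b, length.out = n)
  list(x = x, w = simpson_weights(n, x[2L] - x[1L]))
}

assert_scalar_num <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  invisible(x)
}

assert_finite <- function(x, name) {
  if (!all(is.finite(Re(x))) || (is.complex(x) && !all(is.finite(Im(x)))))
    stop("'", name, "' contains non-finite values", call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
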