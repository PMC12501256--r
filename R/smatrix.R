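#' Test whether an integer is prime
#'
#' Trial division; intended for the small mask orders used here.
#'
#' @param x integer scalar.
#' @return `TRUE` if `x` is prime.
#' @keywords internal
is_prime <- function(x) {
  if (length(x) != 1L || is.na(x) || x != as.integer(x)) return(FALSE)
  x <- as.integer(x)
  if (x < 2L) return(FALSE)
  if (x < 4L) return(TRUE)
  if (x %% 2L == 0L) return(FALSE)
  d <- 3L
  while (d * d <= x) {
    if (x %% d == 0L) return(FALSE)
    d <- d + 2L
  }
  TRUE
}

# nonzero quadratic residues modulo a prime, by exhaustive squaring
quadratic_residues <- function(p) {
  sort(unique((seq_len(p - 1L)^2) %% p))
}

#' Quadratic-residue indicator modulo a prime
#'
#' Returns +1 where `j mod p` is a nonzero quadratic residue, 0 where
#' `j` is divisible by `p`, and -1 otherwise (the Legendre symbol).
#'
#' @param j integer vector (any sign; reduced modulo `p`).
#' @param p odd prime modulus.
#' @return integer vector in \{-1, 0, +1\}.
#' @keywords internal
residue_indicator <- function(j, p) {
  r <- as.integer(j %% p)
  qr <- quadratic_residues(p)
  out <- integer(length(r))
  out[r != 0L] <- -1L
  out[r %in% qr] <- 1L
  out
}

#' Construct a cyclic S-matrix from a twin-prime pair
#'
#' Builds the binary cyclic S-matrix of order `n = p * q` from twin primes
#' `p` and `q = p + 2` using the quadratic-residue (twin-prime) construction.
#' The first row is derived from the two residue indicator functions
#' `f (mod p)` and `g (mod q)`: entry `j` is 0 when
#' `(f(j) - g(j)) * g(j) == 0` and 1 otherwise. Every subsequent row is the
#' left circular shift of the previous one, so `S[i, j] = S[0, (i + j) mod n]`
#' (0-based). The resulting matrix has exactly `(n + 1) / 2` ones in every
#' row and column and satisfies the Gram identity
#' `S %*% t(S) = ((n + 1) / 4) * (I + J)`, which is what makes the
#' closed-form inverse of [smatrix_inverse()] exact.
#'
#' @param p odd prime.
#' @param q odd prime with `q = p + 2`.
#' @return An object of class `"smatrix"`: a list with elements `p`, `q`,
#'   `n`, `first_row` (length-`n` 0/1 integer vector) and `matrix`
#'   (`n x n` 0/1 integer matrix).
#' @examples
#' S <- twin_prime_smatrix(3, 5)
#' S$n               # 15
#' sum(S$first_row)  # (n + 1) / 2 = 8
#' @seealso [smatrix_inverse()], [validate_smatrix()]
#' @export
twin_prime_smatrix <- function(p, q) {
  if (!is_prime(p) || !is_prime(q)) {
    stop("p and q must both be prime (got p = ", p, ", q = ", q, ")")
  }
  p <- as.integer(p); q <- as.integer(q)
  if (q - p != 2L) {
    stop("p and q must be twin primes with q = p + 2 (got p = ", p,
         ", q = ", q, ")")
  }
  n <- p * q
  j <- 0:(n - 1L)
  f <- residue_indicator(j, p)
  g <- residue_indicator(j, q)
  first_row <- ifelse((f - g) * g == 0L, 0L, 1L)
  # S[i, j] = first_row[(i + j) mod n], 0-based
  idx <- outer(0:(n - 1L), 0:(n - 1L), function(i, jj) (i + jj) %% n) + 1L
  mat <- matrix(first_row[idx], n, n)
  storage.mode(mat) <- "integer"
  structure(
    list(p = p, q = q, n = n, first_row = first_row, matrix = mat,
         construction = "twin_prime"),
    class = "smatrix"
  )
}

#' @export
print.smatrix <- function(x, ...) {
  cat(sprintf("Cyclic S-matrix: order n = %d (twin primes p = %d, q = %d)\n",
              x$n, x$p, x$q))
  cat(sprintf("  row/column weight: %d ones out of %d\n",
              sum(x$first_row), x$n))
  invisible(x)
}

#' Closed-form inverse of an S-matrix
#'
#' For an S-matrix of order `n` the inverse is available without numerical
#' inversion: `S^{-1} = 2 / (n + 1) * (2 * t(S) - J)`, with `J` the all-ones
#' matrix. Its entries take exactly two values, `2 / (n + 1)` and
#' `-2 / (n + 1)`.
#'
#' @param S an `"smatrix"` object from [twin_prime_smatrix()].
#' @return A dense numeric `n x n` matrix, the exact inverse of `S$matrix`.
#' @examples
#' S <- twin_prime_smatrix(3, 5)
#' max(abs(smatrix_inverse(S) %*% S$matrix - diag(S$n)))  # 0
#' @export
smatrix_inverse <- function(S) {
  stopifnot(inherits(S, "smatrix"))
  (2 / (S$n + 1)) * (2 * t(S$matrix) - 1)
}

#' Validate the defining invariants of a cyclic S-matrix
#'
#' Checks, on any square binary matrix, the properties that the twin-prime
#' construction guarantees: binarity, the cyclic left-shift structure
#' between consecutive rows, row and column weights of `(n + 1) / 2`, and
#' the Gram identity `S %*% t(S) = ((n + 1) / 4) * (I + J)`. All checks use
#' integer arithmetic. Failures are reported, not raised, so the function
#' can be used to audit candidate matrices.
#'
#' @param S an `"smatrix"` object, or a plain square 0/1 matrix.
#' @return A data.frame with columns `check` and `pass`, one row per
#'   invariant, plus an attribute `"valid"` (all passed).
#' @examples
#' rep <- validate_smatrix(twin_prime_smatrix(3, 5))
#' all(rep$pass)
#' @export
validate_smatrix <- function(S) {
  M <- if (inherits(S, "smatrix")) S$matrix else as.matrix(S)
  n <- nrow(M)
  checks <- list()
  checks$square <- ncol(M) == n
  checks$binary <- all(M %in% c(0L, 1L))
  if (!checks$square || !checks$binary) {
    out <- data.frame(check = names(checks), pass = unlist(checks),
                      row.names = NULL)
    attr(out, "valid") <- FALSE
    return(out)
  }
  storage.mode(M) <- "integer"
  w <- (n + 1L) %/% 2L
  # cyclic: row i+1 is the left circular shift of row i
  cyc <- TRUE
  for (i in seq_len(n - 1L)) {
    if (!identical(M[i + 1L, ], M[i, c(2:n, 1L)])) { cyc <- FALSE; break }
  }
  checks$cyclic_shift <- cyc
  checks$row_weight <- all(rowSums(M) == w)
  checks$col_weight <- all(colSums(M) == w)
  G <- M %*% t(M)
  gram_diag <- all(diag(G) == w)
  off <- G; diag(off) <- (n + 1L) %/% 4L
  checks$gram_structure <- gram_diag && all(off == (n + 1L) %/% 4L) &&
    (n %% 4L) == 3L
  out <- data.frame(check = names(checks), pass = unlist(checks),
                    row.names = NULL)
  attr(out, "valid") <- all(out$pass)
  out
}
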