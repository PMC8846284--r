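#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero, matching how diagnostic
#' tables are conventionally printed (e.g. 77.75 -> 77.8). Base [round()]
#' uses banker's rounding, which would print 0.5-ties inconsistently with
#' clinical tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a proportion as a percentage at table precision
#'
#' @param p proportion in \[0, 1\] (NA allowed).
#' @param digits decimal digits of the percentage (default 1).
#' @return numeric percentage rounded half away from zero.
#' @export
asPercent <- function(p, digits = 1) roundHalfUp(100 * p, digits)

#' Derive a reproducible sub-stream seed
#'
#' Hashes a global seed together with any number of string/numeric tokens
#' (stage name, subject id, replicate index) into a 31-bit seed using the
#' FNV-1a scheme. Inserting or removing one subject therefore never perturbs
#' the random draws of another.
#'
#' @param globalSeed integer master seed.
#' @param ... tokens (coerced to character) naming the sub-stream.
#' @return integer in \[1, 2^31 - 2\] usable with [set.seed()].
#' @export
deriveSeed <- function(globalSeed, ...) {
  tokens <- paste(c(as.character(globalSeed), vapply(list(...), as.character, "")),
                  collapse = "\x1f")
  bytes <- utf8ToInt(tokens)
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor on doubles below 2^32, via 16-bit halves
    lo <- bitwXor(h %% 65536, b %% 65536)
    hi <- bitwXor(h %/% 65536, b %/% 65536)
    h <- hi * 65536 + lo
    # 32-bit modular multiply by the FNV prime, exact in doubles
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (((hi * p) %% 65536) * 65536 + lo * p) %% 4294967296
  }
  as.integer(h %% 2147483645) + 1L
}

#' @keywords internal
stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Separable box smoothing of a 3D array
#'
#' Mean filter with half-width `r` applied along each axis in turn
#' (replicated edges). Used by the learned segmentation backend to build
#' multiscale context features.
#'
#' @param a 3D numeric array.
#' @param r half-width in voxels (window 2r+1).
#' @return smoothed array of the same shape.
#' @export
boxBlur3 <- function(a, r = 1) {
  if (r < 1) return(a)
  blur1 <- function(x, dim) {
    d <- dim(x)
    n <- d[dim]
    idx <- lapply(seq_len(3), function(i) seq_len(d[i]))
    out <- array(0, d)
    for (off in -r:r) {
      j <- pmin(pmax(seq_len(n) + off, 1L), n)
      sel <- idx; sel[[dim]] <- j
      out <- out + do.call(`[`, c(list(x), sel, list(drop = FALSE)))
    }
    out / (2 * r + 1)
  }
  blur1(blur1(blur1(a, 1), 2), 3)
}

# mean-pooling downsample by integer factor (used by the registration pyramid)
#' @keywords internal
poolVolume <- function(a, factor) {
  if (factor == 1L) return(a)
  d <- dim(a)
  nd <- d %/% factor
  a <- a[seq_len(nd[1] * factor), seq_len(nd[2] * factor), seq_len(nd[3] * factor),
         drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  apply(a, c(2, 4, 6), mean)
}
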