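#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

.EPS <- 2.2e-16

## Run `code` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is left untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

## Deterministic sub-seed from a parent seed and a label, kept inside the
## 32-bit integer range so downstream set.seed() calls are portable.
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(as.character(label))) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(seed) %% 2147480009 * 7919 + h + 1) %% 2147480009)
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

## Shift a matrix by (dr, dc), padding the vacated margin with `fill`.
shift_matrix <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs)) out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

## 1-D Gaussian kernel, radius 3*sigma, normalized to sum 1.
gaussian_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k / sum(k)
}

## Convolve a 1-3D array along one axis with reflect boundary handling.
conv_axis_reflect <- function(arr, kernel, axis) {
  d <- dim(arr) %||% length(arr)
  if (length(kernel) == 1L) return(arr * kernel)
  nd <- length(d)
  perm <- c(axis, setdiff(seq_len(nd), axis))
  x <- aperm(array(arr, d), perm)
  L <- dim(x)[1]
  xm <- matrix(x, nrow = L)
  r <- (length(kernel) - 1L) / 2L
  out <- matrix(0, L, ncol(xm))
  idx0 <- seq_len(L)
  for (t in seq_along(kernel)) {
    off <- t - 1L - r
    idx <- idx0 + off
    # reflect (symmetric about the boundary sample)
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > L, 2L * L - idx, idx)
    idx <- pmax(1L, pmin(L, idx))
    out <- out + kernel[t] * xm[idx, , drop = FALSE]
  }
  y <- array(out, dim(x))
  aperm(y, order(perm))
}

## Separable Gaussian smoothing of a 2-D or 3-D array, reflect boundary.
gauss_smooth <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  k <- gaussian_kernel(sigma)
  d <- dim(arr)
  for (ax in seq_along(d)) if (d[ax] > 1) arr <- conv_axis_reflect(arr, k, ax)
  arr
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## Shift an n-D array by `s` along axis `ax`, filling the vacated margin.
shift_array <- function(arr, ax, s, fill = 0) {
  d <- dim(arr)
  out <- array(fill, d)
  n <- d[ax]
  if (abs(s) >= n) return(out)
  src <- if (s >= 0) seq_len(n - s) else seq.int(1 - s, n)
  dst <- src + s
  idx_dst <- lapply(d, seq_len); idx_dst[[ax]] <- dst
  idx_src <- lapply(d, seq_len); idx_src[[ax]] <- src
  block <- do.call(`[`, c(list(arr), idx_src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), idx_dst, list(block)))
}

## Fast quantile (type 7) of a numeric vector.
qtl <- function(x, p) stats::quantile(x, p, names = FALSE, type = 7)
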