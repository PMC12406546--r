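# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global random-number state set from `seed`, then
#' restores the previous state, so library calls never perturb a caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

# Row-normalised Gaussian smoothing matrix (n x n); sigma in pixels.
# sigma <= 0 returns the identity. Kernel truncated at 4 sigma.
gaussian_smoother <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  k <- exp(-0.5 * (d / sigma)^2)
  k[d > 4 * sigma] <- 0
  k / rowSums(k)
}

# Bilinear upsampling of a coarse matrix onto an nr x nc grid, with the
# coarse nodes placed at the grid corners.
bilinear_upsample <- function(coarse, nr, nc) {
  kr <- nrow(coarse); kc <- ncol(coarse)
  if (kr == 1L) coarse <- rbind(coarse, coarse)
  if (kc == 1L) coarse <- cbind(coarse, coarse)
  kr <- nrow(coarse); kc <- ncol(coarse)
  rx <- if (nr == 1L) 1 else seq(1, kr, length.out = nr)
  cx <- if (nc == 1L) 1 else seq(1, kc, length.out = nc)
  r0 <- pmin(floor(rx), kr - 1L); fr <- rx - r0
  c0 <- pmin(floor(cx), kc - 1L); fc <- cx - c0
  a <- coarse[r0, c0, drop = FALSE]
  b <- coarse[r0 + 1L, c0, drop = FALSE]
  cc <- coarse[r0, c0 + 1L, drop = FALSE]
  d <- coarse[r0 + 1L, c0 + 1L, drop = FALSE]
  wfr <- matrix(fr, nr, nc)
  wfc <- matrix(fc, nr, nc, byrow = TRUE)
  a * (1 - wfr) * (1 - wfc) + b * wfr * (1 - wfc) +
    cc * (1 - wfr) * wfc + d * wfr * wfc
}

# Shannon entropy in bits with the 0 * log 0 := 0 convention.
entropy_bits <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
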