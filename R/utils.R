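# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. `seed = NULL` leaves the global stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("crestscope_validation", "error")))
}

stop_bounds <- function(...) {
  stop(errorCondition(paste0(...), class = c("crestscope_bounds", "error")))
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(name, " must be a single finite number")
  }
  if (positive && x <= 0) stop_validation(name, " must be > 0")
  if (nonneg && x < 0) stop_validation(name, " must be >= 0")
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_validation(name, " must be a whole number")
  }
  invisible(x)
}

# index permutation that moves the zero-frequency bin (index 1 of an
# unshifted DFT axis) to the centered position n %/% 2 + 1
fftshift_index <- function(n) {
  ((seq_len(n) - 1L - n %/% 2L) %% n) + 1L
}

# centered DFT frequency axis in cycles per um
freq_axis <- function(n, pixel_size_um) {
  (seq_len(n) - 1L - n %/% 2L) / (n * pixel_size_um)
}

# separable Gaussian blur with edge replication; sigma in pixels
gauss_blur <- function(mat, sigma_px) {
  if (sigma_px <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- dnorm(seq(-r, r), sd = sigma_px)
  k <- k / sum(k)
  blur1d <- function(m) {
    n <- nrow(m)
    pad <- rbind(
      m[rep(1L, r), , drop = FALSE],
      m,
      m[rep(n, r), , drop = FALSE]
    )
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur1d(t(blur1d(mat))))
}
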