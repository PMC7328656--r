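# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators never disturb the global stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a master seed. Keeps all child
# seeds below 2^31 so they remain valid R integers.
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + stream * 16807) %% 2147483647)
}

# Convert an RGB image array (height x width x 3, values in [0, 1]) to an
# 8-bit luminance matrix (integer 0..255) using Rec. 601 weights.
luminance255 <- function(image) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] >= 3L)
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  matrix(as.integer(round(g * 255)), nrow = nrow(g), ncol = ncol(g))
}

# 8-connectivity connected-component labelling by breadth-first flood fill.
# `mask` is a logical matrix; returns an integer matrix of labels (0 =
# background). Intended for small windows (e.g. 100 x 100 pixels).
label_components8 <- function(mask) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  todo <- which(mask)
  lab <- 0L
  off <- c(-1L, 1L, -nr, nr, -nr - 1L, -nr + 1L, nr - 1L, nr + 1L)
  for (start in todo) {
    if (labels[start] != 0L) next
    lab <- lab + 1L
    frontier <- start
    labels[start] <- lab
    while (length(frontier) > 0L) {
      rows <- (frontier - 1L) %% nr + 1L
      nbr <- rep(frontier, each = 8L) + rep(off, times = length(frontier))
      # reject wrap-around across matrix columns and out-of-range indices
      nrow_ok <- abs(((nbr - 1L) %% nr + 1L) - rep(rows, each = 8L)) <= 1L
      keep <- nbr >= 1L & nbr <= nr * nc & nrow_ok
      nbr <- unique(nbr[keep])
      nbr <- nbr[mask[nbr] & labels[nbr] == 0L]
      labels[nbr] <- lab
      frontier <- nbr
    }
  }
  labels
}

# Round half away from zero to `digits` decimals (IEC 60559 banker's rounding
# in base round() would give 0.5 -> 0); used for reported centimeters.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a
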