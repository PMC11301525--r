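# Internal helpers shared across modules.

# Run `expr` under a temporary RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

as_binary_matrix <- function(mask, arg = "mask") {
  if (is.logical(mask)) {
    m <- mask
    storage.mode(m) <- "integer"
    return(m)
  }
  if (!is.matrix(mask) || !is.numeric(mask))
    stop(sprintf("`%s` must be a logical or numeric matrix", arg))
  if (any(!mask %in% c(0, 1)))
    stop(sprintf("`%s` must contain only 0/1 values", arg))
  m <- mask
  storage.mode(m) <- "integer"
  m
}

as_gray_matrix <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix", arg))
  if (anyNA(image) || min(image) < 0 || max(image) > 1)
    stop(sprintf("`%s` must have all values in [0, 1]", arg))
  image
}

# Mirror (edge-repeating) padding by `k` pixels on every side.
pad_mirror <- function(m, k) {
  h <- nrow(m); w <- ncol(m)
  stopifnot(k < h, k < w)
  ridx <- c(k:1, 1:h, h:(h - k + 1))
  cidx <- c(k:1, 1:w, w:(w - k + 1))
  m[ridx, cidx, drop = FALSE]
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
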