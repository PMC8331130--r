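# internal helpers shared across modules

# run `expr` under a fixed RNG seed without disturbing the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# round half away from zero (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x == as.integer(x)

assert_mask <- function(mask) {
  if (!is.matrix(mask)) stop_validation("mask must be a matrix")
  if (!all(mask %in% c(0L, 1L))) stop_validation("mask values must be 0 or 1")
  invisible(mask)
}

# raster order = row-major, top-left to bottom-right; returns the raster
# position (1-based) of matrix element (i, j) in an h x w matrix
raster_pos <- function(i, j, w) (i - 1L) * w + j
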