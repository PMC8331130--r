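# The twelve working color indices: four per-pixel index families (PAT, DIF,
# ROO, GLD), each instantiated on the three channels with the cyclic channel
# order R -> G -> B -> R. For primary channel X with cyclic successor Y and
# remaining channel Z:
#   PAT_X = X / (X + Y)        proportion among two bands
#   DIF_X = 2X - Y - Z         excess-channel difference (can be negative)
#   ROO_X = X / Y              ratio over other
#   GLD_X = (X - Y) / (X + Z)  asymmetric normalized contrast
# All divisions use the zero-denominator guard (0/0 := 0), so every plane is
# finite; a pure black pixel gets 0 in all twelve planes.

#' Guarded division
#'
#' Division with the zero-denominator convention used by all color indices:
#' wherever `den == 0` the result is defined as 0, keeping index planes
#' finite even for pure-black pixels.
#'
#' @param num,den numeric vectors.
#' @return `num / den` with 0 wherever `den == 0`.
#' @export
safe_div <- function(num, den) {
  out <- num / den
  out[den == 0] <- 0
  out
}

index_formula <- function(family, x, y, z) {
  force(x); force(y); force(z)
  switch(family,
    PAT = function(R, G, B) {
      e <- environment(); safe_div(e[[x]], e[[x]] + e[[y]])
    },
    DIF = function(R, G, B) {
      e <- environment(); 2 * e[[x]] - e[[y]] - e[[z]]
    },
    ROO = function(R, G, B) {
      e <- environment(); safe_div(e[[x]], e[[y]])
    },
    GLD = function(R, G, B) {
      e <- environment(); safe_div(e[[x]] - e[[y]], e[[x]] + e[[z]])
    },
    stop_validation("unknown index family '%s'", family))
}

#' Default color-index registry
#'
#' Returns the ordered registry of the twelve default per-pixel color
#' indices: `PAT_R, PAT_G, PAT_B, DIF_R, DIF_G, DIF_B, ROO_R, ROO_G, ROO_B,
#' GLD_R, GLD_G, GLD_B`. Each entry is a pure function of numeric vectors
#' `(R, G, B)`. The registry is an ordinary named list (class
#' `"index_registry"`), so alternative index definitions can be substituted
#' with [register_index()] without touching downstream code.
#'
#' @return An `"index_registry"`: a named, ordered list of functions.
#' @export
default_index_registry <- function() {
  cyc <- list(R = c("R", "G", "B"), G = c("G", "B", "R"), B = c("B", "R", "G"))
  reg <- list()
  for (family in c("PAT", "DIF", "ROO", "GLD"))
    for (ch in c("R", "G", "B")) {
      xyz <- cyc[[ch]]
      reg[[paste(family, ch, sep = "_")]] <-
        index_formula(family, xyz[1], xyz[2], xyz[3])
    }
  structure(reg, class = "index_registry")
}

#' Register or replace a color index
#'
#' @param registry an `"index_registry"` (see [default_index_registry()]).
#' @param name unique plane name.
#' @param formula a pure function of `(R, G, B)` returning one numeric value
#'   per pixel.
#' @param replace set `TRUE` to overwrite an existing plane of that name.
#' @return the updated registry.
#' @examples
#' reg <- register_index(default_index_registry(), "GREENNESS",
#'                       function(R, G, B) safe_div(G, R + G + B))
#' @export
register_index <- function(registry, name, formula, replace = FALSE) {
  if (!inherits(registry, "index_registry"))
    stop_validation("'registry' must be an index_registry")
  if (!is.function(formula))
    stop_validation("'formula' must be a function of (R, G, B)")
  if (name %in% names(registry) && !replace)
    stop_validation("index '%s' already registered (use replace = TRUE)", name)
  registry[[name]] <- formula
  registry
}

#' Compute the color-index stack
#'
#' Evaluates every registered index per pixel, producing an `h x w x d` real
#' array (`d = 12` for the default registry) with planes in registry order.
#' Channel arithmetic is done in floating point after casting from 8-bit.
#'
#' @param image RGB image array from [load_rgb_image()].
#' @param registry index registry; defaults to the twelve standard indices.
#' @return numeric array `h x w x d` with plane names on the third axis.
#' @export
compute_index_stack <- function(image, registry = default_index_registry()) {
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  h <- dim(image)[1]; w <- dim(image)[2]
  R <- as.numeric(image[, , 1])
  G <- as.numeric(image[, , 2])
  B <- as.numeric(image[, , 3])
  d <- length(registry)
  out <- array(NA_real_, c(h, w, d),
               dimnames = list(NULL, NULL, names(registry)))
  for (i in seq_len(d)) {
    v <- registry[[i]](R, G, B)
    if (!all(is.finite(v)))
      stop_validation("index '%s' produced non-finite values", names(registry)[i])
    out[, , i] <- v
  }
  out
}
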