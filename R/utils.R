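# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package functions that consume
#' randomness are pure functions of their `seed` argument and never perturb
#' the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-task seed from a global seed and string labels
#'
#' Polynomial rolling hash of the labels combined with the global seed,
#' reduced mod 2^31 - 1 so every derived seed is a valid R/C++ 32-bit seed.
#' Used to give each (feature, target) permutation test its own independent,
#' order-independent stream.
#' @param global_seed integer.
#' @param ... character labels.
#' @return integer in [0, 2^31 - 2].
#' @keywords internal
#' @noRd
hash_seed <- function(global_seed, ...) {
  s <- paste(c(...), collapse = "\r")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  as.integer(((as.numeric(global_seed) %% 2147483647) * 7919 + h) %% 2147483647)
}

# consistent MAD-based scale: 1.4826 * median absolute deviation
robust_scale <- function(x) stats::mad(x, constant = 1.4826, na.rm = TRUE)

stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# well labels like "B07" -> list(row, col); vectorized
parse_wells <- function(well) {
  row <- toupper(substr(well, 1, 1))
  col <- suppressWarnings(as.integer(substring(well, 2)))
  list(row = row, col = col)
}

# validate wells against a 96- or 384-well layout, returning offending labels
invalid_wells <- function(well, plate_format) {
  pw <- parse_wells(well)
  if (plate_format == 96) {
    bad <- !(pw$row %in% LETTERS[1:8]) | is.na(pw$col) | pw$col < 1 | pw$col > 12
  } else {
    bad <- !(pw$row %in% LETTERS[1:16]) | is.na(pw$col) | pw$col < 1 | pw$col > 24
  }
  unique(well[bad])
}

# infer plate format (96/384) from well labels; error on impossible wells
infer_plate_format <- function(well) {
  if (length(invalid_wells(well, 96)) == 0) return(96L)
  bad <- invalid_wells(well, 384)
  if (length(bad) > 0) {
    stop_format("invalid well label(s) for 96/384-well formats: %s",
                paste(head(bad, 10), collapse = ", "))
  }
  384L
}
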