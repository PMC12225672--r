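# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
assert_scalar_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  invisible(x)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic substream seed: one global seed, one fixed offset per
# generator, folded into [0, 2^31 - 2] so it stays a valid R integer.
derive_seed <- function(seed, stream) {
  offsets <- c(markers = 11L, naf = 23L, leakage = 37L, morphometry = 53L,
               bootstrap = 71L, pipeline = 89L)
  if (!stream %in% names(offsets))
    stop("unknown RNG stream: ", stream, call. = FALSE)
  as.integer((as.double(seed) * 7919 + offsets[[stream]]) %% (2^31 - 1))
}

# Simplex check used by several modules.
check_simplex <- function(p, tol = 1e-9, name = "proportions") {
  if (any(!is.finite(p)) || any(p < -tol))
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("'%s' must sum to 1 (got %.12g)", name, sum(p)),
         call. = FALSE)
  invisible(p)
}

compartments <- function() c("plastid", "cytosol", "vacuole")

# TSV writers/readers: plain tab-separated text, no quoting surprises,
# so reruns are byte-identical.
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}
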