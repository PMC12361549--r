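## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertScalarNumber <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(min), format(max)), call. = FALSE)
  invisible(x)
}

.assertFraction <- function(x, name) .assertScalarNumber(x, name, 0, 1)

## Derive a stage-specific seed from a run seed by a fixed counter scheme,
## kept below .Machine$integer.max so set.seed() accepts it.
.deriveSeed <- function(seed, stage) {
  offsets <- c(simulate = 11L, qc = 23L, summarize = 37L, impute = 41L,
               diffexp = 53L, trajectory = 67L, cross_organ = 71L,
               lmm = 83L, hubs = 97L, surequant = 101L)
  off <- offsets[[stage]] %||% 7L
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483647)
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(path)
}
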