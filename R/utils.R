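#' @include AllClasses.R
NULL

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring
# the caller's state afterwards.
.withSeed <- function(seed, expr) {
  if (is.na(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# djb2 string hash rendered as 8 hex digits; enough to fingerprint a
# configuration for provenance, not cryptographic.
.djb2 <- function(s) {
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 4294967296
  paste0(format(as.hexmode(h %/% 65536), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}

#' Short digest identifying a configuration object
#'
#' Deterministic fingerprint of all settings, recorded alongside feature
#' tables and evaluation reports so results can be traced to the exact
#' configuration that produced them.
#'
#' @param config a \code{\link{WaveletFeatureConfig}},
#'   \code{\link{FSDParams}} or \code{\link{PipelineConfig}}.
#' @return An 8-character hex string.
#' @export
configDigest <- function(config) {
  canon <- function(obj) {
    slots <- sort(slotNames(class(obj)))
    parts <- vapply(slots, function(sn) {
      v <- slot(obj, sn)
      if (isVirtualClass(class(v)) || is(v, "FSDParams") ||
          is(v, "WaveletFeatureConfig"))
        paste0(sn, "={", canon(v), "}")
      else
        paste0(sn, "=", paste(deparse(v), collapse = ""))
    }, character(1))
    paste(parts, collapse = ";")
  }
  .djb2(paste0(class(config), ":", canon(config)))
}
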