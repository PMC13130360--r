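# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable md5 of an R object via canonical JSON; used for manifest checksums.
object_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f), add = TRUE)
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null")
  unname(tools::md5sum(f))
}

file_hash <- function(path) unname(tools::md5sum(path))

# z = (x - mean(ref)) / sd(ref); errors on zero spread in the reference.
zscore_against <- function(x, ref = x, label = "values") {
  m <- mean(ref)
  s <- stats::sd(ref)
  if (!is.finite(s) || s == 0)
    stop(sprintf("zero standard deviation in z-scoring reference for %s",
                 label), call. = FALSE)
  (x - m) / s
}

# Derive a per-task child seed from a base seed, kept inside 32-bit range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483587)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid CohortSpec: field '%s' %s", field, msg), call. = FALSE)
}
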