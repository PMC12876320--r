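#' @keywords internal
"_PACKAGE"

#' @importFrom stats approx coef dnorm kmeans lm.fit mad median model.matrix
#'   p.adjust pbinom pnbinom pnorm pt quantile rbinom rgamma rlnorm rnbinom
#'   rnorm runif sd setNames var wilcox.test cor.test
#' @importFrom utils read.delim write.table head tail
NULL

# stop with the calling function's name attached, for traceable validation errors
abort_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != floor(x) || x < min)
    abort_field(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

check_positive <- function(x, field) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0)
    abort_field(field, "must be a single positive number")
  as.numeric(x)
}

check_fraction <- function(x, field, open_left = FALSE) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1 ||
      (open_left && x == 0))
    abort_field(field, "must be a fraction in [0,1]")
  as.numeric(x)
}

#' Hash an R object
#'
#' MD5 digest of the object's serialized form, used for provenance manifests
#' and leakage checks (e.g. asserting that a training fold is untouched by
#' held-out data).
#'
#' @param x any R object
#' @return character scalar, 32 hex digits
#' @export
hash_object <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(x, tf, version = 2, compress = FALSE)
  unname(tools::md5sum(tf))
}

# deterministic per-stage seed from a global seed: documented counter scheme
# stage_seed = (seed * 101 + counter) mod 2^31-1, kept in 32-bit integer range
stage_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 101 + counter) %% 2147483647)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE, ...)
}
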