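#' @keywords internal
"_PACKAGE"

#' @importFrom stats dhyper phyper rhyper rbinom runif rnbinom rpois qchisq
#'   pchisq median setNames dbinom pbinom
#' @importFrom utils head write.table read.delim
NULL

# log(exp(a) + exp(b)) elementwise, tolerating -Inf
logspace_add <- function(a, b) {
  m <- pmax(a, b)
  d <- -abs(a - b)
  out <- m + log1p(exp(d))
  out[is.infinite(m) & m < 0] <- -Inf
  out
}

# variant key "chrom:pos:ref:alt"
variant_key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop(sprintf("'%s' must be a single non-negative integer", name), call. = FALSE)
  invisible(x)
}
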