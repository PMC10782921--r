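#' @import methods
#' @importFrom stats rnorm runif rpois predict sd setNames t.test
#' @importFrom utils read.table write.table head tail
#' @importFrom Rcpp evalCpp
#' @useDynLib rein, .registration = TRUE
NULL

## Evaluate an expression under a temporary RNG state.  All seeded package
## operations (negative sampling, fixture generation, model training) go
## through here so that callers' RNG streams are left untouched.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has.seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has.seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a child seed from a base seed, kept inside the 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + as.numeric(k) * 12347L) %% 2147483629)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Regulatory element class labels
#'
#' The four cis-regulatory element classes handled by the package, in
#' decreasing label priority, plus the `"unlabeled"` state used for anchor
#' nodes not hit by any annotated element.
#'
#' @return Character vector of the four element classes in priority order.
#' @examples
#' elementClasses()
#' @export
elementClasses <- function() {
  c("silencer", "non_silencer", "enhancer", "promoter")
}

nodeLabelLevels <- function() c(elementClasses(), "unlabeled")
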