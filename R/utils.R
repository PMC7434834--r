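#' @useDynLib sctrnnpb, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef fft predict residuals rnorm runif sd simulate
#' @importFrom utils head write.csv read.csv
NULL

# run expr with a locally seeded RNG, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed derivation; keeps results < 2^31 for any small
# master seed and offset
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483629)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_scalar_num <- function(x, field, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_field(field, "must be a single finite number")
  if (strict_lower && x <= lower)
    stop_field(field, sprintf("must be > %s", lower))
  if (!strict_lower && x < lower)
    stop_field(field, sprintf("must be >= %s", lower))
  if (x > upper)
    stop_field(field, sprintf("must be <= %s", upper))
  invisible(x)
}

proprio_idx <- function(roles) which(roles == "proprio")
vision_idx <- function(roles) which(roles == "vision")

#' Channel roles of a sequence
#'
#' @param x a sequence matrix produced by the generator.
#' @return character vector of per-channel tags (`"proprio"`/`"vision"`).
#' @export
seq_roles <- function(x) {
  r <- attr(x, "roles")
  if (is.null(r)) stop("sequence carries no channel roles", call. = FALSE)
  r
}
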