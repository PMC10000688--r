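# internal helpers shared across the package

# classed error constructors; every user-facing failure mode has a condition
# class so callers (and tests) can discriminate without parsing messages
sn_stop <- function(class, msg, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "stainnorm_error")))
}

sn_format_error      <- function(msg) sn_stop("sn_format_error", msg)
sn_domain_error      <- function(msg) sn_stop("sn_domain_error", msg)
sn_range_error       <- function(msg) sn_stop("sn_range_error", msg)
sn_io_error          <- function(msg) sn_stop("sn_io_error", msg)
sn_metadata_error    <- function(msg) sn_stop("sn_metadata_error", msg)
sn_validation_error  <- function(msg) sn_stop("sn_validation_error", msg)
sn_insufficient_tissue_error <- function(msg) sn_stop("sn_insufficient_tissue_error", msg)
sn_degenerate_stain_error    <- function(msg) sn_stop("sn_degenerate_stain_error", msg)
sn_undefined_agreement_error <- function(msg) sn_stop("sn_undefined_agreement_error", msg)
sn_degenerate_variance_error <- function(msg) sn_stop("sn_degenerate_variance_error", msg)

# round-half-up (base round() is banker's); quantized image values must not
# depend on parity of the integer part
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# run code with an isolated RNG stream seeded by `seed`, restoring the
# caller's stream afterwards -- generators are pure functions of their seed
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# angle between two vectors in degrees
angle_deg <- function(u, v) {
  cu <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(clamp(cu, -1, 1)) * 180 / pi
}
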