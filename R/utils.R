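#' Derive a reproducible sub-seed from a master seed and a character key
#'
#' Stable 31-bit hash so that per-unit seeds (for example one seed per gene
#' set) do not change when other units are added or removed from a run.
#'
#' @param master integer master seed.
#' @param key character scalar (for example a gene set name).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(master, key) {
  stopifnot(length(key) == 1L, is.character(key))
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer((h + (as.numeric(master) %% 2147483647) * 7919) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# logit-scale clamp keeping pi in [1e-8, 1 - 1e-8]
.LOGIT_MAX <- stats::qlogis(1 - 1e-8)

.clamp_logit <- function(eta) clamp(eta, -.LOGIT_MAX, .LOGIT_MAX)
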