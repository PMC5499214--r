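# run code under a seed without disturbing the caller's RNG state;
# NULL seed means "use the current stream"
with_seed_if <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  withr::with_seed(as.integer(seed), force(code))
}

#' Derive a child seed from a master seed and analysis labels
#'
#' Every analysis in a suite (one trait, one set, one test) draws from its
#' own RNG stream seeded deterministically from the master seed and its
#' labels, so adding or reordering analyses never perturbs the others.
#'
#' @param master Integer master seed.
#' @param ... Character labels identifying the analysis.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @examples
#' derive_seed(42, "FY", "H3K27ac", "perm")
#' @export
derive_seed <- function(master, ...) {
  labels <- paste(c(as.character(master), ...), collapse = "/")
  h <- 0
  for (b in utf8ToInt(labels)) h <- (h * 31 + b) %% 2147483629
  as.integer((h + as.numeric(master)) %% 2147483647)
}
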