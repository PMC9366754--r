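# internal helpers

# Set the RNG seed for the remainder of the calling function, restoring the
# caller's RNG state when that function exits. NULL leaves the RNG alone.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE)
  restore <- if (has) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(seed)
  invisible(NULL)
}

# derive a stream of child seeds from one master seed (kept below 2^31)
derive_seeds <- function(seed, n, salt = 0L) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.numeric(seed) * 7919 + salt * 104729 + 1e4 * seq_len(n)) %%
            2147483629)
}

expit <- function(x) stats::plogis(x)
logit <- function(p) stats::qlogis(p)

# numerically stable log(1 + exp(eta))
log1pexp <- function(eta) {
  pmax(eta, 0) + log1p(exp(-abs(eta)))
}
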