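#' @keywords internal
"_PACKAGE"

# Derive a reproducible substream seed from a master seed and a stage label.
# Keeps the result in [1, 2^31 - 2] so it is a valid R integer seed.
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)) * 131)
  as.integer((abs(master) + h * 7919) %% (2^31 - 2) + 1)
}

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so substreams do not perturb each other.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round half away from zero (what clinical tables print), unlike base round()
# which rounds half to even.
round_half_up <- function(x, digits = 1) {
  s <- sign(x)
  s * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

clip01 <- function(p, eps = 1e-6) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
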