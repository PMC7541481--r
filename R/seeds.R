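#' Derive a reproducible sub-stream seed from a master seed
#'
#' All randomness in the package flows from one master seed. Each pipeline
#' component draws its own seed from the master via a label, so adding or
#' reordering stages never perturbs another stage's stream.
#'
#' @param master integer master seed.
#' @param label character label naming the consuming component.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' substream_seed(1L, "flash")
substream_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  # Knuth multiplicative hash over the label bytes, folded with the master
  # seed; arithmetic in doubles stays exact below 2^53.
  h <- 0
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% 2147483647
  as.integer((abs(master) %% 2147483647 + h * 2654435 %% 2147483647) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}
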