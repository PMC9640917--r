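#' Derive a component seed from a global seed
#'
#' Every stochastic component in the package (cohort generation, weight
#' initialisation, augmentation, fold splitting, ...) draws its seed through
#' this fan-out so that one integer reproduces an entire run and adding a new
#' component never perturbs the random stream of an existing one.
#'
#' @param seed Integer global seed.
#' @param component Character tag naming the consuming component, e.g.
#'   `"cohort"` or `"pretrain/fold3"`.
#' @return An integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
derive_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  m <- 2147483647 # 2^31 - 1, keeps everything in exact double integer range
  h <- 0
  for (code in utf8ToInt(component)) h <- (h * 131 + code) %% m
  as.integer((abs(seed) %% m * 48271 + h) %% m)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
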