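# Internal input checks and seed plumbing shared across modules.

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "connectisim_error")
  invisible(TRUE)
}

check_count <- function(x, name, min = 1) {
  assert_that(
    is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == floor(x),
    sprintf("`%s` must be a single integer >= %s", name, min)
  )
  as.integer(x)
}

check_fraction <- function(x, name) {
  assert_that(
    is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 0 && x <= 1,
    sprintf("`%s` must be a single value in [0, 1]", name)
  )
  x
}

#' Derive a stage-specific random seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its seed deterministically
#' from the experiment's master seed, the stage name and the repeat index, so
#' that whole experiments are reproducible while stages remain independent.
#' The derivation is a small multiplicative hash kept below `2^31 - 1`.
#'
#' @param master_seed Integer master seed of the experiment.
#' @param stage Character stage label (e.g. `"assemble"`, `"simulate"`).
#' @param repeat_idx Integer repeat index (1-based).
#' @return A single integer seed.
#' @export
#' @examples
#' stage_seed(42, "assemble", 1)
stage_seed <- function(master_seed, stage, repeat_idx = 1L) {
  assert_that(is.numeric(master_seed) && length(master_seed) == 1,
              "`master_seed` must be a single number")
  h <- (abs(master_seed) %% 1000003) + 1
  for (ch in utf8ToInt(as.character(stage))) {
    h <- (h * 131 + ch) %% 2147483629
  }
  h <- (h * 131 + as.integer(repeat_idx)) %% 2147483629
  as.integer(h + 1L)
}

# run code under a locally-set seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}
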