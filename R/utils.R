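#' Derive a reproducible stage seed from a master seed
#'
#' All pipeline stages draw their randomness from seeds derived
#' deterministically from a single master seed, so that any stage can be
#' re-run in isolation with the same draws. The derivation hashes the stage
#' label into an integer offset and folds it into the master seed modulo
#' 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage label, e.g. `"cohort"` or `"battery_T2"`.
#' @return a single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (abs(as.numeric(master)) * 48271 + h * 16807) %% 2147483646
  as.integer(s) + 1L
}

# run expr with a local RNG state, restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

#' Measure names used throughout the outcome tables
#'
#' The fixed vocabulary of outcome measures emitted by scoring and consumed
#' by the analysis modules.
#'
#' @return character vector of measure names.
#' @export
ef_measures <- function() {
  c("osari_ssrt", "ant_conflict", "ds_total", "corsi_total",
    "wcst_prop_err", "dccs_adv", "brief_gec", "sdq_parent", "sdq_teacher")
}

# latent ability domains tracked per participant
ef_domains <- function() {
  c("response_inhibition", "interference_control", "verbal_wm",
    "visuospatial_wm", "switching", "matching", "everyday_ef", "sewb")
}

# domain that generates each measure
measure_domain <- function(measure) {
  map <- c(osari_ssrt = "response_inhibition",
           ant_conflict = "interference_control",
           ds_total = "verbal_wm",
           corsi_total = "visuospatial_wm",
           wcst_prop_err = "switching",
           dccs_adv = "matching",
           brief_gec = "everyday_ef",
           sdq_parent = "sewb",
           sdq_teacher = "sewb")
  unname(map[measure])
}
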