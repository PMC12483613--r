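# Small shared helpers.

#' Round half away from zero
#'
#' Numeric rating scale scores are integers; rounding ties (x.5) go away from
#' zero rather than to even, so that e.g. 2.5 becomes 3.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Clip scores to the 0-10 numeric rating scale
#' @param x numeric vector.
#' @keywords internal
clip_nrs <- function(x) {
  pmin(pmax(x, 0), 10)
}

geometric_mean <- function(x) exp(mean(log(x)))

#' Derive a per-stage seed from a global seed
#'
#' Stages of the pipeline draw from named substreams of one global seed so
#' that any stage can be rerun independently with identical results.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return an integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

# Validate a single numeric config field; `what` names the field in errors.
check_number <- function(x, what, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop("config field '", what, "' must be a single number", call. = FALSE)
  }
  if (x < min || x > max) {
    stop("config field '", what, "' must be in [", min, ", ", max, "]",
         call. = FALSE)
  }
  if (integer && x != floor(x)) {
    stop("config field '", what, "' must be an integer", call. = FALSE)
  }
  invisible(x)
}

# All phenotype labels the classifier can emit.
phenotype_levels <- function() {
  c("constant_low", "constant_high", "rhythmic_up", "rhythmic_down",
    "mixed", "unclassifiable")
}
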