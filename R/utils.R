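#' @keywords internal
"_PACKAGE"

## Condition helpers: validation errors map to CLI exit status 2, data errors
## (malformed or inconsistent inputs discovered mid-pipeline) to status 3.

ss_validation_error <- function(msg) {
  stop(errorCondition(msg, class = c("splitscape_validation", "splitscape_error", "error")))
}

ss_data_error <- function(msg) {
  stop(errorCondition(msg, class = c("splitscape_data", "splitscape_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic per-stage seed derivation, so that e.g. adding trees to a
## synthetic config never perturbs the alignment fixture stream. Result kept
## strictly below 2^31 - 1 (R integers are 32-bit).
substream_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((abs(seed) %% 65011 * 33029 + h * 97 + 1) %% 2147483629)
}

## Numeric formatting used everywhere a number is serialized (Newick, CSV),
## so that repeated writes of the same object are byte-identical.
fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[is.na(x)] <- NA_character_
  out
}

is_number_like <- function(x) {
  !is.na(suppressWarnings(as.numeric(x)))
}
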