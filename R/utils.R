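# Internal helpers shared across modules.

NON_IED <- "NON_IED"

# Synonyms normalized (case-insensitively) to the reserved NON_IED label.
.nonied_synonyms <- c("non_ied", "non-ied", "nonied", "non ied", "artifact",
                      "artefact", "noise")

normalize_label <- function(label) {
  out <- setNames(as.character(label), names(label))
  hit <- tolower(out) %in% .nonied_synonyms | out == NON_IED
  out[hit] <- NON_IED
  out
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All package randomness funnels
# through this so that every operation is a pure function of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

stop_ied <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
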