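# Internal helpers shared across modules.

# Canonical key for an unordered pair. Tab is safe: identifiers come from
# delimited text and may not contain tabs.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\t")
}

# Order identifiers within each pair lexicographically (protein_a <= protein_b).
canonical_pairs <- function(a, b) {
  data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
             stringsAsFactors = FALSE)
}

# Dense ranking of scores, best (largest) first, with deterministic
# tie-breaking on the lexicographic pair identifiers. NA scores (undefined
# sentinels) receive NA rank and are excluded from any top-k cut.
rank_desc <- function(score, a, b) {
  r <- rep(NA_integer_, length(score))
  ok <- !is.na(score)
  idx <- which(ok)[order(-score[ok], a[ok], b[ok])]
  r[idx] <- seq_along(idx)
  r
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_usage <- function(...) stop(..., call. = FALSE)
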