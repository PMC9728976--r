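# internal helpers shared across modules

# scalar type checks with informative errors
.check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

.check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (if (strict) x <= min else x < min)
    stop(sprintf("'%s' must be %s %g", name, if (strict) ">" else ">=", min),
         call. = FALSE)
  as.numeric(x)
}

.check_prob <- function(p, name, open_left = TRUE) {
  if (!is.numeric(p) || anyNA(p))
    stop(sprintf("'%s' must be numeric without NA", name), call. = FALSE)
  lo <- if (open_left) all(p > 0) else all(p >= 0)
  if (!lo || any(p > 1))
    stop(sprintf("'%s' must lie in %s0, 1]", name, if (open_left) "(" else "["),
         call. = FALSE)
  p
}

# valid DNA over the unambiguous alphabet?
.is_dna <- function(x) grepl("^[ACGT]+$", x)

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# deterministic child seeds so that independent operations driven by one
# user-facing seed do not share an RNG stream; kept below 2^31
.child_seed <- function(seed, stream) {
  (as.integer(seed) %% 1000003L) * 2011L + as.integer(stream)
}
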