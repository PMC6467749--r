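# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Round half away from zero
#'
#' Integer rounding used for percentage display in cohort summaries
#' (85.7 -> 86, 68.2 -> 68), where `base::round()` would round half to even.
#'
#' @param x Numeric vector.
#' @return Numeric vector rounded to the nearest integer, halves up.
#' @export
round_half_up <- function(x) floor(x + 0.5)

# Pack equal-length sequences into a raw byte matrix (one column per
# sequence).  Hot paths compare/edit bases as raw bytes rather than
# splitting strings.
seq_char_matrix <- function(x) {
  if (!length(x)) return(matrix(raw(0), nrow = 0, ncol = 0))
  L <- nchar(x[[1L]])
  stopifnot(all(nchar(x) == L))
  matrix(charToRaw(paste(x, collapse = "")), nrow = L)
}

# Inverse of seq_char_matrix().
raw_to_strings <- function(m) {
  L <- nrow(m)
  if (!ncol(m)) return(character(0))
  big <- rawToChar(as.vector(m))
  starts <- seq.int(1L, by = L, length.out = ncol(m))
  substring(big, starts, starts + L - 1L)
}

# Random DNA strings (used for barcodes and synthetic inserts).
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, lapply(seq_len(width), function(j) m[, j]))
}

# Substitute each base by one of the three other bases, uniformly.
# `cur` is a raw vector of current bases; returns raw vector.
random_other_base <- function(cur) {
  base_raw <- charToRaw(paste(DNA_BASES, collapse = ""))
  idx <- match(cur, base_raw)
  # non-ACGT (e.g. N) bases are replaced by a uniform random base
  unknown <- is.na(idx)
  idx[unknown] <- sample.int(4L, sum(unknown), replace = TRUE)
  new_idx <- ((idx - 1L + sample.int(3L, length(idx), replace = TRUE)) %% 4L) + 1L
  base_raw[new_idx]
}

# Stop with a configuration error naming the offending field.
config_error <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}

is_dna_string <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  is.character(x) && length(x) == 1L && !is.na(x) && grepl(pat, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
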