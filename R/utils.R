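# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

# Normalise a nucleotide string to an uppercase DNA-alphabet character vector
# (U -> T).  Errors on characters outside the given alphabet.
.seq_chars <- function(x, allowed = DNA_BASES, what = "sequence") {
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1]]
  chars[chars == "U"] <- "T"
  bad <- setdiff(unique(chars), allowed)
  if (length(bad) > 0) {
    stop("invalid character(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  chars
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Deterministic random DNA string.
.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Round half up: the documented rule for fractional planted counts.
.round_half_up <- function(x) floor(x + 0.5)

# Run an expression under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards so simulation functions do not disturb user code.
.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == floor(x)
}

.is_scalar_num <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
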