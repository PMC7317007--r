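# Shared low-level helpers: IUPAC alphabets, reverse complement, seeded
# substreams. Internal coordinates are 0-based half-open throughout the
# package; conversion to/from 1-based inclusive happens only at I/O
# boundaries (GenBank, user-facing tables).

IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A",
                R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
                B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-")

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented to their IUPAC counterparts;
#' gap characters pass through unchanged.
#'
#' @param x A single DNA string (upper case IUPAC codes).
#' @return A single string: the reverse complement of `x`.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  ch <- rev(strsplit(x, "", fixed = TRUE)[[1]])
  out <- COMPLEMENT[ch]
  if (anyNA(out)) {
    stop("revcomp(): non-IUPAC character(s): ",
         paste(unique(ch[is.na(out)]), collapse = ", "))
  }
  paste(out, collapse = "")
}

# Deterministic substream seed derived from a master seed and a stream
# index; keeps every derived seed inside the 32-bit integer range.
substream_seed <- function(seed, stream) {
  as.integer((as.double(seed) + 1000003 * as.double(stream)) %% 2147483629)
}

# Evaluate `expr` under a temporary RNG state seeded by `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Split a DNA string into a character vector of single residues.
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

validate_dna <- function(x, what = "sequence", allow_gap = FALSE) {
  ok <- IUPAC_CODES
  if (allow_gap) ok <- c(ok, "-")
  ch <- unique(chars(x))
  bad <- setdiff(ch, ok)
  if (length(bad) > 0) {
    stop(what, " contains invalid residue(s): ", paste(bad, collapse = ", "))
  }
  invisible(x)
}

# Circular substring extraction in 0-based half-open coordinates; `end`
# may exceed the sequence length, in which case the read wraps.
circ_substr <- function(seq, start, end) {
  n <- nchar(seq)
  stopifnot(end > start, end - start <= n)
  s <- start %% n
  e <- s + (end - start)
  if (e <= n) substr(seq, s + 1L, e)
  else paste0(substr(seq, s + 1L, n), substr(seq, 1L, e - n))
}
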