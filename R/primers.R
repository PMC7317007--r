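# Simplified primer-pair picker and amplicon location. Deliberately a
# documented approximation (Wallace-rule-style Tm, no nearest-neighbor
# thermodynamics, no dimer check): sufficient to propose candidate pairs
# around short markers; published primer tables are treated as data for
# amplicon-location checks, not as outputs to reproduce.

#' Primer melting temperature
#'
#' Tm = 64.9 + 41 * (#GC - 16.4) / length, in degrees Celsius.
#'
#' @param primer DNA string (5'->3').
#' @return Tm in degrees C.
#' @export
primer_tm <- function(primer) {
  n <- nchar(primer)
  gc <- sum(chars(toupper(primer)) %in% c("G", "C"))
  64.9 + 41 * (gc - 16.4) / n
}

has_homopolymer <- function(primer, run = 5L) {
  grepl(paste0("A{", run, "}|C{", run, "}|G{", run, "}|T{", run, "}"),
        toupper(primer))
}

# enumerate all 18-24 nt candidates inside a flank (plus strand
# coordinates), scoring and hard-filtering each
primer_candidates <- function(seq, flank_start, flank_end,
                              len_range, gc_range, tm_range, tally) {
  rows <- list()
  for (len in seq.int(len_range[1], len_range[2])) {
    starts <- seq.int(flank_start, flank_end - len)
    if (length(starts) == 0 || flank_end - len < flank_start) next
    for (s in starts) {
      p <- substr(seq, s + 1L, s + len)
      gc <- 100 * sum(chars(p) %in% c("G", "C")) / len
      tm <- primer_tm(p)
      if (gc < gc_range[1] || gc > gc_range[2]) { tally$gc <- tally$gc + 1L; next }
      if (tm < tm_range[1] || tm > tm_range[2]) { tally$tm <- tally$tm + 1L; next }
      if (has_homopolymer(p)) { tally$homopolymer <- tally$homopolymer + 1L; next }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        start = s, end = s + len, seq_plus = p,
        gc = gc, tm = tm, score = abs(tm - 60) + abs(gc - 50) / 10
      )
    }
  }
  list(cand = dplyr::bind_rows(rows), tally = tally)
}

#' Pick the best primer pair flanking a target region
#'
#' Scans every 18-24 nt substring of the 200 bp flanks on either side of
#' the target (the right-flank candidate is reverse-complemented to give
#' the reverse primer). Hard constraints: GC in \[40, 60\]%, Tm in
#' \[57, 63\] degrees C, no homopolymer run of 5+, product at most
#' `max_product` bp and fully containing the target. Among feasible
#' pairs the one minimizing `|Tm - 60| + |GC - 50|/10` summed over both
#' primers is returned.
#'
#' @param x A [plastome()] or DNA string (the ungapped reference).
#' @param target Length-2 integer: 0-based half-open target interval.
#' @param flank Flank width scanned on each side (default 200 bp).
#' @param gc_range,tm_range,len_range Hard constraint ranges.
#' @param max_product Maximum product size in bp (default 1100).
#' @return One-row tibble: `forward`, `reverse` (5'->3'), binding
#'   coordinates, per-primer `tm_*` and `gc_*`, `product_size`. When no
#'   pair is feasible, a zero-row tibble with a `failure_tally`
#'   attribute counting per-constraint rejections.
#' @export
pick_primers <- function(x, target, flank = 200L,
                         gc_range = c(40, 60), tm_range = c(57, 63),
                         len_range = c(18L, 24L), max_product = 1100L) {
  seq <- if (inherits(x, "plastome")) x$sequence else toupper(x)
  n <- nchar(seq)
  stopifnot(length(target) == 2, target[1] < target[2], target[2] <= n)
  left_start <- max(0L, target[1] - flank)
  right_end <- min(n, target[2] + flank)
  tally <- list(gc = 0L, tm = 0L, homopolymer = 0L, product = 0L)

  fwd <- primer_candidates(seq, left_start, target[1], len_range,
                           gc_range, tm_range, tally)
  tally <- fwd$tally
  rev <- primer_candidates(seq, target[2], right_end, len_range,
                           gc_range, tm_range, tally)
  tally <- rev$tally

  empty <- tibble::tibble(
    forward = character(), reverse = character(),
    fwd_start = integer(), fwd_end = integer(),
    rev_start = integer(), rev_end = integer(),
    tm_forward = numeric(), tm_reverse = numeric(),
    gc_forward = numeric(), gc_reverse = numeric(),
    product_size = integer()
  )
  if (nrow(fwd$cand) == 0L || nrow(rev$cand) == 0L) {
    return(structure(empty, failure_tally = tally))
  }
  # product constraint: all combinations (flanks are <= 200 bp, so small)
  best <- NULL
  for (i in order(fwd$cand$score)) {
    for (j in order(rev$cand$score)) {
      prod <- rev$cand$end[j] - fwd$cand$start[i]
      if (prod > max_product) { tally$product <- tally$product + 1L; next }
      sc <- fwd$cand$score[i] + rev$cand$score[j]
      if (is.null(best) || sc < best$sc) best <- list(i = i, j = j, sc = sc, prod = prod)
      break  # rev candidates sorted by score; first feasible is the best for this fwd
    }
  }
  if (is.null(best)) return(structure(empty, failure_tally = tally))
  f <- fwd$cand[best$i, ]
  r <- rev$cand[best$j, ]
  tibble::tibble(
    forward = f$seq_plus,
    reverse = revcomp(r$seq_plus),
    fwd_start = f$start, fwd_end = f$end,
    rev_start = r$start, rev_end = r$end,
    tm_forward = f$tm, tm_reverse = r$tm,
    gc_forward = f$gc, gc_reverse = r$gc,
    product_size = best$prod
  )
}

#' Expected amplicon size of a primer pair on a reference
#'
#' The forward primer must bind exactly once on the plus strand and the
#' reverse primer (as the reverse complement on the plus strand) exactly
#' once downstream of it. The product spans both primers.
#'
#' @param x A [plastome()] or DNA string.
#' @param forward,reverse Primer sequences, both written 5'->3'.
#' @return Product size in bp.
#' @export
locate_amplicon <- function(x, forward, reverse) {
  seq <- if (inherits(x, "plastome")) x$sequence else toupper(x)
  forward <- toupper(forward)
  rc_rev <- revcomp(toupper(reverse))
  fhits <- gregexpr(forward, seq, fixed = TRUE)[[1]]
  fhits <- fhits[fhits > 0]
  if (length(fhits) != 1L) {
    stop("forward primer binds ", length(fhits), " time(s); expected exactly 1")
  }
  rhits <- gregexpr(rc_rev, seq, fixed = TRUE)[[1]]
  rhits <- rhits[rhits > 0]
  rhits <- rhits[rhits > fhits]
  if (length(rhits) != 1L) {
    stop("reverse primer binds ", length(rhits),
         " time(s) downstream of the forward primer; expected exactly 1")
  }
  as.integer(rhits - 1L + nchar(rc_rev) - (fhits - 1L))
}
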