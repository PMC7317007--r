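# Quadripartite architecture of a circular plastome: exact inverted-repeat
# detection, per-region composition (the classic LSC/SSC/IRa/IRb table),
# and pseudogene screening of coding sequences.

#' Locate the inverted repeat and partition a circular plastome
#'
#' Finds the maximal-length pair of disjoint intervals whose sequences
#' are exact reverse complements of each other (seed-and-extend on
#' 21-mer matches against the reverse complement, maximal exact
#' extension, no mismatches) and labels the longer of the two gaps
#' between them LSC and the shorter SSC. Regions are reported in circle
#' order LSC, IRb, SSC, IRa starting from the LSC start. If no repeat of
#' at least `min_len` exists, a degenerate partition (LSC = whole
#' genome, empty IRs) is returned with a warning.
#'
#' Ties between equally long repeat pairs are broken by minimal SSC
#' length, then by the smallest start coordinate, so the result is
#' deterministic.
#'
#' @param x A [plastome()] or a single DNA string (assumed circular only
#'   if `circular = TRUE`).
#' @param min_len Minimum repeat length to accept, in bp (default 1000,
#'   must be >= 100).
#' @param circular Only used when `x` is a bare string.
#' @return A `region_partition`: tibble with columns `region`, `start`
#'   (0-based on the circle), `length`; attributes `genome_length`,
#'   `ir_length`, `degenerate`.
#' @export
find_inverted_repeat <- function(x, min_len = 1000L, circular = NULL) {
  if (inherits(x, "plastome")) {
    seq <- x$sequence
    circ <- x$circular
  } else {
    seq <- toupper(x)
    circ <- if (is.null(circular)) TRUE else circular
  }
  if (!circ) stop("inverted-repeat search is defined for circular sequences only")
  if (min_len < 100L) stop("min_len must be at least 100 bp")
  n <- nchar(seq)

  cand <- ir_candidates(seq, min_len)
  if (nrow(cand) == 0L) {
    warning("no inverted repeat of length >= ", min_len,
            " bp found; returning a degenerate single-copy partition")
    part <- tibble::tibble(
      region = c("LSC", "IRb", "SSC", "IRa"),
      start = c(0L, 0L, 0L, 0L),
      length = c(n, 0L, 0L, 0L)
    )
    return(structure(part, class = c("region_partition", class(part)),
                     genome_length = n, ir_length = 0L, degenerate = TRUE))
  }

  # gaps between the two repeat copies, walking the circle
  gapA <- (cand$b - (cand$a + cand$len)) %% n   # end of I -> start of J
  gapB <- (cand$a - (cand$b + cand$len)) %% n   # end of J -> start of I
  ssc <- pmin(gapA, gapB)
  ord <- order(-cand$len, ssc, cand$a)
  best <- cand[ord[1], ]
  L <- best$len

  if (gapA[ord[1]] >= gapB[ord[1]]) {
    lsc_start <- (best$a + L) %% n
    lsc_len <- gapA[ord[1]]
    ssc_len <- gapB[ord[1]]
    irb_start <- best$b
    ira_start <- best$a
  } else {
    lsc_start <- (best$b + L) %% n
    lsc_len <- gapB[ord[1]]
    ssc_len <- gapA[ord[1]]
    irb_start <- best$a
    ira_start <- best$b
  }

  part <- tibble::tibble(
    region = c("LSC", "IRb", "SSC", "IRa"),
    start = as.integer(c(lsc_start, irb_start,
                         (irb_start + L) %% n, ira_start)),
    length = as.integer(c(lsc_len, L, ssc_len, L))
  )
  structure(part, class = c("region_partition", class(part)),
            genome_length = n, ir_length = as.integer(L), degenerate = FALSE)
}

# All maximal reverse-complement repeat pairs of length >= min_len on the
# circle, as a tibble (a, b, len) with a <= b (0-based starts).
ir_candidates <- function(seq, min_len) {
  n <- nchar(seq)
  k <- 21L
  if (n < 2L * min_len || n < 2L * k) return(tibble::tibble(a = integer(), b = integer(), len = integer()))
  ext <- paste0(seq, substr(seq, 1L, k - 1L))
  starts <- seq_len(n)
  kmers <- substring(ext, starts, starts + k - 1L)
  rcseq <- revcomp(seq)
  rcext <- paste0(rcseq, substr(rcseq, 1L, k - 1L))
  # revcomp of the k-mer starting at 0-based j is the k-mer of rcseq
  # starting at 0-based (n - j - k) mod n
  rckmers <- substring(rcext, starts, starts + k - 1L)

  groups <- split(seq_len(n) - 1L, rckmers)  # rc-kmer string -> j' positions
  idx <- groups[kmers]
  ni <- lengths(idx)
  keep <- ni > 0L
  if (!any(keep)) return(tibble::tibble(a = integer(), b = integer(), len = integer()))
  i0 <- rep((seq_len(n) - 1L)[keep], ni[keep])       # forward start i
  jprime <- unlist(idx[keep], use.names = FALSE)     # start in rcseq coords
  j0 <- (n - jprime - k) %% n                        # forward start j of RC partner

  # pairs (i, j): seq[i, i+k) == revcomp(seq[j, j+k)); run along a repeat
  # keeps d = (i + j) mod n constant while i increments
  d <- (i0 + j0) %% n
  cand <- list()
  for (dv in unique(d)) {
    is <- sort(i0[d == dv])
    runs <- split(is, cumsum(c(1L, diff(is) != 1L)))
    for (r in runs) {
      a <- r[1]
      len <- r[length(r)] - r[1] + k
      b <- (dv - a - len + k) %% n     # start of the partner copy J
      # maximal exact extension at both boundaries (circular)
      repeat {
        if (len >= floor(n / 2)) break
        pa <- (a - 1L) %% n
        pb <- (b + len) %% n
        if (intervals_overlap_circ(pa, b, len + 1L, n) ||
            substr(seq, pa + 1L, pa + 1L) !=
            COMPLEMENT[substr(seq, pb + 1L, pb + 1L)]) break
        a <- pa; len <- len + 1L
      }
      repeat {
        if (len >= floor(n / 2)) break
        pa <- (a + len) %% n
        pb <- (b - 1L) %% n
        if (intervals_overlap_circ(a, pb, len + 1L, n) ||
            substr(seq, pa + 1L, pa + 1L) !=
            COMPLEMENT[substr(seq, pb + 1L, pb + 1L)]) break
        b <- pb; len <- len + 1L
      }
      if (len < min_len) next
      if (intervals_overlap_circ(a, b, len, n)) next
      lo <- min(a, b); hi <- max(a, b)
      cand[[length(cand) + 1L]] <- c(a = lo, b = hi, len = len)
    }
  }
  if (length(cand) == 0L) return(tibble::tibble(a = integer(), b = integer(), len = integer()))
  out <- tibble::as_tibble(do.call(rbind, cand))
  dplyr::distinct(out)
}

intervals_overlap_circ <- function(a, b, len, n) {
  if (2L * len > n) return(TRUE)
  # [a, a+len) and [b, b+len) on the circle
  da <- (b - a) %% n
  db <- (a - b) %% n
  da < len || db < len
}

#' Extract the residues of one region of a partition
#'
#' @param part A `region_partition`.
#' @param seq The genome string (or [plastome()]) the partition was
#'   computed on.
#' @param region One of `"LSC"`, `"SSC"`, `"IRa"`, `"IRb"`.
#' @return A DNA string (empty for zero-length regions).
#' @export
region_sequence <- function(part, seq, region) {
  if (inherits(seq, "plastome")) seq <- seq$sequence
  row <- part[part$region == region, ]
  if (nrow(row) != 1L) stop("unknown region: ", region)
  if (row$length == 0L) return("")
  circ_substr(seq, row$start, row$start + row$length)
}

# ---------------------------------------------------------------------------

#' GC content of a DNA string
#'
#' Computed as (G + C + S) / (A + C + G + T + S + W); other ambiguity
#' codes do not enter numerator or denominator.
#'
#' @param x A non-empty DNA string.
#' @return Fraction in `[0, 1]`.
#' @export
gc_content <- function(x) {
  if (inherits(x, "plastome")) x <- x$sequence
  if (nchar(x) == 0L) stop("gc_content(): empty input")
  cnt <- table(factor(chars(x), levels = IUPAC_CODES))
  num <- cnt[["G"]] + cnt[["C"]] + cnt[["S"]]
  den <- num + cnt[["A"]] + cnt[["T"]] + cnt[["W"]]
  if (den == 0L) stop("gc_content(): no unambiguous A/C/G/T/S/W positions")
  unname(num / den)
}

# ---------------------------------------------------------------------------

# circular overlap in bp between a linear part [s, e) and a circular
# region [rs, rs+rl)
part_region_overlap <- function(s, e, rs, rl, n) {
  if (rl == 0L) return(0L)
  ov <- function(a1, a2, b1, b2) max(0L, min(a2, b2) - max(a1, b1))
  ov(s, e, rs, rs + rl) + ov(s + n, e + n, rs, rs + rl)
}

#' Tally genes per region and class
#'
#' Each feature (introns and misc features excluded) is assigned to the
#' region containing the majority of its bases; genes duplicated in the
#' two IRs count once per copy; pseudogenes are counted within their
#' class and tallied separately.
#'
#' @param x A [plastome()].
#' @param part A `region_partition` for the same sequence.
#' @return Tibble with one row per region x feature class that occurs:
#'   `region`, `class`, `n`, `n_pseudo`.
#' @export
gene_inventory <- function(x, part) {
  stopifnot(inherits(x, "plastome"), inherits(part, "region_partition"))
  n <- nchar(x$sequence)
  if (attr(part, "genome_length") != n) {
    stop("partition genome length does not match the plastome")
  }
  feats <- dplyr::filter(x$features, !.data$class %in% c("intron", "misc"))
  if (nrow(feats) == 0L) {
    return(tibble::tibble(region = character(), class = character(),
                          n = integer(), n_pseudo = integer()))
  }
  assign_region <- function(parts) {
    ov <- vapply(seq_len(nrow(part)), function(r) {
      sum(vapply(seq_len(nrow(parts)), function(p) {
        part_region_overlap(parts[p, 1], parts[p, 2],
                            part$start[r], part$length[r], n)
      }, integer(1)))
    }, integer(1))
    if (sum(ov > 0L) > 2L) {
      warning("feature spans more than two regions; assigned by majority rule")
    }
    part$region[which.max(ov)]
  }
  feats$region <- vapply(feats$parts, assign_region, character(1))
  feats |>
    dplyr::group_by(.data$region, .data$class) |>
    dplyr::summarise(n = dplyr::n(), n_pseudo = sum(.data$pseudo),
                     .groups = "drop")
}

#' Per-region composition table
#'
#' The classic plastome composition summary: one row per region plus a
#' genome total, with sizes, GC percentage (1 decimal) and gene counts
#' by class.
#'
#' @inheritParams gene_inventory
#' @return Tibble with columns `region`, `size_bp`, `gc_pct`, `genes`,
#'   `pseudogenes`, `cds`, `trna`, `rrna`.
#' @export
composition_table <- function(x, part) {
  inv <- gene_inventory(x, part)
  count_of <- function(reg, cls) {
    v <- inv$n[inv$region == reg & inv$class == cls]
    if (length(v) == 0L) 0L else as.integer(v)
  }
  pseudo_of <- function(reg) {
    v <- inv$n_pseudo[inv$region == reg]
    if (length(v) == 0L) 0L else as.integer(sum(v))
  }
  regions <- c("LSC", "SSC", "IRa", "IRb")
  rows <- lapply(regions, function(reg) {
    res <- region_sequence(part, x, reg)
    tibble::tibble(
      region = reg,
      size_bp = part$length[part$region == reg],
      gc_pct = if (nchar(res) > 0) round(100 * gc_content(res), 1) else NA_real_,
      genes = count_of(reg, "CDS") + count_of(reg, "tRNA") + count_of(reg, "rRNA"),
      pseudogenes = pseudo_of(reg),
      cds = count_of(reg, "CDS"),
      trna = count_of(reg, "tRNA"),
      rrna = count_of(reg, "rRNA")
    )
  })
  per_region <- dplyr::bind_rows(rows)
  genome <- tibble::tibble(
    region = "Genome",
    size_bp = nchar(x$sequence),
    gc_pct = round(100 * gc_content(x$sequence), 1),
    genes = sum(per_region$genes),
    pseudogenes = sum(per_region$pseudogenes),
    cds = sum(per_region$cds),
    trna = sum(per_region$trna),
    rrna = sum(per_region$rrna)
  )
  dplyr::bind_rows(genome, per_region)
}

# ---------------------------------------------------------------------------

PLASTID_STARTS <- c("ATG", "GTG")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Screen a coding sequence for pseudogene symptoms
#'
#' Takes the spliced, strand-oriented CDS residues and reports the
#' structural defects used to flag putative pseudogenes: in-frame stop
#' codons before the final codon, length not a multiple of three,
#' missing start codon (plastid/bacterial code: ATG or GTG), missing
#' terminal stop, and — when an expected full length is supplied — an
#' observed open reading frame shorter than half of it (`small_orf`).
#'
#' @param cds DNA string, no gaps.
#' @param expected_length Optional expected full CDS length in bp.
#' @return Character vector of reasons (empty if the CDS looks intact).
#' @export
screen_pseudogene <- function(cds, expected_length = NULL) {
  cds <- toupper(cds)
  if (grepl("-", cds, fixed = TRUE)) {
    stop("screen_pseudogene(): input contains gap characters")
  }
  len <- nchar(cds)
  ncod <- len %/% 3L
  reasons <- character()
  if (len %% 3L != 0L) reasons <- c(reasons, "length_not_multiple_of_3")
  codons <- if (ncod > 0) substring(cds, 3L * (seq_len(ncod) - 1L) + 1L, 3L * seq_len(ncod)) else character()
  if (ncod == 0L || !codons[1] %in% PLASTID_STARTS) {
    reasons <- c(reasons, "missing_start")
  }
  if (ncod == 0L || !codons[ncod] %in% STOP_CODONS) {
    reasons <- c(reasons, "missing_stop")
  }
  if (ncod > 1L && any(codons[seq_len(ncod - 1L)] %in% STOP_CODONS)) {
    reasons <- c(reasons, "internal_stop")
  }
  if (!is.null(expected_length)) {
    first_stop <- which(codons %in% STOP_CODONS)
    orf_bp <- if (length(first_stop) > 0) 3L * first_stop[1] else len
    if (orf_bp < 0.5 * expected_length) reasons <- c(reasons, "small_orf")
  }
  reasons
}

# Spliced, strand-oriented residues of a multi-part feature.
feature_residues <- function(x, parts, strand) {
  seqs <- vapply(seq_len(nrow(parts)), function(i) {
    substr(x$sequence, parts[i, 1] + 1L, parts[i, 2])
  }, character(1))
  s <- paste(seqs, collapse = "")
  if (strand == "-") revcomp(s) else s
}

#' Screen every annotated CDS of a plastome
#'
#' @param x A [plastome()].
#' @return Tibble `gene`, `reasons` (list-column), `flagged`.
#' @export
screen_cds <- function(x) {
  feats <- dplyr::filter(x$features, .data$class == "CDS")
  res <- purrr::map(seq_len(nrow(feats)), function(i) {
    screen_pseudogene(feature_residues(x, feats$parts[[i]], feats$strand[i]))
  })
  tibble::tibble(
    gene = feats$gene,
    reasons = res,
    flagged = lengths(res) > 0
  )
}
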