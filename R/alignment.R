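# Multiple-alignment container and the partition of a whole-plastome
# alignment into cpCDS / cpNCDS / cpIGS markers via a reference column
# map. Columns are 0-based half-open everywhere, like genome coordinates.

#' DNA multiple alignment
#'
#' Stored as a character matrix of single residues, rows named by taxon.
#' Accepts a named character vector of equal-length strings or an
#' existing character matrix.
#'
#' @param x Named character vector of aligned sequences, or a character
#'   matrix (taxa x columns).
#' @return A `dna_alignment` (character matrix subclass).
#' @export
dna_alignment <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else {
    if (is.null(names(x)) || anyDuplicated(names(x))) {
      stop("alignment sequences must have unique names")
    }
    w <- unique(nchar(x))
    if (length(w) != 1L) stop("aligned sequences must all have the same length")
    m <- matrix("", nrow = length(x), ncol = w, dimnames = list(names(x), NULL))
    for (i in seq_along(x)) m[i, ] <- chars(toupper(x[[i]]))
  }
  if (nrow(m) < 2L) stop("an alignment needs at least 2 taxa")
  bad <- setdiff(unique(as.vector(m)), c(IUPAC_CODES, "-"))
  if (length(bad) > 0) stop("invalid alignment character(s): ", paste(bad, collapse = ", "))
  structure(m, class = c("dna_alignment", "matrix", "array"))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("<dna_alignment> ", nrow(x), " taxa x ", ncol(x), " columns\n", sep = "")
  invisible(x)
}

#' @rdname dna_alignment
#' @param aln A `dna_alignment`.
#' @return `aln_strings()`: named character vector of the rows.
#' @export
aln_strings <- function(aln) {
  out <- apply(unclass(aln), 1L, paste, collapse = "")
  stats::setNames(out, rownames(aln))
}

#' Read an alignment from FASTA
#'
#' @param path FASTA file of equal-length aligned sequences.
#' @return A [dna_alignment()].
#' @export
read_alignment_fasta <- function(path) dna_alignment(read_fasta_dna(path))

#' @rdname read_alignment_fasta
#' @param aln A [dna_alignment()].
#' @export
write_alignment_fasta <- function(aln, path) write_fasta_dna(aln_strings(aln), path)

# integer encoding used by all the pairwise statistics: A=1 C=2 G=3 T=4,
# everything else (gaps, ambiguities) NA
encode_alignment <- function(aln) {
  m <- match(unclass(aln), c("A", "C", "G", "T"))
  dim(m) <- dim(aln)
  rownames(m) <- rownames(aln)
  m
}

# ---------------------------------------------------------------------------

#' Mask high-gap/ambiguity columns
#'
#' A column is removed iff the fraction of taxa carrying a gap or an
#' ambiguity code (anything other than A/C/G/T) exceeds `threshold`.
#' Mirrors the usual pre-phylogenetics alignment stripping rule.
#'
#' @param aln A [dna_alignment()].
#' @param threshold Fraction in (0, 1]; default 0.8.
#' @return List with `alignment` (the kept columns, order preserved) and
#'   `removed` (0-based indices of dropped columns).
#' @export
mask_columns <- function(aln, threshold = 0.8) {
  stopifnot(threshold > 0, threshold <= 1)
  bad <- !(unclass(aln) %in% c("A", "C", "G", "T"))
  dim(bad) <- dim(aln)
  frac <- colMeans(bad)
  drop <- which(frac > threshold)
  keep <- setdiff(seq_len(ncol(aln)), drop)
  if (length(keep) == 0L) warning("masking removed every column")
  out <- unclass(aln)[, keep, drop = FALSE]
  list(
    alignment = structure(out, class = c("dna_alignment", "matrix", "array")),
    removed = drop - 1L
  )
}

#' Map reference positions to alignment columns
#'
#' `map[i]` (1-based list position `i`) is the 0-based alignment column
#' of the i-th non-gap residue of the reference row; the map is strictly
#' increasing and has one entry per ungapped reference position.
#'
#' @param aln A [dna_alignment()].
#' @param ref_taxon Name of the reference row.
#' @return List with `ref_taxon` and integer vector `map`.
#' @export
build_column_map <- function(aln, ref_taxon) {
  if (!ref_taxon %in% rownames(aln)) stop("reference taxon not in alignment: ", ref_taxon)
  row <- unclass(aln)[ref_taxon, ]
  cols <- which(row != "-") - 1L
  if (length(cols) == 0L) stop("reference row is all gaps")
  list(ref_taxon = ref_taxon, map = cols)
}

# image of a contiguous 0-based half-open reference interval as one
# 0-based half-open column interval (includes interior columns where the
# reference row is gapped, i.e. insertions in other taxa)
interval_to_columns <- function(cmap, start, end) {
  if (end > length(cmap$map)) stop("feature interval extends past the alignment reference")
  feature_part(cmap$map[start + 1L], cmap$map[end] + 1L)
}

# ---------------------------------------------------------------------------

#' Cut the alignment into cpCDS, cpNCDS and cpIGS markers
#'
#' Produces one `cpCDS` marker per CDS feature (pseudogenes included;
#' columns are the images of the exon parts), one `cpNCDS` marker per
#' tRNA/rRNA gene and per full span (exons plus introns) of each
#' intron-containing gene, and one `cpIGS` marker per maximal reference
#' interval not covered by any gene span, named `"geneA-geneB"` after the
#' flanking genes. A cpNCDS span may contain a nested CDS (the trnK/matK
#' arrangement); both markers are emitted. Zero-length spacers between
#' abutting genes are skipped. On a circular reference the wrap-around
#' spacer, when present, is emitted last with two column intervals.
#'
#' @param x The reference [plastome()] the column map was built on
#'   (typically with one IR copy already stripped).
#' @param cmap A column map from [build_column_map()].
#' @return Tibble `marker`, `class`, `cols` (list of 2-column matrices of
#'   0-based half-open column intervals), `ref_span` (list of reference
#'   intervals).
#' @export
partition_markers <- function(x, cmap) {
  n <- nchar(x$sequence)
  if (length(cmap$map) != n) {
    stop("column map length (", length(cmap$map),
         ") does not match the reference length (", n, ")")
  }
  feats <- x$features
  rows <- list()
  add <- function(name, class, ref_parts) {
    cols <- do.call(rbind, lapply(seq_len(nrow(ref_parts)), function(i) {
      interval_to_columns(cmap, ref_parts[i, 1], ref_parts[i, 2])
    }))
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      marker = name, class = class, cols = list(cols), ref_span = list(ref_parts)
    )
  }

  genic <- dplyr::filter(feats, .data$class %in% c("CDS", "tRNA", "rRNA", "intron"))

  # cpCDS: one marker per CDS feature, exon columns only
  cds <- dplyr::filter(genic, .data$class == "CDS")
  for (i in seq_len(nrow(cds))) add(cds$gene[i], "cpCDS", cds$parts[[i]])

  # cpNCDS: tRNA and rRNA genes (full annotated span incl. introns), plus
  # the full span of intron-containing CDS genes
  span_of <- function(parts) feature_part(min(parts[, 1]), max(parts[, 2]))
  trr <- dplyr::filter(genic, .data$class %in% c("tRNA", "rRNA"))
  for (i in seq_len(nrow(trr))) add(trr$gene[i], "cpNCDS", span_of(trr$parts[[i]]))
  has_intron_feat <- unique(genic$gene[genic$class == "intron"])
  multi_part_cds <- cds$gene[vapply(cds$parts, nrow, 1L) > 1L]
  for (g in union(has_intron_feat, multi_part_cds)) {
    parts <- do.call(rbind, genic$parts[genic$gene == g])
    add(g, "cpNCDS", span_of(parts))
  }

  # cpIGS: complement of merged gene spans on the reference
  if (nrow(genic) > 0L) {
    spans <- tibble::tibble(
      gene = genic$gene,
      start = vapply(genic$parts, function(p) min(p[, 1]), 1L),
      end = vapply(genic$parts, function(p) max(p[, 2]), 1L)
    ) |>
      dplyr::group_by(.data$gene) |>
      dplyr::summarise(start = min(.data$start), end = max(.data$end),
                       .groups = "drop") |>
      dplyr::arrange(.data$start, .data$end)
    # merge overlapping spans, remembering flanking gene names
    merged <- list()
    cur <- list(start = spans$start[1], end = spans$end[1],
                first = spans$gene[1], last = spans$gene[1])
    for (i in seq_len(nrow(spans))[-1]) {
      if (spans$start[i] <= cur$end) {
        if (spans$end[i] > cur$end) {
          cur$end <- spans$end[i]
          cur$last <- spans$gene[i]
        }
      } else {
        merged[[length(merged) + 1L]] <- cur
        cur <- list(start = spans$start[i], end = spans$end[i],
                    first = spans$gene[i], last = spans$gene[i])
      }
    }
    merged[[length(merged) + 1L]] <- cur
    for (i in seq_along(merged)[-length(merged)]) {
      a <- merged[[i]]; b <- merged[[i + 1L]]
      if (b$start > a$end) {
        add(paste0(a$last, "-", b$first), "cpIGS", feature_part(a$end, b$start))
      }
    }
    first <- merged[[1]]; last <- merged[[length(merged)]]
    if (x$circular) {
      # wrap-around spacer: tail of the reference plus its head
      parts <- NULL
      if (last$end < n) parts <- rbind(parts, feature_part(last$end, n))
      if (first$start > 0L) parts <- rbind(parts, feature_part(0L, first$start))
      if (!is.null(parts)) {
        add(paste0(last$last, "-", first$first), "cpIGS", parts)
      }
    } else {
      if (first$start > 0L) add(paste0("start-", first$first), "cpIGS",
                                feature_part(0L, first$start))
      if (last$end < n) add(paste0(last$last, "-end"), "cpIGS",
                            feature_part(last$end, n))
    }
  }
  if (length(rows) == 0L) {
    return(tibble::tibble(marker = character(), class = character(),
                          cols = list(), ref_span = list()))
  }
  dplyr::bind_rows(rows)
}

#' Extract the sub-alignment of one marker
#'
#' @param aln A [dna_alignment()].
#' @param marker One row of the [partition_markers()] tibble (or any list
#'   with a `cols` matrix of 0-based half-open column intervals).
#' @return A [dna_alignment()] of the marker's columns, taxa order kept.
#' @export
extract_marker <- function(aln, marker) {
  cols <- if (is.data.frame(marker)) marker$cols[[1]] else marker$cols
  idx <- unlist(lapply(seq_len(nrow(cols)), function(i) {
    seq.int(cols[i, 1] + 1L, cols[i, 2])
  }))
  if (any(idx > ncol(aln))) stop("marker columns extend past the alignment")
  out <- unclass(aln)[, idx, drop = FALSE]
  structure(out, class = c("dna_alignment", "matrix", "array"))
}

#' Concatenate marker sub-alignments
#'
#' Columns are appended in the order the markers are given; taxa order is
#' preserved.
#'
#' @param aln A [dna_alignment()].
#' @param markers A [partition_markers()] tibble (or subset of its rows).
#' @return A [dna_alignment()].
#' @export
concatenate_markers <- function(aln, markers) {
  mats <- lapply(seq_len(nrow(markers)), function(i) {
    unclass(extract_marker(aln, markers[i, ]))
  })
  out <- do.call(cbind, mats)
  structure(out, class = c("dna_alignment", "matrix", "array"))
}
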