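# I/O layer: GenBank flat files, FASTA, newick and TSV reports, plus the
# `plastome` container every genome coordinate in the package refers to.

#' Construct an annotated plastome
#'
#' A `plastome` bundles a (usually circular) genome sequence with a
#' feature table. Coordinates in `features$parts` are 0-based half-open
#' on the forward strand of the stored sequence; a feature spanning the
#' circular origin is represented by two or more parts.
#'
#' @param sequence Single DNA string (IUPAC codes, upper case).
#' @param features Tibble with columns `gene` (character), `class`
#'   (one of `"CDS"`, `"tRNA"`, `"rRNA"`, `"intron"`, `"misc"`),
#'   `strand` (`"+"` or `"-"`), `parts` (list of two-column integer
#'   matrices `[start, end)`), `pseudo` (logical).
#' @param circular Is the molecule circular? Default `TRUE`.
#' @param id Record identifier.
#' @return An object of class `plastome`.
#' @export
plastome <- function(sequence, features = empty_features(),
                     circular = TRUE, id = "plastome") {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stop("plastome sequence has zero length")
  validate_dna(sequence, "plastome sequence", allow_gap = FALSE)
  features <- tibble::as_tibble(features)
  needed <- c("gene", "class", "strand", "parts", "pseudo")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0) {
    stop("feature table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nchar(sequence)
  for (i in seq_len(nrow(features))) {
    p <- features$parts[[i]]
    if (!is.matrix(p) || ncol(p) != 2L) {
      stop("feature ", features$gene[i], ": parts must be a 2-column matrix")
    }
    if (any(p[, 1] < 0L) || any(p[, 2] > n) || any(p[, 1] >= p[, 2])) {
      stop("feature ", features$gene[i], ": part outside [0, ", n,
           ") or empty interval")
    }
  }
  structure(
    list(id = id, sequence = sequence, circular = circular,
         features = features),
    class = "plastome"
  )
}

#' @export
print.plastome <- function(x, ...) {
  cat("<plastome> ", x$id, ": ", format(nchar(x$sequence), big.mark = ","),
      " bp, ", if (x$circular) "circular" else "linear", ", ",
      nrow(x$features), " features\n", sep = "")
  invisible(x)
}

#' @rdname plastome
#' @export
empty_features <- function() {
  tibble::tibble(
    gene = character(), class = character(), strand = character(),
    parts = list(), pseudo = logical()
  )
}

feature_part <- function(start, end) {
  matrix(as.integer(c(start, end)), ncol = 2,
         dimnames = list(NULL, c("start", "end")))
}

# ---------------------------------------------------------------------------
# GenBank flat file

# Split a GenBank location string at top-level commas (parenthesis aware).
split_toplevel <- function(x) {
  depth <- 0L
  cut <- integer()
  cs <- chars(x)
  for (i in seq_along(cs)) {
    if (cs[i] == "(") depth <- depth + 1L
    else if (cs[i] == ")") depth <- depth - 1L
    else if (cs[i] == "," && depth == 0L) cut <- c(cut, i)
  }
  starts <- c(1L, cut + 1L)
  ends <- c(cut - 1L, nchar(x))
  mapply(function(s, e) substr(x, s, e), starts, ends, USE.NAMES = FALSE)
}

# Parse a location string into strand + 0-based half-open parts, sorted
# in genome orientation. Both complement(join(...)) and
# join(complement(...), ...) normalize to a single strand flag.
parse_gb_location <- function(loc) {
  loc <- gsub("[[:space:]<>]", "", loc)
  parse1 <- function(x, strand) {
    if (startsWith(x, "complement(")) {
      inner <- substr(x, 12L, nchar(x) - 1L)
      return(parse1(inner, if (strand == "+") "-" else "+"))
    }
    if (startsWith(x, "join(") || startsWith(x, "order(")) {
      inner <- sub("^[a-z]+\\(", "", x)
      inner <- substr(inner, 1L, nchar(inner) - 1L)
      parts <- lapply(split_toplevel(inner), parse1, strand = strand)
      strands <- unique(vapply(parts, `[[`, "", "strand"))
      if (length(strands) != 1L) {
        stop("mixed-strand compound location not supported: ", loc)
      }
      return(list(strand = strands,
                  parts = do.call(rbind, lapply(parts, `[[`, "parts"))))
    }
    m <- regmatches(x, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", x))[[1]]
    if (length(m) == 0L) stop("cannot parse location: ", loc)
    a <- as.integer(m[2])
    b <- if (m[4] == "") a else as.integer(m[4])
    if (a > b) stop("location start exceeds end in: ", loc)
    list(strand = strand, parts = feature_part(a - 1L, b))
  }
  out <- parse1(loc, "+")
  ord <- order(out$parts[, 1])
  out$parts <- out$parts[ord, , drop = FALSE]
  out
}

GB_CLASS <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", intron = "intron",
              misc_feature = "misc", gene = "misc")

#' Read a single-record GenBank flat file
#'
#' Parses the sequence and the gene/CDS/tRNA/rRNA/intron features of one
#' GenBank record into a [plastome()]. GenBank 1-based inclusive
#' coordinates are converted to 0-based half-open; `complement(join())`
#' and `join(complement())` locations are normalized to one strand flag
#' plus parts in genome orientation. Features carrying a `/pseudo` or
#' `/pseudogene` qualifier get `pseudo = TRUE`. Standalone `gene` and
#' `misc_feature` records are kept with class `"misc"`. Files with more
#' than one record are rejected.
#'
#' @param path Path to a GenBank flat file.
#' @return A [plastome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_at <- grep("^LOCUS", lines)
  if (length(locus_at) == 0L) stop("not a GenBank flat file (no LOCUS line): ", path)
  if (length(locus_at) > 1L) {
    stop("multi-record GenBank files are not supported (", length(locus_at),
         " LOCUS lines)")
  }
  id <- strsplit(trimws(sub("^LOCUS", "", lines[locus_at])), "[[:space:]]+")[[1]][1]
  circular <- grepl("circular", lines[locus_at], ignore.case = TRUE)

  feat_at <- grep("^FEATURES", lines)
  orig_at <- grep("^ORIGIN", lines)
  if (length(orig_at) != 1L) stop("GenBank record lacks an ORIGIN section")
  end_at <- grep("^//", lines)
  end_at <- if (length(end_at) > 0) end_at[1] else length(lines) + 1L

  seq_lines <- lines[(orig_at + 1L):(end_at - 1L)]
  sequence <- toupper(gsub("[0-9[:space:]/]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("GenBank record has a zero-length sequence")

  feats <- empty_features()
  if (length(feat_at) == 1L && feat_at < orig_at) {
    block <- lines[(feat_at + 1L):(orig_at - 1L)]
    # A new feature starts with a key in column 6; qualifier/continuation
    # lines are indented to column 22.
    is_key <- grepl("^ {5}[A-Za-z]", block)
    idx <- which(is_key)
    rows <- list()
    for (k in seq_along(idx)) {
      first <- block[idx[k]]
      upto <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      body <- block[seq(idx[k], upto)]
      key <- sub("^ {5}([^ ]+).*$", "\\1", first)
      if (!key %in% names(GB_CLASS)) next
      # location may continue over lines until the first qualifier
      qual_start <- grep("^ {21}/", body)
      loc_lines <- if (length(qual_start) > 0) body[seq_len(qual_start[1] - 1L)] else body
      loc <- paste(trimws(sub("^ {5}[^ ]+", "", loc_lines[1])),
                   paste(trimws(loc_lines[-1]), collapse = ""), sep = "")
      loc <- gsub("[[:space:]]", "", loc)
      parsed <- tryCatch(parse_gb_location(loc), error = function(e) {
        stop("GenBank parse error near line ", feat_at + idx[k], ": ",
             conditionMessage(e))
      })
      quals <- paste(trimws(body[grepl("^ {21}", body)]), collapse = " ")
      gene <- regmatches(quals, regexec("/gene=\"([^\"]+)\"", quals))[[1]][2]
      if (is.na(gene)) {
        gene <- regmatches(quals, regexec("/locus_tag=\"([^\"]+)\"", quals))[[1]][2]
      }
      if (is.na(gene)) gene <- paste0(key, "_", idx[k])
      pseudo <- grepl("/pseudo(gene)?\\b", quals)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        gene = gene, class = unname(GB_CLASS[key]), strand = parsed$strand,
        parts = list(parsed$parts), pseudo = pseudo
      )
    }
    if (length(rows) > 0) feats <- dplyr::bind_rows(rows)
  }
  plastome(sequence, feats, circular = circular, id = id)
}

#' Write a plastome as a GenBank flat file
#'
#' Minimal single-record writer (LOCUS, FEATURES, ORIGIN) sufficient to
#' round-trip what [read_genbank()] parses: feature class, strand,
#' multi-part 0-based coordinates (written back as 1-based inclusive
#' join/complement locations), gene names and pseudo flags.
#'
#' @param x A [plastome()].
#' @param path Output path.
#' @export
write_genbank <- function(x, path) {
  n <- nchar(x$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %s UNA 01-JAN-2000",
                     x$id, n, if (x$circular) "circular" else "linear"), con)
  writeLines(sprintf("DEFINITION  %s.", x$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  key_of <- c(CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", intron = "intron",
              misc = "misc_feature")
  for (i in seq_len(nrow(x$features))) {
    f <- x$features[i, ]
    p <- f$parts[[1]]
    locs <- sprintf("%d..%d", p[, 1] + 1L, p[, 2])
    loc <- if (length(locs) > 1L) paste0("join(", paste(locs, collapse = ","), ")") else locs
    if (f$strand == "-") loc <- paste0("complement(", loc, ")")
    writeLines(sprintf("     %-15s %s", key_of[[f$class]], loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$gene), con)
    if (f$pseudo) writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  for (s in seq(1L, n, by = 60L)) {
    chunk <- substr(x$sequence, s, min(n, s + 59L))
    groups <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(nchar(chunk), seq(10, nchar(chunk) + 9, 10)))
    writeLines(sprintf("%9d %s", s, tolower(paste(groups, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA

#' Read and write DNA FASTA files
#'
#' `read_fasta_dna()` returns a named character vector of upper-cased
#' sequences (gaps allowed, so alignments round-trip). Duplicate ids are
#' an error. `write_fasta_dna()` writes sequences wrapped at 70 columns.
#'
#' @param path File path.
#' @return `read_fasta_dna()`: named character vector.
#' @export
read_fasta_dna <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  names(out) <- sub("[[:space:]].*$", "", names(set))
  if (anyDuplicated(names(out))) {
    stop("duplicate FASTA ids: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  }
  for (i in seq_along(out)) validate_dna(out[[i]], names(out)[i], allow_gap = TRUE)
  out
}

#' @rdname read_fasta_dna
#' @param seqs Named character vector of sequences.
#' @export
write_fasta_dna <- function(seqs, path) {
  if (anyDuplicated(names(seqs))) stop("duplicate sequence ids")
  set <- Biostrings::BStringSet(toupper(seqs))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Newick

#' Read and write newick trees
#'
#' Thin validating wrappers around ape. Support values are carried as
#' internal node labels (the common newick dialect). Duplicate leaf
#' labels and malformed strings are errors.
#'
#' @param text A newick string (or path for `read_newick_file()`).
#' @return An ape `phylo` object (unrooted interpretation).
#' @export
read_newick <- function(text) {
  tr <- tryCatch(
    suppressWarnings(ape::read.tree(text = text)),
    error = function(e) NULL
  )
  if (is.null(tr)) stop("malformed newick string")
  if (inherits(tr, "multiPhylo")) stop("expected a single newick tree")
  if (anyDuplicated(tr$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(tr$tip.label[duplicated(tr$tip.label)]), collapse = ", "))
  }
  tr
}

#' @rdname read_newick
#' @export
read_newick_file <- function(text) read_newick(paste(readLines(text, warn = FALSE), collapse = ""))

#' @rdname read_newick
#' @param tree An ape `phylo` object.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

# ---------------------------------------------------------------------------
# TSV reports

#' Write a tabular report
#'
#' Tab-separated, header row, UTF-8, `"."` for missing values — the
#' on-disk shape of every table the pipeline emits.
#'
#' @param df A data frame.
#' @param path Output path.
#' @export
write_report_tsv <- function(df, path) {
  readr::write_tsv(df, path, na = ".")
  invisible(path)
}
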