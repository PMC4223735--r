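# Sequence and feature-table I/O. Internal coordinates are 0-based
# half-open on the heavy strand; feature files use the 1-based closed GFF3
# dialect. Circular genomes allow end > genome length for features that
# wrap the origin (never split).

#' Read DNA sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @param circular Mark records as circular (default `TRUE`; mitogenomes).
#' @return A tibble with columns `id`, `seq` (uppercase `A C G T N`),
#'   `length`, `circular`.
#' @export
read_fasta <- function(path, circular = TRUE) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  set <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) abort(paste0("malformed FASTA: ",
                                                   conditionMessage(e))))
  if (length(set) == 0L) abort("FASTA file contains no records")
  seqs <- str_to_upper(as.character(set))
  if (any(nchar(seqs) == 0L)) abort("FASTA record with empty sequence")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) abort("sequence contains letters outside A/C/G/T/N")
  tibble(
    id = sub("\\s.*$", "", names(set)),
    seq = unname(seqs),
    length = nchar(unname(seqs)),
    circular = circular
  )
}

#' Write sequences to a FASTA file
#'
#' @param records A tibble with columns `id` and `seq`.
#' @param path Output path.
#' @param width Line-wrap width (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::DNAStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

gff_cols <- c("seqid", "source", "type", "start", "end", "score", "strand",
              "phase", "attributes")

attr_get <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))
  vapply(m, function(x) if (length(x) == 3) x[3] else NA_character_,
         character(1))
}

#' Read a GFF3-style feature table
#'
#' Nine tab-separated columns in the GFF3 layout; coordinates in the file
#' are 1-based closed and are converted to the 0-based half-open internal
#' convention. Features wrapping the origin of a circular genome carry
#' `end` greater than the genome length (interpreted modulo length) and are
#' preserved as written, never split. Attributes used: `ID` (label),
#' `kind`, `pseudo`, `aa`.
#'
#' Overlapping features with identical labels and no pseudogene flag raise
#' a warning rather than an error: real mitogenomes contain overlapping
#' reading frames (ND4L/ND4 overlap in vertebrates).
#'
#' @param path Path to the feature table.
#' @return A tibble with columns `label`, `kind`, `start`, `end` (0-based
#'   half-open), `strand`, `pseudo`, `aa`, `seqid`, sorted by `start`.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_names = gff_cols, comment = "#",
                         col_types = "cccddcccc", progress = FALSE)
  if (nrow(raw) == 0L) abort("feature table contains no features")
  out <- tibble(
    label = attr_get(raw$attributes, "ID"),
    kind = attr_get(raw$attributes, "kind"),
    start = as.integer(raw$start) - 1L,
    end = as.integer(raw$end),
    strand = ifelse(raw$strand %in% c("+", "-"), raw$strand, "+"),
    pseudo = attr_get(raw$attributes, "pseudo"),
    aa = attr_get(raw$attributes, "aa"),
    seqid = raw$seqid
  )
  if (anyNA(out$label)) abort("feature without an ID attribute")
  miss_kind <- is.na(out$kind)
  if (any(miss_kind)) {
    out$kind[miss_kind] <- parse_gene_label(out$label[miss_kind])$kind
  }
  out$pseudo[is.na(out$pseudo)] <- "functional"
  if (any(out$start < 0)) abort("feature start before position 1")
  dup <- out |>
    mutate(.base = parse_gene_label(.data$label)$base) |>
    group_by(.data$.base) |>
    filter(n() > 1L, all(.data$pseudo == "functional")) |>
    ungroup()
  if (nrow(dup) > 0L) {
    ivs <- split(dup, dup$.base)
    for (iv in ivs) {
      if (nrow(iv) < 2L) next
      o <- iv[order(iv$start), ]
      if (any(o$start[-1] < o$end[-nrow(o)])) {
        warn(paste0("overlapping copies of ", o$.base[1],
                    " without pseudogene flags"))
      }
    }
  }
  arrange(out, .data$start)
}

#' Write a feature table in the GFF3-style dialect
#'
#' @param features Feature tibble (columns as from [read_feature_table()]).
#' @param path Output path.
#' @param seqid Sequence identifier for the first column when the table has
#'   none.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(features, path, seqid = "genome") {
  sid <- if ("seqid" %in% names(features)) features$seqid else seqid
  aa <- if ("aa" %in% names(features)) features$aa else NA_character_
  ps <- if ("pseudo" %in% names(features)) features$pseudo else "functional"
  attrs <- paste0(
    "ID=", features$label,
    ";kind=", features$kind,
    ";pseudo=", ps,
    ifelse(is.na(aa), "", paste0(";aa=", aa))
  )
  lines <- paste(sid, "mitorearr", features$kind,
                 features$start + 1L, features$end, ".", features$strand,
                 ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Extract the sense-strand sequence of a feature
#'
#' Handles origin-wrapping features (`end` beyond the genome length) on
#' circular genomes and reverse-complements light-strand features, so the
#' result reads 5' to 3' in the gene's own sense.
#'
#' @param genome_seq A single DNA string (forward/heavy strand).
#' @param start,end 0-based half-open coordinates; `end` may exceed the
#'   genome length for wrapping features.
#' @param strand `"+"` or `"-"`.
#' @return The feature sequence as a single string.
#' @export
extract_feature_seq <- function(genome_seq, start, end, strand = "+") {
  len <- nchar(genome_seq)
  if (start < 0 || start >= len) abort("feature start outside the genome")
  if (end <= start) abort("feature end must exceed its start")
  s <- if (end > len) {
    paste0(substr(genome_seq, start + 1L, len),
           substr(genome_seq, 1L, end - len))
  } else {
    substr(genome_seq, start + 1L, end)
  }
  if (strand == "-") dna_revcomp(s) else s
}

#' Length of the intergenic stretch between two annotated genes
#'
#' Measures the unannotated gap on the forward strand between the end of
#' the feature labelled `from` and the start of the feature labelled `to`,
#' wrapping around the origin when needed.
#'
#' @param features A feature tibble.
#' @param from,to Labels of the flanking genes (base labels accepted).
#' @param genome_length Genome length, required when the gap wraps.
#' @return Gap length in bp (0 when the genes abut or overlap).
#' @export
intergenic_length <- function(features, from, to, genome_length = NULL) {
  base <- parse_gene_label(features$label)$base
  i <- which(features$label == from | base == from)
  j <- which(features$label == to | base == to)
  if (length(i) == 0L || length(j) == 0L) {
    abort("flanking gene not found in the feature table")
  }
  gap <- features$start[j[1]] - features$end[i[1]]
  if (gap < 0 && !is.null(genome_length)) gap <- gap + genome_length
  max(gap, 0L)
}
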