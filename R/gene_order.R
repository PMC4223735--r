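# Circular gene orders. A gene order is a tibble (label, strand) of class
# "mito_order"; equality and all comparisons are invariant under rotation,
# which is what circularity means for the analyses here.

#' Construct a circular gene order
#'
#' @param label Character vector of gene labels (see [gene_vocabulary()];
#'   copy indices and trailing `*` pseudogene marks allowed).
#' @param strand Strands, `"+"` (heavy) or `"-"` (light); recycled.
#' @param validate Check labels against the vocabulary (default `TRUE`).
#' @return A `mito_order` tibble with columns `label`, `strand`.
#' @export
gene_order <- function(label, strand = "+", validate = TRUE) {
  if (length(label) == 0L) abort("a gene order needs at least one gene")
  strand <- rep_len(strand, length(label))
  if (!all(strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  if (validate) parse_gene_label(label)  # errors on unknown labels
  out <- tibble(label = label, strand = strand)
  class(out) <- c("mito_order", class(out))
  out
}

#' Read a gene order from its text form
#'
#' The text form is comma-separated labels, light-strand genes prefixed
#' with `-`, e.g. `"trnW,-trnA,-trnN,OL,-trnC,-trnY"`.
#'
#' @param x A single string.
#' @return A `mito_order`.
#' @export
order_from_string <- function(x) {
  parts <- trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) abort("empty gene-order string")
  strand <- ifelse(startsWith(parts, "-"), "-", "+")
  gene_order(sub("^-", "", parts), strand)
}

#' @rdname order_from_string
#' @param order A `mito_order`.
#' @export
order_to_string <- function(order) {
  paste0(ifelse(order$strand == "-", "-", ""), order$label, collapse = ",")
}

signed_labels <- function(order) {
  paste0(ifelse(order$strand == "-", "-", ""), order$label)
}

rotate_order <- function(order, k) {
  n <- nrow(order)
  k <- ((k - 1L) %% n) + 1L
  idx <- c(k:n, seq_len(k - 1L))[seq_len(n)]
  out <- order[idx, ]
  class(out) <- class(order)
  out
}

#' Canonical rotation of a circular gene order
#'
#' Rotates the order to start at `trnF` (the conventional origin of the
#' vertebrate arrangement; any copy of `trnF` counts). Without a `trnF` the
#' lexicographically smallest rotation is used, so that two rotations of the
#' same circle always canonicalise identically.
#'
#' @param order A `mito_order`.
#' @return The rotated `mito_order`.
#' @export
canonicalize_order <- function(order) {
  base <- parse_gene_label(order$label)$base
  hit <- which(base == "trnF")
  if (length(hit) > 0L) return(rotate_order(order, hit[1]))
  keys <- vapply(seq_len(nrow(order)), function(k) {
    order_to_string(rotate_order(order, k))
  }, character(1))
  rotate_order(order, which(keys == min(keys))[1])
}

order_key <- function(order) {
  sl <- signed_labels(order)
  n <- length(sl)
  keys <- vapply(seq_len(n), function(k) {
    paste(sl[c(k:n, seq_len(k - 1L))[seq_len(n)]], collapse = ",")
  }, character(1))
  min(keys)
}

#' Rotation-invariant equality of circular gene orders
#'
#' @param a,b `mito_order` objects (or label vectors).
#' @return `TRUE` when `b` is a rotation of `a` (labels and strands).
#' @export
order_equal <- function(a, b) {
  if (!inherits(a, "mito_order")) a <- gene_order(a, validate = FALSE)
  if (!inherits(b, "mito_order")) b <- gene_order(b, validate = FALSE)
  if (nrow(a) != nrow(b)) return(FALSE)
  order_key(a) == order_key(b)
}

#' Extract the circular gene order from a feature table
#'
#' Features are sorted by start coordinate on the forward strand and the
#' resulting circular order is rooted at `trnF` when present. Pseudogene
#' features are kept, with `*` appended to their label if not already
#' marked. The same genome rotated by any offset yields an equal
#' `mito_order`.
#'
#' @param features A feature tibble as returned by [read_feature_table()]
#'   or [generate_mitogenome()] (columns `label`, `start`, `strand`, and
#'   optionally `pseudo`).
#' @param genome_length Optional genome length, used to order
#'   origin-wrapping features by their (modular) start.
#' @return A `mito_order`.
#' @export
extract_gene_order <- function(features, genome_length = NULL) {
  if (is.null(features) || nrow(features) == 0L) {
    abort("cannot extract a gene order from an empty feature table")
  }
  start <- features$start
  if (!is.null(genome_length)) start <- start %% genome_length
  ord <- order(start)
  label <- features$label[ord]
  if ("pseudo" %in% names(features)) {
    ps <- features$pseudo[ord]
    flag <- (ps %in% c("pseudogene", "possible_pseudogene") | ps == TRUE)
    flag[is.na(flag)] <- FALSE
    label <- ifelse(flag & !grepl("\\*$", label), paste0(label, "*"), label)
  }
  strand <- if ("strand" %in% names(features)) features$strand[ord] else "+"
  canonicalize_order(gene_order(label, strand))
}

#' Project a gene order onto its functional genes
#'
#' Drops pseudogene-marked entries (trailing `*`) and strips copy indices,
#' giving the order of presumed-functional genes.
#'
#' @param order A `mito_order`.
#' @return A `mito_order` over base labels.
#' @export
functional_projection <- function(order) {
  p <- parse_gene_label(order$label)
  keep <- !p$pseudo
  if (!any(keep)) abort("no functional genes left after projection")
  canonicalize_order(gene_order(p$base[keep], order$strand[keep]))
}

#' @export
print.mito_order <- function(x, ...) {
  cat("<mito_order> ", nrow(x), " genes (circular)\n", sep = "")
  cat(order_to_string(x), "\n")
  invisible(x)
}
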