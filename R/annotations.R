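# Gene annotations, operon structures, operon-relative positions and
# intergenic distances. Coordinates are 1-based inclusive (GenBank
# convention) throughout.

#' Read gene annotations
#'
#' Loads gene coordinates and strand from a 5-column TSV
#' (`gene_id`, `chrom`, `start`, `end`, `strand`) or from a GFF3 file
#' (feature type `gene` or `CDS`; the gene identifier is taken from the
#' `ID`, `locus_tag` or `Name` attribute, in that order). Coordinates are
#' 1-based inclusive on both ends.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by file extension), `"tsv"` or `"gff"`.
#' @return A data frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, one row per gene.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("thrA\tchr\t337\t2799\t+", "thrB\tchr\t2801\t3733\t+"), tf)
#' read_annotations(tf)
#' @export
read_annotations <- function(path, format = c("auto", "tsv", "gff")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?(\\.gz)?$", path, ignore.case = TRUE))
      "gff" else "tsv"
  }
  ann <- if (format == "gff") read_annotations_gff(path)
         else read_annotations_tsv(path)
  validate_annotations(ann)
  ann
}

read_annotations_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("annotation file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # optional header: detected by a non-numeric start column
  first <- fields[[1L]]
  has_header <- length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))
  if (has_header) {
    lines <- lines[-1L]
    fields <- fields[-1L]
  }
  n_fields <- lengths(fields)
  bad <- which(n_fields != 5L)
  if (length(bad) > 0L) {
    stop("malformed annotation line ", bad[1L] + has_header,
         ": expected 5 tab-separated fields, got ", n_fields[bad[1L]])
  }
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(m[, 3L]))
  end <- suppressWarnings(as.integer(m[, 4L]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0L) {
    stop("malformed annotation line ", bad[1L] + has_header,
         ": non-integer coordinate")
  }
  data.frame(gene_id = m[, 1L], chrom = m[, 2L], start = start, end = end,
             strand = m[, 5L], stringsAsFactors = FALSE)
}

read_annotations_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  keep <- as.character(gr$type) %in% c("gene", "CDS")
  if (any(keep)) gr <- gr[keep]
  meta <- as.data.frame(GenomicRanges::mcols(gr))
  id <- rep(NA_character_, length(gr))
  for (field in c("ID", "locus_tag", "Name")) {
    if (field %in% names(meta)) {
      v <- as.character(meta[[field]])
      id[is.na(id) & !is.na(v)] <- v[is.na(id) & !is.na(v)]
    }
  }
  if (anyNA(id)) stop("GFF feature without ID/locus_tag/Name attribute")
  data.frame(gene_id = id,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

validate_annotations <- function(ann) {
  stopifnot(is.data.frame(ann),
            all(c("gene_id", "chrom", "start", "end", "strand") %in% names(ann)))
  if (any(ann$start < 1L)) {
    stop("validation error: start coordinate < 1 for gene ",
         ann$gene_id[which(ann$start < 1L)[1L]])
  }
  if (any(ann$end < ann$start)) {
    stop("validation error: end < start for gene ",
         ann$gene_id[which(ann$end < ann$start)[1L]])
  }
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene_id in annotation: ", dup[1L])
  }
  if (!all(ann$strand %in% c("+", "-"))) {
    stop("validation error: strand must be '+' or '-'")
  }
  invisible(ann)
}

#' Read operon structures
#'
#' Loads an operon table: two tab-separated columns, `operon_id` and a
#' comma-separated list of gene ids in transcription direction
#' (5' to 3' of the shared transcript), as in EcoCyc-style exports.
#'
#' @param path Path to the operon TSV.
#' @return A named list of character vectors (one per operon, in
#'   transcription order), of class `"operon_set"`.
#' @export
read_operons <- function(path) {
  if (!file.exists(path)) stop("operon file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n_fields <- lengths(fields)
  if (any(n_fields != 2L)) {
    stop("malformed operon line ", which(n_fields != 2L)[1L],
         ": expected 2 tab-separated fields")
  }
  ids <- vapply(fields, `[[`, character(1), 1L)
  genes <- lapply(fields, function(f) {
    trimws(strsplit(f[[2L]], ",", fixed = TRUE)[[1L]])
  })
  names(genes) <- ids
  as_operon_set(genes)
}

#' Construct an operon set from a named list of gene vectors
#'
#' @param x Named list; each element is a character vector of gene ids in
#'   transcription order.
#' @return The validated list with class `"operon_set"`.
#' @export
as_operon_set <- function(x) {
  stopifnot(is.list(x), !is.null(names(x)), !anyDuplicated(names(x)))
  for (op in names(x)) {
    g <- x[[op]]
    if (length(g) == 0L || any(!nzchar(g))) {
      stop("validation error: operon ", op, " is empty")
    }
    if (anyDuplicated(g)) {
      stop("validation error: duplicate gene in operon ", op)
    }
  }
  all_genes <- unlist(x, use.names = FALSE)
  dup <- all_genes[duplicated(all_genes)]
  if (length(dup) > 0L) {
    stop("gene ", dup[1L], " appears in more than one operon")
  }
  structure(x, class = "operon_set")
}

# gene_id -> operon_id lookup (named character vector)
gene_to_operon <- function(operons) {
  stats::setNames(rep(names(operons), lengths(operons)),
                  unlist(operons, use.names = FALSE))
}

#' Operon-relative positions of genes around a deletion
#'
#' Indexes every gene of one operon relative to the deleted gene:
#' position 0 is the deleted gene itself, negative positions are upstream
#' (5' on the transcript) and positive positions downstream.
#'
#' @param genes Character vector of gene ids in transcription order (one
#'   operon), or a single element of an [as_operon_set()] object.
#' @param deleted_gene Gene id of the deletion; must be in `genes`.
#' @return Data frame with columns `gene_id` and `position` (signed
#'   integer), in transcription order.
#' @examples
#' relative_positions(c("A", "B", "C", "D"), "B")
#' @export
relative_positions <- function(genes, deleted_gene) {
  genes <- as.character(genes)
  i <- match(deleted_gene, genes)
  if (is.na(i)) {
    stop("deleted gene ", deleted_gene, " is not in the operon")
  }
  data.frame(gene_id = genes,
             position = seq_along(genes) - i,
             stringsAsFactors = FALSE)
}

#' Intergenic distance between a deleted gene and a downstream gene
#'
#' Nucleotides separating the last base of the deleted gene's stop codon
#' from the first base of the downstream gene's start codon, on wild-type
#' coordinates: abutting ORFs give 0 and overlapping coding sequences give
#' negative values. Both genes must lie on the same strand (same operon).
#'
#' @param deleted One-row annotation data frame (see [read_annotations()])
#'   for the deleted gene.
#' @param downstream One-row annotation data frame for the downstream gene.
#' @return Signed integer distance in nucleotides.
#' @examples
#' a <- data.frame(gene_id = "A", chrom = "c", start = 1, end = 1000, strand = "+")
#' b <- data.frame(gene_id = "B", chrom = "c", start = 1051, end = 2000, strand = "+")
#' intergenic_distance(a, b)  # 50
#' @export
intergenic_distance <- function(deleted, downstream) {
  stopifnot(nrow(deleted) == 1L, nrow(downstream) == 1L)
  if (deleted$strand != downstream$strand) {
    stop("genes ", deleted$gene_id, " and ", downstream$gene_id,
         " are on different strands")
  }
  if (deleted$strand == "+") {
    as.integer(downstream$start - deleted$end - 1L)
  } else {
    as.integer(deleted$start - downstream$end - 1L)
  }
}

#' Write annotations / operons back to their TSV formats
#'
#' @param ann Annotation data frame.
#' @param operons An `"operon_set"`.
#' @param path Output path.
#' @name write_tables
#' @return The path, invisibly.
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  utils::write.table(ann[, c("gene_id", "chrom", "start", "end", "strand")],
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_operons <- function(operons, path) {
  lines <- paste0(names(operons), "\t",
                  vapply(operons, paste, character(1), collapse = ","))
  writeLines(lines, path)
  invisible(path)
}
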