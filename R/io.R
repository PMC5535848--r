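#' Read a protein FASTA file
#'
#' Wrapped (multi-line) sequences are concatenated. The accession is the
#' first whitespace-delimited token of the header line.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_("FASTA file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- vapply(strsplit(names(aa), "\\s+"), `[[`, character(1), 1L)
  seqs
}

#' Write a protein FASTA file
#'
#' @param proteome Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width. Default 60.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteome, path, width = 60L) {
  aa <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aa, filepath = path, width = width)
  invisible(path)
}

#' Read and write the protein-by-run precursor-area matrix
#'
#' The on-disk dialect is UTF-8 TSV with a header row: first column
#' `accession`, one column per MS run, and an optional final column
#' `unique_peptides`. Empty cells encode missing (not detected) areas;
#' zero areas are treated as missing on read, since a zero precursor area
#' is a non-detection.
#'
#' @param path TSV path.
#' @return For `read_area_tsv`, an [area_matrix()] object.
#' @rdname area-io
#' @export
read_area_tsv <- function(path) {
  if (!file.exists(path)) stop_("area matrix file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  if (!"accession" %in% names(df))
    stop_("area matrix is missing the 'accession' header column")
  up <- NULL
  if ("unique_peptides" %in% names(df)) {
    up <- as.integer(df$unique_peptides)
    df$unique_peptides <- NULL
  }
  runs <- setdiff(names(df), "accession")
  m <- as.matrix(df[runs])
  mode(m) <- "numeric"
  rownames(m) <- df$accession
  area_matrix(m, unique_peptides = up)
}

#' @param x An [area_matrix()] object (for `write_area_tsv`).
#' @rdname area-io
#' @export
write_area_tsv <- function(x, path) {
  stopifnot(inherits(x, "area_matrix"))
  df <- data.frame(accession = rownames(x$areas), x$areas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(x$unique_peptides)) df$unique_peptides <- x$unique_peptides
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read and write the run design table
#'
#' TSV with header columns `run`, `group`, `replicate` mapping each MS run
#' to its experimental group and biological replicate.
#'
#' @param path TSV path.
#' @return For `read_design_tsv`, a data frame with columns `run`, `group`,
#'   `replicate`; `group` keeps its file order as factor levels.
#' @rdname design-io
#' @export
read_design_tsv <- function(path) {
  if (!file.exists(path)) stop_("design file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("run", "group", "replicate")
  if (!all(need %in% names(df)))
    stop_("design table must have columns: ", paste(need, collapse = ", "))
  df$group <- factor(df$group, levels = unique(df$group))
  df
}

#' @param design Design data frame (for `write_design_tsv`).
#' @rdname design-io
#' @export
write_design_tsv <- function(design, path) {
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' The GMT dialect is one term per line: term id, description, then member
#' accessions, all tab-separated.
#'
#' @param path GMT path.
#' @param namespace Namespace label attached to the term set (e.g. `"GO-CC"`
#'   or `"KEGG"`).
#' @return For `read_gmt`, an `annotation_terms` object: a named list of
#'   accession character vectors with a `namespace` attribute.
#' @rdname gmt-io
#' @export
read_gmt <- function(path, namespace = "terms") {
  if (!file.exists(path)) stop_("GMT file not found: ", path)
  terms <- fgsea::gmtPathways(path)
  annotation_terms(terms, namespace = namespace)
}

#' @param terms A named list of member-accession vectors (for `write_gmt`);
#'   descriptions default to the term ids.
#' @rdname gmt-io
#' @export
write_gmt <- function(terms, path) {
  lines <- vapply(names(terms), function(id) {
    paste(c(id, id, terms[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Annotation term-set container
#'
#' @param terms Named list; each element a character vector of member
#'   accessions.
#' @param namespace Single namespace label.
#' @return An `annotation_terms` object.
#' @export
annotation_terms <- function(terms, namespace = "terms") {
  if (length(terms) == 0L) {
    terms <- structure(list(), names = character(0))
  }
  if (is.null(names(terms)) || any(!nzchar(names(terms))))
    stop_("every term must be named")
  if (anyDuplicated(names(terms)))
    stop_("duplicate term id within namespace '", namespace, "'")
  empty <- vapply(terms, length, integer(1)) == 0L
  if (any(empty))
    stop_("term(s) with no members: ",
          paste(names(terms)[empty], collapse = ", "))
  structure(lapply(terms, unique), namespace = namespace,
            class = "annotation_terms")
}

#' @export
print.annotation_terms <- function(x, ...) {
  cat("Annotation term set [", attr(x, "namespace"), "]: ",
      length(x), " terms\n", sep = "")
  sizes <- vapply(unclass(x), length, integer(1))
  if (length(sizes))
    cat("  term sizes: min ", min(sizes), ", median ",
        stats::median(sizes), ", max ", max(sizes), "\n", sep = "")
  invisible(x)
}
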