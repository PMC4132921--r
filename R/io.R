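# File-format helpers.  FASTA goes through Biostrings; GFF3 and the
# RepeatMasker .out dialect are small flat formats written/read directly.
# Coordinates are 0-based half-open internally and 1-based inclusive on disk.

#' Read a FASTA file as a named character vector
#' @param path FASTA file.
#' @param type "AA" or "DNA".
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::readAAStringSet(path)
       else Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write a named character vector as FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @param type "AA" or "DNA".
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  x <- if (type == "AA") Biostrings::AAStringSet(seqs)
       else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write gene loci as GFF3 (1-based inclusive)
#'
#' @param loci data.frame with columns scaffold_id, start, end (0-based
#'   half-open), strand, gene_id and optionally is_pseudogene, is_allele_of.
#' @param path output file.
#' @export
write_gff3 <- function(loci, path) {
  attrs <- paste0("ID=", loci$gene_id)
  if (!is.null(loci$is_pseudogene))
    attrs <- ifelse(loci$is_pseudogene, paste0(attrs, ";pseudo=true"), attrs)
  if (!is.null(loci$is_allele_of))
    attrs <- ifelse(!is.na(loci$is_allele_of),
                    paste0(attrs, ";allele_of=", loci$is_allele_of), attrs)
  if (!is.null(loci$family))
    attrs <- paste0(attrs, ";family=", loci$family)
  lines <- paste(loci$scaffold_id, "chemomine", "gene",
                 loci$start + 1L, loci$end, ".", loci$strand, ".", attrs,
                 sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a chemomine GFF3 gene file back into a loci data.frame
#' @param path GFF3 file written by [write_gff3()].
#' @export
read_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) {
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_id = character(), is_pseudogene = logical(),
                      is_allele_of = character(), family = character()))
  }
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  get_attr <- function(attr, key) {
    pat <- paste0("(^|;)", key, "=([^;]*)")
    has <- grepl(pat, attr)
    out <- rep(NA_character_, length(attr))
    out[has] <- sub(paste0(".*(^|;)", key, "=([^;]*).*"), "\\2", attr[has])
    out
  }
  a <- f[, 9]
  data.frame(scaffold_id = f[, 1],
             start = as.integer(f[, 4]) - 1L,
             end = as.integer(f[, 5]),
             strand = f[, 7],
             gene_id = get_attr(a, "ID"),
             is_pseudogene = !is.na(get_attr(a, "pseudo")),
             is_allele_of = get_attr(a, "allele_of"),
             family = get_attr(a, "family"),
             stringsAsFactors = FALSE)
}

#' Write repeat elements in the RepeatMasker .out dialect
#'
#' Three header lines followed by whitespace-separated columns; coordinates
#' 1-based inclusive; class/family column like "LINE/L2".
#' @param elements data.frame with scaffold_id, start, end (0-based
#'   half-open), strand, family, class.
#' @param path output file.
#' @export
write_repeatmasker_out <- function(elements, path) {
  hdr <- c(
    "   SW   perc perc perc  query     position in query    matching  repeat         position in repeat",
    "score   div. del. ins.  sequence  begin end    (left)  repeat    class/family   begin end (left) ID",
    "")
  if (nrow(elements)) {
    strand <- ifelse(elements$strand == "-", "C", "+")
    classfam <- ifelse(
      elements$class %in% c("SINE", "LINE", "LTR", "DNA"),
      paste0(elements$class, "/", elements$family),
      ifelse(elements$class == "SmallRNA", "Small_RNA", "Simple_repeat"))
    body <- sprintf("%5d %6.1f %4.1f %4.1f  %s %8d %8d (%d) %s %s %s %6d %6d (0) %d",
                    1000L, 10.0, 0.5, 0.5, elements$scaffold_id,
                    elements$start + 1L, elements$end, 0L, strand,
                    elements$family, classfam, 1L,
                    elements$end - elements$start, seq_len(nrow(elements)))
  } else body <- character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
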