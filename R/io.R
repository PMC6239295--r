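# FASTA / GFF3 / TSV plumbing shared by the generator and the pipeline.

#' Write named sequences as FASTA
#'
#' @param seqs Named character vector, or an \code{XStringSet}.
#' @param path Output file.
#' @param type \code{"AA"} or \code{"DNA"} (ignored for \code{XStringSet}
#'   input).
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, type = c("AA", "DNA"), width = 60L) {
  if (is.character(seqs)) {
    type <- match.arg(type)
    seqs <- if (type == "AA") Biostrings::AAStringSet(seqs)
            else Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

#' Read a protein FASTA as a named character vector
#'
#' The full description line is kept in the \code{desc} attribute so labels
#' such as \code{subfamily=TPS-a} survive.
#'
#' @param path FASTA file.
#' @return Named character vector of residue strings, with a \code{desc}
#'   attribute of full description lines.
#' @export
read_fasta_aa <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  desc <- names(ss)
  ids <- sub("\\s.*$", "", desc)
  out <- stats::setNames(as.character(ss), ids)
  attr(out, "desc") <- stats::setNames(desc, ids)
  out
}

#' Read a genome FASTA as a named character vector
#' @param path FASTA file.
#' @return Named character vector of scaffold sequences.
#' @export
read_fasta_dna <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write gene models as GFF3
#'
#' Emits gene / mRNA / exon / CDS features (1-based inclusive coordinates,
#' version-3 header). CDS phase is computed along the transcription order.
#'
#' @param models List of \code{GeneModel}s.
#' @param path Output file.
#' @param source Value of the GFF3 source column.
#' @export
write_gff3 <- function(models, path, source = "tpsminer") {
  lines <- "##gff-version 3"
  for (m in models) {
    gid <- m$gene_id
    span <- c(min(m$exons$start), max(m$exons$end))
    lines <- c(lines,
      sprintf("%s\t%s\tgene\t%d\t%d\t.\t%s\t.\tID=gene:%s",
              m$scaffold_id, source, span[1], span[2], m$strand, gid),
      sprintf("%s\t%s\tmRNA\t%d\t%d\t.\t%s\t.\tID=mRNA:%s;Parent=gene:%s",
              m$scaffold_id, source, span[1], span[2], m$strand, gid, gid))
    ex <- m$exons
    for (i in seq_len(nrow(ex))) {
      lines <- c(lines,
        sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\tParent=mRNA:%s",
                m$scaffold_id, source, ex$start[i], ex$end[i], m$strand, gid))
    }
    cds <- m$cds_intervals
    ord <- if (m$strand == "+") seq_len(nrow(cds)) else rev(seq_len(nrow(cds)))
    done <- 0L
    phase <- integer(nrow(cds))
    for (i in ord) {
      phase[i] <- (3L - (done %% 3L)) %% 3L
      done <- done + (cds$end[i] - cds$start[i] + 1L)
    }
    for (i in seq_len(nrow(cds))) {
      lines <- c(lines,
        sprintf("%s\t%s\tCDS\t%d\t%d\t.\t%s\t%d\tParent=mRNA:%s",
                m$scaffold_id, source, cds$start[i], cds$end[i], m$strand,
                phase[i], gid))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

# Pull one key=value out of a GFF3 attribute column.
gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)", key, "=([^;]+)"), attrs))
  vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_,
         character(1))
}

#' Read gene models from GFF3
#'
#' Groups exon and CDS features by their mRNA parent (and the mRNA by its
#' gene parent) into \code{GeneModel}s. The subset of GFF3 handled matches
#' what [write_gff3()] emits: ID/Parent attributes with optional
#' \code{gene:}/\code{mRNA:} prefixes.
#'
#' @param path GFF3 file.
#' @return Named list of \code{GeneModel}s.
#' @export
read_gene_models <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (!length(ln)) stop("no GFF3 feature lines in ", path)
  f <- strsplit(ln, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L))
    stop("malformed GFF3 line: ", ln[which(lengths(f) != 9L)[1]])
  tab <- data.frame(seqid = vapply(f, `[[`, "", 1),
                    type = vapply(f, `[[`, "", 3),
                    start = as.integer(vapply(f, `[[`, "", 4)),
                    end = as.integer(vapply(f, `[[`, "", 5)),
                    strand = vapply(f, `[[`, "", 7),
                    attrs = vapply(f, `[[`, "", 9),
                    stringsAsFactors = FALSE)
  strip <- function(x) sub("^(gene|mRNA):", "", x)
  mrna <- tab[tab$type == "mRNA", , drop = FALSE]
  mrna_id <- strip(gff3_attr(mrna$attrs, "ID"))
  mrna_gene <- strip(gff3_attr(mrna$attrs, "Parent"))
  gene_of_mrna <- stats::setNames(mrna_gene, mrna_id)

  pick <- function(type) {
    x <- tab[tab$type == type, , drop = FALSE]
    x$parent <- strip(gff3_attr(x$attrs, "Parent"))
    x$gene <- ifelse(x$parent %in% names(gene_of_mrna),
                     gene_of_mrna[x$parent], x$parent)
    x
  }
  exons <- pick("exon")
  cds <- pick("CDS")
  ids <- unique(exons$gene)
  models <- lapply(ids, function(g) {
    e <- exons[exons$gene == g, , drop = FALSE]
    e <- e[order(e$start), , drop = FALSE]
    cc <- cds[cds$gene == g, , drop = FALSE]
    cc <- if (nrow(cc)) cc[order(cc$start), , drop = FALSE] else e
    gene_model(g, e$seqid[1], e$strand[1],
               e[, c("start", "end")], cc[, c("start", "end")])
  })
  stats::setNames(models, ids)
}

#' Write / read the simulation truth table
#' @param truth data.frame of \code{TruthRecord}s.
#' @param path TSV file.
#' @export
write_truth_table <- function(truth, path) {
  utils::write.table(truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth_table
#' @export
read_truth_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
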