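#' Construct a gene model
#'
#' A gene model records where a gene's exons (and coding intervals) lie on a
#' scaffold. All coordinates are 1-based inclusive on the forward strand,
#' the convention of GFF3; for minus-strand genes the intervals are still
#' given in forward-strand coordinates and splicing reverse-complements the
#' joined sequence.
#'
#' @param gene_id Gene identifier.
#' @param scaffold_id Scaffold the gene lies on.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons data.frame (or 2-column matrix) of exon \code{start},
#'   \code{end} intervals, sorted and non-overlapping.
#' @param cds Coding intervals, same convention; defaults to the exons.
#' @return A \code{GeneModel} object.
#' @export
gene_model <- function(gene_id, scaffold_id, strand, exons, cds = exons) {
  as_iv <- function(x) {
    x <- as.data.frame(x)
    names(x)[1:2] <- c("start", "end")
    x$start <- as.integer(x$start); x$end <- as.integer(x$end)
    x
  }
  exons <- as_iv(exons); cds <- as_iv(cds)
  stopifnot(strand %in% c("+", "-"),
            all(exons$start <= exons$end),
            all(cds$start <= cds$end))
  if (nrow(exons) > 1 &&
      (any(diff(exons$start) <= 0) ||
       any(exons$start[-1] <= exons$end[-nrow(exons)])))
    stop("exon intervals of ", gene_id, " must be sorted and non-overlapping")
  structure(list(gene_id = gene_id, scaffold_id = scaffold_id,
                 strand = strand, exons = exons, cds_intervals = cds),
            class = "GeneModel")
}

#' Splice a gene model and translate its coding sequence
#'
#' Coding intervals are extracted from the scaffold, concatenated in genomic
#' order, reverse-complemented when the gene is on the minus strand, and
#' translated with the standard genetic code. Codons containing N translate
#' to \code{X} (never counted as stops). A joined CDS whose length is not a
#' multiple of 3 is flagged as frameshifted and translated up to the last
#' complete codon.
#'
#' @param scaffold Scaffold nucleotide sequence (character or
#'   \code{DNAString}).
#' @param model A \code{GeneModel}.
#' @return A \code{TranslationResult}: list with \code{protein} (residue
#'   string, terminal stop removed), \code{internal_stop_count},
#'   \code{frameshift_flag} and \code{terminal_stop_flag}.
#' @export
splice_and_translate <- function(scaffold, model) {
  scaffold <- as.character(scaffold)
  n <- nchar(scaffold)
  iv <- model$cds_intervals
  if (nrow(iv) == 0 || sum(iv$end - iv$start + 1L) == 0)
    stop("empty CDS for gene ", model$gene_id)
  bad <- which(iv$start < 1L | iv$end > n)
  if (length(bad))
    stop(sprintf("CDS interval [%d, %d] of gene %s out of scaffold bounds (1..%d)",
                 iv$start[bad[1]], iv$end[bad[1]], model$gene_id, n))
  iv <- iv[order(iv$start), , drop = FALSE]
  cds <- paste(substring(scaffold, iv$start, iv$end), collapse = "")
  dna <- Biostrings::DNAString(cds)
  if (model$strand == "-") dna <- Biostrings::reverseComplement(dna)
  len <- length(dna)
  frameshift <- (len %% 3L) != 0L
  usable <- len - (len %% 3L)
  prot <- as.character(Biostrings::translate(
    Biostrings::subseq(dna, 1L, usable), if.fuzzy.codon = "X"))
  terminal_stop <- nchar(prot) > 0 && substring(prot, nchar(prot)) == "*"
  if (terminal_stop) prot <- substring(prot, 1L, nchar(prot) - 1L)
  internal_stops <- sum(split_chars(prot) == "*")
  structure(list(protein = prot,
                 internal_stop_count = internal_stops,
                 frameshift_flag = frameshift,
                 terminal_stop_flag = terminal_stop),
            class = "TranslationResult")
}

#' Splice and translate many gene models at once
#'
#' Batch form of [splice_and_translate()]: all coding sequences are extracted
#' first, then reverse-complemented and translated in single vectorized
#' calls. Results are identical to the per-gene function.
#'
#' @param scaffolds Named character vector of scaffold sequences.
#' @param models Named list of \code{GeneModel}s.
#' @return Named list of \code{TranslationResult}s.
#' @export
translate_gene_models <- function(scaffolds, models) {
  cds <- vapply(models, function(m) {
    scaffold <- scaffolds[[m$scaffold_id]]
    iv <- m$cds_intervals
    if (nrow(iv) == 0 || sum(iv$end - iv$start + 1L) == 0)
      stop("empty CDS for gene ", m$gene_id)
    bad <- which(iv$start < 1L | iv$end > nchar(scaffold))
    if (length(bad))
      stop(sprintf("CDS interval [%d, %d] of gene %s out of scaffold bounds (1..%d)",
                   iv$start[bad[1]], iv$end[bad[1]], m$gene_id,
                   nchar(scaffold)))
    iv <- iv[order(iv$start), , drop = FALSE]
    paste(substring(scaffold, iv$start, iv$end), collapse = "")
  }, character(1))
  strands <- vapply(models, function(m) m$strand, character(1))
  set <- Biostrings::DNAStringSet(cds)
  minus <- strands == "-"
  if (any(minus)) set[minus] <- Biostrings::reverseComplement(set[minus])
  len <- Biostrings::width(set)
  frameshift <- (len %% 3L) != 0L
  prots <- unname(as.character(Biostrings::translate(
    Biostrings::subseq(set, 1L, len - len %% 3L), if.fuzzy.codon = "X")))
  frameshift <- unname(frameshift)
  out <- lapply(seq_along(models), function(i) {
    prot <- prots[i]
    terminal_stop <- nchar(prot) > 0 && substring(prot, nchar(prot)) == "*"
    if (terminal_stop) prot <- substring(prot, 1L, nchar(prot) - 1L)
    structure(list(protein = prot,
                   internal_stop_count = sum(split_chars(prot) == "*"),
                   frameshift_flag = frameshift[i],
                   terminal_stop_flag = terminal_stop),
              class = "TranslationResult")
  })
  stats::setNames(out, names(models))
}

#' Triage configuration
#'
#' The curation thresholds behind the functional/partial/pseudogene split.
#' \code{min_functional_length} (default 250 aa) is the shortest protein still
#' reportable as putatively functional: 250 is the largest round value that
#' admits every full-length reference catalogue entry (minimum printed length
#' 274 aa). Proteins under \code{min_report_length} (default 100 aa) are
#' excluded outright.
#'
#' @param min_functional_length Residues; proteins shorter are at best partial.
#' @param min_report_length Residues; proteins shorter are excluded.
#' @param pseudogene_stop_threshold Internal stop codons at or above which a
#'   gene is called a probable pseudogene.
#' @param require_both_domains_for_functional Demand hits to both the
#'   N-terminal and C-terminal TPS domain profiles for a functional call.
#' @return A \code{TriageConfig} list.
#' @export
triage_config <- function(min_functional_length = 250L,
                          min_report_length = 100L,
                          pseudogene_stop_threshold = 1L,
                          require_both_domains_for_functional = TRUE) {
  stopifnot(min_report_length <= min_functional_length,
            pseudogene_stop_threshold >= 1L)
  structure(list(min_functional_length = as.integer(min_functional_length),
                 min_report_length = as.integer(min_report_length),
                 pseudogene_stop_threshold = as.integer(pseudogene_stop_threshold),
                 require_both_domains_for_functional =
                   isTRUE(require_both_domains_for_functional)),
            class = "TriageConfig")
}

#' Triage one gene
#'
#' Rule order (each rule's trigger is recorded as a machine-readable reason):
#' \enumerate{
#'   \item \strong{pseudogene} if the translation carries internal stop
#'     codons at or above the threshold (\code{INTERNAL_STOP}) or the joined
#'     CDS is frameshifted (\code{FRAMESHIFT});
#'   \item \strong{excluded} if the protein is shorter than
#'     \code{min_report_length} (\code{SHORT_SEQ});
#'   \item \strong{partial} if shorter than \code{min_functional_length}
#'     (\code{SHORT_SEQ}) or, when both domains are required, fewer than two
#'     distinct domain profiles hit (\code{MISSING_DOMAIN});
#'   \item \strong{functional} otherwise (reasons empty).
#' }
#' The pseudogene test runs first, so a gene that is both truncated and
#' stop-disrupted is reported as a probable pseudogene.
#'
#' @param translation A \code{TranslationResult}.
#' @param domain_hits Character vector of distinct domain profile ids hit for
#'   this gene (e.g. \code{c("TPS_NTD", "TPS_CTD")}).
#' @param config A \code{TriageConfig}.
#' @param gene_id Optional identifier carried into the call.
#' @return A \code{TriageCall}: list with \code{gene_id}, \code{category} in
#'   \{functional, partial, pseudogene, excluded\}, \code{reasons} and
#'   \code{protein_length}.
#' @export
triage_gene <- function(translation, domain_hits = character(0),
                        config = triage_config(), gene_id = NULL) {
  len <- nchar(translation$protein)
  reasons <- character(0)
  if (translation$internal_stop_count >= config$pseudogene_stop_threshold)
    reasons <- c(reasons, "INTERNAL_STOP")
  if (isTRUE(translation$frameshift_flag))
    reasons <- c(reasons, "FRAMESHIFT")
  if (length(reasons)) {
    category <- "pseudogene"
  } else if (len < config$min_report_length) {
    category <- "excluded"
    reasons <- "SHORT_SEQ"
    if (config$require_both_domains_for_functional &&
        length(unique(domain_hits)) < 2L)
      reasons <- c(reasons, "MISSING_DOMAIN")
  } else {
    if (len < config$min_functional_length)
      reasons <- c(reasons, "SHORT_SEQ")
    if (config$require_both_domains_for_functional &&
        length(unique(domain_hits)) < 2L)
      reasons <- c(reasons, "MISSING_DOMAIN")
    category <- if (length(reasons)) "partial" else "functional"
  }
  structure(list(gene_id = gene_id, category = category, reasons = reasons,
                 protein_length = len),
            class = "TriageCall")
}

#' Summarize triage calls
#'
#' @param calls List of \code{TriageCall}s.
#' @return Named integer vector with counts for functional, partial,
#'   pseudogene, excluded, and the total.
#' @export
summarize_triage <- function(calls) {
  cats <- c("functional", "partial", "pseudogene", "excluded")
  got <- vapply(calls, function(x) x$category, character(1))
  counts <- vapply(cats, function(ct) sum(got == ct), integer(1))
  c(counts, total = length(got))
}
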