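#' Intron-exon class bands
#'
#' Two banding conventions are in circulation for classifying terpene
#' synthase genes by architecture. The canonical bands put class I at 12-14
#' introns (13-15 exons), class II at exactly 9 introns, and class III at 6
#' introns (7 exons). An extended convention, reflecting how surveyed TPS-a/b/g
#' genes with 5-7 introns and TPS-c/e/f genes with 9-14 introns are grouped in
#' practice, widens class III to 5-7 and class I to 9-14 introns (class II is
#' absorbed into class I there). Both are kept as explicit modes rather than
#' silently reconciled; the default is canonical.
#'
#' @param mode \code{"canonical"} or \code{"extended"}.
#' @return A \code{StructureBands} list with intron-count ranges per class.
#' @export
structure_bands <- function(mode = c("canonical", "extended")) {
  mode <- match.arg(mode)
  b <- if (mode == "canonical") {
    list(class_I = 12:14, class_II = 9L, class_III = 6L)
  } else {
    list(class_I = 9:14, class_II = integer(0), class_III = 5:7)
  }
  structure(c(list(mode = mode), b), class = "StructureBands")
}

#' Count introns and exons of a gene model
#'
#' @param model A \code{GeneModel} (see [gene_model()]).
#' @return Named integer vector \code{c(intron_count, exon_count)}.
#' @export
count_structure <- function(model) {
  n_exon <- nrow(model$exons)
  if (is.null(n_exon) || n_exon == 0)
    stop("gene model ", model$gene_id %||% "?", " has zero exons")
  c(intron_count = n_exon - 1L, exon_count = n_exon)
}

#' Assign the intron-exon structural class
#'
#' @param counts Output of [count_structure()], or an intron count.
#' @param bands A \code{StructureBands} object, or a mode name passed to
#'   [structure_bands()].
#' @param gene_id Optional identifier carried into the call.
#' @param subfamily Optional subfamily label ("a".."g"); used only to note
#'   possible intron gain when a TPS-a/b/g gene shows 7 introns.
#' @return A \code{StructureCall}: list with \code{gene_id},
#'   \code{intron_count}, \code{exon_count}, \code{structural_class} in
#'   \{I, II, III, atypical\} and a free-text \code{note} (non-empty whenever
#'   the class is atypical).
#' @examples
#' classify_structure(c(intron_count = 6, exon_count = 7))$structural_class
#' @export
classify_structure <- function(counts, bands = structure_bands("canonical"),
                               gene_id = NULL, subfamily = NULL) {
  if (is.character(bands)) bands <- structure_bands(bands)
  ic <- unname(counts[["intron_count"]] %||% counts[[1]])
  ec <- if (!is.null(names(counts)) && "exon_count" %in% names(counts))
    unname(counts[["exon_count"]]) else ic + 1L

  cls <- if (ic %in% bands$class_I) "I"
  else if (ic %in% bands$class_II) "II"
  else if (ic %in% bands$class_III) "III"
  else "atypical"

  note <- ""
  if (cls == "atypical") {
    note <- sprintf(paste0("intron count %d outside all %s class bands; ",
                           "possibly an incomplete gene model"),
                    ic, bands$mode)
  } else if (ic == 7L && !is.null(subfamily) && subfamily %in% c("a", "b", "g")) {
    note <- "seven introns in a TPS-a/b/g gene; possible insertion of a new intron"
  }

  structure(list(gene_id = gene_id, intron_count = ic, exon_count = ec,
                 structural_class = cls, note = note),
            class = "StructureCall")
}

#' Export a display track of alternating exon/intron rows
#'
#' Produces the row layout a gene-structure display server would draw:
#' alternating exon and intron features tiling the gene span with no gaps
#' or overlaps.
#'
#' @param model A \code{GeneModel}.
#' @return data.frame with columns \code{feature}, \code{start}, \code{end}.
#' @export
export_structure_track <- function(model) {
  ex <- model$exons
  n <- nrow(ex)
  if (n == 0) stop("gene model has zero exons")
  rows <- data.frame(feature = "exon", start = ex$start[1], end = ex$end[1],
                     stringsAsFactors = FALSE)
  if (n > 1) {
    for (i in 2:n) {
      rows <- rbind(rows,
        data.frame(feature = "intron", start = ex$end[i - 1] + 1L,
                   end = ex$start[i] - 1L, stringsAsFactors = FALSE),
        data.frame(feature = "exon", start = ex$start[i], end = ex$end[i],
                   stringsAsFactors = FALSE))
    }
  }
  rownames(rows) <- NULL
  rows
}
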