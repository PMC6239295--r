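# Catalogue integration: one row per gene unifying triage, motif, structure
# and phylogenetic calls, plus subfamily summaries and coarse product-class
# prediction, and the packaged reference catalogue fixtures.

PRODUCT_CLASS_MAP <- c(
  a = "sesquiterpene/diterpene",
  b = "monoterpene/isoprene",
  g = "acyclic monoterpene",
  c = "copalyl-diphosphate-related diterpene",
  e = "kaurene-type diterpene",
  f = "diterpene/other class I",
  unclassified = "unknown")

#' Coarse product class from a subfamily label
#'
#' TPS-a genes cluster with known angiosperm sesquiterpene and diterpene
#' synthases; TPS-b and TPS-g with monoterpene/isoprene synthases; TPS-c
#' holds the class II copalyl-diphosphate-related diterpene synthases; TPS-e
#' the kaurene-type and TPS-f other class I diterpene synthases.
#'
#' @param subfamily Label in \code{a,b,c,e,f,g} (optionally prefixed
#'   \code{TPS-} or \code{TPS}), or \code{"unclassified"}.
#' @return Product-class label.
#' @export
predict_product_class <- function(subfamily) {
  key <- sub("^TPS-?", "", subfamily)
  if (!key %in% names(PRODUCT_CLASS_MAP))
    stop("unknown subfamily label: ", subfamily)
  unname(PRODUCT_CLASS_MAP[key])
}

#' Integrate per-gene calls into catalogue rows
#'
#' Joins triage, motif, structure and subfamily calls by gene id into one
#' Table-2-style record per gene. Missing upstream calls yield explicit
#' \code{"unclassified"} / \code{NA} values, never silent drops; pseudogene
#' and partial rows are retained.
#'
#' @param triage_calls Named list of \code{TriageCall}s (names = gene ids).
#' @param motif_profiles Named list of \code{MotifProfile}s.
#' @param structure_calls Named list of \code{StructureCall}s.
#' @param subfamily_calls data.frame from [assign_subfamily()] (columns
#'   gene_id, subfamily), or \code{NULL}.
#' @return data.frame of \code{CatalogueRow}s.
#' @export
integrate_catalogue <- function(triage_calls, motif_profiles = list(),
                                structure_calls = list(),
                                subfamily_calls = NULL) {
  ids <- names(triage_calls)
  if (is.null(ids)) stop("triage_calls must be a named list")
  sub_of <- if (!is.null(subfamily_calls) && nrow(subfamily_calls))
    stats::setNames(subfamily_calls$subfamily, subfamily_calls$gene_id)
  else character(0)

  rows <- lapply(ids, function(g) {
    tr <- triage_calls[[g]]
    mp <- motif_profiles[[g]]
    st <- structure_calls[[g]]
    if (!is.null(mp$protein_id) && mp$protein_id != g)
      stop("gene-id mismatch: motif profile ", mp$protein_id,
           " joined to triage call ", g)
    present <- if (!is.null(mp)) mp$present else
      stats::setNames(rep(NA, 5),
                      c("RRX8W", "RXR", "DDXXD", "DXDD", "NSE_DTE"))
    subfam <- if (g %in% names(sub_of)) sub_of[[g]] else "unclassified"
    data.frame(
      gene_code = g,
      subfamily = subfam,
      protein_length = tr$protein_length,
      catalytic_class = if (!is.null(mp)) class_from_motifs(mp) else "unclassified",
      structural_class = st$structural_class %||% NA_character_,
      triage_category = tr$category,
      has_RRX8W = present[["RRX8W"]],
      has_RXR = present[["RXR"]],
      has_DDXXD = present[["DDXXD"]],
      has_DXDD = present[["DXDD"]],
      has_NSE_DTE = present[["NSE_DTE"]],
      product_class = if (subfam %in% c(names(PRODUCT_CLASS_MAP),
                                        paste0("TPS-", names(PRODUCT_CLASS_MAP))))
        predict_product_class(subfam) else "unknown",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a catalogue by subfamily
#'
#' Exact per-subfamily counts over the rows passing the triage-category
#' filter, in the column layout of a cross-species TPS family-size table
#' (a, b, c, e, f, the merged e/f, g, h, unclassified, total).
#'
#' @param rows data.frame of \code{CatalogueRow}s (needs \code{subfamily} and
#'   \code{triage_category} columns).
#' @param filter Triage category to count, or \code{NULL} for all rows.
#' @return One-row data.frame \code{SummaryRow}.
#' @export
summarize_catalogue <- function(rows, filter = "functional") {
  if (!is.null(filter))
    rows <- rows[rows$triage_category == filter, , drop = FALSE]
  key <- sub("^TPS-?", "", rows$subfamily)
  cnt <- function(x) sum(key == x)
  out <- data.frame(a = cnt("a"), b = cnt("b"), c = cnt("c"),
                    e = cnt("e"), f = cnt("f"), g = cnt("g"), h = cnt("h"),
                    e_f = cnt("e") + cnt("f"),
                    unclassified = sum(!key %in% c("a", "b", "c", "e", "f",
                                                   "g", "h")),
                    total = nrow(rows))
  out
}

#' Load the packaged reference catalogue fixtures
#'
#' Two plain-text fixtures transcribed from the published survey of the holy
#' basil genome: the 47-row functional-gene catalogue (gene code, subfamily,
#' protein length, plus the reported best-hit gi and organism, carried for
#' reference only) and the per-subfamily distribution of the 19 partial and
#' 15 probable-pseudogene calls.
#'
#' @return List with \code{catalogue} (47-row data.frame) and
#'   \code{triage_distribution} (category x subfamily counts).
#' @export
load_fixture_catalogue <- function() {
  cat_path <- system.file("extdata", "osatps_table2.tsv", package = "tpsminer",
                          mustWork = TRUE)
  dist_path <- system.file("extdata", "osatps_triage_distribution.tsv",
                           package = "tpsminer", mustWork = TRUE)
  catalogue <- utils::read.delim(cat_path, stringsAsFactors = FALSE)
  dist <- utils::read.delim(dist_path, stringsAsFactors = FALSE)
  if (nrow(catalogue) != 47L)
    stop("catalogue fixture corrupt: expected 47 rows, found ",
         nrow(catalogue))
  if (!all(c("gene_code", "subfamily", "protein_length") %in%
           names(catalogue)))
    stop("catalogue fixture corrupt: missing columns")
  if (sum(dist$count) != 34L)
    stop("triage distribution fixture corrupt: partial+pseudogene != 34")
  list(catalogue = catalogue, triage_distribution = dist)
}
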