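#' Canonical terpene-synthase motif patterns
#'
#' Terpene synthases carry a small set of short degenerate motifs that are
#' diagnostic of the family and of the catalytic mechanism: the tandem
#' arginines of RR(X)8W near the N terminus of many mono-/sesquiterpene
#' synthases, the RXR (canonically RDR) motif, the aspartate-rich DDXXD and
#' the NSE/DTE triad that chelate the divalent metal in class I enzymes, and
#' the DXDD motif of protonation-initiated (class II) enzymes.
#'
#' `compile_pattern()` turns a motif name into an explicit position-by-position
#' pattern: a list of allowed-residue sets, where a wildcard position allows
#' all 20 standard residues.
#'
#' Patterns:
#' \itemize{
#'   \item \code{RRX8W}: R, R, 8 wildcards, W (length 11).
#'   \item \code{RRX8W_MOD}: the "modified" form, (R/K), R, 8 wildcards, W.
#'   \item \code{RXR}: R, (D/H), (R/K/D/V/Q) (length 3); canonical RDR matches.
#'   \item \code{DDXXD}: D, D, 2 wildcards, D (length 5).
#'   \item \code{DXDD}: D, wildcard, D, (D/V) (length 4).
#'   \item \code{NSE_DTE}: the 11-position consensus
#'     (L/V/Y)(I/A/M/P/W/S/C)(N/D/G) D (L/I/V/M/K/Q) x (T/G/S) x x x (E/T).
#' }
#'
#' @param name Motif name, one of \code{"RRX8W"}, \code{"RXR"},
#'   \code{"DDXXD"}, \code{"DXDD"}, \code{"NSE_DTE"}, \code{"RRX8W_MOD"}.
#' @return A \code{MotifPattern}: list with \code{name}, \code{positions}
#'   (list of character vectors of allowed residues) and \code{length}.
#' @examples
#' compile_pattern("DXDD")$length     # 4
#' compile_pattern("NSE_DTE")$positions[[5]]
#' @export
compile_pattern <- function(name) {
  wild <- AA20
  positions <- switch(name,
    RRX8W = c(list("R", "R"), rep(list(wild), 8), list("W")),
    RRX8W_MOD = c(list(c("R", "K"), "R"), rep(list(wild), 8), list("W")),
    RXR = list("R", c("D", "H"), c("R", "K", "D", "V", "Q")),
    DDXXD = list("D", "D", wild, wild, "D"),
    DXDD = list("D", wild, "D", c("D", "V")),
    NSE_DTE = list(c("L", "V", "Y"),
                   c("I", "A", "M", "P", "W", "S", "C"),
                   c("N", "D", "G"),
                   "D",
                   c("L", "I", "V", "M", "K", "Q"),
                   wild,
                   c("T", "G", "S"),
                   wild, wild, wild,
                   c("E", "T")),
    stop("unknown motif name: ", name)
  )
  structure(list(name = name, positions = positions,
                 length = length(positions)),
            class = "MotifPattern")
}

#' The five canonical motif patterns
#'
#' @return Named list of \code{MotifPattern}s for RRX8W, RXR, DDXXD, DXDD
#'   and NSE_DTE.
#' @export
tps_motif_patterns <- function() {
  nm <- c("RRX8W", "RXR", "DDXXD", "DXDD", "NSE_DTE")
  stats::setNames(lapply(nm, compile_pattern), nm)
}

# All start offsets (1-based) at which `pattern` matches the residue vector.
# Vectorised: one logical sweep per pattern position.
pattern_match_starts <- function(chars, pattern) {
  n <- length(chars)
  L <- pattern$length
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1L)
  for (j in seq_len(L)) {
    ok <- ok & (chars[j:(n - L + j)] %in% pattern$positions[[j]])
  }
  which(ok)
}

# Analytic per-offset match probability under uniform residues.
pattern_match_probability <- function(pattern) {
  prod(vapply(pattern$positions, length, integer(1)) / 20)
}

#' Scan a protein for the canonical TPS motifs
#'
#' Every start offset is tested for every pattern, so multiple (and
#' overlapping) hits per motif are all reported. RR(X)8W hits are labelled
#' \code{exact} or \code{modified} (the (R/K)R...W variant that is not an
#' exact RR...W match). \code{spacing_ok} records the canonical arrangement
#' in which a DDXXD start lies 35 (by default within [25, 45]) residues
#' downstream of an RXR start; it is \code{NA} unless both motifs are present.
#'
#' @param protein Residue string (or character vector of single residues).
#' @param protein_id Optional identifier carried into the result.
#' @param patterns List of \code{MotifPattern}s; defaults to the five
#'   canonical TPS motifs.
#' @param spacing_window Integer window (offsets downstream of an RXR start)
#'   in which a DDXXD start counts as canonically spaced.
#' @param include_modified Also scan the modified RR(X)8W pattern.
#' @return A \code{MotifProfile}: list with \code{protein_id}, \code{hits}
#'   (data.frame motif/start/end/matched/form), \code{present} (named logical
#'   over the five motifs, exact matches only) and \code{spacing_ok}.
#' @examples
#' p <- scan_motifs("MRRSANYQPSLWDDIYD")
#' p$present[["RRX8W"]]
#' @export
scan_motifs <- function(protein, protein_id = NULL,
                        patterns = tps_motif_patterns(),
                        spacing_window = c(25L, 45L),
                        include_modified = TRUE) {
  stopifnot(length(protein) > 1 || nzchar(protein))
  chars <- if (length(protein) > 1) protein else split_chars(protein)
  rows <- list()
  for (pat in patterns) {
    st <- pattern_match_starts(chars, pat)
    if (length(st)) {
      rows[[pat$name]] <- data.frame(
        motif = pat$name, start = st, end = st + pat$length - 1L,
        matched = vapply(st, function(s)
          paste(chars[s:(s + pat$length - 1L)], collapse = ""), character(1)),
        form = "exact", stringsAsFactors = FALSE)
    }
  }
  if (include_modified && "RRX8W" %in% names(patterns)) {
    mod <- compile_pattern("RRX8W_MOD")
    st <- setdiff(pattern_match_starts(chars, mod),
                  rows[["RRX8W"]]$start %||% integer(0))
    if (length(st)) {
      rows[["RRX8W_MOD"]] <- data.frame(
        motif = "RRX8W", start = st, end = st + mod$length - 1L,
        matched = vapply(st, function(s)
          paste(chars[s:(s + mod$length - 1L)], collapse = ""), character(1)),
        form = "modified", stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif = character(0), start = integer(0), end = integer(0),
               matched = character(0), form = character(0),
               stringsAsFactors = FALSE)
  hits <- hits[order(hits$motif, hits$start), , drop = FALSE]
  rownames(hits) <- NULL

  present <- vapply(names(patterns), function(nm)
    any(hits$motif == nm & hits$form == "exact"), logical(1))

  spacing_ok <- NA
  rxr <- hits$start[hits$motif == "RXR" & hits$form == "exact"]
  ddx <- hits$start[hits$motif == "DDXXD" & hits$form == "exact"]
  if (length(rxr) && length(ddx)) {
    gaps <- outer(ddx, rxr, "-")
    spacing_ok <- any(gaps >= spacing_window[1] & gaps <= spacing_window[2])
  }

  structure(list(protein_id = protein_id, hits = hits, present = present,
                 spacing_ok = spacing_ok),
            class = "MotifProfile")
}

#' Catalytic class from a motif profile
#'
#' Class I terpene synthases ionize their prenyl-diphosphate substrate via
#' the DDXXD (plus NSE/DTE) metal-binding motifs; class II enzymes protonate
#' it via DXDD and lack DDXXD. Presence of both motifs is reported as
#' \code{ambiguous} (bifunctional-like); neither gives \code{unclassified}.
#'
#' @param profile A \code{MotifProfile} from [scan_motifs()].
#' @return One of \code{"I"}, \code{"II"}, \code{"ambiguous"},
#'   \code{"unclassified"}.
#' @export
class_from_motifs <- function(profile) {
  has_ddxxd <- isTRUE(profile$present[["DDXXD"]])
  has_dxdd <- isTRUE(profile$present[["DXDD"]])
  if (has_ddxxd && !has_dxdd) "I"
  else if (has_dxdd && !has_ddxxd) "II"
  else if (has_ddxxd && has_dxdd) "ambiguous"
  else "unclassified"
}
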