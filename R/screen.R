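# Candidate identification: position-specific scoring of proteins against
# N-/C-terminal TPS domain profiles, with empirical (decoy-based) e-values,
# plus an importer for externally produced HMMER3 domtblout tables.

#' Screening configuration
#'
#' @param e_value_threshold Significance cutoff; a hit is kept only if its
#'   e-value is strictly below this (default 1e-3).
#' @param decoy_count Number of residue-shuffled decoys behind each empirical
#'   p-value (default 9999; must be at least 999). The smallest attainable
#'   smoothed p is 1/(decoy_count+1).
#' @param require_domains \code{"any"} (default): one significant domain hit
#'   makes a candidate; \code{"both"}: hits to two distinct profiles required.
#' @param rng_seed Optional seed applied around each scan's decoy shuffling.
#' @return A \code{ScreenConfig}.
#' @export
screen_config <- function(e_value_threshold = 1e-3, decoy_count = 9999L,
                          require_domains = c("any", "both"),
                          rng_seed = NULL) {
  require_domains <- match.arg(require_domains)
  stopifnot(e_value_threshold > 0, decoy_count >= 999L)
  structure(list(e_value_threshold = e_value_threshold,
                 decoy_count = as.integer(decoy_count),
                 require_domains = require_domains,
                 rng_seed = rng_seed),
            class = "ScreenConfig")
}

#' Build a position-specific scoring profile from a seed alignment
#'
#' Per-column, per-residue log-odds scores in bits:
#' \deqn{s(j, r) = \log_2\frac{(c_{jr} + \kappa\, b_r)/(n_j + \kappa)}{b_r}}
#' where \eqn{c_{jr}} is the residue count in column \eqn{j}, \eqn{n_j} the
#' number of non-gap rows in that column, \eqn{\kappa} the pseudocount weight
#' and \eqn{b} the background frequencies. Majority-gap columns are dropped.
#' With pseudocount 0, residues unseen in a column score \code{-Inf}.
#'
#' @param seed_alignment Character vector of equal-length residue rows
#'   (gaps as \code{-}).
#' @param pseudocount Pseudocount weight \eqn{\kappa \ge 0}.
#' @param background Residue background frequencies in the canonical
#'   ACDEFGHIKLMNPQRSTVWY order; must be positive and sum to 1.
#' @param profile_id Identifier, e.g. \code{"TPS_NTD"} or \code{"TPS_CTD"}.
#' @return A \code{ProfileMatrix}: list with \code{profile_id}, \code{length},
#'   \code{scores} (length x 20 matrix, bits) and \code{background}.
#' @export
build_profile <- function(seed_alignment, pseudocount = 0,
                          background = rep(1 / 20, 20),
                          profile_id = "custom") {
  if (length(seed_alignment) < 2) stop("need at least 2 alignment rows")
  widths <- nchar(seed_alignment)
  if (length(unique(widths)) != 1) stop("alignment rows of unequal length")
  if (widths[1] == 0) stop("empty alignment")
  stopifnot(pseudocount >= 0, length(background) == 20,
            all(background > 0), abs(sum(background) - 1) < 1e-9)
  background <- stats::setNames(as.numeric(background), AA20)

  m <- do.call(rbind, lapply(seed_alignment, split_chars))
  is_gap <- m == "-" | m == "?" | m == "."
  keep <- colSums(is_gap) * 2L <= nrow(m)
  m <- m[, keep, drop = FALSE]
  is_gap <- is_gap[, keep, drop = FALSE]
  L <- ncol(m)
  if (L == 0) stop("no columns left after dropping majority-gap columns")

  scores <- matrix(NA_real_, nrow = L, ncol = 20,
                   dimnames = list(NULL, AA20))
  for (j in seq_len(L)) {
    col <- m[!is_gap[, j], j]
    n_eff <- length(col)
    counts <- vapply(AA20, function(r) sum(col == r), numeric(1))
    scores[j, ] <- log2((counts + pseudocount * background) /
                          (n_eff + pseudocount) / background)
  }
  structure(list(profile_id = profile_id, length = L, scores = scores,
                 background = background),
            class = "ProfileMatrix")
}

#' Consensus sequence of a profile (highest-scoring residue per column)
#' @param profile A \code{ProfileMatrix}.
#' @return Residue string of length \code{profile$length}.
#' @export
profile_consensus <- function(profile) {
  paste(AA20[apply(profile$scores, 1, which.max)], collapse = "")
}

# Scores matrix extended with a sentinel column for non-residue codes
# (gap, '*', 'X'), which can never contribute positively.
extended_scores <- function(profile) {
  cbind(profile$scores, `*` = rep(-Inf, profile$length))
}

#' Scan a protein against a profile
#'
#' The bit score is the maximum over all ungapped window placements of the
#' summed column scores. Significance is empirical: the protein is
#' residue-shuffled \code{decoy_count} times, each decoy is scored
#' identically, and the Laplace-smoothed p-value is
#' \eqn{p = (1 + \#\{decoys \ge score\})/(decoy\_count + 1)}. The reported
#' e-value is \eqn{p \times batch\_size}. Hits with e-value at or above the
#' threshold are dropped (strict \code{<} at the cutoff). Decoy evaluation
#' stops early once enough exceedances have accumulated to put the final
#' e-value above the cutoff.
#'
#' Note the resolution floor: the smallest attainable p is
#' 1/(decoy_count+1), so with the default 9999 decoys and batch_size 1 the
#' best possible e-value is 1e-4 - below the default cutoff, but a
#' batch-size multiplier larger than ~10 would push even perfect scores over
#' it. \code{batch_size} therefore defaults to 1 (per-protein e-values) and
#' the multiplier is opt-in.
#'
#' @param profile A \code{ProfileMatrix}.
#' @param protein Residue string.
#' @param config A \code{ScreenConfig}.
#' @param target_id Identifier recorded in the hit.
#' @param batch_size Multiplier turning the empirical p-value into an
#'   e-value across a screened batch.
#' @return One-row data.frame \code{DomainHit} (target_id, profile_id,
#'   bit_score, e_value, start, end), or \code{NULL} when no significant hit.
#' @export
scan_protein <- function(profile, protein, config = screen_config(),
                         target_id = NULL, batch_size = 1L) {
  chars <- split_chars(protein)
  if (length(chars) < profile$length) {
    message("skipping ", target_id %||% "<protein>",
            ": shorter than profile (", length(chars), " < ",
            profile$length, ")")
    return(NULL)
  }
  codes <- aa_code(chars)
  Sx <- extended_scores(profile)
  obs <- window_scores_max(codes, Sx)
  bit_score <- obs[1]
  start <- as.integer(obs[2])

  N <- config$decoy_count
  thr <- config$e_value_threshold
  stop_at <- max(1L, as.integer(ceiling(thr * (N + 1) / batch_size - 1)))
  cnt <- with_seed(config$rng_seed,
                   decoy_exceedance_count(codes, Sx, bit_score, N, stop_at))
  if (cnt[1] >= stop_at) return(NULL)
  p <- (1 + cnt[1]) / (N + 1)
  e_value <- p * batch_size
  if (e_value >= thr) return(NULL)
  data.frame(target_id = target_id %||% NA_character_,
             profile_id = profile$profile_id,
             bit_score = bit_score, e_value = e_value,
             start = start, end = start + profile$length - 1L,
             stringsAsFactors = FALSE)
}

#' Parse HMMER3 per-domain tabular output (domtblout)
#'
#' Extracts one \code{DomainHit} per record: target name (field 1), query
#' profile name (field 4), this-domain independent E-value (field 13), domain
#' bit score (field 14) and alignment coordinates on the target
#' (fields 18-19). Lines with fewer than 23 whitespace-separated fields are
#' collected in the \code{malformed} attribute, not silently dropped.
#'
#' @param x Path to a domtblout file, or a character vector of its lines.
#' @return data.frame of hits (target_id, profile_id, full_seq_e_value,
#'   e_value, bit_score, start, end) with attribute \code{malformed}.
#' @export
parse_domtblout <- function(x) {
  lines <- if (length(x) == 1 && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(lines)]
  records <- lines[!startsWith(lines, "#")]
  if (!length(records))
    stop("no parseable records in domtblout input (comment-only or empty)")
  fields <- strsplit(trimws(records), "\\s+")
  ok <- lengths(fields) >= 23L
  if (!any(ok))
    stop("no parseable records; first malformed line: ", records[1])
  good <- fields[ok]
  get <- function(i) vapply(good, `[[`, "", i)
  hits <- data.frame(
    target_id = get(1),
    profile_id = get(4),
    full_seq_e_value = as.numeric(get(7)),
    e_value = as.numeric(get(13)),
    bit_score = as.numeric(get(14)),
    start = as.integer(get(18)),
    end = as.integer(get(19)),
    stringsAsFactors = FALSE)
  attr(hits, "malformed") <- records[!ok]
  hits
}

#' Select candidate proteins from domain hits
#'
#' A protein is a candidate iff it has at least one
#' (\code{require_domains = "any"}) or at least two distinct-profile
#' (\code{"both"}) hits with e-value strictly below the threshold.
#'
#' @param hits data.frame of \code{DomainHit}s (from [scan_protein()] /
#'   [screen_proteins()] / [parse_domtblout()]).
#' @param config A \code{ScreenConfig}.
#' @return Sorted character vector of candidate protein identifiers.
#' @export
select_candidates <- function(hits, config = screen_config()) {
  if (is.null(hits) || nrow(hits) == 0) return(character(0))
  sig <- hits[hits$e_value < config$e_value_threshold, , drop = FALSE]
  if (nrow(sig) == 0) return(character(0))
  n_prof <- tapply(sig$profile_id, sig$target_id,
                   function(p) length(unique(p)))
  need <- if (config$require_domains == "both") 2L else 1L
  sort(names(n_prof)[n_prof >= need])
}

#' Screen a set of proteins against domain profiles
#'
#' @param proteins Named character vector of residue strings (or an
#'   \code{AAStringSet}).
#' @param profiles List of \code{ProfileMatrix} objects.
#' @param config A \code{ScreenConfig}.
#' @param batch_size Passed to [scan_protein()].
#' @return data.frame of significant \code{DomainHit}s (possibly 0 rows).
#' @export
screen_proteins <- function(proteins, profiles, config = screen_config(),
                            batch_size = 1L) {
  if (!is.character(proteins)) proteins <- as.character(proteins)
  out <- list()
  for (id in names(proteins)) {
    for (pf in profiles) {
      h <- scan_protein(pf, proteins[[id]], config, target_id = id,
                        batch_size = batch_size)
      if (!is.null(h)) out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out))
    return(data.frame(target_id = character(0), profile_id = character(0),
                      bit_score = numeric(0), e_value = numeric(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the N-/C-terminal TPS domain profiles from a labeled reference panel
#'
#' Reference panels produced by [simulate_dataset()] (and full-length TPS
#' proteins generally) carry an N-terminal and a C-terminal conserved domain
#' region. This helper stacks the corresponding 80-residue slices of the
#' panel proteins (positions 61-140 for the N-terminal domain; 381-460 on
#' ~560-aa mono-/sesquiterpene-synthase-like proteins or 451-530 on ~820-aa
#' diterpene-synthase-like proteins for the C-terminal domain) and builds a
#' scoring profile from each.
#'
#' @param panel Named character vector of full-length reference proteins.
#' @param pseudocount Pseudocount for [build_profile()].
#' @return List of two \code{ProfileMatrix} objects, \code{TPS_NTD} and
#'   \code{TPS_CTD}.
#' @export
reference_domain_profiles <- function(panel, pseudocount = 1) {
  if (!is.character(panel)) panel <- as.character(panel)
  ntd <- substr(panel, 61L, 140L)
  ctd <- ifelse(nchar(panel) >= 700L,
                substr(panel, 451L, 530L), substr(panel, 381L, 460L))
  list(TPS_NTD = build_profile(unname(ntd), pseudocount,
                               profile_id = "TPS_NTD"),
       TPS_CTD = build_profile(unname(ctd), pseudocount,
                               profile_id = "TPS_CTD"))
}
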