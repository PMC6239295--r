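# Synthetic TPS genome generator.
#
# Real TPS surveys start from an unreleased or freshly assembled genome; this
# module emulates one with known ground truth so that every downstream stage
# (screen, triage, motifs, structure, phylogeny, catalogue) is testable.
# Each subfamily gets a protein template with the motif complement the family
# shows (see make_subfamily_template); genes are reverse-translated, split
# into GT..AG-bounded introns per the structural class, and optionally
# disabled (premature stop / 1-nt frameshift) or truncated.

# Two 80-residue conserved "domain cores" shared by all synthetic TPS
# templates. They stand in for the cross-subfamily conservation of the
# N-terminal and C-terminal TPS domains that profile screening keys on.
# Both are synthetic constants, verified to contain no canonical motif match
# even when flanked by arbitrary residues.
NTD_CORE <- "IPGKQSYWEESDKDHADTFAEHIKNIQESNQFANRIPQSPDPEEHRMVPYNVDKMMDPNRHICCMLWGNCFHQIWCKKQN"
CTD_CORE <- "NVKVSEDNLAFTETHKVQFVEPYVIIRFAHFQAPHVHATYSSCRPLCPWCRCQHYSGDETKRWCMHPLTGMDGQFWWRMP"

# Fixed most-frequent-codon table for deterministic reverse translation.
REV_CODON <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
               G = "GGA", H = "CAT", I = "ATT", K = "AAG", L = "CTT",
               M = "ATG", N = "AAT", P = "CCA", Q = "CAA", R = "AGA",
               S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")

SUBFAMILIES <- c("a", "b", "c", "e", "f", "g")

# Template geometry per subfamily: total length, planted motif starts, and
# core placements. Lengths follow the observed catalogue ranges: ~560 aa for
# the a/b/g (mono-/sesquiterpene synthase-like) families, ~820 aa for the
# c/e/f (diterpene synthase-like) families.
template_layout <- function(subfamily) {
  if (!subfamily %in% SUBFAMILIES)
    stop("unknown subfamily label: ", subfamily)
  long <- subfamily %in% c("c", "e", "f")
  len <- if (long) 820L else 560L
  motifs <- switch(subfamily,
    a = c(RRX8W = 25L, RXR = 300L, DDXXD = 335L, NSE_DTE = 470L),
    b = c(RRX8W = 25L, RXR = 300L, DDXXD = 335L, NSE_DTE = 470L),
    g = c(RXR = 300L, DDXXD = 335L, NSE_DTE = 470L),
    c = c(DXDD = 350L),
    e = c(DDXXD = 400L, NSE_DTE = 600L),
    f = c(DDXXD = 400L, NSE_DTE = 600L))
  list(length = len, motif_starts = motifs,
       ntd_core = c(61L, 140L),
       ctd_core = if (long) c(451L, 530L) else c(381L, 460L))
}

motif_span_table <- function(motif_starts) {
  if (!length(motif_starts))
    return(data.frame(motif = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  lens <- vapply(names(motif_starts),
                 function(nm) compile_pattern(nm)$length, integer(1))
  data.frame(motif = names(motif_starts), start = unname(motif_starts),
             end = unname(motif_starts) + lens - 1L, stringsAsFactors = FALSE)
}

span_idx <- function(spans) {
  if (!nrow(spans)) return(integer(0))
  unlist(mapply(seq, spans$start, spans$end, SIMPLIFY = FALSE),
         use.names = FALSE)
}

# Positions of a planted motif instance that are actually constrained
# (allowed set smaller than the 20 residues).
constrained_idx <- function(spans) {
  if (!nrow(spans)) return(integer(0))
  out <- integer(0)
  for (i in seq_len(nrow(spans))) {
    pat <- compile_pattern(spans$motif[i])
    hard <- which(vapply(pat$positions, length, integer(1)) < 20L)
    out <- c(out, spans$start[i] + hard - 1L)
  }
  out
}

# Redraw residues until no *non-planted* canonical motif matches anywhere.
# Positions in `protected_idx` are never redrawn.
scrub_spurious_motifs <- function(chars, planted, protected_idx,
                                  max_iter = 100L) {
  check <- lapply(setdiff(c("RRX8W", "RXR", "DDXXD", "DXDD", "NSE_DTE"),
                          planted), compile_pattern)
  if (!length(check)) return(chars)
  for (iter in seq_len(max_iter)) {
    bad <- integer(0)
    for (pat in check) {
      st <- pattern_match_starts(chars, pat)
      if (length(st))
        bad <- c(bad, unlist(lapply(st, function(s) s:(s + pat$length - 1L))))
    }
    if (!length(bad)) return(chars)
    redraw <- setdiff(unique(bad), protected_idx)
    if (!length(redraw))
      stop("spurious motif match entirely within protected positions")
    chars[redraw] <- sample(AA20, length(redraw), replace = TRUE)
  }
  stop("motif scrubbing did not converge")
}

# Draw one residue per pattern position from its allowed set.
draw_motif_instance <- function(name) {
  pat <- compile_pattern(name)
  vapply(pat$positions, function(s) s[sample.int(length(s), 1L)], character(1))
}

#' Build a subfamily protein template
#'
#' Templates carry the motif complement characteristic of each subfamily:
#' a/b get RR(X)8W + RXR + DDXXD + NSE/DTE; g gets the same minus RR(X)8W;
#' e/f get DDXXD + NSE/DTE; c (the class II family) gets DXDD only and no
#' DDXXD. Where both RXR and DDXXD are planted, the DDXXD start sits exactly
#' 35 residues downstream of the RXR start. All templates additionally share
#' two fixed 80-residue domain cores (N-terminal and C-terminal) emulating
#' the cross-subfamily conservation that domain-profile screening detects.
#' Filler positions are uniform-random residues, re-drawn wherever they would
#' create a chance match to a motif that was not planted.
#'
#' @param subfamily One of \code{"a","b","c","e","f","g"}.
#' @param seed Optional integer; when given, the template is generated under
#'   a temporary RNG seed (identical calls yield identical templates).
#' @return A \code{TPSTemplate}: list with \code{subfamily}, \code{sequence},
#'   \code{length}, \code{motif_spans}, \code{planted_motifs},
#'   \code{ntd_core}, \code{ctd_core}.
#' @export
make_subfamily_template <- function(subfamily, seed = NULL) {
  layout <- template_layout(subfamily)
  with_seed(seed, {
    # decorrelate subfamilies generated under the same seed: each label
    # starts at a different offset of the seeded stream
    invisible(stats::runif(1009L * match(subfamily, SUBFAMILIES)))
    chars <- sample(AA20, layout$length, replace = TRUE)
    spans <- motif_span_table(layout$motif_starts)
    for (i in seq_len(nrow(spans))) {
      inst <- draw_motif_instance(spans$motif[i])
      chars[spans$start[i]:spans$end[i]] <- inst
    }
    chars[layout$ntd_core[1]:layout$ntd_core[2]] <- split_chars(NTD_CORE)
    chars[layout$ctd_core[1]:layout$ctd_core[2]] <- split_chars(CTD_CORE)
    protected <- c(seq(layout$ntd_core[1], layout$ntd_core[2]),
                   seq(layout$ctd_core[1], layout$ctd_core[2]),
                   constrained_idx(spans))
    chars <- scrub_spurious_motifs(chars, spans$motif, protected)
    structure(list(subfamily = subfamily,
                   sequence = paste(chars, collapse = ""),
                   length = layout$length,
                   motif_spans = spans,
                   planted_motifs = spans$motif,
                   ntd_core = layout$ntd_core,
                   ctd_core = layout$ctd_core),
              class = "TPSTemplate")
  })
}

#' Derive a diverged gene copy from a subfamily template
#'
#' Substitutes each position outside the planted motif spans with probability
#' \code{rate} (drawing a different residue), then re-scrubs chance matches
#' to non-planted motifs. Motif spans are untouched, so planted-motif recall
#' and spacing are preserved by construction.
#'
#' @param template A \code{TPSTemplate}.
#' @param rate Per-site substitution probability.
#' @return A \code{TPSTemplate} with the diverged sequence.
#' @export
mutate_template <- function(template, rate) {
  chars <- split_chars(template$sequence)
  keep <- span_idx(template$motif_spans)
  mutable <- setdiff(seq_along(chars), keep)
  hit <- mutable[stats::runif(length(mutable)) < rate]
  if (length(hit)) {
    repl <- vapply(chars[hit],
                   function(ch) sample(setdiff(AA20, ch), 1L), character(1))
    chars[hit] <- repl
  }
  chars <- scrub_spurious_motifs(chars, template$planted_motifs, keep)
  template$sequence <- paste(chars, collapse = "")
  template
}

# Split a CDS into exons separated by GT..AG introns; returns the assembled
# gene sequence plus exon intervals in gene-local (sense) coordinates.
assemble_gene <- function(cds, intron_count, intron_length_range = c(60L, 200L),
                          min_exon = 20L) {
  ncds <- nchar(cds)
  k <- intron_count
  if (k == 0L) {
    return(list(sequence = cds,
                exons = data.frame(start = 1L, end = ncds)))
  }
  if (ncds < (k + 1L) * min_exon)
    stop("CDS too short (", ncds, " nt) for ", k + 1L, " exons")
  repeat {
    cuts <- sort(sample(seq(min_exon, ncds - min_exon), k))
    if (k == 1L || all(diff(cuts) >= min_exon)) break
  }
  bounds <- c(0L, cuts, ncds)
  pieces <- character(2L * k + 1L)
  exon_start <- integer(k + 1L)
  exon_end <- integer(k + 1L)
  pos <- 0L
  for (i in seq_len(k + 1L)) {
    ex <- substring(cds, bounds[i] + 1L, bounds[i + 1L])
    pieces[2L * i - 1L] <- ex
    exon_start[i] <- pos + 1L
    pos <- pos + nchar(ex)
    exon_end[i] <- pos
    if (i <= k) {
      ilen <- sample(seq(intron_length_range[1], intron_length_range[2]), 1L)
      intron <- paste0("GT",
                       paste(sample(c("A", "C", "G", "T"), ilen - 4L,
                                    replace = TRUE), collapse = ""),
                       "AG")
      pieces[2L * i] <- intron
      pos <- pos + ilen
    }
  }
  list(sequence = paste(pieces, collapse = ""),
       exons = data.frame(start = exon_start, end = exon_end))
}

#' Simulate one gene from a protein template
#'
#' Reverse-translates the template with a fixed most-frequent-codon table,
#' appends a terminal stop (except for truncated partial genes), and splits
#' the CDS into exons separated by GT..AG introns. The intron count follows
#' the structural class band (III: 6; II: 9; I: 12-14). Pseudogenes receive
#' either one in-frame internal stop codon or a single-base frameshift,
#' planted in the 45-75\% span of the CDS and outside planted motif spans;
#' partial genes are truncated to 150-280 residues, losing at least one
#' planted catalytic motif region; functional genes splice and translate back
#' to the template exactly.
#'
#' @param template A \code{TPSTemplate}.
#' @param category \code{"functional"}, \code{"partial"} or
#'   \code{"pseudogene"}.
#' @param structure_class \code{"I"}, \code{"II"} or \code{"III"}; defaults
#'   to III for subfamilies a/b/g and I for c/e/f.
#' @param strand \code{"+"} or \code{"-"} (recorded; coordinates are local).
#' @return List with \code{sequence} (gene nucleotides, sense orientation),
#'   \code{exons} (local intervals), \code{intron_count}, \code{strand},
#'   and the \code{TruthRecord} fields (\code{category}, \code{subfamily},
#'   \code{planted_motifs}, \code{protein_length}).
#' @export
simulate_gene <- function(template,
                          category = c("functional", "partial", "pseudogene"),
                          structure_class = NULL, strand = "+") {
  category <- match.arg(category)
  if (is.null(structure_class))
    structure_class <- if (template$subfamily %in% c("a", "b", "g")) "III" else "I"
  stopifnot(structure_class %in% c("I", "II", "III"))
  k <- switch(structure_class, III = 6L, II = 9L, I = sample(12:14, 1L))

  chars <- split_chars(template$sequence)
  spans <- template$motif_spans
  if (category == "partial") {
    tlen <- sample(150:280, 1L)
    chars <- chars[seq_len(tlen)]
    spans <- spans[spans$end <= tlen, , drop = FALSE]
    if (nrow(spans) == nrow(template$motif_spans))
      stop("partial truncation failed to remove a planted motif region")
  }
  n_res <- length(chars)
  codons <- unname(REV_CODON[chars])
  if (anyNA(codons)) stop("template contains a non-standard residue")
  if (category != "partial") codons <- c(codons, "TAA")

  if (category == "pseudogene") {
    lo <- ceiling(0.45 * n_res); hi <- floor(0.75 * n_res)
    in_motif <- span_idx(template$motif_spans)
    repeat {
      j <- sample(seq(lo, hi), 1L)
      if (!j %in% in_motif) break
    }
    if (sample(c(TRUE, FALSE), 1L)) {
      codons[j] <- "TAA"                      # premature in-frame stop
      cds <- paste(codons, collapse = "")
    } else {                                  # single-base frameshift
      cds <- paste(codons, collapse = "")
      del <- 3L * j
      cds <- paste0(substring(cds, 1L, del - 1L),
                    substring(cds, del + 1L, nchar(cds)))
    }
  } else {
    cds <- paste(codons, collapse = "")
  }

  g <- assemble_gene(cds, k)
  list(sequence = g$sequence, exons = g$exons, intron_count = k,
       strand = strand, category = category, subfamily = template$subfamily,
       planted_motifs = spans$motif, protein_length = n_res)
}

#' Simulation specification
#'
#' @param genes_per_subfamily Named counts over subfamilies a, b, c, e, f, g.
#' @param pseudogene_fraction,partial_fraction Per-subfamily fractions of the
#'   gene counts assigned those categories (deterministic rounding; their sum
#'   must not exceed 1; the remainder is functional).
#' @param background_gene_count Number of non-TPS decoy genes (random
#'   proteins, 300-700 aa, no planted motifs).
#' @param core_divergence Per-site substitution probability among genes of
#'   one subfamily.
#' @param between_subfamily_divergence Expected per-site divergence between
#'   subfamily templates; must exceed \code{core_divergence} (templates are
#'   drawn independently, giving ~0.95 at filler sites).
#' @param rng_seed Integer seed; identical seeds give byte-identical outputs.
#' @return A \code{SimulationSpec}.
#' @export
simulation_spec <- function(genes_per_subfamily = c(a = 18, b = 16, c = 5,
                                                    e = 2, f = 1, g = 5),
                            pseudogene_fraction = 0,
                            partial_fraction = 0,
                            background_gene_count = 0,
                            core_divergence = 0.10,
                            between_subfamily_divergence = 0.45,
                            rng_seed = 1L) {
  stopifnot(all(names(genes_per_subfamily) %in% SUBFAMILIES),
            all(genes_per_subfamily >= 0),
            pseudogene_fraction >= 0, partial_fraction >= 0,
            pseudogene_fraction + partial_fraction <= 1,
            background_gene_count >= 0,
            core_divergence >= 0, core_divergence <= 0.5,
            between_subfamily_divergence > core_divergence)
  counts <- stats::setNames(rep(0L, length(SUBFAMILIES)), SUBFAMILIES)
  counts[names(genes_per_subfamily)] <- as.integer(genes_per_subfamily)
  if (sum(counts) == 0) stop("zero TPS genes requested")
  structure(list(genes_per_subfamily = counts,
                 pseudogene_fraction = pseudogene_fraction,
                 partial_fraction = partial_fraction,
                 background_gene_count = as.integer(background_gene_count),
                 core_divergence = core_divergence,
                 between_subfamily_divergence = between_subfamily_divergence,
                 rng_seed = as.integer(rng_seed)),
            class = "SimulationSpec")
}

#' Per-subfamily category counts implied by a simulation spec
#'
#' @param spec A \code{SimulationSpec}.
#' @return data.frame with subfamily and the functional / partial /
#'   pseudogene counts the generator will emit.
#' @export
spec_category_counts <- function(spec) {
  n <- spec$genes_per_subfamily
  np <- round(spec$pseudogene_fraction * n)
  npart <- round(spec$partial_fraction * n)
  nf <- n - np - npart
  if (any(nf < 0)) stop("category fractions exceed subfamily counts")
  data.frame(subfamily = names(n), functional = as.integer(nf),
             partial = as.integer(npart), pseudogene = as.integer(np),
             stringsAsFactors = FALSE)
}

#' Simulate a full synthetic dataset
#'
#' Emits a genome FASTA (one scaffold per ~50 genes, 60-column wrap), a GFF3
#' of gene models, a labeled reference panel FASTA (3 functional exemplars
#' per subfamily, disjoint from the query genes, with
#' \code{subfamily=TPS-x} description tags) and a ground-truth TSV. Re-running
#' with the same seed is byte-identical.
#'
#' @param spec A \code{SimulationSpec}.
#' @param dir Output directory (created if absent).
#' @return List with file paths (\code{genome}, \code{gff3}, \code{panel},
#'   \code{truth}), the truth data.frame, the per-subfamily expected category
#'   counts, and the spec.
#' @export
simulate_dataset <- function(spec, dir = tempfile("tpsim")) {
  stopifnot(inherits(spec, "SimulationSpec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$rng_seed)

  expected <- spec_category_counts(spec)
  genes <- list()
  panel <- character(0)
  panel_desc <- character(0)

  for (sf in SUBFAMILIES) {
    n <- spec$genes_per_subfamily[[sf]]
    if (n == 0 && sf %in% SUBFAMILIES) {
      # panel still needs exemplars only for subfamilies present in queries
      next
    }
    template <- make_subfamily_template(sf)
    row <- expected[expected$subfamily == sf, ]
    cats <- sample(rep(c("functional", "partial", "pseudogene"),
                       c(row$functional, row$partial, row$pseudogene)))
    for (i in seq_len(n)) {
      derived <- mutate_template(template, spec$core_divergence)
      strand <- sample(c("+", "-"), 1L)
      genes[[length(genes) + 1L]] <-
        simulate_gene(derived, cats[i], strand = strand)
    }
    for (i in 1:3) {
      ref <- mutate_template(template, spec$core_divergence)
      id <- sprintf("REF_%s_%d", sf, i)
      panel[id] <- ref$sequence
      panel_desc[id] <- sprintf("%s subfamily=TPS-%s", id, sf)
    }
  }

  for (i in seq_len(spec$background_gene_count)) {
    len <- sample(300:700, 1L)
    chars <- sample(AA20, len, replace = TRUE)
    cds <- paste(c(unname(REV_CODON[chars]), "TAA"), collapse = "")
    g <- assemble_gene(cds, sample(0:3, 1L))
    genes[[length(genes) + 1L]] <-
      list(sequence = g$sequence, exons = g$exons,
           intron_count = nrow(g$exons) - 1L,
           strand = sample(c("+", "-"), 1L), category = "background",
           subfamily = "none", planted_motifs = character(0),
           protein_length = len)
  }

  # assign ids and place genes on scaffolds, ~50 per scaffold
  n_genes <- length(genes)
  ids <- character(n_genes)
  tps_i <- 0L; bg_i <- 0L
  for (i in seq_len(n_genes)) {
    if (genes[[i]]$category == "background") {
      bg_i <- bg_i + 1L; ids[i] <- sprintf("BG%04d", bg_i)
    } else {
      tps_i <- tps_i + 1L; ids[i] <- sprintf("SimTPS%03d", tps_i)
    }
  }
  order_idx <- sample(n_genes)   # mix TPS and decoys along the scaffolds

  scaffolds <- character(0)
  models <- list()
  truth <- vector("list", n_genes)
  cur_scaf <- 0L
  cur_seq <- NULL
  cur_pos <- 0L
  genes_on_scaf <- 0L
  flush <- function() {
    if (!is.null(cur_seq))
      scaffolds[sprintf("scaffold_%02d", cur_scaf)] <<-
        paste(cur_seq, collapse = "")
  }
  for (i in order_idx) {
    if (genes_on_scaf == 0L) {
      flush()
      cur_scaf <- cur_scaf + 1L
      cur_seq <- character(0)
      cur_pos <- 0L
    }
    g <- genes[[i]]
    spacer_len <- sample(200:500, 1L)
    spacer <- paste(sample(c("A", "C", "G", "T"), spacer_len, replace = TRUE),
                    collapse = "")
    G <- nchar(g$sequence)
    p <- cur_pos + spacer_len + 1L
    seg <- if (g$strand == "+") g$sequence else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(g$sequence)))
    cur_seq <- c(cur_seq, spacer, seg)
    cur_pos <- cur_pos + spacer_len + G
    ex <- g$exons
    glob <- if (g$strand == "+") {
      data.frame(start = p + ex$start - 1L, end = p + ex$end - 1L)
    } else {
      data.frame(start = p + G - ex$end, end = p + G - ex$start)
    }
    glob <- glob[order(glob$start), , drop = FALSE]
    models[[ids[i]]] <- gene_model(ids[i], sprintf("scaffold_%02d", cur_scaf),
                                   g$strand, glob)
    truth[[i]] <- data.frame(
      gene_id = ids[i], subfamily = g$subfamily, category = g$category,
      planted_motifs = paste(g$planted_motifs, collapse = ","),
      intron_count = g$intron_count, protein_length = g$protein_length,
      stringsAsFactors = FALSE)
    genes_on_scaf <- (genes_on_scaf + 1L) %% 50L
  }
  flush()

  truth <- do.call(rbind, truth)
  truth <- truth[order(truth$gene_id), , drop = FALSE]
  rownames(truth) <- NULL
  models <- models[order(names(models))]

  genome_path <- file.path(dir, "genome.fasta")
  gff_path <- file.path(dir, "genes.gff3")
  panel_path <- file.path(dir, "panel.faa")
  truth_path <- file.path(dir, "truth.tsv")
  write_fasta(scaffolds, genome_path, type = "DNA")
  write_gff3(models, gff_path)
  write_fasta(stats::setNames(unname(panel), unname(panel_desc)), panel_path,
              type = "AA")
  write_truth_table(truth, truth_path)

  list(dir = dir, genome = genome_path, gff3 = gff_path, panel = panel_path,
       truth_path = truth_path, truth = truth, expected = expected,
       spec = spec)
}
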