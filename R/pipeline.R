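#' Run the full TPS discovery pipeline
#'
#' Ties the stages together the way a genome-wide family survey proceeds:
#' gene models are spliced and translated; proteins are screened against the
#' N-/C-terminal TPS domain profiles built from the labeled reference panel;
#' candidates are triaged into functional / partial / probable pseudogene;
#' candidate proteins are profiled for the five canonical motifs and their
#' gene models classed by intron-exon architecture; putatively functional
#' proteins are placed on a bootstrapped neighbor-joining tree with the
#' reference panel and assigned subfamilies by clade membership; and all
#' calls are joined into the gene catalogue.
#'
#' @param genome_fasta Genome scaffolds (FASTA path).
#' @param gff3 Gene models (GFF3 path).
#' @param panel_fasta Labeled reference panel (FASTA path; description lines
#'   carry \code{subfamily=TPS-x} tags).
#' @param screen_cfg A \code{ScreenConfig}. The pipeline default trims the
#'   decoy count to 4999 (smallest attainable e-value 2e-4, still five-fold
#'   below the cutoff) to keep whole-genome runs fast.
#' @param triage_cfg A \code{TriageConfig}.
#' @param phylo_cfg A \code{PhyloConfig}. The pipeline default uses 100
#'   bootstrap replicates; raise to 1000 for publication-grade supports.
#' @param structure_mode \code{"canonical"} or \code{"extended"}.
#' @param verbose Log stage-boundary counts via \code{message()}.
#' @return List with \code{catalogue} (one row per screened candidate),
#'   \code{summary} (functional per-subfamily counts), \code{triage_counts},
#'   \code{hits}, \code{candidates}, \code{triage}, \code{motifs},
#'   \code{structure}, \code{tree}, \code{assignments}.
#' @export
run_tps_pipeline <- function(genome_fasta, gff3, panel_fasta,
                             screen_cfg = screen_config(decoy_count = 4999L),
                             triage_cfg = triage_config(),
                             phylo_cfg = phylo_config(bootstrap_replicates = 100L),
                             structure_mode = "canonical",
                             verbose = FALSE) {
  say <- function(...) if (verbose) message(...)

  scaffolds <- read_fasta_dna(genome_fasta)
  models <- read_gene_models(gff3)
  panel <- read_fasta_aa(panel_fasta)
  desc <- attr(panel, "desc")
  reference_labels <- stats::setNames(
    sub(".*subfamily=TPS-([a-h]).*", "\\1", desc), names(desc))
  say("loaded ", length(models), " gene models on ", length(scaffolds),
      " scaffolds; panel of ", length(panel), " references")

  translations <- translate_gene_models(scaffolds, models)
  proteins <- vapply(translations, function(t) t$protein, character(1))

  profiles <- reference_domain_profiles(panel)
  hits <- screen_proteins(proteins, profiles, screen_cfg)
  candidates <- select_candidates(hits, screen_cfg)
  say("screen: ", length(proteins), " proteins in, ", length(candidates),
      " candidates out")
  if (!length(candidates))
    stop("no candidate TPS genes passed the screen")

  triage_calls <- lapply(candidates, function(g) {
    prof_hit <- unique(hits$profile_id[hits$target_id == g])
    triage_gene(translations[[g]], prof_hit, triage_cfg, gene_id = g)
  })
  names(triage_calls) <- candidates
  triage_counts <- summarize_triage(triage_calls)
  say("triage: ", paste(names(triage_counts), triage_counts,
                        sep = "=", collapse = ", "))

  motif_profiles <- lapply(candidates, function(g)
    scan_motifs(proteins[[g]], protein_id = g))
  names(motif_profiles) <- candidates

  structure_calls <- lapply(candidates, function(g)
    classify_structure(count_structure(models[[g]]), structure_mode,
                       gene_id = g))
  names(structure_calls) <- candidates

  functional <- candidates[vapply(triage_calls, function(x)
    x$category == "functional", logical(1))]
  tree <- NULL
  assignments <- NULL
  if (length(functional) >= 1 && length(panel) + length(functional) >= 4) {
    seqs <- c(stats::setNames(as.character(panel), names(panel)),
              proteins[functional])
    alignment <- stack_alignment(seqs)
    tree <- bootstrap_support(alignment, phylo_cfg)
    assignments <- assign_subfamily(tree, reference_labels, functional,
                                    phylo_cfg)
    say("phylogeny: ", length(functional), " queries placed against ",
        length(panel), " references")
  }

  catalogue <- integrate_catalogue(triage_calls, motif_profiles,
                                   structure_calls, assignments)
  list(catalogue = catalogue,
       summary = summarize_catalogue(catalogue, "functional"),
       triage_counts = triage_counts,
       hits = hits, candidates = candidates, triage = triage_calls,
       motifs = motif_profiles, structure = structure_calls,
       tree = tree, assignments = assignments)
}
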