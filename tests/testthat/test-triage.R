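one_exon <- function(seq, strand = "+", id = "g1") {
  gene_model(id, "s1", strand, data.frame(start = 1L, end = nchar(seq)))
}

mk_translation <- function(len, stops = 0L, frameshift = FALSE) {
  structure(list(protein = strrep("A", len), internal_stop_count = stops,
                 frameshift_flag = frameshift, terminal_stop_flag = TRUE),
            class = "TranslationResult")
}

test_that("splicing and translation follow the standard code", {
  tr <- splice_and_translate("ATGGCCTAA", one_exon("ATGGCCTAA"))
  expect_equal(tr$protein, "MA")
  expect_equal(tr$internal_stop_count, 0L)
  expect_true(tr$terminal_stop_flag)
  expect_false(tr$frameshift_flag)

  tr <- splice_and_translate("ATGTAAGCCTGA", one_exon("ATGTAAGCCTGA"))
  expect_equal(tr$internal_stop_count, 1L)
  expect_true(grepl("\\*", tr$protein))

  tr <- splice_and_translate("ATGGCCGCCA", one_exon("ATGGCCGCCA"))
  expect_true(tr$frameshift_flag)   # 10 nt, not a multiple of 3

  # codons containing N translate to X and never count as stops
  tr <- splice_and_translate("ATGNNNTAA", one_exon("ATGNNNTAA"))
  expect_equal(tr$protein, "MX")
  expect_equal(tr$internal_stop_count, 0L)

  expect_error(
    splice_and_translate("ATG", gene_model("g", "s", "+",
                                           data.frame(start = 1, end = 9))),
    "out of scaffold bounds")
})

test_that("minus-strand models translate the reverse complement", {
  # reverse complement of ATGGCCTAA laid on the forward strand
  scaffold <- "TTAGGCCAT"
  tr <- splice_and_translate(scaffold, one_exon(scaffold, strand = "-"))
  expect_equal(tr$protein, "MA")
  expect_true(tr$terminal_stop_flag)
})

test_that("strand mirroring leaves translations invariant", {
  withr::with_seed(21, {
    tmpl <- make_subfamily_template("b")
    g <- simulate_gene(tmpl, "functional")
    pad <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                 collapse = "")
    scaffold <- paste0(pad, g$sequence, pad)
    ex <- data.frame(start = g$exons$start + 50L, end = g$exons$end + 50L)
    fwd <- splice_and_translate(scaffold, gene_model("g", "s", "+", ex))

    # mirror: reverse-complement the scaffold and flip all coordinates
    L <- nchar(scaffold)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(scaffold)))
    ex_rc <- data.frame(start = L - ex$end + 1L, end = L - ex$start + 1L)
    ex_rc <- ex_rc[order(ex_rc$start), ]
    rev <- splice_and_translate(rc, gene_model("g", "s", "-", ex_rc))
    expect_identical(fwd, rev)
    expect_equal(fwd$protein, tmpl$sequence)
  })
})

test_that("batch translation matches the per-gene path", {
  withr::with_seed(31, {
    spec <- simulation_spec(c(a = 2, b = 2, c = 1, e = 1, f = 1, g = 1),
                            pseudogene_fraction = 0.25,
                            background_gene_count = 3, rng_seed = 4)
    ds <- simulate_dataset(spec)
    scaffolds <- read_fasta_dna(ds$genome)
    models <- read_gene_models(ds$gff3)
    batch <- translate_gene_models(scaffolds, models)
    for (id in names(models)) {
      expect_identical(batch[[id]],
                       splice_and_translate(scaffolds[[models[[id]]$scaffold_id]],
                                            models[[id]]))
    }
  })
})

test_that("triage applies the curation rules in order", {
  cfg <- triage_config()
  both <- c("TPS_NTD", "TPS_CTD")

  # the shortest full-length catalogue entry (274 aa) stays functional
  call <- triage_gene(mk_translation(274), both, cfg)
  expect_equal(call$category, "functional")
  expect_length(call$reasons, 0)

  call <- triage_gene(mk_translation(540, stops = 2L), both, cfg)
  expect_equal(call$category, "pseudogene")
  expect_equal(call$reasons, "INTERNAL_STOP")

  call <- triage_gene(mk_translation(540, frameshift = TRUE), both, cfg)
  expect_equal(call$category, "pseudogene")
  expect_equal(call$reasons, "FRAMESHIFT")

  call <- triage_gene(mk_translation(90), character(0), cfg)
  expect_equal(call$category, "excluded")
  expect_true("SHORT_SEQ" %in% call$reasons)

  call <- triage_gene(mk_translation(200), both, cfg)
  expect_equal(call$category, "partial")
  expect_equal(call$reasons, "SHORT_SEQ")

  call <- triage_gene(mk_translation(400), "TPS_NTD", cfg)
  expect_equal(call$category, "partial")
  expect_equal(call$reasons, "MISSING_DOMAIN")

  # pseudogene test precedes the length rules
  call <- triage_gene(mk_translation(90, stops = 1L), character(0), cfg)
  expect_equal(call$category, "pseudogene")

  # single-domain proteins are functional when both domains are not required
  lax <- triage_config(require_both_domains_for_functional = FALSE)
  expect_equal(triage_gene(mk_translation(400), "TPS_NTD", lax)$category,
               "functional")
})

test_that("every gene receives exactly one category and summaries add up", {
  calls <- c(lapply(1:47, function(i) triage_gene(mk_translation(400),
                                                  c("TPS_NTD", "TPS_CTD"))),
             lapply(1:19, function(i) triage_gene(mk_translation(150),
                                                  c("TPS_NTD", "TPS_CTD"))),
             lapply(1:15, function(i) triage_gene(mk_translation(400, stops = 1L),
                                                  c("TPS_NTD", "TPS_CTD"))))
  s <- summarize_triage(calls)
  expect_equal(unname(s[c("functional", "partial", "pseudogene")]),
               c(47L, 19L, 15L))
  expect_equal(unname(s[["total"]]), 81L)
  expect_equal(sum(s[c("functional", "partial", "pseudogene", "excluded")]),
               s[["total"]])
  expect_equal(unname(summarize_triage(list())[["total"]]), 0L)
})
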