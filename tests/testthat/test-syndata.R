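planted_sets <- list(
  a = c("RRX8W", "RXR", "DDXXD", "NSE_DTE"),
  b = c("RRX8W", "RXR", "DDXXD", "NSE_DTE"),
  g = c("RXR", "DDXXD", "NSE_DTE"),
  c = "DXDD",
  e = c("DDXXD", "NSE_DTE"),
  f = c("DDXXD", "NSE_DTE"))

test_that("subfamily templates carry exactly the planted motif complement", {
  for (sf in names(planted_sets)) {
    tmpl <- make_subfamily_template(sf, seed = 3)
    prof <- scan_motifs(tmpl$sequence)
    expect_setequal(names(prof$present)[prof$present], planted_sets[[sf]])
    expect_equal(tmpl$length,
                 if (sf %in% c("c", "e", "f")) 820L else 560L)
    expect_equal(nchar(tmpl$sequence), tmpl$length)
    if (all(c("RXR", "DDXXD") %in% planted_sets[[sf]])) {
      expect_true(prof$spacing_ok)   # DDXXD planted 35 aa downstream of RXR
      rxr <- tmpl$motif_spans$start[tmpl$motif_spans$motif == "RXR"]
      ddx <- tmpl$motif_spans$start[tmpl$motif_spans$motif == "DDXXD"]
      expect_equal(ddx - rxr, 35L)
    }
  }
  expect_error(make_subfamily_template("z"), "unknown subfamily")
})

test_that("templates are deterministic under a fixed seed", {
  expect_identical(make_subfamily_template("b", seed = 1),
                   make_subfamily_template("b", seed = 1))
  expect_false(identical(make_subfamily_template("b", seed = 1)$sequence,
                         make_subfamily_template("b", seed = 2)$sequence))
})

test_that("independent subfamily templates diverge at filler sites", {
  ta <- make_subfamily_template("a", seed = 5)
  tg <- make_subfamily_template("g", seed = 5)
  ca <- strsplit(ta$sequence, "")[[1]]
  cg <- strsplit(tg$sequence, "")[[1]]
  shared <- c(seq(ta$ntd_core[1], ta$ntd_core[2]),
              seq(ta$ctd_core[1], ta$ctd_core[2]))
  filler <- setdiff(seq_len(560L), shared)
  expect_gte(mean(ca[filler] != cg[filler]), 0.45)
  expect_true(all(ca[shared] == cg[shared]))
})

test_that("mutated gene copies keep planted motifs and hit the target divergence", {
  withr::with_seed(13, {
    tmpl <- make_subfamily_template("b")
    div <- replicate(10, {
      mut <- mutate_template(tmpl, 0.10)
      prof <- scan_motifs(mut$sequence)
      expect_setequal(names(prof$present)[prof$present], planted_sets$b)
      mean(strsplit(mut$sequence, "")[[1]] != strsplit(tmpl$sequence, "")[[1]])
    })
    expect_gt(mean(div), 0.07)
    expect_lt(mean(div), 0.13)
  })
})

test_that("simulated genes have the class-band architecture and round-trip", {
  withr::with_seed(17, {
    tmpl <- make_subfamily_template("a")
    g <- simulate_gene(tmpl, "functional", structure_class = "III")
    expect_equal(nrow(g$exons), 7L)
    expect_equal(g$intron_count, 6L)
    tr <- splice_and_translate(
      g$sequence, gene_model("x", "s", "+", g$exons))
    expect_equal(tr$protein, tmpl$sequence)
    expect_true(tr$terminal_stop_flag)

    tc <- make_subfamily_template("c")
    g1 <- simulate_gene(tc, "functional", structure_class = "I")
    expect_true(g1$intron_count %in% 12:14)
    g2 <- simulate_gene(tc, "functional", structure_class = "II")
    expect_equal(g2$intron_count, 9L)

    # every intron starts GT and ends AG
    track <- g$exons
    for (i in seq_len(nrow(track) - 1)) {
      intron <- substring(g$sequence, track$end[i] + 1L,
                          track$start[i + 1L] - 1L)
      expect_match(intron, "^GT.*AG$")
      expect_gte(nchar(intron), 60L)
      expect_lte(nchar(intron), 200L)
    }

    # pseudogenes carry an internal stop or a frameshift
    for (i in 1:10) {
      gp <- simulate_gene(tmpl, "pseudogene")
      trp <- splice_and_translate(gp$sequence,
                                  gene_model("p", "s", "+", gp$exons))
      expect_true(trp$internal_stop_count >= 1L || trp$frameshift_flag)
    }

    # partials lose length and at least one planted motif region
    gq <- simulate_gene(tmpl, "partial")
    expect_lt(gq$protein_length, tmpl$length)
    expect_lt(length(gq$planted_motifs), nrow(tmpl$motif_spans))
  })
})

test_that("simulate_dataset emits the requested truth table", {
  spec <- simulation_spec(c(a = 18, b = 16, c = 5, e = 2, f = 1, g = 5),
                          pseudogene_fraction = 0, partial_fraction = 0,
                          rng_seed = 42)
  ds <- simulate_dataset(spec)
  expect_equal(sum(ds$truth$category == "functional"), 47L)
  expect_equal(nrow(ds$truth), 47L)

  all_pseudo <- simulate_dataset(
    simulation_spec(c(a = 2, b = 2), pseudogene_fraction = 1,
                    background_gene_count = 2, rng_seed = 9))
  tps <- all_pseudo$truth[all_pseudo$truth$category != "background", ]
  expect_true(all(tps$category == "pseudogene"))
  expect_true(all(
    all_pseudo$truth$subfamily[all_pseudo$truth$category == "background"] ==
      "none"))
})

test_that("identical seeds give byte-identical datasets", {
  spec <- simulation_spec(c(a = 3, b = 2, c = 1, e = 1, f = 1, g = 1),
                          pseudogene_fraction = 0.3, partial_fraction = 0.3,
                          background_gene_count = 5, rng_seed = 11)
  d1 <- simulate_dataset(spec)
  d2 <- simulate_dataset(spec)
  for (f in c("genome", "gff3", "panel", "truth_path")) {
    expect_identical(unname(tools::md5sum(d1[[f]])),
                     unname(tools::md5sum(d2[[f]])))
  }
})

test_that("emitted GFF3 round-trips: intron counts, splicing, planted motifs", {
  spec <- simulation_spec(c(a = 3, b = 3, c = 2, e = 1, f = 1, g = 2),
                          pseudogene_fraction = 0.2, partial_fraction = 0.2,
                          background_gene_count = 4, rng_seed = 23)
  ds <- simulate_dataset(spec)
  scaffolds <- read_fasta_dna(ds$genome)
  models <- read_gene_models(ds$gff3)
  truth <- ds$truth
  expect_setequal(names(models), truth$gene_id)

  for (i in seq_len(nrow(truth))) {
    m <- models[[truth$gene_id[i]]]
    expect_equal(nrow(m$exons) - 1L, truth$intron_count[i])
  }

  fun <- truth[truth$category == "functional", ]
  for (i in seq_len(nrow(fun))) {
    m <- models[[fun$gene_id[i]]]
    tr <- splice_and_translate(scaffolds[[m$scaffold_id]], m)
    expect_equal(nchar(tr$protein), fun$protein_length[i])
    expect_equal(tr$internal_stop_count, 0L)
    prof <- scan_motifs(tr$protein)
    planted <- strsplit(fun$planted_motifs[i], ",")[[1]]
    expect_setequal(names(prof$present)[prof$present], planted)
  }

  # reference panel: 3 labeled functional exemplars per subfamily, disjoint ids
  panel <- read_fasta_aa(ds$panel)
  desc <- attr(panel, "desc")
  labels <- sub(".*subfamily=TPS-", "", desc)
  expect_equal(unname(table(labels)[c("a", "b", "c", "e", "f", "g")]),
               rep(3L, 6L), ignore_attr = TRUE)
  expect_length(intersect(names(panel), truth$gene_id), 0)
})

test_that("invalid simulation specs are rejected", {
  expect_error(simulation_spec(c(a = 0, b = 0)), "zero TPS genes")
  expect_error(simulation_spec(pseudogene_fraction = 0.7,
                               partial_fraction = 0.7))
  expect_error(simulation_spec(between_subfamily_divergence = 0.05))
  expect_error(simulation_spec(c(q = 3)))
})
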