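test_that("p-distances use pairwise deletion", {
  al <- c(x = "ACDEF", y = "ACDEY")
  expect_equal(pairwise_p_distance(al)["x", "y"], 0.2)

  al <- c(x = "AC-EF", y = "ACD-F")
  expect_equal(pairwise_p_distance(al)["x", "y"], 0)   # sites 1,2,5 all equal

  al <- c(x = "ACDEF", y = "ACDEF", z = "AAAAA")
  d <- pairwise_p_distance(al)
  expect_equal(d["x", "y"], 0)
  expect_equal(unname(diag(d)), rep(0, 3))
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 1))

  expect_error(pairwise_p_distance(c(x = "A-", y = "-A")),
               "zero comparable sites for pair x, y")
})

test_that("neighbor joining recovers a known additive 4-taxon tree", {
  taxa <- c("A", "B", "C", "D")
  d <- matrix(c(0, .3, .5, .6,
                .3, 0, .6, .7,
                .5, .6, 0, .7,
                .6, .7, .7, 0), 4, 4, dimnames = list(taxa, taxa))
  tree <- neighbor_joining(d)
  expect_s3_class(tree, "phylo")
  # split AB|CD with branches A .1, B .2, C .3, D .4, internal .1
  expect_equal(phylo_keys(tree), paste(c("C", "D"), collapse = "\r"))
  expect_equal(sort(tree$edge.length), c(.1, .1, .2, .3, .4))
  ph <- stats::cophenetic(tree)[taxa, taxa]
  expect_equal(ph, d, tolerance = 1e-12)
})

test_that("three taxa resolve with the closed-form branch lengths", {
  taxa <- c("A", "B", "C")
  d <- matrix(c(0, .3, .5,
                .3, 0, .6,
                .5, .6, 0), 3, 3, dimnames = list(taxa, taxa))
  tree <- neighbor_joining(d)
  lens <- stats::setNames(tree$edge.length,
                          tree$tip.label[tree$edge[, 2]])
  expect_equal(lens[["A"]], 0.1)
  expect_equal(lens[["B"]], 0.2)
  expect_equal(lens[["C"]], 0.4)
  expect_error(neighbor_joining(d[1:2, 1:2]), "at least 3")
  asym <- d
  asym[1, 2] <- 0.9
  expect_error(neighbor_joining(asym), "asymmetric")
  expect_error(neighbor_joining(d[, 1:2]), "non-square")
})

test_that("NJ matches the exhaustive least-squares oracle on additive inputs", {
  withr::with_seed(41, {
    for (rep in 1:30) {
      n <- sample(4:6, 1)
      gen <- random_additive_matrix(n)
      tree <- neighbor_joining(gen$d)
      expect_equal(phylo_keys(tree), gen$keys)
      oracle <- oracle_best_tree(gen$d)
      expect_equal(phylo_keys(tree), oracle$keys)
      expect_lt(oracle$fit$rss, 1e-18)
      ph <- stats::cophenetic(tree)[rownames(gen$d), colnames(gen$d)]
      expect_lt(max(abs(ph - gen$d)), 1e-9)
    }
  })
})

test_that("NJ is invariant to taxon input order", {
  withr::with_seed(43, {
    gen <- random_additive_matrix(6)
    t1 <- neighbor_joining(gen$d)
    for (rep in 1:5) {
      perm <- sample(6)
      t2 <- neighbor_joining(gen$d[perm, perm])
      expect_equal(phylo_keys(t2), phylo_keys(t1))
      taxa <- rownames(gen$d)
      expect_equal(stats::cophenetic(t2)[taxa, taxa],
                   stats::cophenetic(t1)[taxa, taxa], tolerance = 1e-12)
    }
  })
})

test_that("NJ agrees with an independent implementation on additive matrices", {
  withr::with_seed(47, {
    for (rep in 1:5) {
      gen <- random_additive_matrix(6)
      ours <- neighbor_joining(gen$d)
      apes <- ape::nj(gen$d)
      expect_equal(phylo_keys(ours), phylo_keys(apes))
    }
  })
})

test_that("bootstrap supports: degenerate alignments give 100, seeds reproduce", {
  # identical rows within each pair: every column resample yields the same
  # distance matrix, so every bipartition recurs in all replicates
  al <- c(t1 = strrep("A", 40), t2 = strrep("A", 40),
          t3 = strrep("C", 40), t4 = strrep("C", 40),
          t5 = strrep("H", 40), t6 = strrep("H", 40))
  cfg <- phylo_config(bootstrap_replicates = 50, rng_seed = 2)
  tree <- bootstrap_support(al, cfg)
  sup <- attr(tree, "supports")
  expect_true(all(sup == 100L))

  t2 <- bootstrap_support(al, cfg)
  expect_identical(ape::write.tree(tree), ape::write.tree(t2))
  expect_identical(tree$node.label, t2$node.label)

  # and invariance to taxon input order under the same seed
  t3 <- bootstrap_support(al[c(4, 2, 6, 1, 3, 5)], cfg)
  expect_identical(sort(names(attr(t3, "supports"))),
                   sort(names(attr(tree, "supports"))))
  expect_identical(ape::write.tree(t3), ape::write.tree(tree))
})

test_that("subfamily assignment follows supported clades with fallback", {
  withr::with_seed(53, {
    panel <- list()
    for (sf in c("a", "b", "c")) {
      tmpl <- make_subfamily_template(sf)
      for (i in 1:3)
        panel[[sprintf("REF_%s_%d", sf, i)]] <-
          mutate_template(tmpl, 0.1)$sequence
      panel[[sprintf("Q_%s", sf)]] <- mutate_template(tmpl, 0.1)$sequence
    }
    al <- stack_alignment(unlist(panel))
    refs <- grep("^REF", names(al), value = TRUE)
    labels <- stats::setNames(sub("REF_([a-g])_.*", "\\1", refs), refs)
    queries <- grep("^Q", names(al), value = TRUE)
    cfg <- phylo_config(bootstrap_replicates = 100, rng_seed = 3)
    tree <- bootstrap_support(al, cfg)
    calls <- assign_subfamily(tree, labels, queries, cfg)
    expect_equal(stats::setNames(calls$subfamily, calls$gene_id),
                 c(Q_a = "a", Q_b = "b", Q_c = "c"))
    expect_true(all(calls$support >= 80))

    # with an unreachable support threshold every query falls back to the
    # nearest reference by patristic distance
    strict <- phylo_config(bootstrap_replicates = 100, rng_seed = 3,
                           support_threshold = 100)
    attr(tree, "supports")[] <- 50L
    fb <- assign_subfamily(tree, labels, queries, strict)
    expect_true(all(fb$note == "FALLBACK_NEAREST"))
    expect_equal(stats::setNames(fb$subfamily, fb$gene_id),
                 c(Q_a = "a", Q_b = "b", Q_c = "c"))

    expect_error(assign_subfamily(tree, c(NOPE = "a"), queries, cfg),
                 "no labeled reference")
  })
})
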