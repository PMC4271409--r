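test_that("mrp_matrix encodes clades with missing data and a root row", {
  m <- mrp_matrix(list(parse_newick("((A,B),C);")))
  expect_equal(ncol(m$chars), 1)
  expect_equal(unname(m$chars[c("A", "B", "C", "__MRP_ROOT__"), 1]),
               c("1", "1", "0", "0"))

  m2 <- mrp_matrix(list(parse_newick("((A,B),C);"), parse_newick("((B,C),D);")))
  expect_equal(ncol(m2$chars), 2)
  expect_equal(unname(m2$chars[c("B", "C", "D", "A"), 2]),
               c("1", "1", "0", "?"))
  expect_true(all(m2$chars["__MRP_ROOT__", ] == "0"))
  expect_equal(m2$provenance$tree, c("tree_1", "tree_2"))

  expect_warning(m3 <- mrp_matrix(list(parse_newick("(A,B);"))),
                 "fewer than 3 leaves")
  expect_equal(ncol(m3$chars), 0)
})

test_that("mrp_matrix is permutation-equivariant", {
  trees <- random_trees(6, 3, seed = 31)
  m <- mrp_matrix(trees)
  perm <- setNames(paste0("x", 1:6), sprintf("t%02d", 1:6))
  m2 <- mrp_matrix(rename_taxa(trees, perm))
  rows <- ifelse(m$taxa == "__MRP_ROOT__", m$taxa, unname(perm[m$taxa]))
  expect_identical(unname(m2$chars[rows, ]), unname(m$chars))
})

test_that("fitch_length matches spec examples", {
  t <- parse_newick("((A,B),(C,D));")
  expect_equal(fitch_length(t, c(A = "0", B = "0", C = "1", D = "1")), 1L)
  expect_equal(fitch_length(t, c(A = "1", B = "1", C = "1", D = "1")), 0L)
  expect_equal(fitch_length(t, c(A = "0", B = "?", C = "1", D = "1")), 1L)
  expect_equal(fitch_length(parse_newick("((A,C),(B,D));"),
                            c(A = "0", B = "0", C = "1", D = "1")), 2L)
})

test_that("fitch_length equals brute force on random instances", {
  set.seed(17)
  for (rep in 1:60) {
    n <- sample(4:6, 1)
    t <- random_trees(n, 1, seed = rep)[[1]]
    states <- sample(c("0", "1", "?"), n, replace = TRUE,
                     prob = c(0.4, 0.4, 0.2))
    chr <- setNames(states, tree_leaves(t))
    expect_equal(fitch_length(t, chr), oracle_fitch(t, chr))
  }
})

test_that("fitch scoring agrees between the R and C paths and phangorn", {
  set.seed(23)
  for (rep in 1:15) {
    n <- sample(5:9, 1)
    t <- random_trees(n, 1, seed = rep + 500)[[1]]
    taxa <- sort(tree_leaves(t))
    k <- sample(2:5, 1)
    chars <- matrix(sample(c("0", "1", "?"), n * k, replace = TRUE),
                    nrow = n, dimnames = list(taxa, NULL))
    r_scores <- sum(vapply(seq_len(k), function(j)
      fitch_length(t, chars[, j]), integer(1)))
    edges <- phyloforge:::phytree_to_edges(t, taxa)
    states <- apply(chars, 2, phyloforge:::state_mask)
    c_score <- phyloforge:::fitch_score_cpp(edges, length(taxa), states)
    expect_equal(c_score, r_scores)
    expect_equal(c_score, phangorn_score(t, chars))
  }
})

test_that("matrix_parsimony_score sums characters and checks taxa", {
  src <- parse_newick("((A,B),C);")
  m <- mrp_matrix(list(src))
  t <- parse_newick("(((A,B),C),__MRP_ROOT__);")
  expect_equal(matrix_parsimony_score(t, m), fitch_length(t, m$chars[, 1]))
  expect_error(matrix_parsimony_score(parse_newick("((A,B),C);"), m),
               "do not match")

  # a binary model tree scores one change per encoded clade on itself
  model <- random_trees(7, 1, seed = 77)[[1]]
  mm <- mrp_matrix(list(model))
  rooted <- parse_newick(sub(";", ",__MRP_ROOT__);",
                             sub("^", "(", write_newick(model))))
  expect_equal(matrix_parsimony_score(rooted, mm), ncol(mm$chars))
})

test_that("mp_search exhaustive mode finds all optimal topologies", {
  m <- mrp_matrix(list(parse_newick("((A,B),C);")))
  mp <- mp_search(m, search_config())
  expect_equal(attr(mp, "score"), 1L)
  expect_length(mp, 1)
  expect_true(set_key_of(mp[[1]]) ==
                set_key_of(parse_newick("((A,B),(C,__MRP_ROOT__));")))

  # zero characters: all three 4-taxon topologies tie at 0
  suppressWarnings(m0 <- mrp_matrix(list(parse_newick("(A,B);"),
                                         parse_newick("(C,D);"))))
  mp0 <- mp_search(m0, search_config())
  expect_equal(attr(mp0, "score"), 0L)
  expect_length(mp0, 15)  # 5 taxa incl. the synthetic outgroup
})

test_that("mp_search minimum equals the ape/phangorn enumeration oracle", {
  for (seed in 1:6) {
    trees <- random_trees(5, 2, seed = seed + 60, missing_frac = 0.2)
    m <- mrp_matrix(trees)
    mp <- mp_search(m, search_config())
    dat <- phangorn::phyDat(m$chars, type = "USER", levels = c("0", "1"),
                            ambiguity = "?")
    all_tops <- phangorn::allTrees(length(m$taxa), rooted = FALSE,
                                    tip.label = m$taxa)
    scores <- vapply(all_tops, phangorn::parsimony, numeric(1), data = dat)
    expect_equal(attr(mp, "score"), as.integer(min(scores)))
    expect_length(mp, sum(scores == min(scores)))
  }
})

test_that("heuristic search attains the exhaustive optimum on small matrices", {
  for (seed in 1:4) {
    trees <- random_trees(7, 3, seed = seed + 90, missing_frac = 0.2)
    m <- mrp_matrix(trees)
    exh <- mp_search(m, search_config(exhaustive_threshold = 10))
    heu <- mp_search(m, search_config(exhaustive_threshold = 4, starts = 25,
                                      seed = seed))
    expect_equal(attr(heu, "score"), attr(exh, "score"))
    # heuristic trees are a subset of the optimal set
    exh_keys <- vapply(exh, set_key_of, character(1))
    expect_true(all(vapply(heu, set_key_of, character(1)) %in% exh_keys))
  }
})

test_that("strict_consensus keeps exactly the shared structure", {
  t <- parse_newick("((A,B),(C,D));")
  expect_identical(topology_key(strict_consensus(list(t, t))), topology_key(t))

  star <- strict_consensus(list(t, parse_newick("((A,C),(B,D));")))
  expect_length(phyloforge:::split_keys(star), 0)
  expect_length(star$children, 4)

  cons <- strict_consensus(list(t, parse_newick("(((A,B),C),D);")))
  expect_identical(topology_key(cons), "((A,B),C,D)")

  expect_error(strict_consensus(list(t, parse_newick("((A,B),C);"))),
               "identical taxon sets")

  # output bipartitions equal the intersection of input bipartition sets
  for (seed in 1:6) {
    tt <- random_trees(8, 3, seed = seed + 20)
    cons <- strict_consensus(tt)
    expect_setequal(phyloforge:::split_keys(cons),
                    Reduce(intersect, lapply(tt, phyloforge:::split_keys)))
  }
})

test_that("mrp_supertree assembles compatible sources", {
  st <- mrp_supertree(list(parse_newick("((A,B),C);"),
                           parse_newick("((B,C),D);")))
  expect_identical(topology_key(st), topology_key(parse_newick("(((A,B),C),D);")))

  t <- parse_newick("((A,B),(C,D));")
  expect_identical(topology_key(mrp_supertree(list(t))), topology_key(t))
  expect_identical(topology_key(mrp_supertree(list(t, t))), topology_key(t))
})

test_that("supertree splits stay compatible with the model without coverage", {
  for (seed in 1:5) {
    model <- random_trees(8, 1, seed = seed + 200)[[1]]
    subs <- lapply(1:4, function(i)
      restrict_to_taxa(model, phyloforge:::with_seed(seed * 10 + i,
        sample(tree_leaves(model), 5))))
    st <- mrp_supertree(subs, search_config(exhaustive_threshold = 9))
    # every supertree split must be pairwise compatible with every model
    # split (by the splits equivalence theorem this means it could be added
    # to the model tree)
    for (b in bipartitions(st))
      expect_true(split_compatible_with_tree(b, model))
  }
})

test_that("matrix export formats read back consistently", {
  m <- mrp_matrix(random_trees(6, 2, seed = 44, missing_frac = 0.2))
  nex <- withr::local_tempfile(fileext = ".nex")
  phy <- withr::local_tempfile(fileext = ".phy")
  write_mrp_nexus(m, nex)
  write_mrp_phylip(m, phy)
  dat <- ape::read.nexus.data(nex)
  expect_setequal(names(dat), m$taxa)
  expect_equal(toupper(paste(dat[["__MRP_ROOT__"]], collapse = "")),
               paste(m$chars["__MRP_ROOT__", ], collapse = ""))
  lines <- readLines(phy)
  expect_equal(lines[1], sprintf("%d %d", length(m$taxa), ncol(m$chars)))
})
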