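test_that("p-distances match direct mismatch counts and the Poisson closed form", {
  set.seed(401)
  base <- rand_aa(120)
  mutate_at <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    at <- sample(length(v), k)
    for (i in at) v[i] <- setdiff(AA_LETTERS, v[i])[1]
    paste(v, collapse = "")
  }
  seqs <- c(a = base, b = mutate_at(base, 12), c = mutate_at(base, 30))
  d <- pdistance_matrix(seqs)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "b"], hamming_p(seqs[["a"]], seqs[["b"]]))
  expect_equal(d["a", "c"], hamming_p(seqs[["a"]], seqs[["c"]]))
  expect_equal(d, t(d))
  dp <- pdistance_matrix(seqs, correction = "poisson")
  expect_equal(dp["a", "b"], -log(1 - d["a", "b"]))
  expect_equal(apply_correction(0.1, "poisson"), -log(0.9))
})

test_that("identical sequences have zero distance", {
  s <- rand_aa(60)
  d <- pdistance_matrix(c(x = s, y = s, z = rand_aa(60)))
  expect_equal(d["x", "y"], 0)
})

test_that("NJ on three taxa reproduces the closed-form branch lengths", {
  d <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_build(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["A"]], (3 + 5 - 6) / 2)  # (dAB + dAC - dBC)/2
  expect_equal(bl[["B"]], (3 + 6 - 5) / 2)
  expect_equal(bl[["C"]], (5 + 6 - 3) / 2)
})

test_that("NJ recovers the split of an additive four-taxon matrix", {
  # tree ((A,B),(C,D)) with internal edge 2 and pendant edges 1,1,3,4
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- d["B", "A"] <- 2
  d["A", "C"] <- d["C", "A"] <- 6;  d["A", "D"] <- d["D", "A"] <- 7
  d["B", "C"] <- d["C", "B"] <- 6;  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  # four-point condition oracle: AB|CD iff dAB + dCD < dAC + dBD
  expect_lt(d["A", "B"] + d["C", "D"], d["A", "C"] + d["B", "D"])
  tr <- nj_build(d)
  pp <- ape::prop.part(ape::root(tr, "D", resolve.root = TRUE))
  sides <- lapply(pp, function(i) sort(attr(pp, "labels")[i]))
  expect_true(any(vapply(sides, identical, logical(1), y = c("A", "B"))))
})

test_that("NJ reconstructs random additive topologies (four-point property)", {
  set.seed(402)
  for (r in 1:10) {
    n <- sample(5:8, 1)
    true_tree <- ape::rtree(n, rooted = FALSE)
    true_tree$edge.length <- true_tree$edge.length + 0.1
    d <- ape::cophenetic.phylo(true_tree)
    d <- d[order(rownames(d)), order(colnames(d))]
    tr <- nj_build(d)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(true_tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("nj_build validates input", {
  d <- matrix(c(0, 1, 2, 1.5, 0, 1, 2, 1, 0), 3, 3)
  expect_error(nj_build(d), "symmetric")
})

test_that("duplicate sequences form a 100%-supported cherry", {
  set.seed(403)
  base <- rand_aa(80)
  seqs <- c(dup1 = base, dup2 = base,
            far1 = rand_aa(80), far2 = rand_aa(80), far3 = rand_aa(80))
  aln <- do.call(rbind, lapply(seqs, function(s) strsplit(s, "")[[1]]))
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 4)
  span <- cyrho:::clade_span(tr, c("dup1", "dup2"), min_support = 0)
  expect_setequal(span$tips, c("dup1", "dup2"))
  expect_equal(span$support, 100)
})

test_that("bootstrap is reproducible and invariant to leaf order", {
  spec <- default_spec()
  refs <- gen_scaffold_refs(spec, list(clade_template("CyR", "DTD", divergence = 0.05),
                                       clade_template("XeR", "DTA", divergence = 0.05)),
                            3, seed = 6)
  aln <- anchored_alignment(refs$sequences, names(refs$sequences)[1])
  t1 <- bootstrap_support(aln, 100, seed = 9)
  t2 <- bootstrap_support(aln, 100, seed = 9)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  perm <- aln[rev(rownames(aln)), , drop = FALSE]
  t3 <- bootstrap_support(perm, 100, seed = 9)
  expect_setequal(setdiff(t3$node.label, ""), setdiff(t1$node.label, ""))
})

test_that("well-separated synthetic clades are monophyletic with high support", {
  spec <- default_spec()
  tpl <- list(clade_template("CyR", "DTD", divergence = 0.05),
              clade_template("CyHR", "TSD", divergence = 0.5))
  for (s in 1:20) {
    refs <- gen_scaffold_refs(spec, tpl, 3, seed = s)
    aln <- anchored_alignment(refs$sequences, names(refs$sequences)[1])
    tr <- bootstrap_support(aln, 100, seed = s)
    for (cl in c("CyR", "CyHR")) {
      tips <- refs$truth$protein_id[refs$truth$clade_label == cl]
      span <- cyrho:::clade_span(tr, tips, min_support = 0)
      expect_setequal(span$tips, tips)
      expect_gte(span$support, 95)
    }
  }
})

test_that("clade assignment recovers planted labels and rejects controls", {
  spec <- default_spec()
  templates <- default_clade_templates()
  refs <- gen_scaffold_refs(spec, templates, 3, seed = 21)
  rc <- setNames(refs$truth$clade_label, refs$truth$protein_id)
  gs <- gen_genome_set(spec, templates, n_genomes = 5, genes_per_genome = 1,
                       decoys_per_genome = 1, seed = 22)
  prot <- unlist(unname(gs$proteomes))
  queries <- gs$truth$protein_id[gs$truth$is_rhodopsin]
  decoy <- gs$truth$protein_id[!gs$truth$is_rhodopsin][1]
  panel <- c(refs$sequences, prot[c(queries, decoy)])
  aln <- anchored_alignment(panel, names(rc)[1])
  tree <- bootstrap_support(aln, 100, seed = 23)
  d <- matrix_pdistance(aln, correction = "poisson")
  asg <- assign_clade(c(queries, decoy), rc, tree, d)
  got <- setNames(asg$clade_label, asg$query_id)
  want <- setNames(gs$truth$clade_label[gs$truth$is_rhodopsin], queries)
  expect_identical(got[queries], want)
  expect_identical(unname(got[decoy]), "unassigned")
})

test_that("a query equidistant to two clades is unassigned by the tie rule", {
  # symmetric constructed distances: Q exactly between both clades
  labs <- c("c1a", "c1b", "c2a", "c2b", "Q")
  d <- matrix(0.6, 5, 5, dimnames = list(labs, labs))
  diag(d) <- 0
  d["c1a", "c1b"] <- d["c1b", "c1a"] <- 0.1
  d["c2a", "c2b"] <- d["c2b", "c2a"] <- 0.1
  d["Q", c("c1a", "c1b", "c2a", "c2b")] <- 0.3
  d[c("c1a", "c1b", "c2a", "c2b"), "Q"] <- 0.3
  tr <- nj_build(d)
  rc <- c(c1a = "CyR", c1b = "CyR", c2a = "XeR", c2b = "XeR")
  asg <- assign_clade("Q", rc, tr, d)
  expect_identical(asg$clade_label, "unassigned")
})
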