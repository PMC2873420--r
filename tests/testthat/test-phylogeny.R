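test_that("the Poisson-corrected distance behaves as a premetric", {
  sch <- blosum()
  q <- seed_queries()[[1]]$sequence
  expect_equal(as.numeric(dbd_distance(q, q, sch)), 0)
  # p exactly 0.5 on an ungapped alignment: -ln(0.5)
  a <- strrep("WC", 20)
  b <- paste0(strrep("WA", 10), strrep("WC", 10)) # 10 of 40 columns differ
  expect_equal(as.numeric(dbd_distance(a, b, sch)), -log(1 - 0.25))
  set.seed(31)
  for (k in 1:30) {
    x <- paste(sample(rfxcilia:::AA20, 30, replace = TRUE), collapse = "")
    y <- paste(sample(rfxcilia:::AA20, 30, replace = TRUE), collapse = "")
    dxy <- as.numeric(dbd_distance(x, y, sch))
    expect_equal(dxy, as.numeric(dbd_distance(y, x, sch)))
    expect_gte(dxy, 0)
  }
})

test_that("saturated pairs are capped at the stated maximum and flagged", {
  sch <- blosum()
  d <- dbd_distance(strrep("W", 20), strrep("P", 20), sch)
  expect_equal(as.numeric(d), -log(1 - 0.95))
  expect_true(attr(d, "capped"))
})

test_that("three taxa solve the three-point equations exactly", {
  dm <- matrix(c(0, 5, 6, 5, 0, 7, 6, 7, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 1L)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 2, b = 3, c = 4))
  expect_error(nj_tree(dm[1:2, 1:2]), "at least 3")
})

test_that("NJ recovers additive trees exactly (topology and branch lengths)", {
  set.seed(99)
  for (k in 1:30) {
    n <- sample(4:10, 1)
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(x) runif(x, 0.05, 1.0))
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), est),
                 structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    Dhat <- ape::cophenetic.phylo(est)[rownames(D), colnames(D)]
    expect_lt(max(abs(Dhat - D)), 1e-9)
  }
})

test_that("NJ output is invariant to input label permutations", {
  set.seed(123)
  tr <- ape::rtree(8, rooted = FALSE, br = function(x) runif(x, 0.1, 1.0))
  D <- ape::cophenetic.phylo(tr)
  base <- nj_tree(D)
  for (k in 1:10) {
    perm <- sample(rownames(D))
    est <- nj_tree(D[perm, perm])
    expect_equal(ape::dist.topo(base, est), structure(0, names = "PH85"),
                 ignore_attr = TRUE)
    expect_equal(sum(est$edge.length), sum(base$edge.length), tolerance = 1e-9)
  }
})

test_that("NJ matches the independent ape implementation on a random matrix", {
  set.seed(55)
  n <- 7
  labs <- paste0("L", 1:n)
  # a noisy (non-additive) symmetric matrix: both implementations must agree
  # on topology because they implement the same agglomeration criterion
  tr0 <- ape::rtree(n, rooted = FALSE, br = function(x) runif(x, 0.1, 0.8))
  tr0$tip.label <- labs
  D <- ape::cophenetic.phylo(tr0)[labs, labs]
  noise <- matrix(runif(n * n, 0, 0.02), n, n)
  noise <- (noise + t(noise)) / 2
  diag(noise) <- 0
  D <- D + noise
  mine <- nj_tree(D)
  theirs <- ape::nj(as.dist(D))
  expect_equal(ape::dist.topo(mine, ape::unroot(theirs)),
               structure(0, names = "PH85"), ignore_attr = TRUE)
})

test_that("clade assignment follows tree proximity with honest ties", {
  # query attached next to a RFX1-3 reference
  txt <- "((r13a:0.1,(r13b:0.05,q1:0.001):0.05):0.3,(r46a:0.1,r46b:0.1):0.3);"
  tr <- ape::read.tree(text = txt)
  refs <- c(r13a = "RFX1-3", r13b = "RFX1-3", r46a = "RFX4-6", r46b = "RFX4-6")
  cl <- assign_clades(tr, refs)
  expect_equal(unname(cl["q1"]), "RFX1-3")
  # perfectly symmetric placement is an honest UNASSIGNED
  txt2 <- "((ra1:0.1,ra2:0.1):0.2,(rb1:0.1,rb2:0.1):0.2,q:0.05);"
  tr2 <- ape::read.tree(text = txt2)
  refs2 <- c(ra1 = "A", ra2 = "A", rb1 = "B", rb2 = "B")
  cl2 <- assign_clades(tr2, refs2)
  expect_equal(unname(cl2["q"]), "UNASSIGNED")
  expect_error(assign_clades(tr2, c(missing_leaf = "A", ra1 = "A")),
               "missing_leaf")
})

test_that("queries evolved inside reference groups are assigned to them", {
  sch <- blosum()
  refs <- synthetic_reference_dbds()
  correct <- 0L
  total <- 0L
  for (rep in 1:15) {
    qres <- rfxcilia:::with_seed(900 + rep, {
      picks <- sample(names(refs$seqs), 3)
      out <- character(0)
      for (i in seq_along(picks)) {
        src <- query_domain("src", refs$seqs[[picks[i]]],
                            synthetic_dbd_anchors())
        out[paste0("q", i)] <- evolve_domain(
          src, 0.2, TRUE, rng_seed = sample.int(2147483646L, 1L))
      }
      list(seqs = out,
           truth = setNames(unname(refs$groups[picks]),
                            paste0("q", seq_along(picks))))
    })
    dm <- distance_matrix(c(refs$seqs, qres$seqs), sch)
    tr <- nj_tree(dm)
    cl <- assign_clades(tr, refs$groups)
    for (nm in names(qres$seqs)) {
      total <- total + 1L
      if (cl[[nm]] == qres$truth[[nm]]) correct <- correct + 1L
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("trees serialize to Newick and read back unchanged", {
  dm <- matrix(c(0, 2, 4, 4, 2, 0, 4, 4, 4, 4, 0, 2, 4, 4, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(dm)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f)
  back <- ape::read.tree(f)
  expect_equal(ape::dist.topo(tr, back), structure(0, names = "PH85"),
               ignore_attr = TRUE)
  expect_equal(sort(back$tip.label), letters[1:4])
})
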