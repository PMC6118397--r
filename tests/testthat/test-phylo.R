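# Anchored alignment, complete deletion, distance models, neighbor-joining
# and bootstrap.

aligned_pair <- function(s34_a = 1L, s34_b = 3L) {
  tab <- default_table()
  recs <- list(
    rec("a", paste0("C", "AA", "C", strrep("A", 9), "C", strrep("A", s34_a),
                    "H", "AA", "H", "AA", "C", strrep("A", 4), "C", "AA", "C")),
    rec("b", paste0("C", "AA", "C", strrep("A", 9), "C", strrep("A", s34_b),
                    "H", "AA", "H", "AA", "C", strrep("A", 4), "C", "AA", "C"))
  )
  hits <- scan_fasta(recs, tab)
  list(aln = anchor_align(hits, recs), hits = hits, recs = recs)
}

test_that("identical domains align without gaps; unequal spacers are right-padded", {
  same <- aligned_pair(2L, 2L)
  expect_false(any(same$aln$matrix == "-"))
  expect_length(same$aln$ligand_columns, 8L)
  # spacer 3-4 lengths 1 vs 3: two gap columns in the shorter row's region
  mix <- aligned_pair(1L, 3L)
  expect_equal(sum(mix$aln$matrix[1, ] == "-"), 2L)
  expect_equal(sum(mix$aln$matrix[2, ] == "-"), 0L)
  # ligand columns are gap-free and carry the ligand residues
  for (cl in mix$aln$ligand_columns) {
    expect_true(all(mix$aln$matrix[, cl] %in% c("C", "H")))
  }
  # partial hits are refused
  ph <- mix$hits; ph$partial[1] <- TRUE
  expect_error(anchor_align(ph, mix$recs), "partial")
})

test_that("a mixed-type planted panel shares ligand columns with per-region maximal widths", {
  tab <- default_table()
  sim <- small_sim()
  hits <- scan_fasta(sim$records, tab)
  full <- hits[!hits$partial & hits$flags == "", ]
  aln <- anchor_align(full, sim$records)
  expect_equal(nrow(aln$matrix), nrow(full))
  pos <- as.matrix(full[paste0("L", 1:8)])
  reg_max <- apply(pos[, 2:8] - pos[, 1:7] - 1L, 2, max)
  expect_equal(ncol(aln$matrix), 8L + sum(reg_max))
  for (cl in aln$ligand_columns) expect_false(any(aln$matrix[, cl] == "-"))
})

test_that("complete deletion removes exactly the gapped columns", {
  mix <- aligned_pair(1L, 3L)$aln
  cd <- complete_deletion(mix)
  # independent recount: columns without any gap
  expect_equal(ncol(cd$matrix), sum(colSums(mix$matrix == "-") == 0L))
  expect_false(any(cd$matrix == "-"))
  # gapless alignment unchanged
  same <- aligned_pair(2L, 2L)$aln
  expect_identical(complete_deletion(same)$matrix, same$matrix)
  # degenerate case: everything gapped somewhere
  allgap <- structure(list(matrix = rbind(c("A", "-"), c("-", "C")),
                           row_ids = c("x", "y"),
                           ligand_columns = rep(NA_integer_, 8)),
                      class = "anchored_alignment")
  expect_error(complete_deletion(allgap), "degenerate")
})

test_that("distance models match their closed forms and order gamma >= poisson >= p", {
  rows <- rbind(strsplit("AAAAAAAAAA", "")[[1]],
                strsplit("AAAAAAAACC", "")[[1]])
  aln <- structure(list(matrix = rows, row_ids = c("r1", "r2"),
                        ligand_columns = rep(NA_integer_, 8)),
                   class = "anchored_alignment")
  expect_equal(aln_distances(aln, "p")$values[1, 2], 0.2)
  expect_equal(aln_distances(aln, "poisson")$values[1, 2], -log(0.8))
  expect_equal(aln_distances(aln, "gamma", alpha = 1)$values[1, 2],
               1 * ((1 - 0.2)^(-1) - 1))
  # identical rows -> zero
  aln0 <- aln; aln0$matrix <- rows[c(1, 1), ]
  expect_equal(aln_distances(aln0, "poisson")$values[1, 2], 0)
  # ordering property over a grid of mismatch fractions
  for (k in 1:9) {
    m <- rbind(rep("A", 10), c(rep("C", k), rep("A", 10 - k)))
    a <- structure(list(matrix = m, row_ids = c("x", "y"),
                        ligand_columns = rep(NA_integer_, 8)),
                   class = "anchored_alignment")
    p <- aln_distances(a, "p")$values[1, 2]
    po <- aln_distances(a, "poisson", max_distance = 100)$values[1, 2]
    ga <- aln_distances(a, "gamma", max_distance = 100)$values[1, 2]
    expect_gte(po, p); expect_gte(ga, po)
  }
  # saturated distances clamp with a warning
  sat <- aln; sat$matrix <- rbind(rep("A", 10), rep("C", 10))
  expect_warning(d <- aln_distances(sat, "poisson", max_distance = 5),
                 "clamped")
  expect_equal(d$values[1, 2], 5)
})

test_that("neighbor-joining recovers additive trees exactly", {
  # 3 taxa: closed-form three-point branch lengths
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- ring_nj(d3)
  expect_s3_class(t3, "phylo")
  expect_equal(sort(t3$edge.length), sort(c(1, 2, 3)))
  expect_error(ring_nj(d3[1:2, 1:2]), ">= 3 taxa")
  # random additive matrices from random topologies, 5-8 taxa
  set.seed(404)
  for (n in 5:8) {
    true <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(true)
    dm <- dm[order(rownames(dm)), order(colnames(dm))]
    fit <- ring_nj(dm)
    expect_equal(ape::dist.topo(ape::unroot(true), fit), 0,
                 ignore_attr = TRUE)
    # path lengths reproduce the input matrix
    back <- ape::cophenetic.phylo(fit)[rownames(dm), colnames(dm)]
    expect_equal(back, dm, tolerance = 1e-8)
  }
})

test_that("neighbor-joining matches the reference implementation on noisy matrices", {
  set.seed(405)
  for (k in 1:5) {
    n <- 7
    true <- ape::rtree(n)
    dm <- ape::cophenetic.phylo(true) + matrix(stats::runif(n * n, 0, 0.05), n)
    dm <- (dm + t(dm)) / 2
    diag(dm) <- 0
    mine <- ring_nj(dm)
    ref <- ape::nj(as.dist(dm))
    expect_equal(ape::dist.topo(mine, ref), 0, ignore_attr = TRUE)
  }
})

test_that("negative branch lengths are clamped with a warning", {
  # triangle violation: the three-point formula gives a negative branch
  d <- matrix(c(0, 1, 1, 1, 0, 3, 1, 3, 0), 3,
              dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(tr <- ring_nj(d), "clamped")
  expect_true(all(tr$edge.length >= 0))
})

test_that("two well-separated clades produce the separating bipartition with full support", {
  tab <- default_table()
  set.seed(55)
  domA <- make_ring_domain("RING-H2", tab)
  domB <- make_ring_domain("RING-HC", tab)
  star <- function(labels) {
    tr <- ape::stree(length(labels), tip.label = labels)
    tr$edge.length <- rep(1, nrow(tr$edge))
    tr
  }
  expect_error(evolve_on_tree(ape::stree(4), domA$fragment, rate = 0.1),
               "branch lengths")
  leavesA <- evolve_on_tree(star(paste0("A", 1:4)),
                            domA$fragment, domA$ligand_offsets,
                            rate = 0.15, seed = 56)
  leavesB <- evolve_on_tree(star(paste0("B", 1:4)),
                            domB$fragment, domB$ligand_offsets,
                            rate = 0.15, seed = 57)
  recs <- c(lapply(names(leavesA), function(n) rec(n, leavesA[[n]])),
            lapply(names(leavesB), function(n) rec(n, leavesB[[n]])))
  hits <- scan_fasta(recs, tab)
  expect_equal(nrow(hits), 8L)
  aln <- anchor_align(hits, recs)
  tree <- ring_nj(aln_distances(complete_deletion(aln), "p"))
  # the A/B bipartition must be present
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  found <- any(vapply(parts, function(p) {
    setequal(labs[p], paste0("A", 1:4)) || setequal(labs[p], paste0("B", 1:4))
  }, logical(1)))
  expect_true(found)
  # bootstrap: full support for the central split, deterministic per seed
  bs1 <- ring_bootstrap(aln, reps = 50, seed = 99)
  bs2 <- ring_bootstrap(aln, reps = 50, seed = 99)
  expect_identical(write_newick(bs1), write_newick(bs2))
  sup <- suppressWarnings(as.integer(bs1$node.label))
  expect_true(100 %in% sup)
  # reps = 1: supports are 0 or 100
  b1 <- ring_bootstrap(aln, reps = 1, seed = 7)
  s1 <- suppressWarnings(as.integer(b1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0L, 100L)))
  # row order does not change supports
  perm <- sample(length(recs))
  hits_p <- scan_fasta(recs[perm], tab)
  aln_p <- anchor_align(hits_p, recs[perm])
  bs3 <- ring_bootstrap(aln_p, reps = 50, seed = 99)
  expect_identical(sort(bs1$node.label), sort(bs3$node.label))
})

test_that("newick export round-trips through an independent parser and quotes metacharacters", {
  set.seed(66)
  for (k in 1:5) {
    true <- ape::rtree(6)
    dm <- ape::cophenetic.phylo(true)
    tr <- ring_nj(dm)
    txt <- write_newick(tr)
    expect_match(txt, ";$")
    back <- ape::read.tree(text = txt)
    expect_equal(ape::dist.topo(back, tr), 0, ignore_attr = TRUE)
    expect_equal(sort(back$edge.length), sort(tr$edge.length),
                 tolerance = 1e-8)
  }
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3,
               dimnames = list(c("sp;1", "B", "C"), c("sp;1", "B", "C")))
  txt <- write_newick(ring_nj(d3))
  expect_match(txt, "'sp;1'", fixed = TRUE)
  # the quoted label keeps the tree parseable (three leaves recovered)
  back <- ape::read.tree(text = txt)
  expect_equal(length(back$tip.label), 3L)
})
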