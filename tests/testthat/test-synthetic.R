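# The seeded generator: determinism, range compliance, recall/decoy
# properties, divergence calibration, tree evolution.

test_that("identical spec and seed give byte-identical output", {
  spec <- sim_spec(seed = 5, n_families = 2L, family_sizes = c(3L, 2L),
                   family_types = c("RING-H2", "RING-HC"),
                   lone_types = "RING-v", n_multi = 0L,
                   decoys_per_class = 1L)
  a <- make_proteome(spec)
  b <- make_proteome(spec)
  expect_identical(a$records, b$records)
  expect_identical(a$manifest, b$manifest)
  g1 <- make_gff3(data.frame(gene_id = "g", cds_introns = 2L,
                             utr5_intron = TRUE), seed = 4)
  g2 <- make_gff3(data.frame(gene_id = "g", cds_introns = 2L,
                             utr5_intron = TRUE), seed = 4)
  expect_identical(g1$gff, g2$gff)
})

test_that("drawn domains respect the spacer ranges of their type", {
  tab <- default_table()
  set.seed(61)
  s34 <- integer(); s45h2 <- integer(); s45v <- integer()
  for (k in 1:200) {
    d <- make_ring_domain("RING-H2", tab)
    s34 <- c(s34, d$ligand_offsets[4] - d$ligand_offsets[3] - 1L)
    s45h2 <- c(s45h2, d$ligand_offsets[5] - d$ligand_offsets[4] - 1L)
    v <- make_ring_domain("RING-v", tab)
    s45v <- c(s45v, v$ligand_offsets[5] - v$ligand_offsets[4] - 1L)
  }
  expect_true(all(s34 %in% 1:3))
  expect_true(all(s45h2 %in% 2:3))
  expect_true(all(s45v == 7L))  # degenerate range
  expect_setequal(unique(s34), 1:3)  # the whole range is exercised
})

test_that("every planted domain is detected with its exact type and positions; decoys yield none", {
  tab <- default_table()
  sim <- small_sim()
  hits <- scan_fasta(sim$records, tab)
  planted <- sim$manifest[!is.na(sim$manifest$domain_start), ]
  for (i in seq_len(nrow(planted))) {
    tr <- planted[i, ]
    lig <- as.integer(strsplit(tr$ligand_positions, ";")[[1]])
    match_row <- hits[hits$protein_id == tr$protein_id &
                      hits$L1 == lig[1], , drop = FALSE]
    expect_equal(nrow(match_row), 1L, info = tr$protein_id)
    expect_equal(match_row$ring_type, tr$ring_type, info = tr$protein_id)
    expect_equal(unlist(match_row[1, paste0("L", 1:8)], use.names = FALSE),
                 lig, info = tr$protein_id)
  }
  # recall is exactly 1
  expect_equal(sum(hits$flags == "" & !hits$partial), nrow(planted))
  # decoys: zero hits with extensions disabled
  strict <- scan_params(allow_extensions = FALSE)
  decoy_ids <- sim$manifest$protein_id[sim$manifest$role == "decoy"]
  drecs <- Filter(function(r) r$id %in% decoy_ids, sim$records)
  dhits <- scan_fasta(drecs, tab, strict)
  expect_equal(nrow(dhits), 0L)
})

test_that("decoy classes behave as designed under each scanner setting", {
  tab <- default_table()
  spec <- sim_spec(seed = 77)
  set.seed(77)
  dec <- make_decoys(c("spacer_out_of_range", "ligand_mutated",
                       "boundary_missing"), tab, spec, per_class = 2L)
  strict <- scan_params(allow_extensions = FALSE)
  for (i in seq_along(dec$records)) {
    r <- dec$records[[i]]
    cls <- dec$manifest$decoy_class[i]
    expect_equal(nrow(scan_protein(r, tab, strict)), 0L, info = r$id)
    if (cls == "ligand_mutated") {
      expect_equal(nrow(scan_protein(r, tab)), 0L, info = r$id)
    }
    if (cls == "boundary_missing") {
      expect_equal(nrow(scan_protein(r, tab)), 0L, info = r$id)
      ph <- scan_protein(r, tab, scan_params(allow_partial = TRUE))
      expect_equal(nrow(ph), 1L, info = r$id)
      expect_true(ph$partial)
    }
    if (cls == "spacer_out_of_range") {
      # one residue beyond the base range: only reachable via the flagged
      # extension allowance
      lax <- scan_protein(r, tab)
      if (nrow(lax)) expect_match(lax$flags, "extended_spacer",
                                  info = r$id)
    }
  }
})

test_that("family divergence calibrates pairwise identity to (1-d)^2 outside the domain", {
  tab <- default_table()
  spec <- sim_spec(seed = 303, divergence = 0.1)
  set.seed(303)
  fam <- make_family("famX", 6L, "RING-H2", tab, spec)
  dom <- fam$ancestor$domains[[1]]
  idx_out <- setdiff(seq_len(nchar(fam$records[[1]]$sequence)),
                     (dom$start + 1L):(dom$ligands[8] + 1L))
  chars <- lapply(fam$records, function(r) strsplit(r$sequence, "")[[1]])
  idents <- c()
  for (i in 1:5) for (j in (i + 1):6) {
    idents <- c(idents, mean(chars[[i]][idx_out] == chars[[j]][idx_out]))
  }
  # two independent mutants of one ancestor: expected identity ~ (1-d)^2
  # (slightly above: coincident substitutions to the same residue)
  expect_gt(mean(idents), 0.81 - 0.04)
  expect_lt(mean(idents), 0.81 + 0.05)
  # divergence 0: identical members
  set.seed(304)
  fam0 <- make_family("famZ", 3L, "RING-HC", tab,
                      sim_spec(seed = 304, divergence = 0))
  seqs <- vapply(fam0$records, `[[`, character(1), "sequence")
  expect_equal(length(unique(seqs)), 1L)
})

test_that("tree evolution respects rate zero, ligand protection, and path-length divergence", {
  tab <- default_table()
  set.seed(91)
  dom <- make_ring_domain("RING-H2", tab)
  tr <- ape::stree(4, tip.label = paste0("t", 1:4))
  tr$edge.length <- rep(0.4, nrow(tr$edge))
  frozen <- evolve_on_tree(tr, dom$fragment, dom$ligand_offsets,
                           rate = 0, seed = 1)
  expect_true(all(frozen == dom$fragment))
  leaves <- evolve_on_tree(tr, dom$fragment, dom$ligand_offsets,
                           rate = 0.5, seed = 2)
  # ligand sites never mutate
  for (s in leaves) {
    ch <- strsplit(s, "")[[1]]
    anc <- strsplit(dom$fragment, "")[[1]]
    expect_equal(ch[dom$ligand_offsets + 1L], anc[dom$ligand_offsets + 1L])
  }
  # star tree: pairwise p-distances statistically comparable
  p <- c()
  cs <- lapply(leaves, function(s) strsplit(s, "")[[1]])
  for (i in 1:3) for (j in (i + 1):4) {
    p <- c(p, mean(cs[[i]] != cs[[j]]))
  }
  expect_lt(max(p) - min(p), 0.45)
})

test_that("NJ on anchored alignments recovers the generating topology for most seeds", {
  tab <- default_table()
  true <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  ok <- 0
  n_runs <- 15
  for (s in seq_len(n_runs)) {
    set.seed(500 + s)
    dom <- make_ring_domain("RING-H2", tab)
    leaves <- evolve_on_tree(true, dom$fragment, dom$ligand_offsets,
                             rate = 0.15, seed = 600 + s)
    rows <- do.call(rbind, lapply(leaves, function(x) strsplit(x, "")[[1]]))
    aln <- structure(list(matrix = rows, row_ids = names(leaves),
                          ligand_columns = dom$ligand_offsets + 1L),
                     class = "anchored_alignment")
    fit <- suppressWarnings(ring_nj(aln_distances(aln, "poisson")))
    ok <- ok + (ape::dist.topo(fit, ape::unroot(true)) == 0)
  }
  expect_gte(ok / n_runs, 0.9)
})
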