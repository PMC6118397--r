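# Masking, similarity outside the RING domain, family clustering, naming,
# reference assignment and survey summaries.

test_that("masking replaces exactly the hit intervals", {
  tab <- default_table()
  r <- rec("p", paste0(strrep("M", 20), h2_demo_sequence(), strrep("K", 10)))
  h <- scan_protein(r, tab)
  m <- mask_ring(r, h)
  expect_equal(nchar(m$sequence), nchar(r$sequence))
  expect_equal(substr(m$sequence, 21, 50), strrep("X", 30))
  expect_equal(substr(m$sequence, 1, 20), strrep("M", 20))
  # no hits: unchanged
  expect_equal(mask_ring(rec("q", "MKLV"), ringcat:::empty_hits())$sequence,
               "MKLV")
  # out-of-bounds interval: consistency error
  bad <- h; bad$end <- nchar(r$sequence) + 5L
  expect_error(mask_ring(r, bad), "consistency error")
})

test_that("two-domain proteins get both intervals masked", {
  tab <- default_table()
  sim <- small_sim()
  multi_id <- sim$manifest$protein_id[sim$manifest$role == "multi"][1]
  r <- Filter(function(x) x$id == multi_id, sim$records)[[1]]
  h <- scan_protein(r, tab)
  m <- mask_ring(r, h)
  for (i in seq_len(nrow(h))) {
    expect_equal(substr(m$sequence, h$start[i] + 1L, h$end[i]),
                 strrep("X", h$end[i] - h$start[i]))
  }
})

test_that("normalized similarity is 1 for identical sequences and ignores masked regions", {
  set.seed(5)
  s <- random_protein(80)
  edges <- all_vs_all_similarity(c(a = s, b = s))
  expect_equal(edges$normalized_score, 1.0)
  # two sequences sharing ONLY the masked region: no edge
  dom <- strrep("X", 40)
  set.seed(6)
  pair <- c(u = paste0(random_protein(60), dom),
            v = paste0(random_protein(60), dom))
  expect_equal(nrow(all_vs_all_similarity(pair, threshold = 0.3)), 0L)
  # an all-masked sequence is excluded with a warning
  expect_warning(all_vs_all_similarity(c(w = strrep("X", 50), z = s)),
                 "all-masked")
})

test_that("single-linkage clustering forms connected components", {
  none <- all_vs_all_similarity(c(a = "MKLVWA"), threshold = 2)  # no pairs
  g0 <- cluster_families(none, c("a", "b", "c"))
  expect_length(g0, 3L)
  expect_true(all(vapply(g0, `[[`, character(1), "kind") == "lone"))
  chain <- data.frame(id_a = c("a", "b"), id_b = c("b", "c"),
                      score = c(1, 1), normalized_score = c(1, 1))
  g1 <- cluster_families(chain, c("a", "b", "c"))
  expect_length(g1, 1L)
  expect_setequal(g1[[1]]$member_ids, c("a", "b", "c"))
  expect_equal(g1[[1]]$kind, "family")
})

test_that("planted families are recovered exactly and named by size order", {
  skip_if_not_installed("mclust")
  tab <- default_table()
  sim <- small_sim()
  planted <- sim$manifest[sim$manifest$role %in% c("family", "lone"), ]
  recs <- Filter(function(r) r$id %in% planted$protein_id, sim$records)
  hits <- scan_fasta(recs, tab)
  ct <- build_catalog(recs, hits)
  tabdf <- catalog_table(ct)
  truth <- planted$family_id[match(tabdf$protein_id, planted$protein_id)]
  truth[is.na(truth)] <- paste0("lone_", tabdf$protein_id[is.na(truth)])
  ari <- mclust::adjustedRandIndex(truth, tabdf$group_code)
  expect_equal(ari, 1.0)
  # partition property
  expect_setequal(tabdf$protein_id, vapply(recs, `[[`, character(1), "id"))
  expect_equal(anyDuplicated(tabdf$protein_id), 0L)
  # naming: two RING-H2 families of sizes 8 and 6 -> FHH01 is the larger
  sizes <- table(tabdf$group_code)
  expect_gt(sizes[["FHH01"]], sizes[["FHH02"]])
  expect_true(all(grepl("^(FHH|FHC|Fv|FCC|LHH|LHC|Lv|LCC)\\d{2}$",
                        tabdf$group_code)))
})

test_that("clustering and naming are invariant to input order", {
  tab <- default_table()
  sim <- small_sim()
  recs <- Filter(function(r) !grepl("^decoy", r$id), sim$records)
  hits <- scan_fasta(recs, tab)
  ct1 <- catalog_table(build_catalog(recs, hits))
  set.seed(9)
  perm <- sample(length(recs))
  ct2 <- catalog_table(build_catalog(recs[perm], scan_fasta(recs[perm], tab)))
  ord <- function(d) { d <- d[order(d$protein_id), ]; rownames(d) <- NULL; d }
  expect_identical(ord(ct1), ord(ct2))
})

test_that("group naming applies the modal-type rule and rejects unmapped lone types", {
  hits <- bind_fake_hits <- data.frame(
    protein_id = c("a", "b", "c", "d"),
    ring_type = c("RING-H2", "RING-H2", "RING-HC", "RING-D"),
    stringsAsFactors = FALSE
  )
  groups <- list(list(kind = "family", member_ids = c("a", "b", "c")),
                 list(kind = "lone", member_ids = "d"))
  expect_error(name_groups(groups, hits), "naming error.*RING-D")
  groups <- list(list(kind = "family", member_ids = c("a", "b", "c")))
  ct <- name_groups(groups, hits)
  expect_equal(ct$groups[[1]]$code, "FHH01")  # majority H2 over one HC
  expect_equal(ct$groups[[1]]$dominant_ring_type, "RING-H2")
  # lone genes of the four mapped types
  lone <- name_groups(list(list(kind = "lone", member_ids = "c")), hits)
  expect_equal(lone$groups[[1]]$code, "LHC01")
  # aliases attach to codes
  ali <- name_groups(groups, hits, aliases = c(FHH01 = "ATL"))
  expect_equal(ali$groups[[1]]$alias, "ATL")
})

test_that("queries map to their source reference group; unrelated queries are novel", {
  tab <- default_table()
  sim <- small_sim()
  fam_ids <- sim$manifest$protein_id[sim$manifest$role == "family"]
  recs <- Filter(function(r) r$id %in% fam_ids, sim$records)
  hits <- scan_fasta(recs, tab)
  ref <- build_catalog(recs, hits)
  ref_tab <- catalog_table(ref)
  # identical query
  q <- recs[[1]]
  a <- assign_to_reference(list(rec("q1", q$sequence)), ref, recs)
  expect_equal(a$assigned_group,
               ref_tab$group_code[ref_tab$protein_id == q$id])
  expect_equal(a$normalized_score, 1.0)
  # unrelated random query
  set.seed(31)
  a2 <- assign_to_reference(list(rec("q2", random_protein(200))), ref, recs)
  expect_equal(a2$assigned_group, "novel")
  # a 20%-divergence derived second species assigns back correctly
  set.seed(32)
  queries <- lapply(recs[seq(1, length(recs), by = 3)], function(r) {
    chars <- ringcat:::mutate_seq(strsplit(r$sequence, "")[[1]], 0.2)
    rec(paste0(r$id, "_sp2"), paste(chars, collapse = ""))
  })
  a3 <- assign_to_reference(queries, ref, recs)
  truth <- ref_tab$group_code[match(sub("_sp2$", "", a3$protein_id),
                                    ref_tab$protein_id)]
  expect_gte(mean(a3$assigned_group == truth), 0.95)
  expect_error(assign_to_reference(list(q), ref, list()), "empty reference")
})

test_that("survey summaries have consistent margins", {
  tab <- default_table()
  sim <- small_sim()
  recs <- Filter(function(r) !grepl("^decoy", r$id), sim$records)
  hits <- scan_fasta(recs, tab)
  ct <- build_catalog(recs, hits, species_label = "spA")
  ct2 <- ct; ct2$species_label <- "spB"
  sv <- summarize_survey(list(ct, ct2))
  expect_equal(unname(sv$type_counts[, "total"]),
               rep(nrow(catalog_table(ct)), 2))
  expect_equal(sv$type_counts["spA", ], sv$type_counts["spB", ])
  expect_equal(unname(rowSums(sv$group_matrix)),
               unname(sv$type_counts[, "total"]))
  expect_true(all(sv$group_matrix >= 0))
})
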