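# Seeded synthetic proteomes with truth manifests. The generator inverts the
# scanner's constraints: ligand residues are drawn from the canonical sets,
# spacer lengths uniformly from the allowed ranges, spacer and flank residues
# from a background distribution. Every emitted protein is post-checked with
# the scanner and resampled if it accidentally contains any placement beyond
# the planted ones, so truth manifests stay unambiguous. Decoys violate
# exactly one constraint of exactly one type definition.

#' Simulation specification
#'
#' Defines the conditions of a synthetic proteome: family layout, divergence,
#' planted motifs, decoys, background. Defaults describe a small survey-like
#' panel dominated by RING-H2/RING-HC families (the two abundant types in
#' real repertoires), 10% within-family divergence, an ATL-like motif planted
#' directly upstream of the domain in the first two families, and two decoys
#' per class.
#'
#' @param seed RNG seed; identical spec + seed gives byte-identical output.
#' @param n_families Number of families.
#' @param family_sizes Integer vector (recycled) of members per family
#'   (each >= 2).
#' @param family_types RING type per family (recycled).
#' @param divergence Per-site substitution probability within families, in
#'   [0, 1).
#' @param motif_seq Planted motif sequence (exact residues), or `NULL`.
#' @param motif_families Indices of families that carry the motif.
#' @param motif_distance Signed offset from motif end to domain start
#'   (negative = upstream gap).
#' @param lone_types RING types of lone (singleton) genes.
#' @param decoy_classes Decoy classes to plant, from
#'   \{`spacer_out_of_range`, `ligand_mutated`, `boundary_missing`\}.
#' @param decoys_per_class Count per class.
#' @param n_multi Number of two-domain proteins (two RING-HC domains).
#' @param flank_n,flank_c Length ranges (min, max) for N- and C-terminal
#'   flanks.
#' @param background Residue sampling weights over the 20-letter alphabet
#'   (default uniform).
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(seed = 1L,
                     n_families = 6L,
                     family_sizes = c(8L, 6L, 5L, 4L, 4L, 3L),
                     family_types = c("RING-H2", "RING-H2", "RING-HC",
                                      "RING-HC", "RING-v", "RING-C2"),
                     divergence = 0.1,
                     motif_seq = "GSLDFVWELKAG",
                     motif_families = c(1L, 2L),
                     motif_distance = -10L,
                     lone_types = c("RING-H2", "RING-HC", "RING-v",
                                    "RING-C2"),
                     decoy_classes = c("spacer_out_of_range",
                                       "ligand_mutated", "boundary_missing"),
                     decoys_per_class = 2L,
                     n_multi = 1L,
                     flank_n = c(40L, 90L), flank_c = c(30L, 80L),
                     background = NULL) {
  stopifnot(divergence >= 0, divergence < 1)
  if (!is.null(motif_seq)) {
    stopifnot(nchar(motif_seq) >= 6L, nchar(motif_seq) <= 100L,
              motif_distance <= 0L)
  }
  structure(list(
    seed = as.integer(seed), n_families = as.integer(n_families),
    family_sizes = rep_len(as.integer(family_sizes), n_families),
    family_types = rep_len(family_types, n_families),
    divergence = divergence, motif_seq = motif_seq,
    motif_families = as.integer(motif_families),
    motif_distance = as.integer(motif_distance),
    lone_types = lone_types, decoy_classes = decoy_classes,
    decoys_per_class = as.integer(decoys_per_class),
    n_multi = as.integer(n_multi),
    flank_n = as.integer(flank_n), flank_c = as.integer(flank_c),
    background = background
  ), class = "sim_spec")
}

random_residues <- function(n, background = NULL) {
  if (n <= 0L) return(character(0))
  if (is.null(background)) {
    sample(AA20, n, replace = TRUE)
  } else {
    sample(AA20, n, replace = TRUE, prob = background)
  }
}

#' Draw one RING domain fragment
#'
#' Ligand residues are drawn from the canonical (allowed) sets, spacer
#' lengths uniformly from the allowed ranges (no extensions), spacer
#' residues from the background distribution.
#'
#' @param ring_type Type name present in `table`.
#' @param table A `ring_type_table`.
#' @param background Optional residue weights.
#' @return List `fragment` (string) and `ligand_offsets` (0-based positions
#'   of the 8 ligands within the fragment).
#' @export
make_ring_domain <- function(ring_type, table, background = NULL) {
  def <- table$defs[[ring_type]]
  if (is.null(def)) stop("unknown ring type: ", ring_type)
  chars <- character(0)
  offsets <- integer(8)
  for (i in 1:8) {
    offsets[i] <- length(chars)
    allowed <- slot_allowed(def, i)
    chars <- c(chars, if (length(allowed) == 1L) allowed
                      else sample(allowed, 1L))
    if (i < 8L) {
      sp <- def$spacers[[i]]
      len <- if (sp$max > sp$min) sample(sp$min:sp$max, 1L) else sp$min
      chars <- c(chars, random_residues(len, background))
    }
  }
  list(fragment = paste(chars, collapse = ""), ligand_offsets = offsets)
}

# assemble flanks + optional motif + one or more domains; resample until the
# scanner reports exactly the planted placements (unambiguous truth)
assemble_protein <- function(id, ring_types, table, spec,
                             motif_seq = NULL, motif_distance = 0L,
                             max_tries = 200L) {
  params <- scan_params()
  for (try in seq_len(max_tries)) {
    chars <- random_residues(sample(spec$flank_n[1]:spec$flank_n[2], 1L),
                             spec$background)
    if (!is.null(motif_seq) && length(ring_types)) {
      gap <- -motif_distance
      motif_start <- length(chars)
      chars <- c(chars, strsplit(motif_seq, "")[[1]],
                 random_residues(gap, spec$background))
    } else {
      motif_start <- NA_integer_
    }
    domains <- list()
    for (tp in ring_types) {
      dom <- make_ring_domain(tp, table, spec$background)
      domains[[length(domains) + 1L]] <- list(
        ring_type = tp, start = length(chars),
        ligands = dom$ligand_offsets + length(chars)
      )
      chars <- c(chars, strsplit(dom$fragment, "")[[1]])
      if (length(domains) < length(ring_types)) {
        chars <- c(chars, random_residues(sample(20:60, 1L), spec$background))
      }
    }
    chars <- c(chars, random_residues(sample(spec$flank_c[1]:spec$flank_c[2], 1L),
                                      spec$background))
    seq <- paste(chars, collapse = "")
    rec <- list(id = id, description = id, sequence = seq)
    hits <- scan_protein(rec, table, params)
    if (planted_match(hits, domains)) {
      return(list(record = rec, domains = domains,
                  motif_start = motif_start))
    }
  }
  stop("failed to assemble an unambiguous protein for ", id,
       " after ", max_tries, " tries")
}

planted_match <- function(hits, domains) {
  if (nrow(hits) != length(domains)) return(FALSE)
  if (!length(domains)) return(TRUE)
  hits <- hits[order(hits$start), , drop = FALSE]
  ord <- order(vapply(domains, `[[`, integer(1), "start"))
  domains <- domains[ord]
  for (i in seq_along(domains)) {
    d <- domains[[i]]
    if (hits$ring_type[i] != d$ring_type) return(FALSE)
    if (any(unlist(hits[i, paste0("L", 1:8)]) != d$ligands)) return(FALSE)
    if (nzchar(hits$flags[i]) || hits$partial[i]) return(FALSE)
  }
  TRUE
}

# mutate a sequence at the given per-site rate, protected positions exempt
mutate_seq <- function(chars, rate, protect = integer(0)) {
  hit <- which(stats::runif(length(chars)) < rate)
  hit <- setdiff(hit, protect)
  for (i in hit) {
    chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }
  chars
}

#' Generate one synthetic family
#'
#' One ancestral protein (background + RING domain + optional planted motif
#' at a fixed distance upstream of the domain), mutated independently per
#' member at the divergence rate; ligand positions and the motif core are
#' exempt from mutation. Members are post-checked with the scanner.
#'
#' @param family_id Family label used to derive member ids.
#' @param size Number of members (>= 2).
#' @param ring_type RING type of the family domain.
#' @param table A `ring_type_table`.
#' @param spec A `sim_spec` (divergence, flanks, background).
#' @param motif_seq,motif_distance Optional planted motif.
#' @return List `records`, `manifest` (data frame), `ancestor`.
#' @export
make_family <- function(family_id, size, ring_type, table, spec,
                        motif_seq = NULL, motif_distance = -10L) {
  stopifnot(size >= 2L)
  anc <- assemble_protein(paste0(family_id, "_anc"), ring_type, table, spec,
                          motif_seq = motif_seq,
                          motif_distance = motif_distance)
  anc_chars <- strsplit(anc$record$sequence, "")[[1]]
  protect <- anc$domains[[1]]$ligands + 1L
  if (!is.na(anc$motif_start) && !is.null(motif_seq)) {
    protect <- c(protect,
                 (anc$motif_start + 1L):(anc$motif_start + nchar(motif_seq)))
  }
  params <- scan_params()
  records <- vector("list", size)
  rows <- vector("list", size)
  for (m in seq_len(size)) {
    id <- sprintf("%s_m%02d", family_id, m)
    for (try in 1:200) {
      chars <- mutate_seq(anc_chars, spec$divergence, protect)
      rec <- list(id = id, description = id,
                  sequence = paste(chars, collapse = ""))
      hits <- scan_protein(rec, table, params)
      if (planted_match(hits, anc$domains)) break
      if (try == 200) stop("failed to mutate an unambiguous member for ", id)
    }
    records[[m]] <- rec
    d <- anc$domains[[1]]
    rows[[m]] <- data.frame(
      protein_id = id, role = "family", family_id = family_id,
      ring_type = ring_type, domain_index = 1L,
      domain_start = d$start,
      ligand_positions = paste(d$ligands, collapse = ";"),
      motif_name = if (is.null(motif_seq)) NA_character_ else "planted",
      motif_start = anc$motif_start,
      motif_distance = if (is.null(motif_seq)) NA_integer_
                       else spec$motif_distance,
      decoy_class = NA_character_, stringsAsFactors = FALSE
    )
  }
  list(records = records, manifest = do.call(rbind, rows), ancestor = anc)
}

#' Generate decoy proteins
#'
#' Each decoy violates exactly one constraint of exactly one type
#' definition: `spacer_out_of_range` (spacer 4-5 one residue beyond the base
#' maximum; undetectable with extensions disabled), `ligand_mutated` (ligand
#' 4 replaced by lysine, a non-tolerated residue; never detectable), or
#' `boundary_missing` (sequence ends before ligands 7-8 can be placed; only
#' a partial hit is possible). Decoys are post-checked to yield zero hits
#' under `scan_params(allow_extensions = FALSE)`.
#'
#' @param classes Decoy classes to generate.
#' @param table A `ring_type_table`.
#' @param spec A `sim_spec`.
#' @param per_class Count per class.
#' @return List `records` and `manifest`.
#' @export
make_decoys <- function(classes, table, spec, per_class = 2L) {
  classes <- match.arg(classes,
                       c("spacer_out_of_range", "ligand_mutated",
                         "boundary_missing"),
                       several.ok = TRUE)
  strict <- scan_params(allow_extensions = FALSE)
  records <- list()
  rows <- list()
  k <- 0L
  for (cls in classes) for (r in seq_len(per_class)) {
    k <- k + 1L
    id <- sprintf("decoy_%s_%02d", gsub("_", "", cls), r)
    tp <- sample(c("RING-H2", "RING-HC", "RING-v", "RING-C2"), 1L)
    def <- table$defs[[tp]]
    for (try in 1:200) {
      dom <- make_ring_domain(tp, table, spec$background)
      chars <- strsplit(dom$fragment, "")[[1]]
      lig <- dom$ligand_offsets + 1L  # 1-based within fragment
      if (cls == "spacer_out_of_range") {
        # insert one extra background residue into spacer 4-5
        at <- lig[4]
        chars <- append(chars, random_residues(1L, spec$background), after = at)
      } else if (cls == "ligand_mutated") {
        chars[lig[4]] <- "K"
      } else {
        # drop everything beyond ligand 6 + 3 residues: no room for 7-8
        chars <- chars[seq_len(min(length(chars), lig[6] + 3L))]
      }
      pre <- random_residues(sample(spec$flank_n[1]:spec$flank_n[2], 1L),
                             spec$background)
      post <- if (cls == "boundary_missing") character(0) else
        random_residues(sample(spec$flank_c[1]:spec$flank_c[2], 1L),
                        spec$background)
      seq <- paste(c(pre, chars, post), collapse = "")
      rec <- list(id = id, description = id, sequence = seq)
      if (nrow(scan_protein(rec, table, strict)) == 0L) break
      if (try == 200) stop("failed to build decoy ", id)
    }
    records[[k]] <- rec
    rows[[k]] <- data.frame(
      protein_id = id, role = "decoy", family_id = NA_character_,
      ring_type = tp, domain_index = NA_integer_,
      domain_start = NA_integer_, ligand_positions = NA_character_,
      motif_name = NA_character_, motif_start = NA_integer_,
      motif_distance = NA_integer_, decoy_class = cls,
      stringsAsFactors = FALSE
    )
  }
  list(records = records, manifest = do.call(rbind, rows))
}

#' Generate a full synthetic proteome with truth manifest
#'
#' Families (shared ancestry, controlled divergence, optional planted
#' motif), lone genes, two-domain proteins, and decoys, all seeded from
#' `spec$seed`. Identical spec yields byte-identical output.
#'
#' @param spec A [sim_spec()].
#' @param table A `ring_type_table` (default: the canonical table).
#' @return List `records` (protein records), `manifest` (truth data frame,
#'   one row per planted domain or domainless protein), `spec`.
#' @export
make_proteome <- function(spec = sim_spec(), table = load_type_table()) {
  stopifnot(inherits(spec, "sim_spec"))
  withr_seed(spec$seed, {
    records <- list()
    manifest <- list()
    for (f in seq_len(spec$n_families)) {
      fid <- sprintf("fam%02d", f)
      carries <- f %in% spec$motif_families && !is.null(spec$motif_seq)
      fam <- make_family(
        fid, spec$family_sizes[f], spec$family_types[f], table, spec,
        motif_seq = if (carries) spec$motif_seq else NULL,
        motif_distance = spec$motif_distance
      )
      records <- c(records, fam$records)
      manifest[[length(manifest) + 1L]] <- fam$manifest
    }
    for (l in seq_along(spec$lone_types)) {
      id <- sprintf("lone%02d", l)
      p <- assemble_protein(id, spec$lone_types[l], table, spec)
      records <- c(records, list(p$record))
      d <- p$domains[[1]]
      manifest[[length(manifest) + 1L]] <- data.frame(
        protein_id = id, role = "lone", family_id = NA_character_,
        ring_type = spec$lone_types[l], domain_index = 1L,
        domain_start = d$start,
        ligand_positions = paste(d$ligands, collapse = ";"),
        motif_name = NA_character_, motif_start = NA_integer_,
        motif_distance = NA_integer_, decoy_class = NA_character_,
        stringsAsFactors = FALSE
      )
    }
    for (m in seq_len(spec$n_multi)) {
      id <- sprintf("multi%02d", m)
      p <- assemble_protein(id, c("RING-HC", "RING-HC"), table, spec)
      records <- c(records, list(p$record))
      for (di in seq_along(p$domains)) {
        d <- p$domains[[di]]
        manifest[[length(manifest) + 1L]] <- data.frame(
          protein_id = id, role = "multi", family_id = NA_character_,
          ring_type = d$ring_type, domain_index = di,
          domain_start = d$start,
          ligand_positions = paste(d$ligands, collapse = ";"),
          motif_name = NA_character_, motif_start = NA_integer_,
          motif_distance = NA_integer_, decoy_class = NA_character_,
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(spec$decoy_classes) && spec$decoys_per_class > 0L) {
      dec <- make_decoys(spec$decoy_classes, table, spec,
                         per_class = spec$decoys_per_class)
      records <- c(records, dec$records)
      manifest[[length(manifest) + 1L]] <- dec$manifest
    }
    list(records = records, manifest = do.call(rbind, manifest), spec = spec)
  })
}

#' Write a proteome as FASTA
#'
#' @param records List of protein records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(records, path) {
  ss <- Biostrings::AAStringSet(vapply(records, `[[`, character(1),
                                       "sequence"))
  names(ss) <- vapply(records, `[[`, character(1), "id")
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Generate synthetic GFF3 gene models
#'
#' Builds one transcript per requested gene with the requested CDS intron
#' count and 5'UTR-intron occurrence, on alternating strands, at
#' non-overlapping positions along one synthetic chromosome.
#'
#' @param gene_specs Data frame with columns `gene_id`, `cds_introns`
#'   (>= 0), `utr5_intron` (logical), and optionally `strand`.
#' @param seed RNG seed.
#' @return List `gff` (character vector of GFF3 lines) and `manifest`.
#' @export
make_gff3 <- function(gene_specs, seed = 1L) {
  stopifnot(all(gene_specs$cds_introns >= 0L))
  if (is.null(gene_specs$strand)) {
    gene_specs$strand <- rep_len(c("+", "-"), nrow(gene_specs))
  }
  withr_seed(seed, {
    lines <- c("##gff-version 3")
    offset <- 1000L
    for (i in seq_len(nrow(gene_specs))) {
      gs <- gene_specs[i, ]
      g <- build_gene_model(gs$gene_id, gs$cds_introns, gs$utr5_intron,
                            gs$strand, offset)
      lines <- c(lines, g$lines)
      offset <- g$next_offset + sample(200:500, 1L)
    }
    list(gff = lines, manifest = gene_specs)
  })
}

# one gene: transcript-order exon blocks of utr/cds pieces, mapped to genome
build_gene_model <- function(gene_id, cds_introns, utr5_intron, strand,
                             offset) {
  utr_lens <- if (utr5_intron) sample(40:120, 2L, replace = TRUE)
              else sample(40:120, 1L)
  n_cds <- cds_introns + 1L
  cds_lens <- sample(60:240, n_cds, replace = TRUE)
  # exon blocks in transcript order: list of data.frames(kind, len)
  blocks <- list()
  if (utr5_intron) {
    blocks[[1]] <- data.frame(kind = "utr5", len = utr_lens[1])
    blocks[[2]] <- data.frame(kind = c("utr5", "cds"),
                              len = c(utr_lens[2], cds_lens[1]))
  } else {
    blocks[[1]] <- data.frame(kind = c("utr5", "cds"),
                              len = c(utr_lens[1], cds_lens[1]))
  }
  for (k in seq_len(n_cds - 1L)) {
    blocks[[length(blocks) + 1L]] <- data.frame(kind = "cds",
                                                len = cds_lens[k + 1L])
  }
  intron_lens <- if (length(blocks) > 1L) {
    sample(80:300, length(blocks) - 1L, replace = TRUE)
  } else integer(0)
  exon_lens <- vapply(blocks, function(b) sum(b$len), numeric(1))
  total <- sum(exon_lens) + sum(intron_lens)
  # transcript-order exon genomic starts (1-based)
  step <- exon_lens + c(intron_lens, 0)
  shift <- cumsum(c(0, step[-length(step)]))
  if (strand == "+") {
    ex_start <- offset + shift
  } else {
    right_end <- offset + total - 1L
    ex_start <- (right_end - shift) - exon_lens + 1L
  }
  feat <- list()
  add <- function(type, s, e, id = NULL, parent = NULL) {
    attrs <- c(if (!is.null(id)) paste0("ID=", id),
               if (!is.null(parent)) paste0("Parent=", parent))
    feat[[length(feat) + 1L]] <<- data.frame(
      s = s, e = e,
      line = paste("chrS", "ringcat_sim", type, s, e, ".", strand,
                   if (type == "CDS") "0" else ".",
                   paste(attrs, collapse = ";"), sep = "\t"),
      stringsAsFactors = FALSE
    )
  }
  mrna_id <- paste0(gene_id, ".1")
  for (b in seq_along(blocks)) {
    s <- ex_start[b]; e <- s + exon_lens[b] - 1L
    add("exon", s, e, parent = mrna_id)
    # pieces within the exon run in transcript orientation
    pos <- if (strand == "+") s else e
    for (p in seq_len(nrow(blocks[[b]]))) {
      len <- blocks[[b]]$len[p]
      kind <- blocks[[b]]$kind[p]
      if (strand == "+") {
        ps <- pos; pe <- pos + len - 1L; pos <- pe + 1L
      } else {
        pe <- pos; ps <- pos - len + 1L; pos <- ps - 1L
      }
      add(if (kind == "cds") "CDS" else "five_prime_UTR", ps, pe,
          parent = mrna_id)
    }
  }
  gs <- min(vapply(feat, `[[`, numeric(1), "s"))
  ge <- max(vapply(feat, `[[`, numeric(1), "e"))
  gene_line <- paste("chrS", "ringcat_sim", "gene", gs, ge, ".", strand, ".",
                     paste0("ID=", gene_id), sep = "\t")
  mrna_line <- paste("chrS", "ringcat_sim", "mRNA", gs, ge, ".", strand, ".",
                     paste0("ID=", mrna_id, ";Parent=", gene_id), sep = "\t")
  feat_df <- do.call(rbind, feat)
  feat_df <- feat_df[order(feat_df$s, feat_df$e), , drop = FALSE]
  list(lines = c(gene_line, mrna_line, feat_df$line), next_offset = ge + 1L)
}

#' Evolve a domain along a tree
#'
#' Independent per-site Poisson substitution along each branch (expected
#' `rate` substitutions per site per unit branch length); ligand sites are
#' held fixed. Leaves carry divergence proportional to their path length.
#'
#' @param tree A `phylo` tree with branch lengths >= 0.
#' @param fragment Ancestral sequence fragment (string).
#' @param ligand_offsets 0-based positions held invariant.
#' @param rate Substitutions per site per unit branch length.
#' @param seed RNG seed.
#' @return Named character vector of leaf sequences (names = tip labels).
#' @export
evolve_on_tree <- function(tree, fragment, ligand_offsets = integer(0),
                           rate = 1, seed = 1L) {
  if (is.null(tree$edge.length)) {
    stop("tree must carry branch lengths (edge.length)")
  }
  stopifnot(inherits(tree, "phylo"), all(tree$edge.length >= 0))
  chars0 <- strsplit(toupper(fragment), "")[[1]]
  protect <- ligand_offsets + 1L
  free <- setdiff(seq_along(chars0), protect)
  n <- length(tree$tip.label)
  root <- n + 1L
  withr_seed(seed, {
    seqs <- list()
    evolve_branch <- function(chars, len) {
      k <- stats::rpois(length(free), rate * len)
      for (idx in which(k > 0)) {
        site <- free[idx]
        for (s in seq_len(k[idx])) {
          chars[site] <- sample(setdiff(AA20, chars[site]), 1L)
        }
      }
      chars
    }
    walk <- function(node, chars) {
      rows <- which(tree$edge[, 1] == node)
      for (r in rows) {
        child <- tree$edge[r, 2]
        ch <- evolve_branch(chars, tree$edge.length[r])
        if (child <= n) {
          seqs[[tree$tip.label[child]]] <<- paste(ch, collapse = "")
        } else {
          walk(child, ch)
        }
      }
    }
    walk(root, chars0)
    unlist(seqs)[tree$tip.label]
  })
}

#' Write a truth manifest as TSV
#'
#' @param manifest Manifest data frame from [make_proteome()] or
#'   [make_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
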