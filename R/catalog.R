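# Families vs lone genes. Proteins are related by the sequence OUTSIDE the
# RING domain: detected domains are masked before the all-against-all local
# alignment, families are single-linkage connected components above a
# normalized-score threshold, and groups receive systematic names by kind
# and dominant RING type (FHH/FHC/Fv/FCC/FD/FS-T/FG + ordinal for families;
# LHH/LHC/Lv/LCC + ordinal for lone genes).

FAMILY_PREFIX <- c("RING-H2" = "FHH", "RING-HC" = "FHC", "RING-v" = "Fv",
                   "RING-C2" = "FCC", "RING-D" = "FD", "RING-S/T" = "FS-T",
                   "RING-G" = "FG")
LONE_PREFIX <- c("RING-H2" = "LHH", "RING-HC" = "LHC", "RING-v" = "Lv",
                 "RING-C2" = "LCC")

# BLOSUM62 with the mask/unknown letter X scoring zero against everything
masked_blosum62 <- function() {
  mat <- get_blosum62()
  if (!"X" %in% rownames(mat)) {
    mat <- rbind(cbind(mat, X = 0L), X = 0L)
  }
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat
}

get_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

#' Mask the RING domain(s) of a protein
#'
#' Replaces every hit interval with the mask character `X` (which scores zero
#' in all downstream alignments), so that similarity reflects only the
#' sequence outside the RING domain.
#'
#' @param record A list with `id` and `sequence`.
#' @param hits `ring_hits` rows belonging to this record.
#' @return A list with `protein_id` and the masked `sequence` (same length).
#' @export
mask_ring <- function(record, hits) {
  chars <- strsplit(check_sequence(record$sequence, record$id), "")[[1]]
  hits <- hits[hits$protein_id == record$id, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]; e <- hits$end[i]
    if (s < 0L || e > length(chars) || s >= e) {
      stop("consistency error: hit interval [", s, ",", e,
           ") out of bounds for ", record$id)
    }
    chars[(s + 1L):e] <- "X"
  }
  list(protein_id = record$id, sequence = paste(chars, collapse = ""))
}

#' Mask a whole set of records
#'
#' @param records List of protein records.
#' @param hits A `ring_hits` data frame covering them.
#' @return Named character vector of masked sequences.
#' @export
mask_proteome <- function(records, hits) {
  out <- vapply(records, function(r) mask_ring(r, hits)$sequence, character(1))
  names(out) <- vapply(records, `[[`, character(1), "id")
  out
}

# self-score: optimal local self-alignment = sum of diagonal scores
# (all BLOSUM62 diagonal entries are positive; X scores 0)
self_scores <- function(seqs, mat) {
  diag_sc <- diag(mat)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[!ch %in% rownames(mat)] <- "X"
    sum(diag_sc[ch])
  }, numeric(1))
}

# local-alignment scores of every sequence in `patterns` against `subject`
local_scores <- function(patterns, subject, mat,
                         gap_open = 11, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(patterns),
    subject = Biostrings::AAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE
  )
}

#' All-against-all similarity of masked sequences
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps open 11 / extend 1)
#' of every pair; scores are normalized by the self-score of the shorter
#' sequence, so identical sequences score 1.0 and the measure is independent
#' of database size. Masked (`X`) positions score 0 against everything.
#'
#' @param seqs Named character vector of (masked) sequences.
#' @param threshold Minimum `normalized_score` for an edge (default 0.3).
#' @param gap_open,gap_extend Affine gap penalties.
#' @return Data frame of edges `id_a`, `id_b`, `score`, `normalized_score`
#'   with `normalized_score >= threshold`; symmetric pairs reported once
#'   (`id_a` earlier in input order).
#' @export
all_vs_all_similarity <- function(seqs, threshold = 0.3,
                                  gap_open = 11, gap_extend = 1) {
  stopifnot(length(seqs) >= 1L, !is.null(names(seqs)))
  mat <- masked_blosum62()
  self <- self_scores(seqs, mat)
  usable <- self > 0
  if (any(!usable)) {
    warning("excluding all-masked sequence(s): ",
            paste(names(seqs)[!usable], collapse = ", "))
  }
  ids <- names(seqs)[usable]
  ss <- seqs[usable]
  self <- self[usable]
  lens <- nchar(ss)
  rows <- list()
  for (j in seq_along(ss)[-1]) {
    sc <- local_scores(ss[seq_len(j - 1L)], ss[[j]], mat,
                       gap_open, gap_extend)
    for (i in seq_len(j - 1L)) {
      denom <- if (lens[i] < lens[j]) self[i]
               else if (lens[j] < lens[i]) self[j]
               else min(self[i], self[j])
      ns <- sc[i] / denom
      if (ns >= threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          id_a = ids[i], id_b = ids[j], score = sc[i],
          normalized_score = ns, stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(id_a = character(), id_b = character(),
                      score = numeric(), normalized_score = numeric(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Cluster proteins into families and lone genes
#'
#' Single-linkage: connected components of the similarity graph. Components
#' with at least two members are families; singletons are lone genes.
#'
#' @param edges Edge data frame from [all_vs_all_similarity()].
#' @param all_ids All protein ids (so that edgeless proteins become lone
#'   genes).
#' @return List of unnamed groups, each `list(kind, member_ids)`; member ids
#'   sorted, groups ordered by decreasing size then first member id.
#' @export
cluster_families <- function(edges, all_ids) {
  all_ids <- sort(unique(all_ids))
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = all_ids)
  )
  comp <- igraph::components(g)
  members <- split(all_ids, comp$membership[all_ids])
  groups <- lapply(members, function(m) {
    list(kind = if (length(m) >= 2L) "family" else "lone",
         member_ids = sort(unname(m)))
  })
  sizes <- vapply(groups, function(g) length(g$member_ids), integer(1))
  firsts <- vapply(groups, function(g) g$member_ids[1], character(1))
  groups[order(-sizes, firsts)]
}

modal_type <- function(types) {
  tab <- table(types)
  top <- names(tab)[tab == max(tab)]
  if (length(top) > 1L) {
    # tie: prefer the type of higher canonical priority
    ord <- match(top, RING_TYPE_NAMES)
    top <- top[order(ord)][1]
  }
  top
}

#' Name groups systematically
#'
#' Families: `FHH`/`FHC`/`Fv`/`FCC`/`FD`/`FS-T`/`FG` by dominant (modal) RING
#' type plus a two-digit ordinal assigned in order of decreasing size (ties
#' by first member id). Lone genes: `LHH`/`LHC`/`Lv`/`LCC` plus an ordinal in
#' member-id order. A RING type without a defined prefix for its kind is a
#' naming error.
#'
#' @param groups Unnamed groups from [cluster_families()].
#' @param hits A `ring_hits` data frame covering the members (dominant type =
#'   modal type over the members' hits).
#' @param species_label Free-text label stored on the catalog.
#' @param aliases Optional named character vector mapping systematic codes to
#'   legacy names (e.g. ATL...UTL).
#' @return A `ring_catalog`: `groups` (each with `code`, `kind`,
#'   `member_ids`, `dominant_ring_type`, optional `alias`) and
#'   `species_label`.
#' @export
name_groups <- function(groups, hits, species_label = "", aliases = NULL) {
  kinds <- vapply(groups, `[[`, character(1), "kind")
  doms <- vapply(groups, function(g) {
    ht <- hits$ring_type[hits$protein_id %in% g$member_ids]
    if (!length(ht)) stop("naming error: no hits for group containing ",
                          g$member_ids[1])
    modal_type(ht)
  }, character(1))
  counters <- new.env()
  named <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    prefix_map <- if (kinds[i] == "family") FAMILY_PREFIX else LONE_PREFIX
    prefix <- prefix_map[doms[i]]
    if (is.na(prefix)) {
      stop("naming error: no ", kinds[i], " prefix defined for type ", doms[i])
    }
    k <- (get0(prefix, envir = counters, ifnotfound = 0L)) + 1L
    assign(prefix, k, envir = counters)
    g <- groups[[i]]
    g$code <- sprintf("%s%02d", prefix, k)
    g$dominant_ring_type <- unname(doms[i])
    if (!is.null(aliases) && g$code %in% names(aliases)) {
      g$alias <- unname(aliases[g$code])
    }
    named[[i]] <- g
  }
  codes <- vapply(named, `[[`, character(1), "code")
  stopifnot(!anyDuplicated(codes))
  structure(list(groups = named, species_label = species_label),
            class = "ring_catalog")
}

#' Build a catalog from scan results in one call
#'
#' Masks hits, computes all-against-all similarity outside the RING domain,
#' clusters single-linkage, and names the groups.
#'
#' @param records List of protein records (only those with at least one hit
#'   are catalogued).
#' @param hits A `ring_hits` data frame.
#' @param threshold Family similarity threshold (normalized score).
#' @param species_label,aliases Passed to [name_groups()].
#' @return A `ring_catalog`.
#' @export
build_catalog <- function(records, hits, threshold = 0.3,
                          species_label = "", aliases = NULL) {
  with_hits <- vapply(records, function(r) r$id %in% hits$protein_id,
                      logical(1))
  records <- records[with_hits]
  if (!length(records)) stop("no RING proteins to catalogue")
  masked <- mask_proteome(records, hits)
  edges <- all_vs_all_similarity(masked, threshold = threshold)
  groups <- cluster_families(edges, names(masked))
  name_groups(groups, hits, species_label = species_label, aliases = aliases)
}

#' Catalog as a flat table
#'
#' @param catalog A `ring_catalog`.
#' @return Data frame `protein_id`, `group_code`, `kind`, `ring_type`.
#' @export
catalog_table <- function(catalog) {
  stopifnot(inherits(catalog, "ring_catalog"))
  do.call(rbind, lapply(catalog$groups, function(g) {
    data.frame(protein_id = g$member_ids, group_code = g$code,
               kind = g$kind, ring_type = g$dominant_ring_type,
               stringsAsFactors = FALSE)
  }))
}

#' @export
print.ring_catalog <- function(x, ...) {
  sizes <- vapply(x$groups, function(g) length(g$member_ids), integer(1))
  cat("RING catalog", if (nzchar(x$species_label)) paste0("(", x$species_label, ")"),
      ": ", sum(sizes), " proteins in ", length(x$groups), " groups (",
      sum(sizes >= 2), " families, ", sum(sizes == 1), " lone)\n", sep = "")
  invisible(x)
}

#' Assign query proteins to reference groups
#'
#' Each query is aligned full-length (unmasked, local alignment) against
#' every reference sequence and assigned to the group of its best hit when
#' the normalized score reaches the threshold; otherwise labelled `novel`.
#'
#' @param query_records List of query protein records.
#' @param reference A `ring_catalog` for the reference species.
#' @param reference_records List of the reference protein records (unmasked).
#' @param threshold Minimum normalized score for assignment.
#' @return Data frame `protein_id`, `assigned_group`, `best_reference`,
#'   `normalized_score`.
#' @export
assign_to_reference <- function(query_records, reference, reference_records,
                                threshold = 0.3) {
  stopifnot(inherits(reference, "ring_catalog"))
  if (!length(reference_records)) stop("empty reference")
  ref_tab <- catalog_table(reference)
  ref_seqs <- vapply(reference_records, `[[`, character(1), "sequence")
  names(ref_seqs) <- vapply(reference_records, `[[`, character(1), "id")
  ref_seqs <- ref_seqs[names(ref_seqs) %in% ref_tab$protein_id]
  if (!length(ref_seqs)) stop("empty reference")
  mat <- masked_blosum62()
  ref_self <- self_scores(ref_seqs, mat)
  ref_lens <- nchar(ref_seqs)
  rows <- lapply(query_records, function(q) {
    qseq <- check_sequence(q$sequence, q$id)
    sc <- local_scores(ref_seqs, qseq, mat)
    qself <- self_scores(stats::setNames(qseq, q$id), mat)
    qlen <- nchar(qseq)
    denom <- ifelse(ref_lens < qlen, ref_self,
                    ifelse(qlen < ref_lens, qself, pmin(ref_self, qself)))
    ns <- sc / denom
    best <- which.max(ns)
    if (ns[best] >= threshold) {
      grp <- ref_tab$group_code[match(names(ref_seqs)[best],
                                      ref_tab$protein_id)]
      data.frame(protein_id = q$id, assigned_group = grp,
                 best_reference = names(ref_seqs)[best],
                 normalized_score = ns[best], stringsAsFactors = FALSE)
    } else {
      data.frame(protein_id = q$id, assigned_group = "novel",
                 best_reference = NA_character_,
                 normalized_score = ns[best], stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Summarize a multi-species survey
#'
#' @param catalogs List of `ring_catalog` objects (one per species).
#' @return List with `type_counts` (species x RING-type count table whose row
#'   sums equal catalog sizes) and `group_matrix` (species x group-code count
#'   matrix).
#' @export
summarize_survey <- function(catalogs) {
  stopifnot(length(catalogs) >= 1L)
  labels <- vapply(seq_along(catalogs), function(i) {
    lb <- catalogs[[i]]$species_label
    if (nzchar(lb)) lb else paste0("species", i)
  }, character(1))
  type_counts <- t(vapply(catalogs, function(ct) {
    tab <- catalog_table(ct)
    vapply(RING_TYPE_NAMES, function(tp) sum(tab$ring_type == tp), integer(1))
  }, integer(length(RING_TYPE_NAMES))))
  rownames(type_counts) <- labels
  type_counts <- cbind(type_counts, total = rowSums(type_counts))
  all_codes <- sort(unique(unlist(lapply(catalogs, function(ct) {
    vapply(ct$groups, `[[`, character(1), "code")
  }))))
  group_matrix <- t(vapply(catalogs, function(ct) {
    sizes <- stats::setNames(
      vapply(ct$groups, function(g) length(g$member_ids), integer(1)),
      vapply(ct$groups, `[[`, character(1), "code")
    )
    out <- stats::setNames(integer(length(all_codes)), all_codes)
    out[names(sizes)] <- sizes
    out
  }, integer(length(all_codes))))
  rownames(group_matrix) <- labels
  list(type_counts = type_counts, group_matrix = group_matrix)
}
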