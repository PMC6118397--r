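# RING domain detection. The scan anchors on the central core (ligands 3-6),
# then seeks ligand 2 at 9-39 residues upstream of ligand 3 with ligand 1 two
# residues before it, and ligands 7-8 at 4-48 and then 2 residues downstream
# of ligand 6. Hits lacking a boundary pair are dropped unless partial hits
# are explicitly allowed. Coordinates are 0-based half-open throughout;
# 1-based inclusive only at the report boundary.

#' Scanner parameter set
#'
#' @param allow_boundary_substitutions Accept tolerated ligand substitutions
#'   (flagged `boundary_substitution`). Default `TRUE`.
#' @param allow_extensions Accept spacer extension allowances (flagged
#'   `extended_spacer_<k>`). Default `TRUE`.
#' @param allow_partial Emit hits whose boundary ligands (1-2 or 7-8) could
#'   not be placed, marked `partial`. Default `FALSE`.
#' @param max_hits_per_protein Cap on retained hits per protein after overlap
#'   resolution. Default unlimited.
#' @return A `scan_params` list.
#' @export
scan_params <- function(allow_boundary_substitutions = TRUE,
                        allow_extensions = TRUE,
                        allow_partial = FALSE,
                        max_hits_per_protein = Inf) {
  structure(list(
    allow_boundary_substitutions = isTRUE(allow_boundary_substitutions),
    allow_extensions = isTRUE(allow_extensions),
    allow_partial = isTRUE(allow_partial),
    max_hits_per_protein = max_hits_per_protein
  ), class = "scan_params")
}

HIT_COLUMNS <- c("protein_id", "ring_type",
                 paste0("L", 1:8),
                 "start", "end", "central_span", "flags", "partial")

empty_hits <- function() {
  out <- data.frame(
    protein_id = character(), ring_type = character(),
    L1 = integer(), L2 = integer(), L3 = integer(), L4 = integer(),
    L5 = integer(), L6 = integer(), L7 = integer(), L8 = integer(),
    start = integer(), end = integer(), central_span = integer(),
    flags = character(), partial = logical(),
    stringsAsFactors = FALSE
  )
  class(out) <- c("ring_hits", "data.frame")
  out
}

check_sequence <- function(sequence, id = "<sequence>") {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("input error: ", id, ": sequence must be a non-empty string")
  }
  if (grepl("[^A-Za-z]", sequence)) {
    stop("input error: ", id,
         ": sequence contains non-letter characters (digits/whitespace?)")
  }
  toupper(sequence)
}

# allowed spacer lengths after ligand i; lengths beyond the base maximum are
# admissible only via the extension allowance and carry a flag
spacer_lengths <- function(def, i, allow_ext) {
  sp <- def$spacers[[i]]
  mx <- if (allow_ext) sp$max + sp$ext else sp$max
  sp$min:mx
}

spacer_flag <- function(def, i, len) {
  if (len > def$spacers[[i]]$max) paste0("extended_spacer_", i) else character()
}

# does chars[pos+1] satisfy slot i? returns NA (no), FALSE (canonical) or
# TRUE (via tolerated substitution, flagged)
slot_match <- function(chars, pos, def, i, allow_sub) {
  if (pos < 0L || pos >= length(chars)) return(NA)
  ch <- chars[pos + 1L]
  if (ch %in% slot_allowed(def, i)) return(FALSE)
  if (allow_sub && ch %in% slot_tolerated(def, i)) return(TRUE)
  NA
}

#' Scan one protein for RING domains
#'
#' Detects every placement of the eight zinc ligands consistent with some
#' type in the table, anchored on the central core (ligands 3-6) and extended
#' outward, then resolves overlapping candidates deterministically with
#' [resolve_overlaps()].
#'
#' @param record A list with `id` and `sequence` (amino-acid string; `X` and
#'   non-standard letters never satisfy a ligand slot but count as spacer
#'   residues), e.g. from [read_protein_fasta()].
#' @param table A validated `ring_type_table`.
#' @param params A [scan_params()] set.
#' @return A `ring_hits` data frame, one row per retained hit, sorted by
#'   `start`: 0-based ligand positions `L1..L8`, half-open domain interval
#'   `[start, end)`, `central_span` (ligand 3 through 6 inclusive, always in
#'   [9, 16]), comma-joined deviation `flags`, and a `partial` marker.
#' @export
#' @examples
#' tab <- load_type_table()
#' seq <- paste0("C", "AA", "C", strrep("A", 9), "C", "A", "H", "AA", "H",
#'               "AA", "C", strrep("A", 4), "C", "AA", "C")
#' scan_protein(list(id = "demo", sequence = seq), tab)
scan_protein <- function(record, table, params = scan_params()) {
  stopifnot(inherits(table, "ring_type_table"))
  sequence <- check_sequence(record$sequence, record$id %||% "<sequence>")
  chars <- strsplit(sequence, "")[[1]]
  cand <- scan_candidates(record$id %||% "", chars, table, params)
  hits <- resolve_overlaps(cand)
  if (is.finite(params$max_hits_per_protein) &&
      nrow(hits) > params$max_hits_per_protein) {
    hits <- hits[seq_len(params$max_hits_per_protein), , drop = FALSE]
  }
  hits
}

# all candidate hits before overlap resolution (exposed for the
# oracle-equivalence tests)
scan_candidates <- function(protein_id, chars, table, params) {
  allow_sub <- params$allow_boundary_substitutions
  allow_ext <- params$allow_extensions
  n <- length(chars)
  rows <- list()
  for (def in table$defs) {
    # per-slot match vectors: ok = satisfies the slot, tol = only via a
    # tolerated substitution (flagged)
    ok <- lapply(1:8, function(i) chars %in% slot_residues(def, i, allow_sub))
    tol <- lapply(1:8, function(i) chars %in% slot_tolerated(def, i) &
                                   !(chars %in% slot_allowed(def, i)))
    if (!allow_sub) tol <- lapply(tol, function(x) x & FALSE)
    m <- list(ok = ok, tol = tol)
    l34 <- spacer_lengths(def, 3L, allow_ext)
    l45 <- spacer_lengths(def, 4L, allow_ext)
    l56 <- spacer_lengths(def, 5L, allow_ext)
    p3s <- which(ok[[3]]) - 1L
    for (p3 in p3s) {
      for (s34 in l34) {
        p4 <- p3 + s34 + 1L
        if (p4 >= n || !ok[[4]][p4 + 1L]) next
        for (s45 in l45) {
          p5 <- p4 + s45 + 1L
          if (p5 >= n || !ok[[5]][p5 + 1L]) next
          for (s56 in l56) {
            p6 <- p5 + s56 + 1L
            if (p6 >= n || !ok[[6]][p6 + 1L]) next
            core_flags <- c(
              if (tol[[3]][p3 + 1L] || tol[[4]][p4 + 1L] ||
                  tol[[5]][p5 + 1L] || tol[[6]][p6 + 1L])
                "boundary_substitution",
              spacer_flag(def, 3L, s34), spacer_flag(def, 4L, s45),
              spacer_flag(def, 5L, s56)
            )
            lefts <- extend_left(m, p3, def, allow_ext)
            rights <- extend_right(m, p6, def, allow_ext, n)
            if (length(lefts) && length(rights)) {
              for (lf in lefts) for (rt in rights) {
                rows[[length(rows) + 1L]] <- hit_row(
                  protein_id, def,
                  c(lf$p1, lf$p2, p3, p4, p5, p6, rt$p7, rt$p8),
                  flags = c(core_flags, lf$flags, rt$flags), partial = FALSE
                )
              }
            } else if (params$allow_partial) {
              lf <- if (length(lefts)) lefts[[1]] else NULL
              rt <- if (length(rights)) rights[[1]] else NULL
              rows[[length(rows) + 1L]] <- hit_row(
                protein_id, def,
                c(lf$p1 %||% NA_integer_, lf$p2 %||% NA_integer_,
                  p3, p4, p5, p6,
                  rt$p7 %||% NA_integer_, rt$p8 %||% NA_integer_),
                flags = c(core_flags, lf$flags, rt$flags), partial = TRUE
              )
            }
          }
        }
      }
    }
  }
  bind_hits(rows)
}

extend_left <- function(m, p3, def, allow_ext) {
  out <- list()
  for (s23 in spacer_lengths(def, 2L, allow_ext)) {
    p2 <- p3 - s23 - 1L
    if (p2 < 0L || !m$ok[[2]][p2 + 1L]) next
    for (s12 in spacer_lengths(def, 1L, allow_ext)) {
      p1 <- p2 - s12 - 1L
      if (p1 < 0L || !m$ok[[1]][p1 + 1L]) next
      out[[length(out) + 1L]] <- list(
        p1 = p1, p2 = p2,
        flags = c(if (m$tol[[1]][p1 + 1L] || m$tol[[2]][p2 + 1L])
                    "boundary_substitution",
                  spacer_flag(def, 1L, s12), spacer_flag(def, 2L, s23))
      )
    }
  }
  out
}

extend_right <- function(m, p6, def, allow_ext, n) {
  out <- list()
  for (s67 in spacer_lengths(def, 6L, allow_ext)) {
    p7 <- p6 + s67 + 1L
    if (p7 >= n || !m$ok[[7]][p7 + 1L]) next
    for (s78 in spacer_lengths(def, 7L, allow_ext)) {
      p8 <- p7 + s78 + 1L
      if (p8 >= n || !m$ok[[8]][p8 + 1L]) next
      out[[length(out) + 1L]] <- list(
        p7 = p7, p8 = p8,
        flags = c(if (m$tol[[7]][p7 + 1L] || m$tol[[8]][p8 + 1L])
                    "boundary_substitution",
                  spacer_flag(def, 6L, s67), spacer_flag(def, 7L, s78))
      )
    }
  }
  out
}

hit_row <- function(protein_id, def, pos, flags, partial) {
  pos <- as.integer(pos)
  known <- pos[!is.na(pos)]
  list(protein_id = protein_id, ring_type = def$name, pos = pos,
       start = min(known), end = max(known) + 1L,
       central_span = pos[6] - pos[3] + 1L,
       flags = paste(sort(unique(flags)), collapse = ","),
       partial = partial)
}

bind_hits <- function(rows) {
  if (!length(rows)) return(empty_hits())
  # rows are either hit_row() lists or ring_hits data frames
  if (is.data.frame(rows[[1]])) {
    rows <- rows[vapply(rows, nrow, integer(1)) > 0L]
    if (!length(rows)) return(empty_hits())
    out <- do.call(rbind, lapply(rows, as.data.frame))
  } else {
    pos <- do.call(rbind, lapply(rows, `[[`, "pos"))
    colnames(pos) <- paste0("L", 1:8)
    out <- data.frame(
      protein_id = vapply(rows, `[[`, character(1), "protein_id"),
      ring_type = vapply(rows, `[[`, character(1), "ring_type"),
      pos,
      start = vapply(rows, `[[`, integer(1), "start"),
      end = vapply(rows, `[[`, integer(1), "end"),
      central_span = vapply(rows, `[[`, integer(1), "central_span"),
      flags = vapply(rows, `[[`, character(1), "flags"),
      partial = vapply(rows, `[[`, logical(1), "partial"),
      stringsAsFactors = FALSE
    )
  }
  class(out) <- c("ring_hits", "data.frame")
  rownames(out) <- NULL
  out
}

n_flags <- function(flags) {
  ifelse(nzchar(flags), lengths(strsplit(flags, ",", fixed = TRUE)), 0L)
}

#' Resolve overlapping candidate hits
#'
#' Retains a maximal set of mutually non-overlapping hits from one protein.
#' Among overlapping alternatives the preference order is: fewer deviation
#' flags; non-partial over partial; higher type priority (lower priority
#' number); smaller domain span; leftmost start. Fully deterministic.
#'
#' @param candidates A `ring_hits` data frame of candidates from one protein.
#' @param table Optional `ring_type_table` supplying type priorities; the
#'   canonical table's priorities are used when omitted.
#' @return The retained `ring_hits`, sorted by `start`.
#' @export
resolve_overlaps <- function(candidates, table = NULL) {
  if (!nrow(candidates)) return(bind_hits(list()))
  prio <- if (is.null(table)) {
    stats::setNames(seq_along(RING_TYPE_NAMES), RING_TYPE_NAMES)
  } else {
    stats::setNames(vapply(table$defs, `[[`, integer(1), "priority"),
                    names(table$defs))
  }
  p <- prio[candidates$ring_type]
  p[is.na(p)] <- max(prio, na.rm = TRUE) + 1L
  ord <- order(n_flags(candidates$flags), candidates$partial, p,
               candidates$end - candidates$start, candidates$start,
               candidates$L3, candidates$ring_type)
  kept <- integer()
  for (i in ord) {
    s <- candidates$start[i]; e <- candidates$end[i]
    if (!length(kept) ||
        all(e <= candidates$start[kept] | s >= candidates$end[kept])) {
      kept <- c(kept, i)
    }
  }
  out <- candidates[kept[order(candidates$start[kept])], , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ring_hits", "data.frame")
  out
}

#' Read a protein FASTA into plain records
#'
#' @param path FASTA file (multi-record, wrapped or single-line).
#' @return List of records, each `list(id, description, sequence)`; ids are
#'   the first whitespace-delimited token of each header.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("input error: FASTA not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("input error: duplicated FASTA ids: ", paste(dup, collapse = ", "))
  }
  lapply(seq_along(ss), function(i) {
    list(id = ids[i], description = names(ss)[i],
         sequence = as.character(ss[[i]]))
  })
}

#' Scan a FASTA file for RING domains
#'
#' Runs [scan_protein()] on every record; multi-domain proteins yield
#' multiple rows. Output ordering is deterministic: input record order, then
#' `start`.
#'
#' @param path FASTA file path, or a list of records as returned by
#'   [read_protein_fasta()].
#' @param table A validated `ring_type_table`.
#' @param params A [scan_params()] set.
#' @return A `ring_hits` data frame (empty, with header, when nothing
#'   matches).
#' @export
scan_fasta <- function(path, table, params = scan_params()) {
  records <- if (is.character(path)) read_protein_fasta(path) else path
  bind_hits(lapply(records, function(r) scan_protein(r, table, params)))
}

#' Convert hits to a 1-based report table
#'
#' User-facing coordinates: 1-based inclusive ligand positions and domain
#' interval.
#'
#' @param hits A `ring_hits` data frame.
#' @return A plain data frame with 1-based `L1..L8`, `start`, `end`.
#' @export
hits_report <- function(hits) {
  out <- as.data.frame(hits)
  for (cl in paste0("L", 1:8)) out[[cl]] <- out[[cl]] + 1L
  out$start <- out$start + 1L  # end stays: half-open 0-based == inclusive 1-based
  out
}

# check every invariant of one emitted hit against its type definition;
# used by tests and the simulator's post-checks
validate_hit <- function(hit, table) {
  def <- table$defs[[hit$ring_type]]
  pos <- unlist(hit[paste0("L", 1:8)], use.names = FALSE)
  known <- which(!is.na(pos))
  stopifnot(!is.unsorted(pos[known], strictly = TRUE))
  for (k in seq_len(7L)) {
    if (is.na(pos[k]) || is.na(pos[k + 1])) next
    len <- pos[k + 1] - pos[k] - 1L
    sp <- def$spacers[[k]]
    stopifnot(len >= sp$min, len <= sp$max + sp$ext)
  }
  span <- pos[6] - pos[3] + 1L
  stopifnot(span >= 9L, span <= 16L, span == hit$central_span)
  invisible(TRUE)
}
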