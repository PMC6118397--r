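# Exhaustive reference detector, kept as an independent code path from the
# anchored scanner: it enumerates full 8-tuples of ligand positions
# left-to-right from per-slot match sets, instead of anchoring on the
# central core and extending outward. Used as the equivalence oracle in the
# test-suite; guarded to short sequences.

#' Brute-force RING detection oracle
#'
#' Exhaustively enumerates every 8-tuple of positions satisfying the slot
#' identities and spacer ranges of every type in the table, then applies the
#' same overlap resolution as [scan_protein()]. Independent of the anchored
#' scanner's code path; intended for verification on short sequences.
#'
#' @param record A list with `id` and `sequence`.
#' @param table A validated `ring_type_table`.
#' @param params A [scan_params()] set (`allow_partial` is not supported by
#'   the oracle; complete tuples only).
#' @param resolve Apply [resolve_overlaps()] (default) or return all
#'   candidates.
#' @return A `ring_hits` data frame.
#' @export
brute_force_oracle <- function(record, table, params = scan_params(),
                               resolve = TRUE) {
  stopifnot(inherits(table, "ring_type_table"))
  sequence <- check_sequence(record$sequence, record$id %||% "<sequence>")
  if (nchar(sequence) > 200L) {
    stop("refusal: brute_force_oracle is limited to sequences of <= 200 residues")
  }
  if (isTRUE(params$allow_partial)) {
    stop("refusal: the oracle enumerates complete tuples only (allow_partial unsupported)")
  }
  chars <- strsplit(sequence, "")[[1]]
  allow_sub <- params$allow_boundary_substitutions
  allow_ext <- params$allow_extensions
  rows <- list()
  for (def in table$defs) {
    # positions matching each slot (0-based), tolerated matches marked
    matches <- lapply(seq_len(8L), function(i) {
      ok <- which(chars %in% slot_residues(def, i, allow_sub)) - 1L
      tol <- chars[ok + 1L] %in% slot_tolerated(def, i)
      list(pos = ok, tol = tol)
    })
    # left-to-right join over slots: partial chains are (positions so far)
    chains <- lapply(seq_along(matches[[1]]$pos), function(k) {
      list(pos = matches[[1]]$pos[k], tol = matches[[1]]$tol[k],
           flags = character())
    })
    for (i in 2:8) {
      sp <- def$spacers[[i - 1L]]
      mx <- if (allow_ext) sp$max + sp$ext else sp$max
      nxt <- list()
      for (ch in chains) {
        last <- ch$pos[length(ch$pos)]
        sel <- which(matches[[i]]$pos >= last + sp$min + 1L &
                     matches[[i]]$pos <= last + mx + 1L)
        for (k in sel) {
          p <- matches[[i]]$pos[k]
          len <- p - last - 1L
          nxt[[length(nxt) + 1L]] <- list(
            pos = c(ch$pos, p),
            tol = ch$tol || matches[[i]]$tol[k],
            flags = c(ch$flags, spacer_flag(def, i - 1L, len))
          )
        }
      }
      chains <- nxt
      if (!length(chains)) break
    }
    for (ch in chains) {
      rows[[length(rows) + 1L]] <- hit_row(
        record$id %||% "", def, ch$pos,
        flags = c(if (ch$tol) "boundary_substitution", ch$flags),
        partial = FALSE
      )
    }
  }
  cand <- bind_hits(rows)
  if (resolve) resolve_overlaps(cand, table) else cand
}
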