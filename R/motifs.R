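# Conservation profiling and motif work: per-column residue frequencies over
# group alignments, deterministic extraction of conserved ungapped blocks (a
# semantic stand-in for LOGO inventories produced by EM motif discovery,
# which this package deliberately does not reimplement), scanning of
# user-supplied degenerate consensus motifs, and presence-sharing tables
# across groups. Motif widths are bounded to [6, 100] residues.

HYDROPHOBIC_CLASS <- c("A", "V", "L", "I", "M", "F", "W", "C")

#' Build a conservation profile from alignment rows
#'
#' Per-column residue frequencies computed over non-gap residues, plus
#' occupancy (fraction of non-gap rows). The consensus letter of a column is
#' the modal residue when its frequency reaches the cutoff; when the combined
#' frequency of the hydrophobic class \{A,V,L,I,M,F,W,C\} reaches the cutoff
#' and exceeds the modal frequency, the class consensus `J` (any hydrophobic
#' residue) is reported instead; otherwise `.`.
#'
#' @param rows Character matrix of aligned residues/gaps (e.g.
#'   `anchored_alignment$matrix`), or an `anchored_alignment`.
#' @param cutoff Consensus frequency cutoff (default 0.5).
#' @return A `conservation_profile`: `frequencies` (list of named numeric
#'   vectors summing to 1), `occupancy`, `conservation` (max of modal and
#'   hydrophobic-class frequency), `consensus` (character vector).
#' @export
build_profile <- function(rows, cutoff = 0.5) {
  if (inherits(rows, "anchored_alignment")) rows <- rows$matrix
  stopifnot(is.matrix(rows))
  if (nrow(rows) < 2L) stop("profile undefined for a single row")
  nc <- ncol(rows)
  freqs <- vector("list", nc)
  occupancy <- numeric(nc)
  conservation <- numeric(nc)
  consensus <- character(nc)
  for (j in seq_len(nc)) {
    col <- rows[, j]
    obs <- col[col != "-"]
    occupancy[j] <- length(obs) / length(col)
    if (!length(obs)) {
      freqs[[j]] <- numeric(0)
      conservation[j] <- 0
      consensus[j] <- "."
      next
    }
    f <- table(obs) / length(obs)
    f <- stats::setNames(as.numeric(f), names(f))
    freqs[[j]] <- f
    modal <- max(f)
    hydro <- sum(f[names(f) %in% HYDROPHOBIC_CLASS])
    conservation[j] <- max(modal, hydro)
    consensus[j] <- if (modal >= cutoff && modal >= hydro) {
      names(f)[which.max(f)]
    } else if (hydro >= cutoff) {
      "J"
    } else {
      "."
    }
  }
  structure(list(frequencies = freqs, occupancy = occupancy,
                 conservation = conservation, consensus = consensus,
                 cutoff = cutoff, n_rows = nrow(rows)),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Conservation profile: ", length(x$consensus), " columns, ",
      x$n_rows, " rows; consensus:\n", paste(x$consensus, collapse = ""),
      "\n", sep = "")
  invisible(x)
}

#' Extract conserved ungapped blocks from a profile
#'
#' Maximal runs of columns whose conservation reaches the cutoff; runs
#' shorter than `min_width` are dropped and runs longer than `max_width` are
#' truncated to `max_width`. Deterministic and idempotent.
#'
#' @param profile A `conservation_profile`.
#' @param min_width,max_width Block width bounds in residues (defaults 6 and
#'   100).
#' @param conservation_cutoff Column conservation cutoff (default 0.8).
#' @return Data frame `start` (0-based column), `width`, `consensus`, sorted
#'   by `start`.
#' @export
extract_blocks <- function(profile, min_width = 6L, max_width = 100L,
                           conservation_cutoff = 0.8) {
  stopifnot(inherits(profile, "conservation_profile"),
            min_width >= 1L, max_width >= min_width)
  ok <- profile$conservation >= conservation_cutoff
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  rows <- list()
  for (k in which(r$values)) {
    w <- r$lengths[k]
    if (w < min_width) next
    w <- min(w, max_width)
    s <- starts[k]
    rows[[length(rows) + 1L]] <- data.frame(
      start = s - 1L, width = w,
      consensus = paste(profile$consensus[s:(s + w - 1L)], collapse = ""),
      stringsAsFactors = FALSE
    )
  }
  if (!length(rows)) {
    return(data.frame(start = integer(), width = integer(),
                      consensus = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Define a degenerate consensus motif
#'
#' The pattern is a string of position tokens: an amino-acid letter, `.` or
#' `x` (any residue), or a bracketed set like `[LIV]`. Width must be in
#' [6, 100].
#'
#' @param name Motif name.
#' @param pattern Pattern string.
#' @return A `motif_model`: `name`, `width`, `position_sets`.
#' @export
motif_model <- function(name, pattern) {
  tokens <- regmatches(pattern,
                       gregexpr("\\[[A-Za-z]+\\]|[A-Za-z.]", pattern))[[1]]
  if (paste(tokens, collapse = "") != pattern) {
    stop("cannot parse motif pattern: ", pattern)
  }
  sets <- lapply(tokens, function(tk) {
    if (startsWith(tk, "[")) {
      strsplit(toupper(substr(tk, 2, nchar(tk) - 1)), "")[[1]]
    } else if (tk %in% c(".", "x", "X")) {
      character(0)  # empty set encodes the any-residue wildcard
    } else {
      toupper(tk)
    }
  })
  width <- length(sets)
  if (width < 6L || width > 100L) {
    stop("motif width must be within [6, 100], got ", width)
  }
  structure(list(name = name, width = width, position_sets = sets),
            class = "motif_model")
}

#' Read motif models from a text file
#'
#' One motif per line: `name<whitespace>pattern`; `#` starts a comment.
#'
#' @param path File path.
#' @return List of `motif_model`s.
#' @export
read_motif_models <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  lapply(lines, function(ln) {
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) != 2L) stop("malformed motif line: ", ln)
    motif_model(parts[1], parts[2])
  })
}

#' Scan sequences for a consensus motif
#'
#' Reports every position where all position sets match (the wildcard
#' matches any residue; `X` in the sequence matches only the wildcard), and
#' the signed distance from the motif end to the start of the nearest
#' downstream RING domain (negative = motif upstream of the domain); `NA`
#' when the protein has no RING hit downstream.
#'
#' @param model A `motif_model`.
#' @param records List of protein records.
#' @param hits A `ring_hits` data frame used for `distance_to_ring`.
#' @return Data frame `protein_id`, `start` (0-based), `motif_name`,
#'   `distance_to_ring`.
#' @export
scan_motif <- function(model, records, hits = empty_hits()) {
  stopifnot(inherits(model, "motif_model"))
  rows <- list()
  for (rec in records) {
    chars <- strsplit(check_sequence(rec$sequence, rec$id), "")[[1]]
    n <- length(chars)
    w <- model$width
    if (n < w) next
    ring_starts <- sort(hits$start[hits$protein_id == rec$id])
    for (s in 0:(n - w)) {
      ok <- TRUE
      for (k in seq_len(w)) {
        set <- model$position_sets[[k]]
        if (length(set) && !(chars[s + k] %in% set)) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
      motif_end <- s + w  # half-open
      down <- ring_starts[ring_starts >= s]
      dist <- if (length(down)) motif_end - down[1] else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        protein_id = rec$id, start = s, motif_name = model$name,
        distance_to_ring = dist, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(protein_id = character(), start = integer(),
                      motif_name = character(), distance_to_ring = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Motif presence per catalog group
#'
#' A motif is marked present in a group when at least `min_fraction` of the
#' members carry at least one occurrence.
#'
#' @param catalog A `ring_catalog`.
#' @param occurrences Data frame from [scan_motif()] (one or several motifs).
#' @param min_fraction Member fraction threshold (default 0.5).
#' @return Logical matrix, groups x motifs.
#' @export
motif_sharing <- function(catalog, occurrences, min_fraction = 0.5) {
  stopifnot(inherits(catalog, "ring_catalog"))
  motifs <- sort(unique(occurrences$motif_name))
  codes <- vapply(catalog$groups, `[[`, character(1), "code")
  out <- matrix(FALSE, length(codes), max(length(motifs), 1L),
                dimnames = list(codes,
                                if (length(motifs)) motifs else "none"))
  if (!length(motifs)) return(out[, 0, drop = FALSE])
  for (i in seq_along(catalog$groups)) {
    g <- catalog$groups[[i]]
    for (m in motifs) {
      carriers <- unique(occurrences$protein_id[occurrences$motif_name == m])
      frac <- mean(g$member_ids %in% carriers)
      out[i, m] <- frac >= min_fraction
    }
  }
  out
}
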