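# RING-domain phylogenies. Because every complete hit shares the same
# 8-ligand architecture, a multiple alignment needs no heuristic aligner:
# ligand columns are anchored across rows and each inter-ligand spacer region
# is right-padded with gaps to its maximum observed length. Distances are
# p / Poisson / gamma-corrected; trees are neighbor-joining with a fixed
# tie-break, with column-bootstrap supports; export is Newick.

#' Ligand-anchored multiple alignment of RING domains
#'
#' Aligns complete (non-partial) hits by their shared architecture: the 8
#' ligand columns are anchored across all rows and each of the 7 spacer
#' regions is right-padded with `-` to the maximum observed length for that
#' region. Gaps therefore occur only in spacer regions, never at ligand
#' columns.
#'
#' @param hits A `ring_hits` data frame of complete hits (an error names any
#'   partial hit, which must be excluded first).
#' @param records List of the protein records the hits came from.
#' @param row_ids Optional row labels; default `protein_id`, suffixed with
#'   the domain start when a protein carries several domains.
#' @return An `anchored_alignment`: character `matrix` (rows x columns),
#'   `row_ids`, and the 8 `ligand_columns`.
#' @export
anchor_align <- function(hits, records, row_ids = NULL) {
  if (!nrow(hits)) stop("no hits to align")
  if (any(hits$partial)) {
    stop("partial hit(s) present (",
         paste(unique(hits$protein_id[hits$partial]), collapse = ", "),
         "); exclude them before alignment")
  }
  seqs <- stats::setNames(
    lapply(records, function(r) strsplit(toupper(r$sequence), "")[[1]]),
    vapply(records, `[[`, character(1), "id")
  )
  if (is.null(row_ids)) {
    row_ids <- hits$protein_id
    dup <- hits$protein_id %in% hits$protein_id[duplicated(hits$protein_id)]
    row_ids[dup] <- paste0(hits$protein_id[dup], "@", hits$start[dup] + 1L)
  }
  pos <- as.matrix(hits[paste0("L", 1:8)])
  # region r (1..7) of row i runs (pos[i,r]+1 .. pos[i,r+1]-1), 0-based
  reg_len <- pos[, 2:8, drop = FALSE] - pos[, 1:7, drop = FALSE] - 1L
  reg_max <- apply(reg_len, 2, max)
  width <- 8L + sum(reg_max)
  m <- matrix("-", nrow = nrow(hits), ncol = width)
  ligand_columns <- integer(8)
  col <- 1L
  for (r in 1:8) {
    ligand_columns[r] <- col
    for (i in seq_len(nrow(hits))) {
      m[i, col] <- seqs[[hits$protein_id[i]]][pos[i, r] + 1L]
    }
    col <- col + 1L
    if (r < 8L) {
      for (i in seq_len(nrow(hits))) {
        len <- reg_len[i, r]
        if (len > 0L) {
          m[i, col:(col + len - 1L)] <-
            seqs[[hits$protein_id[i]]][(pos[i, r] + 2L):(pos[i, r + 1L])]
        }
      }
      col <- col + reg_max[r]
    }
  }
  structure(list(matrix = m, row_ids = row_ids,
                 ligand_columns = ligand_columns),
            class = "anchored_alignment")
}

#' Import an externally aligned FASTA as an anchored alignment
#'
#' @param path Aligned FASTA (equal-length rows, `-` gaps).
#' @param ligand_columns Optional 1-based ligand column indices.
#' @return An `anchored_alignment` (with `ligand_columns = NA` when unknown).
#' @export
read_alignment_fasta <- function(path, ligand_columns = NULL) {
  ss <- Biostrings::readAAStringSet(path)
  rows <- toupper(as.character(ss))
  if (length(unique(nchar(rows))) != 1L) {
    stop("input error: aligned FASTA rows differ in length")
  }
  m <- do.call(rbind, strsplit(rows, ""))
  structure(list(matrix = m, row_ids = sub("\\s.*$", "", names(ss)),
                 ligand_columns = ligand_columns %||% rep(NA_integer_, 8)),
            class = "anchored_alignment")
}

#' Write an anchored alignment as FASTA
#'
#' @param aln An `anchored_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(aln, path) {
  rows <- apply(aln$matrix, 1, paste, collapse = "")
  ss <- Biostrings::AAStringSet(rows)
  names(ss) <- aln$row_ids
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat("Anchored alignment: ", nrow(x$matrix), " rows x ", ncol(x$matrix),
      " columns; ligand columns ",
      paste(x$ligand_columns, collapse = ","), "\n", sep = "")
  invisible(x)
}

#' Complete-deletion filtering
#'
#' Removes every column containing at least one gap. Ligand columns never
#' contain gaps, so they are always retained (indices are remapped).
#'
#' @param aln An `anchored_alignment`.
#' @return The filtered `anchored_alignment`.
#' @export
complete_deletion <- function(aln) {
  stopifnot(inherits(aln, "anchored_alignment"))
  keep <- colSums(aln$matrix == "-") == 0L
  if (!any(keep)) stop("degenerate alignment: no gap-free columns remain")
  newpos <- cumsum(keep)
  lig <- aln$ligand_columns
  lig <- ifelse(!is.na(lig) & keep[lig], newpos[lig], NA_integer_)
  structure(list(matrix = aln$matrix[, keep, drop = FALSE],
                 row_ids = aln$row_ids, ligand_columns = lig),
            class = "anchored_alignment")
}

#' Pairwise distances from an alignment
#'
#' For each pair, `p` is the mismatch fraction over columns where both rows
#' are ungapped. Models: `p` (observed proportion), `poisson`
#' (`-ln(1 - p)`), `gamma` (`alpha * ((1 - p)^(-1/alpha) - 1)`, default
#' `alpha = 1`). Saturated pairs (`p` at or above the model's domain limit)
#' are clamped to `max_distance` with a warning. For `p` in (0, 1):
#' gamma >= poisson >= p.
#'
#' @param aln An `anchored_alignment` (typically after [complete_deletion()]).
#' @param model One of `"p"`, `"poisson"`, `"gamma"`.
#' @param alpha Gamma shape parameter.
#' @param max_distance Clamp for saturated distances.
#' @return A `dist_matrix`: list with `ids` and the symmetric `values`
#'   matrix (zero diagonal). The gamma model notes `alpha` and its
#'   category count as attributes.
#' @export
aln_distances <- function(aln, model = c("p", "poisson", "gamma"),
                          alpha = 1, k_categories = 5L, max_distance = 5) {
  stopifnot(inherits(aln, "anchored_alignment"))
  model <- match.arg(model)
  m <- aln$matrix
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 rows")
  if (ncol(m) < 1L) stop("need >= 1 column")
  vals <- matrix(0, n, n)
  clamped <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) stop("rows ", i, " and ", j, " share no ungapped columns")
      p <- mean(m[i, ok] != m[j, ok])
      d <- switch(model,
        p = p,
        poisson = if (p >= 1) NA_real_ else -log(1 - p),
        gamma = if (p >= 1) NA_real_ else alpha * ((1 - p)^(-1 / alpha) - 1)
      )
      if (is.na(d) || d > max_distance) {
        d <- max_distance
        clamped <- TRUE
      }
      vals[i, j] <- vals[j, i] <- d
    }
  }
  if (clamped) warning("saturated distance(s) clamped to ", max_distance)
  dimnames(vals) <- list(aln$row_ids, aln$row_ids)
  structure(list(ids = aln$row_ids, values = vals, model = model,
                 alpha = if (model == "gamma") alpha else NA_real_,
                 k_categories = if (model == "gamma") k_categories else NA_integer_),
            class = "dist_matrix")
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q-criterion. Ties on Q are
#' broken by the lowest index pair (current matrix order), so the result is
#' fully deterministic. Negative branch lengths are clamped to 0 with a
#' warning. For any additive distance matrix the generating topology and
#' branch lengths are recovered exactly.
#'
#' @param dm A `dist_matrix`, or a symmetric numeric matrix with dimnames.
#' @return An unrooted `phylo` tree (ape format, binary internal nodes).
#' @export
ring_nj <- function(dm) {
  d <- if (inherits(dm, "dist_matrix")) dm$values else as.matrix(dm)
  ids <- if (inherits(dm, "dist_matrix")) dm$ids else rownames(d)
  n <- nrow(d)
  if (n < 3L) stop("neighbor-joining needs >= 3 taxa")
  stopifnot(max(abs(d - t(d))) < 1e-9, all(diag(d) == 0))
  # node numbering: tips 1..n, internals n+1 .. 2n-2 in creation order;
  # the last internal created is the (trifurcating) root
  active <- seq_len(n)          # node ids of current rows
  next_node <- n + 1L
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  neg <- FALSE
  while (length(active) > 3L) {
    r <- nrow(d)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    # lowest-index pair among the minima
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    vi <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    vj <- d[i, j] - vi
    if (vi < 0 || vj < 0) neg <- TRUE
    edges <- rbind(edges, c(next_node, active[i]), c(next_node, active[j]))
    lens <- c(lens, max(vi, 0), max(vj, 0))
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    du <- du[-c(i, j)]
    d <- d[-c(i, j), -c(i, j), drop = FALSE]
    d <- rbind(cbind(d, du), c(du, 0))
    active <- c(active[-c(i, j)], next_node)
    next_node <- next_node + 1L
  }
  # final three-point join
  x <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  y <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  z <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  if (min(x, y, z) < 0) neg <- TRUE
  edges <- rbind(edges, c(next_node, active[1]), c(next_node, active[2]),
                 c(next_node, active[3]))
  lens <- c(lens, max(x, 0), max(y, 0), max(z, 0))
  if (neg) warning("negative branch length(s) clamped to 0")
  root <- next_node
  n_internal <- root - n
  # renumber internals to ape convention: root = n+1, preorder
  map <- integer(root)
  map[seq_len(n)] <- seq_len(n)
  counter <- n
  assign_ids <- function(node) {
    counter <<- counter + 1L
    map[node] <<- counter
    for (ch in edges[edges[, 1] == node, 2]) {
      if (ch > n) assign_ids(ch)
    }
  }
  assign_ids(root)
  edge <- cbind(map[edges[, 1]], map[edges[, 2]])
  ord <- order(edge[, 1], edge[, 2])
  tree <- structure(list(edge = edge[ord, , drop = FALSE],
                         edge.length = lens[ord],
                         tip.label = ids, Nnode = n_internal),
                    class = "phylo")
  attr(tree, "order") <- NULL
  ape::reorder.phylo(tree, "cladewise")
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement `reps` times, rebuilds the
#' NJ tree per replicate, and reports for each internal edge of the original
#' tree the percentage of replicates containing the same bipartition.
#' Reproducible for a fixed seed; supports do not depend on row order.
#'
#' @param aln An `anchored_alignment` (complete-deletion is applied first).
#' @param reps Number of replicates (>= 1).
#' @param seed RNG seed (mandatory).
#' @param model,alpha Distance model passed to [aln_distances()].
#' @return The original NJ `phylo` tree with integer supports (0-100) in
#'   `node.label` (root label empty).
#' @export
ring_bootstrap <- function(aln, reps = 100L, seed, model = "p", alpha = 1) {
  stopifnot(inherits(aln, "anchored_alignment"), reps >= 1L)
  if (missing(seed)) stop("a seed is required for bootstrap")
  aln <- complete_deletion(aln)
  ord <- order(aln$row_ids)  # row-order invariance
  base <- aln
  base$matrix <- base$matrix[ord, , drop = FALSE]
  base$row_ids <- base$row_ids[ord]
  tree <- ring_nj(aln_distances(base, model = model, alpha = alpha))
  nc <- ncol(base$matrix)
  boot <- withr_seed(seed, {
    lapply(seq_len(reps), function(k) {
      cols <- sample.int(nc, nc, replace = TRUE)
      rep_aln <- base
      rep_aln$matrix <- base$matrix[, cols, drop = FALSE]
      rep_aln$ligand_columns <- rep(NA_integer_, 8)
      # replicate trees feed only bipartition counts; their clamping noise
      # is not user-relevant
      suppressWarnings(
        ring_nj(aln_distances(rep_aln, model = model, alpha = alpha))
      )
    })
  })
  counts <- ape::prop.clades(tree, boot, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / reps))
  support_label <- as.character(support)
  support_label[1] <- ""  # root of the unrooted tree carries no support
  tree$node.label <- support_label
  tree
}

# evaluate `expr` under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

needs_quoting <- function(label) grepl("[][(){},;:'\"[:space:]]", label)

quote_label <- function(label) {
  ifelse(needs_quoting(label),
         paste0("'", gsub("'", "''", label), "'"),
         label)
}

#' Write a tree as Newick text
#'
#' Branch lengths are always written; internal `node.label`s (e.g. bootstrap
#' supports) become internal labels. Labels containing Newick metacharacters
#' are single-quoted per the standard. `ape::read.tree()` round-trips the
#' output.
#'
#' @param tree A `phylo` tree.
#' @param path Optional file path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt <- function(x) sprintf("%.*g", digits, x)
  rec <- function(node) {
    if (node <= n) return(quote_label(tree$tip.label[node]))
    rows <- kids[[as.character(node)]]
    inner <- vapply(rows, function(r) {
      paste0(rec(tree$edge[r, 2]), ":", fmt(tree$edge.length[r]))
    }, character(1))
    lab <- if (!is.null(tree$node.label)) {
      quote_label(tree$node.label[node - n])
    } else ""
    paste0("(", paste(inner, collapse = ","), ")", lab)
  }
  out <- paste0(rec(root), ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}
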