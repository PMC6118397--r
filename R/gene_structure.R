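# Intron architecture of RING genes from GFF3 gene models: spliceosomal
# intron counts within the CDS and 5'UTR-intron occurrence, summarized per
# catalog group. GFF3 is 1-based inclusive on disk; internal coordinates are
# 0-based half-open. "Upstream" always follows transcript orientation.

# intervals: integer matrix with columns start, end (0-based half-open),
# sorted by genomic start
as_intervals <- function(starts1, ends1) {
  m <- cbind(start = as.integer(starts1) - 1L, end = as.integer(ends1))
  m[order(m[, 1]), , drop = FALSE]
}

transcript_model <- function(gene_id, transcript_id, strand,
                             exons, cds, utr5) {
  stopifnot(strand %in% c("+", "-"))
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 strand = strand, exons = exons, cds_segments = cds,
                 utr5_segments = utr5),
            class = "transcript_model")
}

#' Parse gene models from GFF3
#'
#' Reads gene/mRNA/exon/CDS (and optionally five_prime_UTR) features and
#' returns one representative transcript per gene: the transcript with the
#' longest total CDS (ties broken by lexicographic transcript id). When
#' five_prime_UTR features are absent, the 5'UTR is inferred as the exonic
#' sequence upstream of the CDS start in transcript orientation.
#'
#' @param path GFF3 file.
#' @return Named list of `transcript_model` objects (one per gene), each with
#'   0-based half-open `exons`, `cds_segments` and `utr5_segments` interval
#'   matrices sorted by genomic start.
#' @export
parse_gff3 <- function(path) {
  if (!file.exists(path)) stop("input error: GFF3 not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  typ <- as.character(md$type)
  ids <- as.character(md$ID)
  parents <- md$Parent  # CharacterList
  parent1 <- vapply(seq_along(gr), function(i) {
    p <- parents[[i]]
    if (length(p)) as.character(p[1]) else NA_character_
  }, character(1))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))

  is_mrna <- typ %in% c("mRNA", "transcript")
  mrna_idx <- which(is_mrna)
  skipped <- character()
  models <- list()
  for (k in mrna_idx) {
    tid <- ids[k]
    gid <- parent1[k]
    if (is.na(gid)) {
      skipped <- c(skipped, tid)
      next
    }
    child <- which(!is.na(parent1) & parent1 == tid)
    ex <- child[typ[child] == "exon"]
    cd <- child[typ[child] == "CDS"]
    ut <- child[typ[child] == "five_prime_UTR"]
    if (!length(ex) || !length(cd)) {
      skipped <- c(skipped, tid)
      next
    }
    exons <- as_intervals(starts[ex], ends[ex])
    cds <- as_intervals(starts[cd], ends[cd])
    # every CDS segment must lie within some exon
    for (i in seq_len(nrow(cds))) {
      inside <- any(exons[, 1] <= cds[i, 1] & cds[i, 2] <= exons[, 2])
      if (!inside) {
        stop("validation error: CDS segment outside exons for transcript ", tid)
      }
    }
    strand <- strands[k]
    utr5 <- if (length(ut)) {
      as_intervals(starts[ut], ends[ut])
    } else {
      infer_utr5(exons, cds, strand)
    }
    models[[tid]] <- transcript_model(gid, tid, strand, exons, cds, utr5)
  }
  if (length(skipped)) {
    warning("skipped transcript(s) without usable parentage/exons/CDS: ",
            paste(skipped, collapse = ", "))
  }
  if (!length(models)) stop("input error: no usable gene models in ", path)
  # representative transcript per gene: longest total CDS, ties by id
  by_gene <- split(models, vapply(models, `[[`, character(1), "gene_id"))
  reps <- lapply(by_gene, function(ms) {
    cds_len <- vapply(ms, function(m) {
      sum(m$cds_segments[, 2] - m$cds_segments[, 1])
    }, integer(1))
    tids <- vapply(ms, `[[`, character(1), "transcript_id")
    ms[[order(-cds_len, tids)[1]]]
  })
  reps[order(names(reps))]
}

# exonic intervals upstream of the CDS start, transcript orientation
infer_utr5 <- function(exons, cds, strand) {
  if (strand == "+") {
    lim <- min(cds[, 1])
    keep <- exons[exons[, 1] < lim, , drop = FALSE]
    if (nrow(keep)) keep[, 2] <- pmin(keep[, 2], lim)
  } else {
    lim <- max(cds[, 2])
    keep <- exons[exons[, 2] > lim, , drop = FALSE]
    if (nrow(keep)) keep[, 1] <- pmax(keep[, 1], lim)
  }
  keep
}

#' Intron profile of a transcript model
#'
#' `cds_introns` is the number of CDS segments minus one. `utr5_intron` is
#' `TRUE` when at least one intron (gap between consecutive exons) lies
#' entirely upstream of the CDS start in transcript orientation; introns
#' straddling the UTR/CDS junction count as CDS introns, not UTR introns.
#'
#' @param model A `transcript_model`.
#' @return List `gene_id`, `cds_introns`, `utr5_intron` (class
#'   `intron_profile`).
#' @export
count_introns <- function(model) {
  stopifnot(inherits(model, "transcript_model"))
  cds_introns <- nrow(model$cds_segments) - 1L
  ex <- model$exons
  utr5 <- FALSE
  if (nrow(ex) >= 2L) {
    introns <- cbind(ex[-nrow(ex), 2], ex[-1, 1])  # genomic gaps
    if (model$strand == "+") {
      lim <- min(model$cds_segments[, 1])
      utr5 <- any(introns[, 2] <= lim)
    } else {
      lim <- max(model$cds_segments[, 2])
      utr5 <- any(introns[, 1] >= lim)
    }
  }
  structure(list(gene_id = model$gene_id, cds_introns = cds_introns,
                 utr5_intron = utr5),
            class = "intron_profile")
}

#' Intron profiles for a set of models
#'
#' @param models List of `transcript_model`s (e.g. from [parse_gff3()]).
#' @return Data frame `gene_id`, `cds_introns`, `utr5_intron`.
#' @export
intron_profiles <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    pr <- count_introns(m)
    data.frame(gene_id = pr$gene_id, cds_introns = pr$cds_introns,
               utr5_intron = pr$utr5_intron, stringsAsFactors = FALSE)
  }))
}

#' Summarize intron architecture per catalog group
#'
#' For each group, the min-max range of members' CDS intron counts (a single
#' value when min = max) and whether any member carries a 5'UTR intron.
#' Members without gene models are listed separately.
#'
#' @param profiles Data frame from [intron_profiles()]; `gene_id` is matched
#'   against catalog member ids.
#' @param catalog A `ring_catalog`.
#' @return List with `summary` (data frame `group_code`, `cds_range`,
#'   `utr5_occurrence`, `n_members`, `n_with_models`) and `missing`
#'   (member ids lacking models).
#' @export
summarize_group_introns <- function(profiles, catalog) {
  stopifnot(inherits(catalog, "ring_catalog"))
  missing <- character()
  rows <- lapply(catalog$groups, function(g) {
    pr <- profiles[profiles$gene_id %in% g$member_ids, , drop = FALSE]
    missing <<- c(missing, setdiff(g$member_ids, profiles$gene_id))
    if (!nrow(pr)) {
      return(data.frame(group_code = g$code, cds_range = NA_character_,
                        utr5_occurrence = NA, n_members = length(g$member_ids),
                        n_with_models = 0L, stringsAsFactors = FALSE))
    }
    lo <- min(pr$cds_introns); hi <- max(pr$cds_introns)
    data.frame(
      group_code = g$code,
      cds_range = if (lo == hi) as.character(lo) else paste0(lo, "-", hi),
      utr5_occurrence = any(pr$utr5_intron),
      n_members = length(g$member_ids), n_with_models = nrow(pr),
      stringsAsFactors = FALSE
    )
  })
  list(summary = do.call(rbind, rows), missing = sort(unique(missing)))
}
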