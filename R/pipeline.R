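# End-to-end runner and table output. Every output table starts with comment
# headers naming the package version, a hash of the effective configuration,
# and the seed, so runs are attributable and reruns comparable. User-facing
# tables use 1-based inclusive coordinates.

#' Pipeline configuration
#'
#' @param fasta Protein FASTA path (`NULL` when simulating).
#' @param gff3 Optional GFF3 path for intron profiling.
#' @param type_table Optional YAML type-table path (default: packaged table).
#' @param motif_file Optional motif-model file for motif scanning.
#' @param aliases Optional two-column TSV mapping group codes to legacy
#'   names.
#' @param out_dir Output directory.
#' @param family_threshold Normalized-score cutoff for family edges.
#' @param conservation_cutoff Block-extraction cutoff.
#' @param sharing_fraction Motif-sharing member fraction.
#' @param scan Scanner flags, a [scan_params()].
#' @param distance_model,bootstrap_reps Phylogeny settings.
#' @param seed Seed for simulation/bootstrap stages.
#' @param simulate `NULL`, or a [sim_spec()] to generate the input proteome.
#' @param stages Character vector of stages to run, from
#'   \{`scan`, `catalog`, `phylo`, `introns`, `motifs`\}.
#' @param species_label Label stored on the catalog.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta = NULL, gff3 = NULL, type_table = NULL,
                            motif_file = NULL, aliases = NULL,
                            out_dir = "ringcat_out",
                            family_threshold = 0.3,
                            conservation_cutoff = 0.8,
                            sharing_fraction = 0.5,
                            scan = scan_params(),
                            distance_model = "poisson",
                            bootstrap_reps = 100L,
                            seed = 1L,
                            simulate = NULL,
                            stages = c("scan", "catalog", "phylo",
                                       "introns", "motifs"),
                            species_label = "") {
  structure(as.list(environment()), class = "pipeline_config")
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  keep <- config[setdiff(names(config), "out_dir")]
  dput(keep, file = tmp)
  unname(tools::md5sum(tmp))
}

output_header <- function(config) {
  c(paste0("# ringcat ",
           as.character(utils::packageVersion("ringcat"))),
    paste0("# config_hash: ", config_hash(config)),
    paste0("# seed: ", config$seed))
}

write_output_table <- function(df, path, config) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = !is.null(dimnames(df)[[1]]) &&
                       !identical(rownames(df),
                                  as.character(seq_len(nrow(df)))),
    na = "")
  invisible(path)
}

#' Run the full cataloguing pipeline
#'
#' Stages: simulate (optional) or read FASTA; scan; catalog; RING-domain
#' phylogeny (anchored alignment, complete deletion, distances, NJ with
#' bootstrap, Newick); intron profiling when a GFF3 is supplied; motif
#' scanning and sharing when a motif file is supplied. Stage failures abort
#' with the stage name; unavailable inputs skip their stage with a notice.
#' Outputs are deterministic given identical inputs and seeds.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results
#'   (`hits`, `catalog`, `tree`, `introns`, `motifs`, paths of files
#'   written).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  table <- load_type_table(config$type_table)
  res <- list(files = character())
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_output_table(df, path, config)
    res$files <<- c(res$files, path)
  }
  note <- function(...) message("[ringcat] ", ...)

  if (!is.null(config$simulate)) {
    note("stage simulate")
    sim <- make_proteome(config$simulate, table)
    records <- sim$records
    emit(sim$manifest, "truth_manifest.tsv")
    fasta_path <- file.path(config$out_dir, "simulated_proteome.fasta")
    write_protein_fasta(records, fasta_path)
    res$files <- c(res$files, fasta_path)
  } else {
    if (is.null(config$fasta)) stop("stage input: no FASTA and no simulation spec")
    records <- read_protein_fasta(config$fasta)
  }

  hits <- NULL
  if ("scan" %in% config$stages) {
    note("stage scan: ", length(records), " proteins")
    hits <- tryCatch(scan_fasta(records, table, config$scan),
                     error = function(e) stop("stage scan: ",
                                              conditionMessage(e)))
    emit(hits_report(hits), "hits.tsv")
    res$hits <- hits
  }

  catalog <- NULL
  if ("catalog" %in% config$stages && !is.null(hits) && nrow(hits)) {
    note("stage catalog")
    aliases <- if (!is.null(config$aliases)) read_alias_map(config$aliases)
    catalog <- tryCatch(
      build_catalog(records, hits, threshold = config$family_threshold,
                    species_label = config$species_label, aliases = aliases),
      error = function(e) stop("stage catalog: ", conditionMessage(e))
    )
    emit(catalog_table(catalog), "catalog.tsv")
    survey <- summarize_survey(list(catalog))
    emit(as.data.frame(survey$type_counts), "type_counts.tsv")
    res$catalog <- catalog
  }

  if ("phylo" %in% config$stages && !is.null(hits)) {
    full <- hits[!hits$partial, , drop = FALSE]
    if (nrow(full) >= 3L) {
      note("stage phylo: ", nrow(full), " domains")
      aln <- anchor_align(full, records)
      tree <- tryCatch(
        ring_bootstrap(aln, reps = config$bootstrap_reps, seed = config$seed,
                       model = config$distance_model),
        error = function(e) stop("stage phylo: ", conditionMessage(e))
      )
      tree_path <- file.path(config$out_dir, "ring_domains.nwk")
      write_newick(tree, tree_path)
      res$files <- c(res$files, tree_path)
      res$tree <- tree
    } else {
      note("stage phylo skipped: fewer than 3 complete domains")
    }
  }

  if ("introns" %in% config$stages) {
    if (!is.null(config$gff3)) {
      note("stage introns")
      models <- tryCatch(parse_gff3(config$gff3),
                         error = function(e) stop("stage introns: ",
                                                  conditionMessage(e)))
      profiles <- intron_profiles(models)
      emit(profiles, "intron_profiles.tsv")
      if (!is.null(catalog)) {
        gi <- summarize_group_introns(profiles, catalog)
        emit(gi$summary, "group_introns.tsv")
      }
      res$introns <- profiles
    } else {
      note("stage introns skipped: no GFF3 supplied")
    }
  }

  if ("motifs" %in% config$stages) {
    if (!is.null(config$motif_file) && !is.null(hits)) {
      note("stage motifs")
      models <- read_motif_models(config$motif_file)
      occ <- do.call(rbind, lapply(models, scan_motif, records = records,
                                   hits = hits))
      emit(occ, "motif_occurrences.tsv")
      if (!is.null(catalog)) {
        sharing <- motif_sharing(catalog, occ,
                                 min_fraction = config$sharing_fraction)
        emit(as.data.frame(sharing), "motif_sharing.tsv")
      }
      res$motifs <- occ
    } else {
      note("stage motifs skipped: no motif file supplied")
    }
  }
  invisible(res)
}

#' Read a code-to-legacy-name alias map
#'
#' @param path Two-column TSV (code, legacy name), no header.
#' @return Named character vector.
#' @export
read_alias_map <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  stats::setNames(df[[2]], df[[1]])
}
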