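# End-to-end orchestration: scan -> statistics -> feature context ->
# similarity -> clustering/PCA, with deterministic file outputs and a
# machine-readable run manifest.  Progress goes to stderr via message();
# reports go to files only.

#' Pipeline run configuration
#'
#' Defaults equal the standard scan parameters (arms 6-60 bp, spacer
#' 0-10 bp, one mismatch, 100 bp neighborhoods, Levenshtein radius 2).
#'
#' @param fasta path to the genome FASTA file.
#' @param features optional path to an annotation file (NCBI feature table
#'   or GFF3).
#' @param manifest optional path to a genome-to-group manifest TSV.
#' @param out_dir output directory for reports.
#' @param params an [ir_params()].
#' @param flank_bp feature neighborhood width (bp).
#' @param similarity_max_dist Levenshtein inclusion radius.
#' @param top_k top arm sequences per length in the similarity report.
#' @param similarity_arm_lens arm lengths reported in the similarity
#'   table.
#' @param pca_scale unit-scale columns before PCA.
#' @return list of class `run_config`.
#' @export
run_config <- function(fasta, features = NULL, manifest = NULL,
                       out_dir = tempfile("sirscan_run"),
                       params = ir_params(), flank_bp = 100L,
                       similarity_max_dist = 2L, top_k = 5L,
                       similarity_arm_lens = c(6L, 8L, 10L, 12L, 15L, 22L, 27L),
                       pca_scale = TRUE) {
  structure(list(fasta = fasta, features = features, manifest = manifest,
                 out_dir = out_dir, params = params,
                 flank_bp = as.integer(flank_bp),
                 similarity_max_dist = as.integer(similarity_max_dist),
                 top_k = as.integer(top_k),
                 similarity_arm_lens = as.integer(similarity_arm_lens),
                 pca_scale = isTRUE(pca_scale)),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys mirror [run_config()]; scan parameters use
#' `min_arm`, `max_arm`, `max_spacer`, `max_mismatch`.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  params <- ir_params(min_arm = y$min_arm %||% 6L,
                      max_arm = y$max_arm %||% 60L,
                      max_spacer = y$max_spacer %||% 10L,
                      max_mismatch = y$max_mismatch %||% 1L)
  run_config(fasta = y$fasta, features = y$features,
             manifest = y$manifest,
             out_dir = y$out_dir %||% tempfile("sirscan_run"),
             params = params,
             flank_bp = y$flank_bp %||% 100L,
             similarity_max_dist = y$similarity_max_dist %||% 2L,
             top_k = y$top_k %||% 5L,
             pca_scale = y$pca_scale %||% TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

scan_header <- function(config) {
  p <- config$params
  sprintf("# sirscan min_arm=%d max_arm=%d max_spacer=%d max_mismatch=%d flank=%d",
          p$min_arm, p$max_arm, p$max_spacer, p$max_mismatch,
          config$flank_bp)
}

#' Scan every genome of a FASTA file and write hit lists
#'
#' Writes `<id>.hits.tsv` and `<id>.hits.bed` per genome plus a pooled
#' `hits.tsv`; logs genome count, bp and hit count to stderr.  Outputs are
#' deterministic: rerunning on the same inputs reproduces them byte for
#' byte.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with `records` and `hits` (pooled
#'   data.frame).
#' @export
run_scan <- function(config) {
  if (!file.exists(config$fasta))
    stop("cannot read FASTA '", config$fasta, "'", call. = FALSE)
  records <- read_fasta(config$fasta)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hit_list <- lapply(records, find_irs, params = config$params)
  for (i in seq_along(records)) {
    id <- records[[i]]$id
    write_hits_tsv(hit_list[[i]],
                   file.path(config$out_dir, paste0(id, ".hits.tsv")))
    write_hits_bed(hit_list[[i]],
                   file.path(config$out_dir, paste0(id, ".hits.bed")))
  }
  hits <- do.call(rbind, hit_list)
  rownames(hits) <- NULL
  write_hits_tsv(hits, file.path(config$out_dir, "hits.tsv"))
  message(sprintf("scan: %d genome(s), %d bp, %d S-IR hit(s)",
                  length(records),
                  sum(vapply(records, `[[`, numeric(1), "length")),
                  nrow(hits)))
  invisible(list(records = records, hits = hits))
}

#' Run the full pipeline and write the report bundle
#'
#' Stages: scan, per-genome and per-group length statistics, dataset
#' length table, feature-context counts and gene-baseline enrichment
#' (skipped without annotations), arm-abundance/similarity report, group
#' Ward.D2 dendrogram (Newick) and per-group PCA score tables (multi-
#' member groups only).  A `run_manifest.json` with parameters and input
#' MD5 hashes accompanies the bundle.  Group-level stages are skipped with
#' a warning when no manifest is supplied.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the computed objects (`records`,
#'   `hits`, `profiles`, `groups`, `context`, `table1`).
#' @export
run_all <- function(config) {
  scan <- run_scan(config)
  records <- scan$records
  hits <- scan$hits
  out <- config$out_dir

  profiles <- lapply(records, function(r)
    profile_genome(hits[hits$genome_id == r$id, ], r, config$params))
  write_profiles_tsv(profiles, file.path(out, "genome_profiles.tsv"))
  t1 <- table1_report(profiles)
  write.table(t1, file.path(out, "length_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  groups <- NULL
  if (!is.null(config$manifest)) {
    manifest <- read_manifest(config$manifest)
    for (r in records) if (r$id %in% names(manifest))
      r$group <- manifest[[r$id]]
    labels <- manifest[vapply(records, `[[`, "", "id")]
    by_group <- split(seq_along(records), labels)
    groups <- lapply(names(by_group), function(g) {
      idx <- by_group[[g]]
      aggregate_group(profiles[idx], records[idx], g)
    })
    names(groups) <- names(by_group)
    write.table(do.call(rbind, lapply(groups, `[[`, "summary")),
                file.path(out, "group_summary.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_profiles_tsv(lapply(groups, `[[`, "profile"),
                       file.path(out, "group_profiles.tsv"))
    if (length(groups) >= 2L) {
      gm <- profile_matrix(lapply(groups, `[[`, "profile"))
      writeLines(to_newick(ward_cluster(gm)),
                 file.path(out, "group_dendrogram.nwk"))
    }
    for (g in names(by_group)) {
      idx <- by_group[[g]]
      if (length(idx) < 3L) next
      pm <- profile_matrix(profiles[idx])
      keep <- apply(pm, 2L, var) > 0
      if (sum(keep) < 2L) next
      fit <- pca(pm[, keep, drop = FALSE], scale. = config$pca_scale)
      write_pca_tsv(fit, file.path(out, paste0("pca_", g)))
    }
  } else {
    warning("no group manifest: group statistics, dendrogram and PCA skipped",
            call. = FALSE)
  }

  context <- NULL
  if (!is.null(config$features)) {
    lens <- vapply(records, `[[`, numeric(1), "length")
    names(lens) <- vapply(records, `[[`, "", "id")
    feats <- read_feature_table(config$features, genome_lengths = lens)
    context <- enrichment(context_counts(hits, feats, lens,
                                         flank = config$flank_bp))
    write_context_tsv(context, file.path(out, "feature_context.tsv"))
  }

  write_similarity_tsv(hits, config$similarity_arm_lens,
                       file.path(out, "similarity.tsv"),
                       top_k = config$top_k,
                       max_dist = config$similarity_max_dist)

  inputs <- Filter(Negate(is.null),
                   list(fasta = config$fasta, features = config$features,
                        manifest = config$manifest))
  manifest_json <- list(
    parameters = c(unclass(config$params),
                   list(flank_bp = config$flank_bp,
                        similarity_max_dist = config$similarity_max_dist,
                        top_k = config$top_k,
                        pca_scale = config$pca_scale)),
    inputs = lapply(inputs, function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    n_genomes = length(records),
    n_hits = nrow(hits))
  jsonlite::write_json(manifest_json,
                       file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  message("run_all: reports written to ", out)
  invisible(list(records = records, hits = hits, profiles = profiles,
                 groups = groups, context = context, table1 = t1))
}
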