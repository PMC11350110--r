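# End-to-end orchestration: simulate (or load) a strain panel, survey it
# for the reference cluster, profile flanks, screen %GC, build trees and
# write one reproducible report bundle. A single seed drives every
# stochastic stage through derived substreams.

#' Build and validate a run configuration
#'
#' @param panel A `bgc_panel` from [simulate_panel()], or NULL to load a
#'   panel previously written with [write_panel()] from `input_dir`.
#' @param input_dir Directory holding `genomes/`, `markers.fasta`,
#'   `cluster_template.json`, `taxa.tsv` (as written by [write_panel()]).
#' @param out_dir Output directory for the report bundle.
#' @param min_cluster_identity Identity floor as a fraction in (0, 1].
#' @param min_gene_coverage Per-gene coverage floor, fraction in (0, 1].
#' @param flank_length Flank length in bp.
#' @param homolog_identity Flank homolog-grouping cutoff, percent.
#' @param gc_flag_threshold %GC anomaly flag threshold, points.
#' @param bootstrap_reps Bootstrap replicates for tree supports.
#' @param seed Integer master seed.
#' @return A validated `run_config`.
#' @export
run_config <- function(panel = NULL, input_dir = NULL, out_dir,
                       min_cluster_identity = 0.40,
                       min_gene_coverage = 0.5,
                       flank_length = 5000L,
                       homolog_identity = 30,
                       gc_flag_threshold = 5.0,
                       bootstrap_reps = 100L,
                       seed = 1L) {
  if (is.null(panel) && is.null(input_dir)) {
    stop("supply a simulated panel or an input_dir")
  }
  if (!(min_cluster_identity > 0 && min_cluster_identity <= 1)) {
    stop("min_cluster_identity must be a fraction in (0, 1]")
  }
  if (!(min_gene_coverage > 0 && min_gene_coverage <= 1)) {
    stop("min_gene_coverage must be a fraction in (0, 1]")
  }
  stopifnot(flank_length > 0, homolog_identity >= 0,
            homolog_identity <= 100, gc_flag_threshold >= 0,
            bootstrap_reps >= 1)
  structure(
    list(panel = panel, input_dir = input_dir, out_dir = out_dir,
         min_cluster_identity = min_cluster_identity,
         min_gene_coverage = min_gene_coverage,
         flank_length = as.integer(flank_length),
         homolog_identity = homolog_identity,
         gc_flag_threshold = gc_flag_threshold,
         bootstrap_reps = as.integer(bootstrap_reps),
         seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()] (minus `panel`).
#'
#' @param path YAML path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

load_panel_inputs <- function(input_dir) {
  gdir <- file.path(input_dir, "genomes")
  files <- sort(list.files(gdir, pattern = "\\.fasta$", full.names = TRUE))
  if (length(files) == 0) stop("no genome FASTAs under ", gdir)
  genomes <- list()
  for (f in files) {
    id <- sub("\\.fasta$", "", basename(f))
    contigs <- read_fasta(f)
    names(contigs) <- sub("^[^|]*\\|", "", names(contigs))
    genomes[[id]] <- genome_record(id, contigs)
  }
  taxa_df <- utils::read.table(file.path(input_dir, "taxa.tsv"),
                               header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
  markers_path <- file.path(input_dir, "markers.fasta")
  list(genomes = genomes,
       taxa = stats::setNames(taxa_df$genus, taxa_df$strain),
       markers = if (file.exists(markers_path)) read_fasta(markers_path),
       template = read_cluster_definition(
         file.path(input_dir, "cluster_template.json")))
}

# Cluster sequences of accepted single-contig hits, template orientation.
cluster_seqs_from_hits <- function(genomes, hits) {
  acc <- hits[hits$accepted & !hits$cross_contig, , drop = FALSE]
  seqs <- stats::setNames(vapply(seq_len(nrow(acc)), function(i) {
    h <- acc[i, ]
    s <- substr(genomes[[h$strain]]$contigs[[h$contig]],
                h$start + 1L, h$end)
    if (h$strand == "-") s <- revcomp(s)
    s
  }, character(1)), acc$strain)
  seqs
}

#' Run the full survey pipeline
#'
#' Stages: survey -> %GC -> flanks -> phylogenetics -> report. Outputs
#' under `config$out_dir`: `hits.tsv`, `prevalence.tsv`, `hits.gff3`,
#' `gc.tsv`, `flank_groups.tsv`, `flank_conservation.tsv`,
#' `interrupted_genes.tsv`, `cluster_tree.nwk`, `species_tree.nwk`,
#' `congruence.json` and `manifest.json` (tool version, config hash,
#' seed). Rerunning with the same config reproduces identical content.
#'
#' @param config A [run_config()].
#' @return Invisible list with the in-memory results of every stage.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$panel)) {
    panel <- config$panel
    genomes <- panel$genomes
    taxa <- vapply(names(genomes), function(s) {
      unname(panel$genus_map[[sub("_clone[0-9]+$", "", s)]])
    }, character(1))
    markers <- panel$markers
    template <- panel$template
  } else {
    inputs <- load_panel_inputs(config$input_dir)
    genomes <- inputs$genomes
    taxa <- inputs$taxa
    markers <- inputs$markers
    template <- inputs$template
    panel <- NULL
  }

  params <- survey_params(
    min_cluster_identity = 100 * config$min_cluster_identity,
    min_gene_coverage = config$min_gene_coverage)

  sv <- survey_panel(genomes, template, taxa, params, out_dir = out)
  acc <- sv$hits[sv$hits$accepted & !sv$hits$cross_contig, , drop = FALSE]

  gc_tbl <- if (nrow(acc) > 0) {
    gc_report(acc, genomes, flag_threshold = config$gc_flag_threshold)
  } else {
    data.frame(cluster = character(0), strain = character(0),
               cluster_gc = numeric(0), replicon_gc = numeric(0),
               delta = numeric(0), hgt_flag = logical(0),
               direction = character(0))
  }
  utils::write.table(gc_tbl, file.path(out, "gc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  flank_res <- NULL
  if (nrow(acc) >= 2) {
    profiles <- lapply(seq_len(nrow(acc)), function(i) {
      h <- acc[i, ]
      flank_profile(genomes[[h$strain]], h$contig, h$start, h$end,
                    h$strand, length = config$flank_length,
                    strain = h$strain)
    })
    flank_res <- conservation_matrix(profiles,
                                     min_identity = config$homolog_identity)
    utils::write.table(flank_res$groups,
                       file.path(out, "flank_groups.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(strain = rownames(flank_res$jaccard),
                 round(flank_res$jaccard, 4), check.names = FALSE),
      file.path(out, "flank_conservation.tsv"), sep = "\t",
      quote = FALSE, row.names = FALSE)
    mge <- do.call(rbind, lapply(profiles, function(p) {
      if (nrow(p$orfs) == 0) return(NULL)
      fl <- flag_mobile_elements(p$orfs,
                                 reference = mge_reference_proteins())
      if (!any(fl)) return(NULL)
      data.frame(strain = p$strain, orf_id = p$orfs$orf_id[fl])
    }))
    if (!is.null(mge)) {
      utils::write.table(mge, file.path(out, "mge_flags.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    ref_prots <- stats::setNames(vapply(template$genes$gene, function(g) {
      sub("\\*$", "", translate_dna(cluster_gene_seq(template, g)))
    }, character(1)), template$genes$gene)
    interrupted <- do.call(rbind, lapply(seq_len(nrow(acc)), function(i) {
      h <- acc[i, ]
      cl_seq <- substr(genomes[[h$strain]]$contigs[[h$contig]],
                       h$start + 1L, h$end)
      if (h$strand == "-") cl_seq <- revcomp(cl_seq)
      cand <- detect_interrupted_genes(
        predict_orfs(cl_seq, min_length = 60L), ref_prots, seq = cl_seq)
      if (nrow(cand) == 0) return(NULL)
      cbind(strain = h$strain, cand)
    }))
    if (is.null(interrupted)) interrupted <- cbind(strain = character(0),
                                                   empty_interrupted())
    utils::write.table(interrupted,
                       file.path(out, "interrupted_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  phylo_res <- NULL
  cl_seqs <- cluster_seqs_from_hits(genomes, sv$hits)
  if (length(cl_seqs) >= 4 && !is.null(markers)) {
    cl_msa <- build_msa(cl_seqs)
    cl_tree <- bootstrap_support(cl_msa, n_reps = config$bootstrap_reps,
                                 seed = derive_seed(config$seed, "boot_cl"))
    mk <- markers[names(cl_seqs)]
    mk_msa <- build_msa(mk)
    sp_tree <- bootstrap_support(mk_msa, n_reps = config$bootstrap_reps,
                                 seed = derive_seed(config$seed, "boot_sp"))
    write_newick(cl_tree, file.path(out, "cluster_tree.nwk"))
    write_newick(sp_tree, file.path(out, "species_tree.nwk"))
    genus_map <- stats::setNames(taxa[names(cl_seqs)], names(cl_seqs))
    cong <- congruence_report(cl_tree, sp_tree, genus_map)
    jsonlite::write_json(
      list(rf = cong$rf, max_rf = cong$max_rf,
           normalized_rf = cong$normalized_rf, n_shared = cong$n_shared,
           monophyly = cong$monophyly, displaced = cong$displaced),
      file.path(out, "congruence.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    phylo_res <- list(cluster_tree = cl_tree, species_tree = sp_tree,
                      congruence = cong)
  }

  # hash the analytic parameters only: where the inputs/outputs live on
  # disk does not change what was computed
  cfg_for_hash <- config
  cfg_for_hash$panel <- NULL
  cfg_for_hash$out_dir <- NULL
  cfg_for_hash$input_dir <- NULL
  manifest <- list(
    tool = "bgcsurvey",
    version = as.character(utils::packageVersion("bgcsurvey")),
    seed = config$seed,
    config_hash = digest_hex(paste(deparse(cfg_for_hash), collapse = "")),
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  invisible(list(survey = sv, gc = gc_tbl, flanks = flank_res,
                 phylo = phylo_res, manifest = manifest))
}
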