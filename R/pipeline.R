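`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline run configuration (YAML or JSON)
#'
#' @param path Config file path.
#' @return Named list (`pv_runconfig`).
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validate_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg Named list to validate / default-fill.
#' @export
validate_run_config <- function(cfg) {
  stopifnot(is.list(cfg))
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$reference <- cfg$reference %||% list(length = 1e5, gc = 0.35)
  cfg$pool <- cfg$pool %||% list(n_haplotypes = 10L)
  cfg$sim <- cfg$sim %||% list()
  cfg$caller <- cfg$caller %||% list()
  cfg$filters <- cfg$filters %||% list()
  cfg$sv <- cfg$sv %||% list(min_pairs = 4L)
  cfg$annotate <- cfg$annotate %||% list(promoter_window = 150L)
  cfg$evaluate <- cfg$evaluate %||% list(af_tolerance = 0.05)
  structure(cfg, class = c("pv_runconfig", "list"))
}

caller_from_config <- function(cfg)
  do.call(caller_config, cfg$caller %||% list())

filter_from_config <- function(cfg)
  do.call(filter_config, cfg$filters %||% list())

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE), tf)
  unname(tools::md5sum(tf))
}

write_provenance <- function(stage, cfg, outdir) {
  prov <- list(stage = stage, seed = cfg$seed,
               poolvar_version = as.character(packageVersion("poolvar")),
               config_md5 = config_hash(cfg), config = unclass(cfg),
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(prov, file.path(outdir,
                                       paste0(stage, ".provenance.json")),
                       auto_unbox = TRUE, pretty = TRUE)
}

need_file <- function(path, what) {
  if (is.null(path) || !file.exists(path))
    stop("missing ", what, ": ", path %||% "(not configured)", call. = FALSE)
  path
}

pipeline_reference <- function(cfg, outdir) {
  fa <- cfg$reference$fasta %||% file.path(outdir, "reference.fasta")
  if (file.exists(fa)) return(read_reference(fa))
  ref <- generate_reference(1L, as.integer(cfg$reference$length %||% 1e5),
                            cfg$reference$gc %||% 0.35,
                            seed = cfg$reference$seed %||% cfg$seed)
  write_reference(ref, fa)
  ref
}

pipeline_variants <- function(cfg) {
  v <- cfg$pool$variants
  if (is.null(v)) return(NULL)
  if (is.character(v)) {
    tv <- read.table(v, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    return(planted_variant(tv$contig, tv$pos, tv$kind, tv$ref, tv$alt,
                           tv$true_freq %||% tv$freq))
  }
  if (is.data.frame(v))
    return(planted_variant(v$contig, v$pos, v$kind,
                           v$ref %||% NA_character_, v$alt, v$freq))
  do.call(rbind, lapply(v, function(x)
    planted_variant(x$contig %||% "contig01", x$pos, x$kind %||% "snp",
                    x$ref %||% NA_character_, x$alt, x$freq)))
}

#' Run one pipeline stage (or the whole chain)
#'
#' Subcommands: `simulate`, `pileup`, `call`, `sv`, `filter`, `annotate`,
#' `evaluate`, `all`. Each stage writes its outputs plus a provenance
#' block (stage, seed, package version, config hash, config echo) into
#' `outdir`; `all` chains them in order. Stages communicate through files
#' in `outdir` (`reference.fasta`, `truth.sam`, `pileup.rds`, ...), so
#' reruns are idempotent and no stage mutates another's outputs.
#'
#' @param subcommand Stage name.
#' @param config A `pv_runconfig` (or path to a YAML/JSON config).
#' @param outdir Output directory (created if needed).
#' @return Invisible list of artifact paths produced by the stage.
#' @export
pv_run <- function(subcommand, config, outdir = NULL) {
  sub <- match.arg(subcommand, c("simulate", "pileup", "call", "sv",
                                 "filter", "annotate", "evaluate", "all"))
  cfg <- if (is.character(config)) read_run_config(config)
  else validate_run_config(config)
  outdir <- outdir %||% cfg$outdir %||% "."
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (sub == "all") {
    arts <- list()
    for (s in c("simulate", "pileup", "call", "sv", "filter", "annotate",
                "evaluate")) {
      if (s == "annotate" && is.null(cfg$annotate$gff)) next
      arts[[s]] <- pv_run(s, cfg, outdir)
    }
    return(invisible(arts))
  }
  paths <- list()
  if (sub == "simulate") {
    ref <- pipeline_reference(cfg, outdir)
    vars <- pipeline_variants(cfg)
    pool <- build_pool(ref, as.integer(cfg$pool$n_haplotypes %||% 10L),
                       vars, seed = cfg$seed + 1L)
    sim_args <- cfg$sim[setdiff(names(cfg$sim), "artifacts")] %||% list()
    sim_args$seed <- cfg$seed + 2L
    sim_args$artifact_spec <- cfg$sim$artifacts %||% list()
    rs <- simulate_reads(pool, do.call(simulation_config, sim_args))
    paths$fastq <- write_fastq(rs, file.path(outdir, "reads_R1.fastq"),
                               file.path(outdir, "reads_R2.fastq"))
    paths$sam <- write_sam(rs, file.path(outdir, "truth.sam"))
    paths$truth <- write_truth(rs, file.path(outdir, "truth.tsv"))
    saveRDS(rs$alignments, file.path(outdir, "alignments.rds"))
  } else if (sub == "pileup") {
    ref <- read_reference(need_file(
      cfg$inputs$reference_fasta %||% file.path(outdir, "reference.fasta"),
      "reference FASTA"))
    aln_rds <- file.path(outdir, "alignments.rds")
    aln <- if (file.exists(aln_rds)) readRDS(aln_rds)
    else read_alignments(need_file(
      cfg$inputs$alignments %||% file.path(outdir, "truth.sam"),
      "alignments (SAM/BAM)"))
    pu <- build_pileup(aln, ref,
                       cfg$pileup$min_mapping_quality %||% 20L,
                       cfg$pileup$min_base_quality %||% 20L)
    saveRDS(pu, file.path(outdir, "pileup.rds"))
    paths$pileup <- file.path(outdir, "pileup.rds")
  } else if (sub == "call") {
    pu <- readRDS(need_file(file.path(outdir, "pileup.rds"),
                            "pileup (run the pileup stage first)"))
    calls <- call_variants(pu, caller_from_config(cfg))
    saveRDS(calls, file.path(outdir, "calls.rds"))
    paths$vcf <- write_vcf(calls, file.path(outdir, "calls.vcf"),
                           pu$reference, config_echo = cfg$caller)
  } else if (sub == "sv") {
    pu <- readRDS(need_file(file.path(outdir, "pileup.rds"), "pileup"))
    aln_rds <- file.path(outdir, "alignments.rds")
    aln <- if (file.exists(aln_rds)) readRDS(aln_rds)
    else read_alignments(need_file(
      cfg$inputs$alignments %||% file.path(outdir, "truth.sam"),
      "alignments (SAM/BAM)"))
    svs <- find_svs(aln, pu, as.integer(cfg$sv$min_pairs %||% 4L))
    saveRDS(svs, file.path(outdir, "sv.rds"))
    paths$bedpe <- write_bedpe(svs, file.path(outdir, "sv.bedpe"))
  } else if (sub == "filter") {
    pu <- readRDS(need_file(file.path(outdir, "pileup.rds"), "pileup"))
    calls <- readRDS(need_file(file.path(outdir, "calls.rds"), "calls"))
    svp <- file.path(outdir, "sv.rds")
    svs <- if (file.exists(svp)) readRDS(svp) else NULL
    founder <- if (!is.null(cfg$founder$calls))
      read_founder_calls(need_file(cfg$founder$calls, "founder calls"))
    calls <- apply_filters(calls, pu, filter_from_config(cfg), svs, founder)
    saveRDS(calls, file.path(outdir, "filtered.rds"))
    paths$vcf <- write_vcf(calls, file.path(outdir, "filtered.vcf"),
                           pu$reference, config_echo = cfg$filters)
    paths$tsv <- write_calls_tsv(calls, file.path(outdir, "filtered.tsv"))
  } else if (sub == "annotate") {
    fp <- file.path(outdir, "filtered.rds")
    calls <- readRDS(need_file(if (file.exists(fp)) fp
                               else file.path(outdir, "calls.rds"), "calls"))
    gm <- read_gene_models(need_file(cfg$annotate$gff, "gene models (GFF3)"))
    ref <- read_reference(need_file(
      cfg$inputs$reference_fasta %||% file.path(outdir, "reference.fasta"),
      "reference FASTA"))
    calls <- annotate_calls(calls, gm, ref,
                            as.integer(cfg$annotate$promoter_window %||% 150L))
    paths$tsv <- write_calls_tsv(calls, file.path(outdir, "annotated.tsv"))
    paths$vcf <- write_vcf(calls, file.path(outdir, "annotated.vcf"))
  } else if (sub == "evaluate") {
    fp <- file.path(outdir, "filtered.rds")
    calls <- readRDS(need_file(if (file.exists(fp)) fp
                               else file.path(outdir, "calls.rds"), "calls"))
    truth <- read.table(need_file(
      cfg$inputs$truth %||% file.path(outdir, "truth.tsv"), "truth table"),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    ref <- read_reference(need_file(
      cfg$inputs$reference_fasta %||% file.path(outdir, "reference.fasta"),
      "reference FASTA"))
    rep <- eval_report(calls, truth, sum(nchar(ref$seq)),
                       cfg$evaluate$af_tolerance %||% 0.05)
    paths$json <- write_eval_json(rep, file.path(outdir, "eval.json"))
    write.table(rep$power_by_frequency,
                file.path(outdir, "power_by_frequency.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_provenance(sub, cfg, outdir)
  invisible(paths)
}

#' Command-line entry point
#'
#' `poolvar <subcommand> --config cfg.yaml --outdir out [--seed N]`;
#' installed as `exec/poolvar` (run with `Rscript`).
#'
#' @param args Character vector of CLI arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
pv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L || args[1] %in% c("-h", "--help")) {
    cat("usage: poolvar <simulate|pileup|call|sv|filter|annotate|evaluate|all>",
        "--config <yaml|json> [--outdir DIR] [--seed N]\n")
    return(invisible(0L))
  }
  sub <- args[1]
  parser <- optparse::OptionParser(option_list = list(
    optparse::make_option(c("-c", "--config"), type = "character"),
    optparse::make_option(c("-o", "--outdir"), type = "character",
                          default = NULL),
    optparse::make_option(c("-s", "--seed"), type = "integer",
                          default = NULL)))
  opt <- optparse::parse_args(parser, args = args[-1])
  if (is.null(opt$config)) stop("--config is required")
  cfg <- read_run_config(opt$config)
  if (!is.null(opt$seed)) cfg$seed <- opt$seed
  pv_run(sub, cfg, outdir = opt$outdir)
  invisible(0L)
}
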