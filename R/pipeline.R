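#' Read and validate a run configuration
#'
#' A single YAML file drives every stage; unknown keys are rejected so typos
#' fail loudly.  Recognised top-level keys: `seed`, `outdir`, `reference`,
#' `assemblies`, `taxon_priority`, `efficiency_exclude`, and per-stage blocks
#' `panel`, `discovery`, `design`, `capture` whose entries override the
#' corresponding parameter constructors' defaults.
#'
#' @param path YAML config file.
#' @return a named list with resolved parameter objects.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("seed", "outdir", "reference", "assemblies", "taxon_priority",
             "efficiency_exclude", "panel", "discovery", "design", "capture")
  bad <- setdiff(names(raw), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  check_args <- function(block, fn, name) {
    if (is.null(block)) return(list())
    extra <- setdiff(names(block), names(formals(fn)))
    if (length(extra)) stop("unknown ", name, " keys: ",
                            paste(extra, collapse = ", "))
    block
  }
  list(seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed),
       outdir = if (is.null(raw$outdir)) "uceprobe_run" else raw$outdir,
       reference = raw$reference,
       assemblies = raw$assemblies,
       taxon_priority = as.character(raw$taxon_priority %||% character()),
       efficiency_exclude = as.character(raw$efficiency_exclude %||% character()),
       panel = do.call(panel_params, check_args(raw$panel, panel_params, "panel")),
       discovery = do.call(discovery_params,
                           check_args(raw$discovery, discovery_params, "discovery")),
       design = do.call(design_params,
                        check_args(raw$design, design_params, "design")),
       capture = do.call(capture_params,
                         check_args(raw$capture, capture_params, "capture")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_counts_tsv <- function(counts, path) {
  df <- data.frame(stat = names(counts), value = unname(unlist(counts)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full design pipeline on a panel of assemblies
#'
#' Discovery, temporary-set design, final-locus selection and master-set
#' design, with a per-stage counts log.
#'
#' @param reference the reference [assembly].
#' @param others list of non-reference [assembly] objects.
#' @param dparams a [discovery_params()].
#' @param gparams a [design_params()].
#' @return list with `loci`, `temporary`, `final_loci`, `master`, `counts`.
#' @export
run_design <- function(reference, others, dparams = discovery_params(),
                       gparams = design_params()) {
  loci <- discover_loci(reference, others, dparams)
  temporary <- build_temporary_set(loci, reference, gparams)
  all_assemblies <- c(list(reference), others)
  final_loci <- select_final_loci(temporary, all_assemblies, gparams)
  master <- build_master_set(final_loci, loci, reference, all_assemblies,
                             gparams)
  counts <- c(attr(loci, "counts"),
              setNames(attr(temporary, "counts"),
                       paste0("temp_", names(attr(temporary, "counts")))),
              final_loci = length(final_loci),
              setNames(attr(master, "counts"),
                       paste0("master_", names(attr(master, "counts")))))
  list(loci = loci, temporary = temporary, final_loci = final_loci,
       master = master, counts = counts)
}

#' Run capture and summarise a probe set against a panel
#'
#' @param probes a `probe_set`.
#' @param assemblies list of [assembly] objects.
#' @param cparams a [capture_params()].
#' @param exclude taxa excluded from the mean efficiency.
#' @return list with `capture` (a `capture_table`), `efficiency`, `matrices`
#'   (from [occupancy_and_shared()], `NULL` when fewer than 2 taxa).
#' @export
run_capture <- function(probes, assemblies, cparams = capture_params(),
                        exclude = character()) {
  cap <- capture_panel(probes, assemblies, cparams)
  eff <- efficiency(cap, probes, exclude = exclude)
  mats <- if (ncol(cap$occupancy) >= 2)
    occupancy_and_shared(cap, cparams$min_taxa_per_locus) else NULL
  list(capture = cap, efficiency = eff, matrices = mats)
}

#' Run a configured end-to-end pipeline and write its outputs
#'
#' With no input FASTA files configured, a synthetic panel is generated from
#' the config's `panel` block and `seed`.  Outputs: locus TSV, probe FASTAs,
#' per-taxon capture FASTAs, occupancy and shared-locus matrices, per-taxon
#' summary TSV, a counts report, and a resolved-config YAML echo.
#'
#' @param config a list from [read_run_config()] (or compatible).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(config$reference)) {
    panel <- generate_panel(config$panel, seed = config$seed)
    reference <- panel$assemblies[[1]]
    others <- panel$assemblies[-1]
  } else {
    reference <- read_assembly(config$reference)
    others <- lapply(config$assemblies, read_assembly)
  }
  design <- run_design(reference, others, config$discovery, config$design)
  capture <- run_capture(design$master, c(list(reference), others),
                         config$capture, exclude = config$efficiency_exclude)

  write_locus_tsv(design$loci, file.path(config$outdir, "loci.tsv"))
  write_probe_fasta(design$temporary,
                    file.path(config$outdir, "temporary_probes.fasta"))
  write_probe_fasta(design$master,
                    file.path(config$outdir, "master_probes.fasta"))
  write_capture_fastas(capture$capture, file.path(config$outdir, "captured"))
  if (!is.null(capture$matrices)) {
    utils::write.table(capture$matrices$occupancy * 1L,
                       file.path(config$outdir, "occupancy.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(capture$matrices$shared,
                       file.path(config$outdir, "shared_loci.tsv"),
                       sep = "\t", quote = FALSE)
  }
  summ <- data.frame(taxon = names(capture$capture$counts),
                     n_loci = unname(capture$capture$counts),
                     efficiency = unname(capture$efficiency$per_taxon))
  utils::write.table(summ, file.path(config$outdir, "per_taxon_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_counts_tsv(c(design$counts,
                     mean_efficiency = capture$efficiency$mean),
                   file.path(config$outdir, "run_report.tsv"))
  cfg_echo <- config
  cfg_echo$panel <- unclass(cfg_echo$panel)
  cfg_echo$discovery <- unclass(cfg_echo$discovery)
  cfg_echo$design <- unclass(cfg_echo$design)
  cfg_echo$capture <- unclass(cfg_echo$capture)
  yaml::write_yaml(cfg_echo, file.path(config$outdir, "resolved_config.yaml"))
  invisible(config$outdir)
}
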