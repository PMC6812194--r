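.CONFIG_DEFAULTS <- list(
  core_size = 100000L,   # bases per core interval
  pad = NULL,            # overlap flank; default 2 * read_len
  read_len = 100L,       # declared read length (bases)
  workers = 1L,
  caller = "builtin",    # or "external"
  caller_template = NULL,
  min_depth = 4L,
  het_min = 0.2,
  hom_min = 0.8,
  err = 0.01,
  qual_cap = 255L,
  diff_threshold = 0.05,
  merge_short_final = FALSE,
  resume = FALSE,
  seed = 1L)

#' Load and validate the pipeline configuration
#'
#' Declarative YAML key/value file; unknown keys are refused rather than
#' silently ignored. Precedence is overrides (CLI flags) over file over
#' documented defaults. The pad must be at least the declared read length:
#' a shorter pad would leave reads at piece boundaries without full
#' alignment context and break the split-equals-unsplit guarantee.
#'
#' @param path Optional YAML config file.
#' @param overrides Named list of values overriding the file.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- .CONFIG_DEFAULTS
  from_file <- if (!is.null(path)) {
    x <- yaml::read_yaml(path)
    if (is.null(x)) list() else x
  } else list()
  for (src in list(from_file, overrides)) {
    unknown <- setdiff(names(src), names(.CONFIG_DEFAULTS))
    if (length(unknown))
      stop(sprintf("unknown configuration key(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    cfg[names(src)] <- src
  }
  if (is.null(cfg$pad)) cfg$pad <- 2L * as.integer(cfg$read_len)
  for (k in c("core_size", "pad", "read_len", "workers", "min_depth",
              "qual_cap", "seed"))
    cfg[[k]] <- as.integer(cfg[[k]])
  stopifnot(cfg$core_size >= 1, cfg$pad >= 0, cfg$read_len >= 1,
            cfg$workers >= 1)
  if (cfg$pad < cfg$read_len)
    stop(sprintf(
      "pad (%d) must be at least the read length (%d): the overlap kept around each piece must be longer than the sequencing reads",
      cfg$pad, cfg$read_len), call. = FALSE)
  if (identical(cfg$caller, "external") && is.null(cfg$caller_template))
    stop("caller \"external\" requires caller_template", call. = FALSE)
  cfg$caller_cfg <- caller_config(cfg$min_depth, cfg$het_min, cfg$hom_min,
                                  cfg$err, cfg$qual_cap)
  structure(cfg, class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE))
}

#' Run the whole scatter-gather pipeline
#'
#' End-to-end driver: split the reference into overlap-padded pieces,
#' partition each sample's sorted alignments per piece, run one calling
#' job per piece on the local concurrent backend, then lift, deduplicate
#' by core ownership, and merge into the final sorted VCF. All artifacts
#' land in a run directory; the run report (JSON) echoes the effective
#' configuration so a run can be reproduced exactly.
#'
#' @param reference Path to the reference FASTA.
#' @param alignments Named character vector: sample name -> sorted SAM
#'   path.
#' @param out_dir Run directory (created).
#' @param config A [pipeline_config()].
#' @return List: `vcf` (final VCF path), `variants` (`variant_set`),
#'   `table`, `partition` reports, `run_report`, `report_json`.
#' @export
run_pipeline <- function(reference, alignments, out_dir,
                         config = pipeline_config()) {
  if (is.null(names(alignments)) || any(!nzchar(names(alignments))))
    stop("alignments must be a named vector: sample -> SAM path",
         call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  ref <- .stage("split-ref", read_reference(reference))
  table <- .stage("split-ref", {
    tb <- build_piece_table(ref, config$core_size, config$pad,
                            merge_short_final = config$merge_short_final)
    write_piece_table(tb, file.path(out_dir, "piece-map.tsv"))
    tb
  })
  fastas <- .stage("split-ref",
                   write_piece_fastas(ref, table, file.path(out_dir, "pieces"),
                                      skip_existing = config$resume))

  reports <- .stage("split-bam", {
    missing <- alignments[!file.exists(alignments)]
    if (length(missing))
      stop(sprintf("alignment file(s) not found: %s",
                   paste(missing, collapse = ", ")))
    lapply(names(alignments), function(s)
      partition_alignments(alignments[[s]], table,
                           file.path(out_dir, "piece-alignments"),
                           sample = s, skip_existing = config$resume))
  })

  run_rep <- .stage("call", {
    action <- if (identical(config$caller, "builtin")) "builtin"
              else list(template = config$caller_template)
    manifest <- build_manifest(table, fastas, reports, action,
                               file.path(out_dir, "piece-vcfs"))
    write_manifest(manifest, file.path(out_dir, "manifest.json"))
    run_manifest(manifest, workers = config$workers,
                 config = config$caller_cfg, resume = config$resume,
                 log_dir = file.path(out_dir, "logs"))
  })
  .stage("call", stop_if_failed(run_rep))

  final_vcf <- file.path(out_dir, "final.vcf")
  merged <- .stage("merge", {
    manifest <- read_manifest(file.path(out_dir, "manifest.json"))
    vcfs <- stats::setNames(
      vapply(manifest$jobs, `[[`, "", "out_vcf"),
      vapply(manifest$jobs, `[[`, "", "piece_id"))
    merge_piece_vcfs(vcfs, table, out_vcf = final_vcf)
  })

  report_json <- file.path(out_dir, "run-report.json")
  cfg_echo <- unclass(config)
  cfg_echo$caller_cfg <- NULL
  jsonlite::write_json(list(
    config = cfg_echo,
    n_pieces = nrow(table$pieces),
    samples = names(alignments),
    partition = lapply(reports, function(r)
      r[c("sample", "total", "assigned", "unmapped", "unassignable")]),
    jobs = list(ok = run_rep$n_ok, failed = run_rep$n_failed,
                skipped = run_rep$n_skipped),
    n_variants = n_variants(merged),
    final_vcf = final_vcf),
    report_json, auto_unbox = TRUE, pretty = TRUE)

  list(vcf = final_vcf, variants = merged, table = table,
       partition = reports, run_report = run_rep,
       report_json = report_json)
}

#' Call variants without splitting (reference-run baseline)
#'
#' Runs the built-in caller over the whole reference and all samples at
#' once — the baseline the scatter-gather pipeline must reproduce
#' record-for-record.
#'
#' @param reference Path to the reference FASTA.
#' @param alignments Named character vector: sample -> sorted SAM path.
#' @param config A [caller_config()].
#' @param out_vcf Optional output VCF path.
#' @return A `variant_set`.
#' @export
call_unsplit <- function(reference, alignments, config = caller_config(),
                         out_vcf = NULL) {
  ref <- read_reference(reference)
  recs <- do.call(rbind, lapply(names(alignments), function(s)
    read_sam(alignments[[s]], sample = s)$records))
  vs <- call_builtin(stats::setNames(as.character(ref), names(ref)),
                     recs, config, samples = names(alignments))
  if (!is.null(out_vcf))
    write_vcf(vs, out_vcf, contigs = reference_lengths(ref))
  vs
}
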