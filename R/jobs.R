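#' Build a deterministic per-piece job manifest
#'
#' One calling job per genome piece, ordered by (chromosome rank, core
#' start). Each job binds the piece FASTA, one alignment file per sample,
#' and the output VCF path. The manifest is plain data and serializes to
#' JSON stably, so identical inputs always produce the identical manifest.
#'
#' @param table A `piece_table`.
#' @param piece_fastas Named character vector: piece id -> FASTA path
#'   (from [write_piece_fastas()]).
#' @param partition_reports List of `partition_report`s, one per sample,
#'   in the sample order the final VCF should use.
#' @param caller Either `"builtin"` or a list
#'   `list(template = "<cmd with {ref} {bams} {out}>")`.
#' @param out_dir Directory for per-piece VCFs.
#' @return A `job_manifest` object (list of job specs).
#' @export
build_manifest <- function(table, piece_fastas, partition_reports,
                           caller = "builtin", out_dir) {
  samples <- vapply(partition_reports, `[[`, "", "sample")
  if (anyDuplicated(samples))
    stop("duplicate sample names across partition reports", call. = FALSE)
  missing <- character(0)
  for (rep in partition_reports) {
    absent <- setdiff(table$pieces$piece_id, names(rep$paths))
    absent <- c(absent, names(rep$paths)[!file.exists(rep$paths)])
    if (length(absent))
      missing <- c(missing, sprintf("%s:%s", rep$sample, absent))
  }
  if (length(missing))
    stop(sprintf("missing piece alignment file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jobs <- lapply(seq_len(nrow(table$pieces)), function(i) {
    piece <- table$pieces[i, ]
    list(job_id = sprintf("job-%04d-%s", i, .safe_name(piece$piece_id)),
         piece_id = piece$piece_id,
         fasta = unname(piece_fastas[[piece$piece_id]]),
         # named list (not vector): survives JSON serialization with names
         alignments = as.list(stats::setNames(
           vapply(partition_reports, function(r)
             unname(r$paths[[piece$piece_id]]), ""),
           samples)),
         caller = caller,
         out_vcf = file.path(out_dir,
                             paste0(.safe_name(piece$piece_id), ".vcf")))
  })
  structure(list(jobs = jobs, samples = samples), class = "job_manifest")
}

#' @export
print.job_manifest <- function(x, ...) {
  cat(sprintf("job_manifest: %d job(s), %d sample(s)\n",
              length(x$jobs), length(x$samples)))
  invisible(x)
}

#' Serialize a manifest to JSON
#' @param manifest A `job_manifest`.
#' @param path Output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Read a manifest back from JSON
#' @param path Path written by [write_manifest()].
#' @return A `job_manifest`.
#' @export
read_manifest <- function(path) {
  raw <- jsonlite::read_json(path)
  structure(list(jobs = raw$jobs, samples = unlist(raw$samples)),
            class = "job_manifest")
}

# execute one job; returns list(status, seconds, log)
.run_job <- function(job, config, samples, resume = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  inputs <- c(job$fasta, unlist(job$alignments))
  if (resume && file.exists(job$out_vcf) &&
      all(file.exists(inputs)) &&
      file.mtime(job$out_vcf) >= max(file.mtime(inputs))) {
    return(list(status = "skipped", seconds = 0,
                log = sprintf("%s: output up to date", job$job_id)))
  }
  res <- tryCatch({
    if (identical(job$caller, "builtin")) {
      ref <- read_reference(job$fasta)
      recs <- do.call(rbind, lapply(samples, function(s)
        read_sam(job$alignments[[s]], sample = s)$records))
      vs <- call_builtin(stats::setNames(as.character(ref), names(ref)),
                         recs, config, samples = samples)
      write_vcf(vs, job$out_vcf,
                contigs = stats::setNames(nchar(ref[[1]]), names(ref)[1]))
      list(status = "ok",
           log = sprintf("%s: %d variant(s)", job$job_id, n_variants(vs)))
    } else {
      r <- run_external_caller(job$caller$template, job$fasta,
                               unname(unlist(job$alignments)), job$out_vcf)
      if (r$status != 0)
        list(status = "failed",
             log = sprintf("%s: exit %d\n%s", job$job_id, r$status,
                           paste(r$stderr_tail, collapse = "\n")))
      else list(status = "ok", log = sprintf("%s: external caller ok",
                                             job$job_id))
    }
  }, error = function(e)
    list(status = "failed",
         log = sprintf("%s: %s", job$job_id, conditionMessage(e))))
  res$seconds <- proc.time()[["elapsed"]] - t0
  res
}

#' Execute a job manifest on the local concurrent backend
#'
#' Runs every job; jobs communicate only through the filesystem (one VCF
#' per piece), so the set of output files is a pure function of the
#' manifest — identical for any `workers` value and completion order. On
#' failure the report marks the job and downstream merging must refuse to
#' run; with `keep_going = FALSE` this is the only failure policy, with
#' `keep_going = TRUE` all failures are collected first.
#'
#' @param manifest A `job_manifest`.
#' @param workers Number of concurrent workers (>= 1; forked processes).
#' @param config A [caller_config()] for built-in jobs.
#' @param resume Skip jobs whose output exists and is newer than all
#'   inputs.
#' @param log_dir Optional directory receiving one log file per job.
#' @return A `run_report`: per-job status/wall-time/log plus totals.
#' @export
run_manifest <- function(manifest, workers = 1L, config = caller_config(),
                         resume = FALSE, log_dir = NULL) {
  stopifnot(workers >= 1L)
  jobs <- manifest$jobs
  runner <- function(job) .run_job(job, config, manifest$samples, resume)
  results <- if (workers > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(jobs, runner, mc.cores = workers)
  else lapply(jobs, runner)
  for (i in seq_along(results))
    if (inherits(results[[i]], "try-error"))
      results[[i]] <- list(status = "failed", seconds = NA_real_,
                           log = as.character(results[[i]]))
  if (!is.null(log_dir)) {
    dir.create(log_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(jobs))
      writeLines(results[[i]]$log,
                 file.path(log_dir, paste0(jobs[[i]]$job_id, ".log")))
  }
  status <- vapply(results, `[[`, "", "status")
  report <- structure(list(
    job_id = vapply(jobs, `[[`, "", "job_id"),
    piece_id = vapply(jobs, `[[`, "", "piece_id"),
    status = status,
    seconds = vapply(results, `[[`, 0, "seconds"),
    log = vapply(results, `[[`, "", "log"),
    n_ok = sum(status == "ok"), n_failed = sum(status == "failed"),
    n_skipped = sum(status == "skipped")), class = "run_report")
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report: %d ok, %d failed, %d skipped (%.1fs total)\n",
              x$n_ok, x$n_failed, x$n_skipped, sum(x$seconds, na.rm = TRUE)))
  if (x$n_failed)
    cat("failed pieces:", paste(x$piece_id[x$status == "failed"],
                                collapse = ", "), "\n")
  invisible(x)
}

#' Refuse to proceed on failed jobs
#' @param report A `run_report`.
#' @export
stop_if_failed <- function(report) {
  if (report$n_failed > 0L)
    stop(sprintf("refusing to merge: %d job(s) failed (pieces: %s)",
                 report$n_failed,
                 paste(report$piece_id[report$status == "failed"],
                       collapse = ", ")), call. = FALSE)
  invisible(report)
}
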