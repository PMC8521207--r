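#' Run the full CEC processing pipeline
#'
#' Orchestrates parse -> compute -> QC -> correction -> report over one
#' assay run: joins plate grids with layouts, computes well-level CEC
#' under the requested referencing method(s), aggregates triplicates with
#' CV-based rejection, applies the four-control plate correction, and
#' assembles the performance report. Deterministic given its inputs:
#' rerunning on the same run yields identical outputs (the JSON report
#' carries a timestamp field as its only varying element).
#'
#' @param input A `cec_run` from [simulate_run()], a manifest YAML path,
#'   or a directory containing `manifest.yaml`.
#' @param method `"both"` (default), `"per_well"` or `"t0"`.
#' @param qc A [qc_config()]; its `correction_enabled` switch controls
#'   the plate correction.
#' @param expected Optional named reference CEC values for the correction
#'   controls (see [plate_corrections()]).
#' @param out_dir Optional output directory; when given, writes
#'   `wells.csv`, `samples.csv`, `plates.csv` and `report.json`.
#' @return List of class `cec_pipeline`: `wells` (a `cec_well_table`),
#'   `samples` (per-method sample tables, corrected where enabled),
#'   `corrections` (per-method [plate_corrections()] plate tables),
#'   `report` (a [performance_report()]), `counts`.
#' @export
run_pipeline <- function(input, method = c("both", "per_well", "t0"),
                         qc = qc_config(), expected = NULL, out_dir = NULL) {
  method <- match.arg(method)

  if (inherits(input, "cec_run")) {
    records <- run_records(input)
  } else if (is.character(input) && length(input) == 1) {
    path <- input
    if (dir.exists(path)) path <- file.path(path, "manifest.yaml")
    plates <- read_manifest(path)
    recs <- lapply(plates, function(p)
      join_layout(p$grids, p$layout, wells_per_sample = NULL))
    records <- do.call(rbind, c(recs, make.row.names = FALSE))
  } else stopf("input must be a cec_run or a manifest path")

  wt <- compute_wells(records, method = method,
                      t0_cv_max = qc$replicate_cv_max)

  methods <- if (method == "both") c("per_well", "t0") else method
  samples <- list(); corrections <- list()
  for (m in methods) {
    agg <- aggregate_samples(wt, method = m, cfg = qc)
    if (qc$correction_enabled &&
        any(agg$role == "correction_control" & !agg$rejected)) {
      pc <- plate_corrections(agg, expected = expected, cfg = qc)
      samples[[m]] <- pc$samples
      corrections[[m]] <- pc$plates
    } else {
      samples[[m]] <- agg
    }
  }

  report <- performance_report(per_well = samples$per_well,
                               t0 = samples$t0, cfg = qc)
  counts <- list(n_plates = nrow(wt$plates), n_wells = nrow(wt$wells),
                 n_samples = sum(samples[[1]]$role == "sample"))
  out <- structure(list(wells = wt, samples = samples,
                        corrections = corrections, report = report,
                        counts = counts, method = method),
                   class = "cec_pipeline")
  if (!is.null(out_dir)) write_pipeline(out, out_dir)
  out
}

#' @export
print.cec_pipeline <- function(x, ...) {
  cat(sprintf("<cec_pipeline> %d plate(s), %d wells, %d samples; method '%s'\n",
              x$counts$n_plates, x$counts$n_wells, x$counts$n_samples,
              x$method))
  print(x$report)
  invisible(x)
}

report_as_list <- function(report, counts, method) {
  num <- function(x) if (is.null(x)) NULL else unclass(x)
  perf <- lapply(report$methods, function(p) list(
    rejection = list(n_rejected = p$n_rejected, n_total = p$n_total,
                     rate_pct = p$rejection_rate),
    intra_assay_cv_pct = p$intra_assay_cv,
    interassay = p$interassay))
  list(tool = "cecflux",
       version = as.character(utils::packageVersion("cecflux")),
       method = method,
       counts = counts,
       performance = perf,
       comparison = num(report$comparison))
}

write_pipeline <- function(x, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$wells$wells, file.path(out_dir, "wells.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(do.call(rbind, c(x$samples, make.row.names = FALSE)),
                   file.path(out_dir, "samples.csv"),
                   row.names = FALSE, na = "")
  plates <- x$wells$plates
  for (m in names(x$corrections)) {
    pc <- x$corrections[[m]]
    names(pc)[-1] <- paste0(names(pc)[-1], "_", m)
    plates <- merge(plates, pc, by = "plate_id", all.x = TRUE)
  }
  utils::write.csv(plates, file.path(out_dir, "plates.csv"),
                   row.names = FALSE, na = "")
  rep <- report_as_list(x$report, x$counts, x$method)
  rep$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(rep, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, na = "null")
  invisible(out_dir)
}
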