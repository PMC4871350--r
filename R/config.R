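#' Validate a run configuration file
#'
#' A run configuration (YAML or JSON) names the library scheme, the screens
#' with their input files and roles, and the analysis options. Screens may
#' enter either as raw FASTQ (to be extracted) or as previously extracted
#' count tables, so the selection step can be re-run under new roles without
#' touching the raw reads.
#'
#' Required structure:
#' \preformatted{
#' scheme: NEB-PhD7          # preset name, or a mapping with name/flank5/
#'                           # flank3/peptide_length/constraint/amber_as_gln
#' screens:
#'   - {id: REF,  counts: ref.counts.csv, role: reference}
#'   - {id: POS1, fastq: pos1.fastq.gz,   role: positive}
#'   - {id: NEG1, fastq: neg1.fastq.gz,   role: negative}
#' options:                  # all optional
#'   try_revcomp: false
#'   top_n: 40
#'   ubiquitous: false
#' }
#'
#' Exactly one reference and at least one positive screen are required (a
#' reference standard sequenced with every run is mandatory — it is the
#' denominator of the whole normalization); screen ids must be unique and
#' every referenced file must exist.
#'
#' @param path Path to the configuration file.
#' @return An object of class `run_config`: `scheme`, `screens`
#'   (data.frame id/path/type/role), `assignment`, `options`.
#' @export
validate_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration error: file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$screens) || length(cfg$screens) == 0L) {
    stop("configuration error: no screens defined", call. = FALSE)
  }
  scheme <- if (is.character(cfg$scheme)) {
    make_scheme(cfg$scheme)
  } else if (is.list(cfg$scheme)) {
    make_scheme(cfg$scheme$name %||% "custom", cfg$scheme$flank5,
                cfg$scheme$flank3, cfg$scheme$peptide_length,
                cfg$scheme$constraint %||% "NNK",
                cfg$scheme$amber_as_gln %||% TRUE,
                cfg$scheme$codon_filter)
  } else {
    stop("configuration error: 'scheme' must be a preset name or a mapping",
         call. = FALSE)
  }
  rows <- lapply(cfg$screens, function(s) {
    if (is.null(s$id) || is.null(s$role)) {
      stop("configuration error: every screen needs 'id' and 'role'",
           call. = FALSE)
    }
    if (!s$role %in% c("reference", "positive", "negative")) {
      stop("configuration error: unknown role '", s$role, "' for screen '",
           s$id, "'", call. = FALSE)
    }
    has_fastq <- !is.null(s$fastq)
    has_counts <- !is.null(s$counts)
    if (has_fastq == has_counts) {
      stop("configuration error: screen '", s$id,
           "' must give exactly one of 'fastq' or 'counts'", call. = FALSE)
    }
    p <- if (has_fastq) s$fastq else s$counts
    p <- file.path(dirname(path), p)
    if (!file.exists(p)) {
      stop("configuration error: input for screen '", s$id,
           "' not found: ", p, call. = FALSE)
    }
    data.frame(id = s$id, path = p,
               type = if (has_fastq) "fastq" else "counts", role = s$role)
  })
  screens <- do.call(rbind, rows)
  if (anyDuplicated(screens$id)) {
    stop("configuration error: duplicate screen_id '",
         screens$id[anyDuplicated(screens$id)], "'", call. = FALSE)
  }
  opts <- cfg$options %||% list()
  opts <- list(try_revcomp = isTRUE(opts$try_revcomp),
               top_n = opts$top_n %||% Inf,
               ubiquitous = isTRUE(opts$ubiquitous),
               heatmap = isTRUE(opts$heatmap))
  refs <- screens$id[screens$role == "reference"]
  if (length(refs) != 1L) {
    stop("configuration error: exactly one reference screen is required, got ",
         length(refs), call. = FALSE)
  }
  assignment <- role_assignment(refs,
                                screens$id[screens$role == "positive"],
                                screens$id[screens$role == "negative"],
                                allow_no_positives = opts$ubiquitous)
  structure(list(scheme = scheme, screens = screens, assignment = assignment,
                 options = opts),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full two-part workflow from a configuration
#'
#' Loads every screen (extracting FASTQ inputs with the configured scheme,
#' reading count-level inputs directly), writes per-screen count CSVs and
#' stats JSON under `out_dir`, normalizes against the reference, builds and
#' sorts the selectivity matrix, and writes `matrix.tsv`,
#' `matrix.imputed.tsv`, `report.json`, the replicate scatter TSV and a
#' manifest of the resolved configuration. Identical configuration and inputs
#' yield byte-identical outputs.
#'
#' @param config A [validate_config()] result, or a path to a config file.
#' @param out_dir Output directory (created if needed).
#' @return The sorted `selectivity_matrix`, invisibly; screen tables and
#'   normalized screens are attached as attributes `"tables"` and
#'   `"screens"`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tables <- list()
  for (i in seq_len(nrow(config$screens))) {
    sc <- config$screens[i, ]
    tab <- if (sc$type == "fastq") {
      process_screen(sc$path, config$scheme, sc$id,
                     try_revcomp = config$options$try_revcomp)
    } else {
      read_screen_table(sc$path)
    }
    tab$screen_id <- sc$id
    tables[[sc$id]] <- tab
    write_screen_table(tab, file.path(out_dir,
                                      paste0(gsub("[^A-Za-z0-9._-]", "_", sc$id),
                                             ".counts.csv")))
    jsonlite::write_json(tab$stats,
                         file.path(out_dir,
                                   paste0(gsub("[^A-Za-z0-9._-]", "_", sc$id),
                                          ".stats.json")),
                         auto_unbox = TRUE)
  }
  screens <- normalize_screens(tables, config$assignment)
  matrix <- build_matrix(screens, config$assignment,
                         ubiquitous = config$options$ubiquitous)
  export_matrix(matrix, file.path(out_dir, "matrix.tsv"),
                top_n = config$options$top_n,
                heatmap = if (config$options$heatmap)
                  file.path(out_dir, "heatmap.png") else NULL)
  run_report(tables, screens = screens, assignment = config$assignment,
             out_dir = out_dir)
  manifest <- list(
    package = "selpep",
    version = as.character(utils::packageVersion("selpep")),
    scheme = config$scheme[c("name", "flank5", "flank3", "peptide_length",
                             "codon_constraint", "amber_as_gln",
                             "codon_filter")],
    screens = config$screens,
    options = lapply(config$options,
                     function(x) if (is.infinite(x)) "all" else x))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  attr(matrix, "tables") <- tables
  attr(matrix, "screens") <- screens
  invisible(matrix)
}

#' Per-screen summary and replicate-agreement report
#'
#' Summarizes each screen's read accounting (total reads, accepted reads,
#' unique peptides) as one table row, and — when at least two positive
#' replicates are available — emits replicate scatter data: for every
#' (peptide, positive replicate) pair, the replicate's normalized frequency
#' alongside the across-replicate mean (mode-imputed for absences), the raw
#' material for replicate-agreement scatter plots.
#'
#' @param tables Named list of [screen_table()] objects.
#' @param screens Optional named list of `normalized_screen` objects (needed
#'   for the scatter data).
#' @param assignment Optional [role_assignment()] identifying the positive
#'   replicates.
#' @param out_dir Optional directory; writes `report.json` and
#'   `replicate_scatter.tsv` there.
#' @return List with `summary` (data.frame) and `scatter` (data.frame or
#'   `NULL`).
#' @export
run_report <- function(tables, screens = NULL, assignment = NULL,
                       out_dir = NULL) {
  summary <- do.call(rbind, lapply(tables, function(t) {
    data.frame(screen_id = t$screen_id,
               total_reads = t$stats$total_reads,
               accepted_reads = t$stats$accepted_reads,
               unique_peptides = t$stats$unique_peptides,
               row.names = NULL)
  }))
  scatter <- NULL
  if (!is.null(screens) && !is.null(assignment) &&
      length(assignment$positives) >= 2L) {
    pos <- assignment$positives
    peps <- sort(unique(unlist(lapply(screens[pos],
                                      function(s) names(s$values)))))
    filled <- vapply(pos, function(id) {
      v <- screens[[id]]$values[peps]
      v[is.na(v)] <- screens[[id]]$nonzero_mode
      v
    }, numeric(length(peps)))
    rep_mean <- rowMeans(matrix(filled, nrow = length(peps)))
    names(rep_mean) <- peps
    scatter <- do.call(rbind, lapply(pos, function(id) {
      v <- screens[[id]]$values
      data.frame(peptide = names(v), replicate = id, value = unname(v),
                 replicate_mean = unname(rep_mean[names(v)]),
                 row.names = NULL)
    }))
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(list(screens = summary),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(scatter)) {
      utils::write.table(scatter, file.path(out_dir, "replicate_scatter.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  list(summary = summary, scatter = scatter)
}
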