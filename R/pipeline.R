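# End-to-end orchestration: genome -> precursor candidates -> species
# enumeration -> MS1 linking -> MS/MS topology scoring, from a validated
# configuration, with machine-readable reports.

.CONFIG_DEFAULTS <- list(
  fasta = NULL, gff = NULL, ms1_peaks = NULL, ms2_spectra = NULL,
  window_bp = 6000, k = 10, min_orf_aa = 20, max_len = 100,
  cterm_window = 20, min_core = 5, max_core = 50,
  max_dehydrations = "auto", allow_methylation = NA,
  max_methylations = 1, allow_dehydrogenation = FALSE,
  max_dehydrogenations = 1, tol_ppm_ms1 = 10, tol_ppm_ms2 = 10,
  charges = c(1, 2, 3), ms2_charges = 1, ring_mode = "cgs-rupture",
  max_rings = 3, seed = 1, out_dir = NULL)

#' Validate a pipeline configuration
#'
#' Fills documented defaults, rejects unknown keys, and aggregates every
#' type/range violation into a single error. `allow_methylation = NA`
#' (default) means "decide per locus from the GFF3 attribute
#' `methyltransferase=true` on the lanM feature".
#'
#' @param config named list of settings, or a path to a JSON (or YAML)
#'   config file.
#' @return validated config list of class `lanmine_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("YAML config requires the 'yaml' package; use JSON instead")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  errs <- character()
  unknown <- setdiff(names(config), names(.CONFIG_DEFAULTS))
  if (length(unknown)) {
    errs <- c(errs, paste0("unknown key(s): ",
                           paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(.CONFIG_DEFAULTS,
                           config[setdiff(names(config), unknown)])
  num_pos <- c(window_bp = 1, k = 1, min_orf_aa = 1, max_len = 2,
               cterm_window = 1, min_core = 1, max_core = 1,
               tol_ppm_ms1 = 1e-9, tol_ppm_ms2 = 1e-9, max_rings = 0,
               seed = -Inf)
  for (key in names(num_pos)) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v)) {
      errs <- c(errs, paste0(key, ": must be a single number, got '",
                             paste(v, collapse = ","), "'"))
    } else if (v < num_pos[[key]]) {
      errs <- c(errs, paste0(key, ": must be >= ", num_pos[[key]],
                             ", got ", v))
    }
  }
  if (!identical(cfg$max_dehydrations, "auto") &&
      !(is.numeric(cfg$max_dehydrations) && cfg$max_dehydrations >= 0)) {
    errs <- c(errs, "max_dehydrations: must be 'auto' or a count >= 0")
  }
  if (!is.numeric(cfg$charges) || any(cfg$charges < 1)) {
    errs <- c(errs, "charges: must be positive integers")
  }
  if (!is.numeric(cfg$ms2_charges) || any(cfg$ms2_charges < 1)) {
    errs <- c(errs, "ms2_charges: must be positive integers")
  }
  if (!cfg$ring_mode %in% c("cgs-rupture", "suppress")) {
    errs <- c(errs, "ring_mode: must be 'cgs-rupture' or 'suppress'")
  }
  if (!is.logical(cfg$allow_methylation) ||
      length(cfg$allow_methylation) != 1L) {
    if (!is.na(cfg$allow_methylation)[1]) {
      errs <- c(errs, "allow_methylation: must be TRUE, FALSE or NA")
    }
  }
  if (length(errs)) {
    stop("invalid configuration:\n  - ", paste(errs, collapse = "\n  - "))
  }
  if (!is.null(cfg$min_core) && cfg$min_core > cfg$max_core) {
    stop("invalid configuration:\n  - min_core exceeds max_core")
  }
  class(cfg) <- "lanmine_config"
  cfg
}

#' Run the full genome-to-metabolite pipeline
#'
#' Stages: (1) precursor mining — ORFs around every annotated lanM locus,
#' nearest-k selection, precursor filters, leader-motif scan; (2) MS1
#' linking — modified-species enumeration per core split and ppm matching
#' against the MS1 peak list; (3) ring topology — candidate topologies for
#' the best-linked species scored against MS/MS spectra whose precursor
#' m/z matches. Stages whose inputs are absent are skipped and marked
#' `"not run"`; empty results are a success, not an error.
#'
#' @param config settings list / path accepted by [validate_config()], or
#'   an already validated `lanmine_config`.
#' @return `lanmine_report`: list with schema_version, config, seed,
#'   candidates, links, topology, versions and timestamps.
#' @export
run_pipeline <- function(config) {
  cfg <- if (inherits(config, "lanmine_config")) config else
    validate_config(config)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  if (is.null(cfg$fasta) || is.null(cfg$gff)) {
    stop("config must provide 'fasta' and 'gff' input paths")
  }
  genome <- read_genome(cfg$fasta, cfg$gff)
  lanMs <- genome$features[genome$features$type == "lanM", , drop = FALSE]
  if (!nrow(lanMs)) stop("no lanM features found in ", cfg$gff)

  # --- stage 1: precursor mining
  cand_list <- list()
  for (i in seq_len(nrow(lanMs))) {
    orfs <- find_orfs(genome, lanMs$feature_id[i], cfg$window_bp,
                      cfg$min_orf_aa)
    near <- select_adjacent(orfs, cfg$k)
    cands <- filter_precursors(near, cfg$max_len, cfg$cterm_window)
    if (nrow(cands)) {
      cands$lanM <- lanMs$feature_id[i]
      cand_list[[lanMs$feature_id[i]]] <- cands
    }
  }
  candidates <- if (length(cand_list)) do.call(rbind, cand_list) else
    data.frame()
  rownames(candidates) <- NULL

  # --- stage 2: MS1 linking
  links <- NULL
  if (!is.null(cfg$ms1_peaks) && nrow(candidates)) {
    peaks <- read_ms1_peaks(cfg$ms1_peaks)
    link_list <- list()
    for (i in seq_len(nrow(lanMs))) {
      sub <- candidates[candidates$lanM == lanMs$feature_id[i], ,
                        drop = FALSE]
      if (!nrow(sub)) next
      allow_meth <- cfg$allow_methylation
      if (is.na(allow_meth)) {
        allow_meth <- isTRUE(tolower(lanMs$methyltransferase[i]) == "true")
      }
      space <- modification_space(
        max_dehydrations = cfg$max_dehydrations,
        allow_methylation = allow_meth,
        max_methylations = cfg$max_methylations,
        allow_dehydrogenation = cfg$allow_dehydrogenation,
        max_dehydrogenations = cfg$max_dehydrogenations,
        charge_states = cfg$charges)
      lk <- link_bgc_to_peaks(sub, peaks, space, cfg$tol_ppm_ms1,
                              cfg$min_core, cfg$max_core)
      if (nrow(lk)) {
        lk$lanM <- lanMs$feature_id[i]
        link_list[[lanMs$feature_id[i]]] <- lk
      }
    }
    links <- if (length(link_list))
      do.call(rbind, lapply(link_list, function(x) {
        attr(x, "all_matches") <- NULL; x
      })) else data.frame()
    rownames(links) <- NULL
  }

  # --- stage 3: ring topology from MS/MS
  topology <- "not run"
  if (!is.null(cfg$ms2_spectra) && !is.null(links) && nrow(links)) {
    spectra <- read_mgf(cfg$ms2_spectra)
    pepmasses <- vapply(spectra, function(s)
      if (is.null(s$pepmass)) NA_real_ else s$pepmass, numeric(1))
    verdicts <- list()
    best_per_cand <- links[!duplicated(links$candidate), , drop = FALSE]
    for (i in seq_len(nrow(best_per_cand))) {
      row <- best_per_cand[i, ]
      matching <- which(!is.na(pepmasses) &
                          abs(ppm_error(pepmasses, row$theoretical_mz)) <=
                          cfg$tol_ppm_ms1)
      if (!length(matching)) next
      # each ring consumes one dehydration; the candidate search space is
      # factorial in the link count, so species with implausibly many
      # dehydrations are not evaluated
      if (row$n_dehydration > cfg$max_rings ||
          row$n_dehydrogenation > 0) next
      mods <- modification_set(row$n_dehydration, row$n_methylation,
                               row$n_dehydrogenation)
      cand_tops <- enumerate_candidate_topologies(row$core,
                                                  row$n_dehydration)
      if (!length(cand_tops)) next
      for (si in matching) {
        sc <- score_topologies(spectra[[si]], row$core, mods, cand_tops,
                               cfg$tol_ppm_ms2, cfg$ms2_charges,
                               cfg$ring_mode)
        verdicts[[length(verdicts) + 1L]] <- data.frame(
          candidate = row$candidate, lanM = row$lanM, core = row$core,
          spectrum = si,
          spectrum_title = if (is.null(spectra[[si]]$title))
            NA_character_ else spectra[[si]]$title,
          topology = sc$topology[1], label = if (attr(sc, "indeterminate"))
            "indeterminate" else sc$label[1],
          n_discriminating = sc$n_discriminating[1],
          coverage = sc$coverage[1], stringsAsFactors = FALSE)
      }
    }
    topology <- if (length(verdicts)) do.call(rbind, verdicts) else
      data.frame()
    rownames(topology) <- NULL
  }

  report <- list(
    schema_version = "1.0",
    config = unclass(cfg),
    seed = cfg$seed,
    candidates = candidates,
    links = if (is.null(links)) "not run" else links,
    topology = topology,
    versions = list(
      lanmine = as.character(utils::packageVersion("lanmine")),
      R = R.version.string),
    timestamps = list(started = started,
                      finished = format(Sys.time(),
                                        "%Y-%m-%dT%H:%M:%S%z")))
  class(report) <- "lanmine_report"
  if (!is.null(cfg$out_dir)) write_report(report, cfg$out_dir)
  report
}

#' @export
print.lanmine_report <- function(x, ...) {
  cat("<lanmine_report> schema ", x$schema_version, "\n", sep = "")
  cat("  candidates: ", if (is.data.frame(x$candidates))
    nrow(x$candidates) else 0, "\n", sep = "")
  cat("  links: ", if (is.data.frame(x$links)) nrow(x$links) else
    x$links, "\n", sep = "")
  cat("  topology: ", if (is.data.frame(x$topology)) nrow(x$topology)
      else x$topology, "\n", sep = "")
  invisible(x)
}

#' Write a pipeline report to disk (JSON + flat TSV tables)
#'
#' The JSON report is canonical; timestamps live in their own field so that
#' re-runs with identical inputs differ only there.
#'
#' @param report `lanmine_report`.
#' @param dir output directory.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report), paths, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       force = TRUE)
  for (tab in c("candidates", "links", "topology")) {
    if (is.data.frame(report[[tab]]) && nrow(report[[tab]])) {
      p <- file.path(dir, paste0(tab, ".tsv"))
      utils::write.table(report[[tab]], p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
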