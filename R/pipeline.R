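validation_error <- function(...) {
  stop(structure(class = c("axoxl_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Pipeline configuration
#'
#' Bundles inputs and thresholds for [run_pipeline()]. Inputs may be given
#' as file paths (read at run time) or as in-memory objects; thresholds
#' default to the DSSO conventions (FDR <= 1 percent, score > 40,
#' satisfied <= 30 A, moderate <= 40 A, extreme > 100 A). Validation
#' errors carry class `axoxl_validation_error`.
#'
#' @param xl_tables character vector of cross-link table paths, or `NULL`.
#' @param records in-memory `xl_records` (alternative to `xl_tables`).
#' @param dialect an [xl_dialect()] for reading tables.
#' @param orthomap path or [ortho_map()] (optional).
#' @param fasta path or named sequence vector (optional; enables arc data).
#' @param fdr_max,score_min record filters.
#' @param thresholds an [xl_thresholds()].
#' @param structures named list; each element a list with `structure` (path
#'   or [xl_structure()]), `chain_map`, optional `transfers`.
#' @param ensemble optional list with `ensemble` ([xl_ensemble()] or member
#'   paths), `chain_map`, optional `transfers`, `cutoff`.
#' @param lattice optional list with `lattice` ([xl_lattice()]), optional
#'   `chain_map`, `cutoff`.
#' @param out_dir output directory for the report bundle files; `NULL`
#'   keeps results in memory only.
#' @param seed recorded in provenance (the pipeline itself is
#'   deterministic).
#' @return A list of class `xl_pipeline_config`.
#' @export
pipeline_config <- function(xl_tables = NULL, records = NULL,
                            dialect = xl_dialect(), orthomap = NULL,
                            fasta = NULL, fdr_max = 0.01, score_min = 40,
                            thresholds = xl_thresholds(),
                            structures = list(), ensemble = NULL,
                            lattice = NULL, out_dir = NULL, seed = 1) {
  cfg <- structure(list(xl_tables = xl_tables, records = records,
                        dialect = dialect, orthomap = orthomap,
                        fasta = fasta, fdr_max = fdr_max,
                        score_min = score_min, thresholds = thresholds,
                        structures = structures, ensemble = ensemble,
                        lattice = lattice, out_dir = out_dir, seed = seed),
                   class = "xl_pipeline_config")
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$xl_tables) && is.null(cfg$records))
    validation_error("either xl_tables or records must be supplied")
  th <- cfg$thresholds
  if (!inherits(th, "xl_thresholds")) {
    ok <- tryCatch({xl_thresholds(th$satisfied, th$moderate, th$extreme); TRUE},
                   error = function(e) FALSE)
    if (!ok) validation_error("invalid thresholds: must be ordered ",
                              "satisfied <= moderate < extreme")
  }
  for (p in c(cfg$xl_tables,
              if (is.character(cfg$orthomap)) cfg$orthomap,
              if (is.character(cfg$fasta)) cfg$fasta))
    if (!file.exists(p)) validation_error("input path does not exist: ", p)
  for (nm in names(cfg$structures)) {
    s <- cfg$structures[[nm]]
    if (is.character(s$structure) && !file.exists(s$structure))
      validation_error("structure path does not exist: ", s$structure)
    if (is.null(s$chain_map))
      validation_error("structure entry '", nm, "' lacks a chain_map")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' File-based counterpart of [pipeline_config()]: paths are resolved
#' relative to the YAML file's directory. Recognised keys mirror the
#' function arguments (`xl_tables`, `dialect`, `orthomap`, `fasta`,
#' `fdr_max`, `score_min`, `thresholds: {satisfied, moderate, extreme}`,
#' `structures: name: {path, chain_map}`, `out_dir`, `seed`).
#'
#' @param path YAML file.
#' @return An `xl_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) ifelse(grepl("^/", p), p, file.path(base, p))
  th <- if (!is.null(y$thresholds))
    do.call(xl_thresholds, y$thresholds) else xl_thresholds()
  dia <- if (!is.null(y$dialect)) do.call(xl_dialect, y$dialect) else xl_dialect()
  structures <- list()
  for (nm in names(y$structures)) {
    s <- y$structures[[nm]]
    structures[[nm]] <- list(structure = rel(s$path),
                             chain_map = lapply(s$chain_map, as.character))
  }
  pipeline_config(
    xl_tables = if (!is.null(y$xl_tables)) rel(unlist(y$xl_tables)),
    dialect = dia,
    orthomap = if (!is.null(y$orthomap)) rel(y$orthomap),
    fasta = if (!is.null(y$fasta)) rel(y$fasta),
    fdr_max = if (!is.null(y$fdr_max)) y$fdr_max else 0.01,
    score_min = if (!is.null(y$score_min)) y$score_min else 40,
    thresholds = th, structures = structures,
    out_dir = if (!is.null(y$out_dir)) rel(y$out_dir),
    seed = if (!is.null(y$seed)) y$seed else 1)
}

# 32-bit FNV-1a over a deparsed object, hex string — provenance hash only.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "\n")
  h <- 2166136261 %% 2^31
  for (b in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Run the cross-link analysis pipeline
#'
#' Import -> orthogroup collapse -> FDR/score filter -> deduplicate ->
#' summarise -> map to structures -> ensemble / lattice disambiguation,
#' with machine-readable outputs. Deterministic given an identical
#' configuration and inputs: all orderings are stable and keyed. Any stage
#' failure aborts with the stage name.
#'
#' @param config an [pipeline_config()].
#' @return A list of class `xl_bundle`: `summary`, `links`, `records`,
#'   `mapped` + `satisfaction` (named by structure entry), `heatmap`,
#'   `verdicts`, `lattice_verdicts`, `provenance`. When `out_dir` is set,
#'   JSON/TSV/CSV files are written there as a side effect.
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  records <- stage("import", {
    if (!is.null(config$records)) validate_xl_records(as.data.frame(config$records))
    else {
      parts <- lapply(seq_along(config$xl_tables), function(i)
        read_xl_table(config$xl_tables[i], config$dialect,
                      dataset_id = paste0("XL", i)))
      validate_xl_records(do.call(rbind, lapply(parts, as.data.frame)))
    }
  })
  om <- stage("orthomap", {
    if (is.character(config$orthomap)) read_orthomap(config$orthomap)
    else config$orthomap
  })
  if (!is.null(om)) records <- stage("collapse", collapse_to_orthogroups(records, om))
  filtered <- stage("filter",
                    filter_records(records, config$fdr_max, config$score_min))
  links <- stage("deduplicate", deduplicate_links(filtered))
  summary <- summarize_network(links, filtered)

  mapped <- list(); satisfaction <- list()
  for (nm in names(config$structures)) {
    s <- config$structures[[nm]]
    st <- stage(paste0("read-structure:", nm), {
      if (is.character(s$structure)) read_structure(s$structure) else s$structure
    })
    mapped[[nm]] <- stage(paste0("map:", nm),
      map_links(links, st, s$chain_map, s$transfers, config$thresholds))
    satisfaction[[nm]] <- satisfaction_summary(mapped[[nm]], config$thresholds)
  }

  heatmap <- NULL; verdicts <- NULL
  if (!is.null(config$ensemble)) {
    e <- config$ensemble
    ens <- if (inherits(e$ensemble, "xl_ensemble")) e$ensemble
      else xl_ensemble("ensemble", lapply(e$ensemble, read_structure))
    heatmap <- stage("ensemble", distance_heatmap(links, ens, e$chain_map,
                                                  e$transfers,
                                                  config$thresholds))
    verdicts <- satisfiable_by_any(
      heatmap, if (!is.null(e$cutoff)) e$cutoff else config$thresholds$satisfied)
  }
  lattice_verdicts <- NULL
  if (!is.null(config$lattice)) {
    l <- config$lattice
    lattice_verdicts <- stage("lattice", reinterpret_intralinks(
      links, l$lattice, l$chain_map,
      if (!is.null(l$cutoff)) l$cutoff else config$thresholds$satisfied,
      l$transfers))
  }

  bundle <- structure(list(
    summary = summary, links = links, records = filtered,
    mapped = mapped, satisfaction = satisfaction,
    heatmap = heatmap, verdicts = verdicts,
    lattice_verdicts = lattice_verdicts,
    provenance = list(
      tool = "axoxl", version = as.character(utils::packageVersion("axoxl")),
      config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
      seed = config$seed,
      thresholds = unclass(config$thresholds),
      fdr_max = config$fdr_max, score_min = config$score_min)
  ), class = "xl_bundle")

  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(bundle$summary),
                       file.path(dir, "network_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(as.data.frame(bundle$links),
                     file.path(dir, "unique_links.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  write_network(bundle$links, file.path(dir, "network_xiview.csv"),
                "xiview-csv")
  for (nm in names(bundle$mapped)) {
    utils::write.table(as.data.frame(bundle$mapped[[nm]]),
                       file.path(dir, paste0("mapped_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    s <- bundle$satisfaction[[nm]]
    jsonlite::write_json(
      list(n_links = s$n_links, n_mapped = s$n_mapped,
           n_unmappable = s$n_unmappable,
           n_within_satisfied = s$n_within_satisfied,
           n_within_moderate = s$n_within_moderate,
           n_extreme = s$n_extreme,
           frac_within_satisfied = s$frac_within_satisfied,
           frac_within_moderate = s$frac_within_moderate,
           mean_distance_intra = s$mean_distance_intra,
           mean_distance_inter = s$mean_distance_inter),
      file.path(dir, paste0("satisfaction_", nm, ".json")),
      auto_unbox = TRUE, digits = NA, na = "null")
    utils::write.table(s$histogram,
                       file.path(dir, paste0("histogram_", nm, ".tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(bundle$heatmap)) {
    hm <- as.data.frame(unclass(bundle$heatmap))
    hm <- cbind(link = rownames(hm), hm)
    utils::write.table(hm, file.path(dir, "ensemble_heatmap.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(bundle$verdicts,
                       file.path(dir, "ensemble_verdicts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(bundle$lattice_verdicts))
    utils::write.table(bundle$lattice_verdicts,
                       file.path(dir, "lattice_verdicts.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(bundle$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

# Percent rounded half-up to integer (sprintf rounds half-even).
pct_half_up <- function(frac) floor(100 * frac + 0.5)

#' Human-readable pipeline report
#'
#' Mirrors the reporting style of XL/MS interactome studies: record and
#' unique-link counts, protein count, intra/inter split, and — per mapped
#' structure — the fractions within the satisfied and moderate cutoffs as
#' integer percentages (rounded half-up).
#'
#' @param bundle an [run_pipeline()] result.
#' @return Character vector of report lines (also printed).
#' @export
pipeline_report <- function(bundle) {
  s <- bundle$summary
  lines <- character()
  if (s$n_unique_links == 0) {
    lines <- c(lines, "No cross-links passed the filters: no links to report.")
  } else {
    lines <- c(lines, sprintf(
      "Analysis yielded %d cross-links, comprising %d unique binary amino acid interactions measured for %d proteins.",
      s$n_records, s$n_unique_links, s$n_proteins))
    lines <- c(lines, sprintf(
      "Of these, %d unique links included two distinct proteins (intermolecular); %d were intramolecular. %d unique group pairs.",
      s$n_intermolecular, s$n_intramolecular, s$n_unique_group_pairs))
  }
  for (nm in names(bundle$satisfaction)) {
    st <- bundle$satisfaction[[nm]]
    if (st$n_mapped == 0) {
      lines <- c(lines, sprintf("[%s] no mappable links.", nm))
    } else {
      lines <- c(lines, sprintf(
        "[%s] %d%% of %d mapped XLs measure within %g A; %d%% within %g A; %d extreme (> %g A).",
        nm, pct_half_up(st$frac_within_satisfied), st$n_mapped,
        st$thresholds$satisfied, pct_half_up(st$frac_within_moderate),
        st$thresholds$moderate, st$n_extreme, st$thresholds$extreme))
    }
  }
  if (!is.null(bundle$verdicts)) {
    v <- bundle$verdicts$satisfiable
    lines <- c(lines, sprintf(
      "Ensemble: %d/%d links satisfiable by at least one conformation.",
      sum(v, na.rm = TRUE), sum(!is.na(v))))
  }
  if (!is.null(bundle$lattice_verdicts)) {
    v <- bundle$lattice_verdicts$satisfied
    lines <- c(lines, sprintf(
      "Lattice: %d/%d links satisfied as inter-copy contacts.",
      sum(v, na.rm = TRUE), sum(!is.na(v))))
  }
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.xl_bundle <- function(x, ...) {
  cat("<xl_bundle>\n")
  print(x$summary)
  invisible(x)
}
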