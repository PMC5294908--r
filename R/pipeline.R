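# Pipeline driver: configuration, staged execution, artifact writers.

CONFIG_KEYS <- c(
  "ontology", "ontology_dialect", "icd10", "icdo3_topography",
  "icdo3_morphology", "cui_map", "cui_map_dialect", "seer", "out_dir",
  "namespace", "ancestor_completion", "seed", "icd10_ranges", "sab",
  "hematopoietic_icd10", "hematopoietic_morph", "excluded_behaviors"
)

#' Validate a pipeline configuration
#'
#' Checks the key set against the published schema (unknown keys are
#' rejected), fills defaults, and verifies types and required inputs.
#'
#' @param config Named list (e.g. from [read_pipeline_config()]).
#' @return The completed configuration list.
#' @export
validate_pipeline_config <- function(config) {
  unknown <- setdiff(names(config), CONFIG_KEYS)
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  required <- c("ontology", "icd10", "icdo3_topography", "icdo3_morphology",
                "cui_map", "out_dir")
  missing <- setdiff(required, names(config))
  if (length(missing)) {
    abort(paste0("missing config key(s): ", paste(missing, collapse = ", ")))
  }
  defaults <- list(
    ontology_dialect = "NATIVE_TSV",
    cui_map_dialect = "TSV",
    seer = NULL,
    namespace = DEFAULT_NS,
    ancestor_completion = TRUE,
    seed = 1L,
    excluded_behaviors = c("1", "6", "9")
  )
  for (k in names(defaults)) {
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  }
  stopifnot(is.logical(config$ancestor_completion))
  config
}

#' Read a pipeline configuration file
#'
#' YAML key-value file validated against the schema in
#' [validate_pipeline_config()]; relative paths are resolved against the
#' config file's directory.
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  config <- yaml::read_yaml(path)
  config <- validate_pipeline_config(config)
  base <- dirname(normalizePath(path))
  for (k in c("ontology", "icd10", "icdo3_topography", "icdo3_morphology",
              "cui_map", "seer", "out_dir")) {
    v <- config[[k]]
    if (!is.null(v) && !grepl("^([A-Za-z]:)?[/\\\\]", v)) {
      config[[k]] <- file.path(base, v)
    }
  }
  config
}

binding_config_from <- function(config) {
  bc <- default_binding_config()
  for (k in c("sab", "hematopoietic_icd10", "hematopoietic_morph")) {
    if (!is.null(config[[k]])) bc[[k]] <- config[[k]]
  }
  if (!is.null(config$icd10_ranges)) {
    bc$icd10_ranges <- as_tibble(config$icd10_ranges)
  }
  bc
}

# Tiny FNV-1a hash for config provenance lines (no hashing package on hand).
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 216613626
  for (b in bytes) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", h)
}

artifact_header <- function(config) {
  cfg <- jsonlite::toJSON(config[order(names(config))], auto_unbox = TRUE)
  sprintf("# oncolattice %s; config %s",
          as.character(utils::packageVersion("oncolattice")), fnv1a(cfg))
}

write_table_artifact <- function(df, path, header) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(header, con)
  body <- utils::capture.output(
    utils::write.table(df, stdout(), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "")
  )
  writeLines(body, con)
  invisible(path)
}

flatten_bindings <- function(bindings) {
  bindings |>
    mutate(
      direct = map_chr(.data$direct, paste, collapse = ";"),
      n_satisfied = lengths(.data$satisfied),
      bound_anatomy = map_chr(.data$bound_anatomy, paste, collapse = ";"),
      mapped_concepts = map_chr(.data$mapped_concepts, paste, collapse = ";")
    ) |>
    select("system", "code", "label", "behavior", "status", "direct",
           "n_satisfied", "bound_anatomy", "mapped_concepts", "reason")
}

#' Run the full pipeline
#'
#' Stages: build the derivative model, bind terminology codes, audit the
#' bindings, and (when a SEER-style file is configured) evaluate against the
#' gold standard. Each stage's artifacts are written under `out_dir`:
#' `model.ttl`, `bindings.tsv`, `audit_summary.tsv`, `audit.json`,
#' `eval_summary.tsv`, `eval.json`. Every table carries a header comment
#' with the tool version and a config hash; identical config and seed yield
#' byte-identical artifacts.
#'
#' @param config Configuration list or path to a YAML file.
#' @return Invisibly, a list with the model, bindings, audit and eval
#'   objects, plus stage timings.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- validate_pipeline_config(config)
  bc <- binding_config_from(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- artifact_header(config[setdiff(names(config), "out_dir")])
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            parent = e)
    })
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    inform(sprintf("[oncolattice] stage %-8s done in %.2fs", name, timings[[name]]))
    out
  }

  model <- stage("build", {
    onto <- load_source_ontology(config$ontology, config$ontology_dialect)
    build_derivative_model(onto,
                           ancestor_completion = config$ancestor_completion,
                           ns = config$namespace)
  })
  inform(sprintf("[oncolattice] model: %d topographies, %d morphologies, %d diagnoses",
                 length(model$topos), length(morphology_ids(model$axis)),
                 nrow(model$retained)))

  bindings <- stage("bind", {
    codes <- bind_rows(
      read_terminology(config$icd10, "ICD10", bc),
      read_terminology(config$icdo3_topography, "ICDO3_T", bc),
      read_terminology(config$icdo3_morphology, "ICDO3_M", bc)
    )
    cuimap <- read_cui_map(config$cui_map, config$cui_map_dialect, bc)
    bind_codes(codes, cuimap, model, bc)
  })
  inform(sprintf("[oncolattice] bound %d / %d codes",
                 sum(bindings$status == "BOUND"), nrow(bindings)))

  audit <- stage("audit", audit_bindings(bindings, model))

  evalrep <- NULL
  if (!is.null(config$seer) && file.exists(config$seer)) {
    evalrep <- stage("evaluate", {
      gold <- read_seer_conversion(config$seer, bc,
                                   excluded_behaviors = config$excluded_behaviors)
      evaluate_against_gold(gold, bindings, model)
    })
  } else if (!is.null(config$seer)) {
    inform("[oncolattice] no SEER-style file found; evaluation skipped")
  } else {
    inform("[oncolattice] no SEER-style file configured; evaluation skipped")
  }

  stage("export", {
    serialize_derivative_model(model, file.path(config$out_dir, "model.ttl"),
                               bindings = bindings)
    write_table_artifact(flatten_bindings(bindings),
                         file.path(config$out_dir, "bindings.tsv"), header)
    write_table_artifact(audit$summary,
                         file.path(config$out_dir, "audit_summary.tsv"), header)
    jsonlite::write_json(
      list(summary = audit$summary, conflicts = audit$conflicts,
           hypotheses = audit$hypotheses),
      file.path(config$out_dir, "audit.json"), digits = NA
    )
    if (!is.null(evalrep)) {
      write_table_artifact(evalrep$summary,
                           file.path(config$out_dir, "eval_summary.tsv"), header)
      jsonlite::write_json(
        list(summary = evalrep$summary, n_excluded = evalrep$n_excluded),
        file.path(config$out_dir, "eval.json"), digits = NA
      )
    }
    NULL
  })

  invisible(list(model = model, bindings = bindings, audit = audit,
                 evaluation = evalrep, timings = timings, config = config))
}
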