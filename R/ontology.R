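# Source-ontology container and NATIVE_TSV ingestion.
#
# A source ontology is five tibbles: concepts (id, label, axis), is_a edges,
# part-whole edges (PART_PHYSICAL / PART_LOCATION), primary-site role
# assertions, and ICD-O-3 morphology annotations.

#' Construct a source ontology
#'
#' @param concepts Tibble with columns `id`, `label`, `axis`
#'   (`ANATOMY`/`NEOPLASM`/`OTHER`).
#' @param is_a Tibble with columns `child`, `parent`.
#' @param parts Tibble with columns `child`, `parent`, `role`
#'   (`PART_PHYSICAL` or `PART_LOCATION`).
#' @param sites Tibble with columns `concept`, `site`: primary-anatomic-site
#'   role assertions of neoplasm concepts.
#' @param morphs Tibble with columns `concept`, `code`: ICD-O-3 morphology
#'   annotations (`HHHH/B`).
#' @param validate Check structural invariants (acyclicity per axis, no
#'   dangling endpoints) and fail on violations.
#' @return An object of class `src_ontology`.
#' @export
ontology <- function(concepts,
                     is_a = NULL, parts = NULL, sites = NULL, morphs = NULL,
                     validate = TRUE) {
  empty_tbl <- function(...) {
    cols <- c(...)
    as_tibble(setNames(rep(list(character()), length(cols)), cols))
  }
  norm <- function(x, ...) {
    if (is.null(x) || (is.data.frame(x) && ncol(x) == 0)) empty_tbl(...)
    else as_tibble(x)
  }
  concepts <- as_tibble(concepts)
  stopifnot(all(c("id", "label", "axis") %in% names(concepts)))
  bad_axis <- setdiff(unique(concepts$axis), AXIS_TAGS)
  if (length(bad_axis)) {
    abort(paste0("unknown axis tag(s): ", paste(bad_axis, collapse = ", ")))
  }
  if (anyDuplicated(concepts$id)) {
    abort(paste0("duplicate concept id(s): ",
                 paste(unique(concepts$id[duplicated(concepts$id)]), collapse = ", ")))
  }
  is_a <- norm(is_a, "child", "parent")
  parts <- norm(parts, "child", "parent", "role")
  sites <- norm(sites, "concept", "site")
  morphs <- norm(morphs, "concept", "code")
  bad_role <- setdiff(unique(parts$role), c("PART_PHYSICAL", "PART_LOCATION"))
  if (length(bad_role)) {
    abort(paste0("part edges must use PART_PHYSICAL/PART_LOCATION, got: ",
                 paste(bad_role, collapse = ", ")))
  }
  onto <- structure(
    list(
      concepts = arrange(distinct(concepts), .data$id),
      is_a = arrange(distinct(is_a), .data$child, .data$parent),
      parts = arrange(distinct(parts), .data$child, .data$parent, .data$role),
      sites = arrange(distinct(sites), .data$concept, .data$site),
      morphs = arrange(distinct(morphs), .data$concept, .data$code)
    ),
    class = "src_ontology"
  )
  if (validate) {
    rep <- validate_ontology(onto)
    if (!ontology_valid(rep)) {
      abort(paste0("invalid source ontology:\n", format_validation(rep)),
            class = "oncolattice_invalid_ontology")
    }
  }
  onto
}

#' @export
print.src_ontology <- function(x, ...) {
  cat(sprintf(
    "<src_ontology> %d concepts (%d anatomy, %d neoplasm), %d is_a, %d part, %d site, %d morphology rows\n",
    nrow(x$concepts), sum(x$concepts$axis == "ANATOMY"),
    sum(x$concepts$axis == "NEOPLASM"),
    nrow(x$is_a), nrow(x$parts), nrow(x$sites), nrow(x$morphs)
  ))
  invisible(x)
}

axis_of <- function(onto) setNames(onto$concepts$axis, onto$concepts$id)

#' Validate a source ontology
#'
#' Detects is_a cycles (restricted to each axis), dangling edge endpoints, and
#' primary-site fillers that are not anatomy concepts. Report-valued: an empty
#' report means the ontology passes.
#'
#' @param onto A `src_ontology`.
#' @return A list of class `ontology_validation` with tibbles `cycles`,
#'   `dangling`, `off_axis_sites`.
#' @export
validate_ontology <- function(onto) {
  ids <- onto$concepts$id
  dangling <- bind_rows(
    tibble(table = "is_a", from = onto$is_a$child, to = onto$is_a$parent),
    tibble(table = "parts", from = onto$parts$child, to = onto$parts$parent),
    tibble(table = "sites", from = onto$sites$concept, to = onto$sites$site),
    tibble(table = "morphs", from = onto$morphs$concept, to = onto$morphs$concept)
  )
  dangling <- filter(dangling, !(.data$from %in% ids) | !(.data$to %in% ids))

  ax <- axis_of(onto)
  cycles <- list()
  for (axis in c("ANATOMY", "NEOPLASM", "OTHER")) {
    keep <- onto$is_a$child %in% ids[ax[ids] == axis] &
      onto$is_a$parent %in% ids[ax[ids] == axis]
    cyc <- find_cycle(onto$is_a[keep, , drop = FALSE])
    if (!is.null(cyc)) cycles[[axis]] <- tibble(axis = axis, cycle = paste(cyc, collapse = " -> "))
  }
  # part edges also feed the anatomy order; a part cycle breaks antisymmetry too
  anat <- ids[ax[ids] == "ANATOMY"]
  keepp <- onto$parts$child %in% anat & onto$parts$parent %in% anat
  keepi <- onto$is_a$child %in% anat & onto$is_a$parent %in% anat
  anat_edges <- bind_rows(
    select(onto$is_a[keepi, , drop = FALSE], "child", "parent"),
    select(onto$parts[keepp, , drop = FALSE], "child", "parent")
  )
  cycp <- find_cycle(anat_edges)
  if (!is.null(cycp)) {
    cycles[["ANATOMY_PART"]] <- tibble(axis = "ANATOMY(part)", cycle = paste(cycp, collapse = " -> "))
  }

  off_axis <- filter(onto$sites, .data$site %in% ids & ax[.data$site] != "ANATOMY")

  structure(
    list(
      cycles = if (length(cycles)) bind_rows(cycles) else tibble(axis = character(), cycle = character()),
      dangling = select(dangling, "table", "from", "to"),
      off_axis_sites = select(off_axis, concept = "concept", filler = "site")
    ),
    class = "ontology_validation"
  )
}

#' @rdname validate_ontology
#' @param report An `ontology_validation`.
#' @export
ontology_valid <- function(report) {
  nrow(report$cycles) == 0 && nrow(report$dangling) == 0 &&
    nrow(report$off_axis_sites) == 0
}

format_validation <- function(rep) {
  out <- character()
  if (nrow(rep$cycles)) {
    out <- c(out, paste0("  cycle [", rep$cycles$axis, "]: ", rep$cycles$cycle))
  }
  if (nrow(rep$dangling)) {
    out <- c(out, sprintf("  dangling %s edge: %s -> %s",
                          rep$dangling$table, rep$dangling$from, rep$dangling$to))
  }
  if (nrow(rep$off_axis_sites)) {
    out <- c(out, sprintf("  off-axis site filler: %s -> %s",
                          rep$off_axis_sites$concept, rep$off_axis_sites$filler))
  }
  paste(out, collapse = "\n")
}

#' @export
print.ontology_validation <- function(x, ...) {
  if (ontology_valid(x)) {
    cat("<ontology_validation> clean\n")
  } else {
    cat("<ontology_validation>\n", format_validation(x), "\n", sep = "")
  }
  invisible(x)
}

# Returns one cycle (vector of ids, first repeated at the end) or NULL.
find_cycle <- function(edges) {
  if (nrow(edges) == 0) return(NULL)
  nodes <- sort_ids(c(edges$child, edges$parent))
  succ <- split(edges$parent, factor(edges$child, levels = nodes))
  state <- setNames(integer(length(nodes)), nodes) # 0 unseen, 1 on stack, 2 done
  found <- NULL
  visit <- function(v, path) {
    if (!is.null(found)) return()
    state[[v]] <<- 1L
    for (w in succ[[v]]) {
      if (!is.null(found)) return()
      if (state[[w]] == 1L) {
        i <- match(w, path)
        found <<- c(path[i:length(path)], w)
      } else if (state[[w]] == 0L) {
        visit(w, c(path, w))
      }
    }
    state[[v]] <<- 2L
  }
  for (v in nodes) if (state[[v]] == 0L) visit(v, v)
  found
}

# ---- NATIVE_TSV ----------------------------------------------------------
# Four UTF-8 tab-separated files with header rows and '#' comments:
#   concepts.tsv        id  label  axis
#   is_a.tsv            child  parent
#   part_edges.tsv      child  parent  role
#   role_assertions.tsv concept  role  value
# role_assertions carries PRIMARY_SITE fillers and MORPHOLOGY annotations
# (role HAS_MORPHOLOGY, value an ICD-O-3 code).

read_tsv_strict <- function(path, cols) {
  if (!file.exists(path)) {
    abort(paste0("missing ontology file: ", path))
  }
  df <- readr::read_tsv(path, comment = "#", col_types = readr::cols(.default = "c"),
                        progress = FALSE, show_col_types = FALSE)
  if (nrow(df) == 0 && ncol(df) == 0) {
    df <- as_tibble(setNames(rep(list(character()), length(cols)), cols))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(sprintf("%s: missing column(s) %s", path, paste(missing, collapse = ", ")))
  }
  df[cols]
}

#' Read a source ontology from NATIVE_TSV files
#'
#' Expects `concepts.tsv`, `is_a.tsv`, `part_edges.tsv` and
#' `role_assertions.tsv` under `dir` (tab-separated, UTF-8, `#` comments,
#' header rows). Axis tags are explicit in this dialect.
#'
#' @param dir Directory holding the four files.
#' @param validate Fail on structural violations (see [validate_ontology()]).
#' @return A `src_ontology`.
#' @export
read_ontology_tsv <- function(dir, validate = TRUE) {
  concepts <- read_tsv_strict(file.path(dir, "concepts.tsv"), c("id", "label", "axis"))
  is_a <- read_tsv_strict(file.path(dir, "is_a.tsv"), c("child", "parent"))
  parts <- read_tsv_strict(file.path(dir, "part_edges.tsv"), c("child", "parent", "role"))
  roles <- read_tsv_strict(file.path(dir, "role_assertions.tsv"), c("concept", "role", "value"))
  bad <- setdiff(unique(roles$role), c("PRIMARY_SITE", "HAS_MORPHOLOGY"))
  if (length(bad)) {
    abort(paste0("role_assertions.tsv: unrecognized role(s): ", paste(bad, collapse = ", ")))
  }
  ontology(
    concepts,
    is_a = is_a,
    parts = parts,
    sites = roles |> filter(.data$role == "PRIMARY_SITE") |>
      select(concept = "concept", site = "value"),
    morphs = roles |> filter(.data$role == "HAS_MORPHOLOGY") |>
      select(concept = "concept", code = "value"),
    validate = validate
  )
}

#' Write a source ontology as NATIVE_TSV files
#'
#' Inverse of [read_ontology_tsv()]; lossless for recognized constructs up to
#' row order (rows are emitted in lexicographic order).
#'
#' @param onto A `src_ontology`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_ontology_tsv <- function(onto, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name) {
    readr::write_tsv(df, file.path(dir, name), progress = FALSE)
  }
  wr(onto$concepts, "concepts.tsv")
  wr(onto$is_a, "is_a.tsv")
  wr(onto$parts, "part_edges.tsv")
  roles <- bind_rows(
    tibble(concept = onto$sites$concept, role = "PRIMARY_SITE", value = onto$sites$site),
    tibble(concept = onto$morphs$concept, role = "HAS_MORPHOLOGY", value = onto$morphs$code)
  ) |> arrange(.data$concept, .data$role, .data$value)
  wr(roles, "role_assertions.tsv")
  invisible(dir)
}

#' Load a source ontology in either supported dialect
#'
#' @param path Directory of NATIVE_TSV files, or a Turtle file for
#'   `TURTLE_OWL_SUBSET`.
#' @param dialect `"NATIVE_TSV"` or `"TURTLE_OWL_SUBSET"`.
#' @param ... Passed to the dialect reader (e.g. `anatomy_root` for Turtle).
#' @return A `src_ontology`.
#' @export
load_source_ontology <- function(path, dialect = c("NATIVE_TSV", "TURTLE_OWL_SUBSET"), ...) {
  dialect <- match.arg(dialect)
  switch(dialect,
    NATIVE_TSV = read_ontology_tsv(path, ...),
    TURTLE_OWL_SUBSET = read_ontology_ttl(path, ...)
  )
}

#' Extract the neoplasm subgraph
#'
#' Restricts the ontology to NEOPLASM-tagged concepts with their is_a edges,
#' primary-site fillers and morphology annotations (fillers point into the
#' anatomy axis and are kept as-is).
#'
#' @param onto A `src_ontology`.
#' @return A list of class `neoplasm_graph` with tibbles `concepts`, `is_a`,
#'   `sites`, `morphs`.
#' @export
extract_neoplasm_graph <- function(onto) {
  neo <- onto$concepts$id[onto$concepts$axis == "NEOPLASM"]
  structure(
    list(
      concepts = filter(onto$concepts, .data$id %in% neo),
      is_a = filter(onto$is_a, .data$child %in% neo & .data$parent %in% neo),
      sites = filter(onto$sites, .data$concept %in% neo),
      morphs = filter(onto$morphs, .data$concept %in% neo)
    ),
    class = "neoplasm_graph"
  )
}
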