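# Restricted Turtle support.
#
# Recognized constructs (the TURTLE_OWL_SUBSET dialect): class declarations,
# rdfs:subClassOf (named classes and someValuesFrom restrictions on the five
# role kinds), owl:equivalentClass with intersections/unions of the same,
# rdfs:label, and a designated annotation property carrying ICD-O-3
# morphology codes. Anything else is counted and reported, never silently
# dropped. Written by hand because no Turtle tooling is available to R here;
# the tokenizer/parser covers exactly this subset.

TTL_PREFIXES <- c(
  rdf = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  owl = "http://www.w3.org/2002/07/owl#",
  skos = "http://www.w3.org/2004/02/skos/core#",
  xsd = "http://www.w3.org/2001/XMLSchema#"
)

CURIE_NS <- "urn:lex:" # source concept ids (CURIEs) live here when serialized

ROLE_PROPERTY_NAMES <- c(
  anatomic_structure_is_physical_part_of = "PART_PHYSICAL",
  anatomic_structure_has_location = "PART_LOCATION",
  part_of = "PART_PHYSICAL",
  disease_has_primary_anatomic_site = "PRIMARY_SITE",
  disease_has_finding = "HAS_FINDING"
)

MORPH_ANNOTATION <- "icdo3Morphology"
ANATOMY_ROOT_MARKER <- "OL:AnatomyRoot"
NEOPLASM_ROOT_MARKER <- "OL:NeoplasmRoot"

# --- tokenizer ------------------------------------------------------------

ttl_tokenize <- function(text) {
  # strip comments outside string literals, line by line
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  strip <- function(line) {
    out <- character()
    in_str <- FALSE
    in_iri <- FALSE
    chars <- strsplit(line, "", fixed = TRUE)[[1]]
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[[i]]
      if (ch == "\"" && !in_iri) in_str <- !in_str
      if (ch == "<" && !in_str) in_iri <- TRUE
      if (ch == ">" && !in_str) in_iri <- FALSE
      if (ch == "#" && !in_str && !in_iri) break
      out <- c(out, ch)
      i <- i + 1L
    }
    paste(out, collapse = "")
  }
  text <- paste(vapply(lines, strip, character(1)), collapse = "\n")
  pattern <- paste0(
    "(\"(?:[^\"\\\\]|\\\\.)*\")",      # string literal
    "|(<[^>]*>)",                      # IRI
    "|(@prefix|@base)",                # directives
    "|(\\^\\^)",
    "|([][();,.])",                    # punctuation
    "|([A-Za-z_][A-Za-z0-9_.-]*)?:([A-Za-z0-9_][A-Za-z0-9_./%-]*)?", # pname
    "|\\ba\\b"
  )
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[[1]] == -1) return(character())
  regmatches(text, list(m))[[1]]
}

# --- parser ---------------------------------------------------------------

ttl_parse <- function(path) {
  text <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  toks <- ttl_tokenize(text)
  pos <- 1L
  n <- length(toks)
  prefixes <- c(TTL_PREFIXES)
  peek <- function() if (pos <= n) toks[[pos]] else NA_character_
  advance <- function() {
    t <- peek()
    pos <<- pos + 1L
    t
  }
  expect <- function(tok) {
    t <- advance()
    if (!identical(t, tok)) {
      abort(sprintf("Turtle parse error near token %d: expected '%s', got '%s'",
                    pos - 1L, tok, t %||% "<eof>"))
    }
    t
  }
  resolve <- function(tok) {
    if (is.na(tok)) abort("Turtle parse error: unexpected end of input")
    if (tok == "a") return("rdf:type")
    if (startsWith(tok, "<")) {
      iri <- substr(tok, 2L, nchar(tok) - 1L)
      if (startsWith(iri, CURIE_NS)) return(substring(iri, nchar(CURIE_NS) + 1L))
      for (p in names(prefixes)) {
        if (startsWith(iri, prefixes[[p]])) {
          return(paste0(p, ":", substring(iri, nchar(prefixes[[p]]) + 1L)))
        }
      }
      return(iri)
    }
    if (grepl(":", tok, fixed = TRUE)) {
      p <- sub(":.*$", "", tok)
      if (p == "") p <- "%default%"
      local <- sub("^[^:]*:", "", tok)
      base <- prefixes[p]
      if (!is.na(base)) {
        if (identical(unname(base), CURIE_NS)) return(local)
        if (startsWith(unname(base), CURIE_NS)) {
          return(paste0(substring(unname(base), nchar(CURIE_NS) + 1L), local))
        }
        if (p %in% names(TTL_PREFIXES)) return(tok)
        return(local) # package namespace or local prefix: bare local name
      }
      return(tok)
    }
    tok
  }
  parse_object <- function() {
    t <- peek()
    if (identical(t, "[")) {
      advance()
      node <- list(kind = "bnode", props = list())
      while (!identical(peek(), "]")) {
        pred <- resolve(advance())
        repeat {
          obj <- parse_object()
          node$props[[length(node$props) + 1L]] <- list(pred = pred, obj = obj)
          if (identical(peek(), ",")) advance() else break
        }
        if (identical(peek(), ";")) advance()
      }
      expect("]")
      node
    } else if (identical(t, "(")) {
      advance()
      items <- list()
      while (!identical(peek(), ")")) {
        items[[length(items) + 1L]] <- parse_object()
      }
      expect(")")
      list(kind = "list", items = items)
    } else if (startsWith(t %||% "", "\"")) {
      advance()
      val <- gsub("\\\"", "\"", substr(t, 2L, nchar(t) - 1L), fixed = TRUE)
      if (identical(peek(), "^^")) {
        advance()
        advance() # datatype, ignored
      }
      list(kind = "literal", value = val)
    } else {
      list(kind = "iri", value = resolve(advance()))
    }
  }
  statements <- list()
  while (pos <= n) {
    t <- peek()
    if (identical(t, "@prefix")) {
      advance()
      pname <- advance()
      p <- sub(":$", "", sub(":.*$", ":", pname))
      p <- sub(":", "", pname, fixed = TRUE)
      p <- sub("^([A-Za-z0-9_.-]*):?.*$", "\\1", pname)
      if (p == "") p <- "%default%"
      iri_tok <- advance()
      iri <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      prefixes[[p]] <- iri
      expect(".")
      next
    }
    subj <- resolve(advance())
    props <- list()
    repeat {
      pred <- resolve(advance())
      repeat {
        obj <- parse_object()
        props[[length(props) + 1L]] <- list(pred = pred, obj = obj)
        if (identical(peek(), ",")) advance() else break
      }
      if (identical(peek(), ";")) {
        advance()
        if (identical(peek(), ".")) { advance(); break }
      } else {
        expect(".")
        break
      }
    }
    statements[[length(statements) + 1L]] <- list(subject = subj, props = props)
  }
  statements
}

restriction_of <- function(bnode) {
  # returns list(role=..., filler=...) or NULL
  if (!identical(bnode$kind, "bnode")) return(NULL)
  preds <- map_chr(bnode$props, "pred")
  get1 <- function(p) {
    i <- which(preds == p)
    if (length(i)) bnode$props[[i[[1]]]]$obj else NULL
  }
  ty <- get1("rdf:type")
  if (is.null(ty) || !identical(ty$value, "owl:Restriction")) return(NULL)
  prop <- get1("owl:onProperty")
  filler <- get1("owl:someValuesFrom")
  if (is.null(prop) || is.null(filler) || filler$kind != "iri") return(NULL)
  name <- sub("^.*[:#/]", "", prop$value)
  role <- ROLE_PROPERTY_NAMES[name]
  if (is.na(role)) return(NULL)
  list(role = unname(role), filler = filler$value)
}

#' Read a source ontology from a restricted Turtle file
#'
#' Axis tagging follows the root-descendant convention: concepts whose
#' `rdfs:subClassOf` chains reach the configured anatomy (neoplasm) root are
#' tagged `ANATOMY` (`NEOPLASM`); everything else is `OTHER`. Edges to the
#' root markers are tag carriers only and are not recorded as is_a edges.
#' Unrecognized statements are counted and reported via a message and the
#' `"n_unrecognized"` attribute.
#'
#' @param path Turtle file.
#' @param anatomy_root,neoplasm_root Root marker ids.
#' @param validate Fail on structural violations.
#' @return A `src_ontology`.
#' @export
read_ontology_ttl <- function(path, anatomy_root = ANATOMY_ROOT_MARKER,
                              neoplasm_root = NEOPLASM_ROOT_MARKER,
                              validate = TRUE) {
  statements <- ttl_parse(path)
  ids <- character()
  labels <- list()
  is_a <- list()
  parts <- list()
  sites <- list()
  morphs <- list()
  root_edges <- list()
  unrecognized <- 0L
  declare <- function(id) {
    if (!id %in% ids) ids <<- c(ids, id)
  }
  handle_super <- function(subj, obj) {
    if (obj$kind == "iri") {
      if (obj$value %in% c(anatomy_root, neoplasm_root)) {
        root_edges[[length(root_edges) + 1L]] <<- c(subj, obj$value)
      } else if (!startsWith(obj$value, "skos:") && !startsWith(obj$value, "owl:")) {
        is_a[[length(is_a) + 1L]] <<- c(subj, obj$value)
      }
      return(TRUE)
    }
    r <- restriction_of(obj)
    if (is.null(r)) return(FALSE)
    if (r$role %in% c("PART_PHYSICAL", "PART_LOCATION")) {
      parts[[length(parts) + 1L]] <<- c(subj, r$filler, r$role)
    } else if (r$role == "PRIMARY_SITE") {
      sites[[length(sites) + 1L]] <<- c(subj, r$filler)
    } else {
      return(FALSE) # HAS_FINDING on a source concept is not part of the subset
    }
    TRUE
  }
  for (st in statements) {
    subj <- st$subject
    if (startsWith(subj, "owl:") || startsWith(subj, "skos:")) next
    if (subj %in% c(anatomy_root, neoplasm_root)) next
    types <- map_chr(keep(st$props, function(p) {
      p$pred == "rdf:type" && p$obj$kind == "iri"
    }), function(p) p$obj$value)
    if (any(types %in% c("owl:ObjectProperty", "owl:AnnotationProperty"))) next
    declare(subj)
    for (pr in st$props) {
      pred <- pr$pred
      obj <- pr$obj
      ok <- FALSE
      if (pred == "rdf:type") {
        ok <- obj$kind == "iri" &&
          obj$value %in% c("owl:Class", "owl:ObjectProperty",
                           "owl:AnnotationProperty")
      } else if (pred == "rdfs:label") {
        if (obj$kind == "literal") {
          labels[[subj]] <- obj$value
          ok <- TRUE
        }
      } else if (pred == "rdfs:subClassOf") {
        ok <- handle_super(subj, obj)
      } else if (pred == "owl:equivalentClass") {
        # intersections/unions of named classes and restrictions
        if (obj$kind == "bnode") {
          preds <- map_chr(obj$props, "pred")
          i <- which(preds %in% c("owl:intersectionOf", "owl:unionOf"))
          if (length(i)) {
            items <- obj$props[[i[[1]]]]$obj$items
            ok <- TRUE
            for (it in items) {
              if (!handle_super(subj, it)) ok <- FALSE
            }
          }
        }
      } else if (sub("^.*[:#/]", "", pred) == MORPH_ANNOTATION) {
        if (obj$kind == "literal") {
          morphs[[length(morphs) + 1L]] <- c(subj, obj$value)
          ok <- TRUE
        }
      }
      if (!ok) unrecognized <- unrecognized + 1L
    }
  }
  # axis tags: reachability to the root markers over is_a + root edges
  all_isa <- c(is_a, root_edges)
  parent_of <- list()
  for (e in all_isa) parent_of[[e[[1]]]] <- c(parent_of[[e[[1]]]], e[[2]])
  reaches <- function(id, target) {
    seen <- character()
    queue <- id
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1L]
      if (v == target) return(TRUE)
      if (v %in% seen) next
      seen <- c(seen, v)
      queue <- c(queue, parent_of[[v]])
    }
    FALSE
  }
  axis <- vapply(ids, function(id) {
    if (reaches(id, anatomy_root)) "ANATOMY"
    else if (reaches(id, neoplasm_root)) "NEOPLASM"
    else "OTHER"
  }, character(1))
  to_tbl <- function(lst, cols) {
    if (!length(lst)) {
      return(as_tibble(setNames(rep(list(character()), length(cols)), cols)))
    }
    m <- do.call(rbind, lst)
    as_tibble(setNames(as.data.frame(m, stringsAsFactors = FALSE), cols))
  }
  if (unrecognized > 0) {
    inform(sprintf("read_ontology_ttl: %d unrecognized statement(s) skipped", unrecognized))
  }
  onto <- ontology(
    tibble(id = ids,
           label = map_chr(ids, function(i) labels[[i]] %||% i),
           axis = unname(axis)),
    is_a = to_tbl(is_a, c("child", "parent")),
    parts = to_tbl(parts, c("child", "parent", "role")),
    sites = to_tbl(sites, c("concept", "site")),
    morphs = to_tbl(morphs, c("concept", "code")),
    validate = validate
  )
  attr(onto, "n_unrecognized") <- unrecognized
  onto
}

# --- writers --------------------------------------------------------------

curie_prefixes_of <- function(ids) {
  with_pre <- grepl(":", ids, fixed = TRUE)
  sort(unique(sub(":.*$", "", ids[with_pre])))
}

ttl_ref <- function(id) {
  ifelse(grepl(":", id, fixed = TRUE), id, paste0("ol:", id))
}

ttl_header <- function(ids, ns = DEFAULT_NS) {
  pre <- curie_prefixes_of(ids)
  c(
    sprintf("@prefix : <%s> .", ns),
    sprintf("@prefix ol: <%s> .", CURIE_NS),
    sprintf("@prefix %s: <%s%s:> .", pre, CURIE_NS, pre),
    "@prefix owl: <http://www.w3.org/2002/07/owl#> .",
    "@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .",
    "@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .",
    "@prefix skos: <http://www.w3.org/2004/02/skos/core#> .",
    ""
  )
}

esc_lit <- function(x) gsub("\"", "\\\"", x, fixed = TRUE)

#' Write a source ontology as restricted Turtle
#'
#' Inverse of [read_ontology_ttl()]: axis membership is encoded by linking
#' each concept without an is_a parent inside its axis to the configured root
#' marker; part-whole edges and primary-site assertions become
#' `someValuesFrom` restrictions; morphology annotations use the designated
#' annotation property.
#'
#' @param onto A `src_ontology`.
#' @param path Output file.
#' @param anatomy_root,neoplasm_root Root marker ids.
#' @return `path`, invisibly.
#' @export
write_ontology_ttl <- function(onto, path, anatomy_root = ANATOMY_ROOT_MARKER,
                               neoplasm_root = NEOPLASM_ROOT_MARKER) {
  ids <- onto$concepts$id
  ax <- axis_of(onto)
  role_prop <- c(PART_PHYSICAL = ":anatomic_structure_is_physical_part_of",
                 PART_LOCATION = ":anatomic_structure_has_location")
  lines <- ttl_header(c(ids, anatomy_root, neoplasm_root))
  lines <- c(lines,
             sprintf("<%s%s> a owl:Class .", CURIE_NS, anatomy_root),
             sprintf("<%s%s> a owl:Class .", CURIE_NS, neoplasm_root),
             sprintf(":%s a owl:AnnotationProperty .", MORPH_ANNOTATION),
             "")
  has_parent <- split(onto$is_a$parent, factor(onto$is_a$child, levels = ids))
  for (id in ids) {
    sup <- character()
    within_axis_parents <- intersect(has_parent[[id]], ids[ax[ids] == ax[[id]]])
    if (length(within_axis_parents) == 0 && ax[[id]] != "OTHER") {
      marker <- if (ax[[id]] == "ANATOMY") anatomy_root else neoplasm_root
      sup <- c(sup, ttl_ref(marker))
    }
    sup <- c(sup, ttl_ref(has_parent[[id]]))
    p_rows <- onto$parts[onto$parts$child == id, , drop = FALSE]
    if (nrow(p_rows)) {
      sup <- c(sup, sprintf(
        "[ a owl:Restriction ; owl:onProperty %s ; owl:someValuesFrom %s ]",
        role_prop[p_rows$role], ttl_ref(p_rows$parent)
      ))
    }
    s_rows <- onto$sites[onto$sites$concept == id, , drop = FALSE]
    if (nrow(s_rows)) {
      sup <- c(sup, sprintf(
        "[ a owl:Restriction ; owl:onProperty :disease_has_primary_anatomic_site ; owl:someValuesFrom %s ]",
        ttl_ref(s_rows$site)
      ))
    }
    label <- onto$concepts$label[onto$concepts$id == id]
    body <- c(
      "a owl:Class",
      sprintf("rdfs:label \"%s\"", esc_lit(label)),
      if (length(sup)) paste0("rdfs:subClassOf ", sup),
      sprintf(":%s \"%s\"", MORPH_ANNOTATION,
              esc_lit(onto$morphs$code[onto$morphs$concept == id]))
    )
    lines <- c(lines, paste0(ttl_ref(id), " ", paste(body, collapse = " ;\n    "), " ."))
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

# --- derivative model serialization ---------------------------------------

#' Canonical axiom table of a derivative model
#'
#' The model as a flat set of axioms: reflexive-part union definitions,
#' morphology behavior placements, diagnosis intersection definitions, SKOS
#' placements, and (optionally) code individuals typed by their direct
#' classes. The Turtle serializer emits exactly these axioms and
#' [read_model_ttl()] parses them back, so round-trip equality is set
#' equality of this table.
#'
#' @param model A `derivative_model`.
#' @param bindings Optional bindings tibble to include as individuals.
#' @return Tibble with columns `kind`, `subject`, `object`.
#' @export
model_axioms <- function(model, bindings = NULL) {
  rp <- model$rp$classes
  mo <- filter(model$axis$nodes, .data$kind != "root")
  dx <- if (is.null(model$lattice)) {
    tibble(id = character(), morph = character(), base = character())
  } else {
    model$lattice$classes
  }
  ax <- bind_rows(
    tibble(kind = "rp_union", subject = rp$id, object = rp$base),
    tibble(kind = "skos_concept", subject = rp$id, object = "skos:Concept"),
    tibble(kind = "morph_parent", subject = mo$id,
           object = ifelse(mo$kind == "behavior", MORPH_ROOT_ID, mo$parent)),
    tibble(kind = "skos_concept", subject = mo$id, object = "skos:Concept"),
    tibble(kind = "dx_finding", subject = dx$id, object = dx$morph),
    tibble(kind = "dx_site", subject = dx$id, object = rp_id(dx$base)),
    tibble(kind = "skos_concept", subject = dx$id, object = "skos:Concept")
  )
  if (!is.null(bindings)) {
    bound <- filter(bindings, .data$status == "BOUND")
    inst <- map(seq_len(nrow(bound)), function(i) {
      tibble(kind = "individual_type",
             subject = paste0(bound$system[[i]], "/", bound$code[[i]]),
             object = bound$direct[[i]])
    })
    ax <- bind_rows(ax, bind_rows(inst))
  }
  ax |> distinct() |> arrange(.data$kind, .data$subject, .data$object)
}

model_class_ref <- function(id, kind = c("auto")) {
  if (startsWith(id, "RP:")) {
    paste0(":RP_", iri_safe(rp_base(id)))
  } else if (startsWith(id, "DX:")) {
    p <- dx_parts(id)
    paste0(":DX_", iri_safe(p$morph), "_", iri_safe(p$base))
  } else {
    paste0(":M_", iri_safe(id))
  }
}

#' Serialize the derivative model as Turtle
#'
#' Reflexive-part classes are written as `equivalentClass` unions
#' (`base OR part_of SOME base`), diagnosis classes as `equivalentClass`
#' intersections of the two existential restrictions, morphology classes
#' under their behavior roots; every class is a subclass of `skos:Concept`,
#' and bound terminology codes (when given) appear as individuals typed by
#' their direct classes. Output is byte-stable for a fixed model.
#'
#' @param model A `derivative_model`.
#' @param path Output file.
#' @param bindings Optional bindings tibble.
#' @return `path`, invisibly.
#' @export
serialize_derivative_model <- function(model, path, bindings = NULL) {
  rp <- model$rp$classes
  mo <- filter(model$axis$nodes, .data$kind != "root") |> arrange(.data$id)
  dx <- if (is.null(model$lattice)) NULL else model$lattice$classes
  lines <- ttl_header(rp$base, ns = model$ns)
  lines <- c(
    lines,
    ":part_of a owl:ObjectProperty .",
    ":disease_has_finding a owl:ObjectProperty .",
    ":disease_has_primary_anatomic_site a owl:ObjectProperty .",
    sprintf(":M_%s a owl:Class ; rdfs:subClassOf skos:Concept .", iri_safe(MORPH_ROOT_ID)),
    ""
  )
  for (i in seq_len(nrow(rp))) {
    base <- rp$base[[i]]
    lines <- c(lines, sprintf(
      paste0("%s a owl:Class ;\n    rdfs:subClassOf skos:Concept ;\n",
             "    owl:equivalentClass [ a owl:Class ; owl:unionOf ( %s ",
             "[ a owl:Restriction ; owl:onProperty :part_of ; owl:someValuesFrom %s ] ) ] ."),
      model_class_ref(rp$id[[i]]), ttl_ref(base), ttl_ref(base)
    ))
  }
  lines <- c(lines, "")
  for (i in seq_len(nrow(mo))) {
    parent <- if (mo$kind[[i]] == "behavior") MORPH_ROOT_ID else mo$parent[[i]]
    lines <- c(lines, sprintf(
      "%s a owl:Class ; rdfs:label \"%s\" ; rdfs:subClassOf skos:Concept , :M_%s .",
      model_class_ref(mo$id[[i]]), esc_lit(mo$id[[i]]), iri_safe(parent)
    ))
  }
  lines <- c(lines, "")
  if (!is.null(dx)) {
    for (i in seq_len(nrow(dx))) {
      lines <- c(lines, sprintf(
        paste0("%s a owl:Class ;\n    rdfs:subClassOf skos:Concept ;\n",
               "    owl:equivalentClass [ a owl:Class ; owl:intersectionOf ( ",
               "[ a owl:Restriction ; owl:onProperty :disease_has_finding ; owl:someValuesFrom %s ] ",
               "[ a owl:Restriction ; owl:onProperty :disease_has_primary_anatomic_site ; owl:someValuesFrom %s ] ) ] ."),
        model_class_ref(dx$id[[i]]), model_class_ref(dx$morph[[i]]),
        model_class_ref(rp_id(dx$base[[i]]))
      ))
    }
  }
  if (!is.null(bindings)) {
    bound <- filter(bindings, .data$status == "BOUND") |>
      arrange(.data$system, .data$code)
    lines <- c(lines, "")
    for (i in seq_len(nrow(bound))) {
      types <- map_chr(bound$direct[[i]], model_class_ref)
      lines <- c(lines, sprintf(
        ":code_%s_%s a %s ; skos:notation \"%s\" .",
        bound$system[[i]], iri_safe(bound$code[[i]]),
        paste(types, collapse = " , "), esc_lit(bound$code[[i]])
      ))
    }
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Axiom table in serialized (IRI-local) naming
#'
#' [model_axioms()] under the local names used in the Turtle output, directly
#' comparable with [read_model_ttl()] results.
#'
#' @param model A `derivative_model`.
#' @param bindings Optional bindings tibble.
#' @return Tibble with columns `kind`, `subject`, `object`.
#' @export
model_axioms_serialized <- function(model, bindings = NULL) {
  local_ref <- function(id) sub("^:", "", map_chr(id, model_class_ref))
  ax <- model_axioms(model, bindings = bindings)
  out <- tibble(
    kind = ax$kind,
    subject = dplyr::case_when(
      ax$kind == "individual_type" ~ paste0(
        "code_", sub("/.*$", "", ax$subject), "_",
        iri_safe(sub("^[^/]*/", "", ax$subject))),
      TRUE ~ local_ref(ax$subject)
    ),
    object = dplyr::case_when(
      ax$kind == "rp_union" ~ ax$object,
      ax$kind == "skos_concept" ~ ax$object,
      TRUE ~ local_ref(ax$object)
    )
  )
  out <- bind_rows(
    out,
    tibble(kind = "skos_concept",
           subject = paste0("M_", iri_safe(MORPH_ROOT_ID)),
           object = "skos:Concept")
  )
  out |> distinct() |> arrange(.data$kind, .data$subject, .data$object)
}

#' Parse a serialized derivative model back into its axiom table
#'
#' Reads Turtle emitted by [serialize_derivative_model()] and reconstructs
#' the [model_axioms()] table, for round-trip verification.
#'
#' @param path Turtle file.
#' @return Tibble with columns `kind`, `subject`, `object`.
#' @export
read_model_ttl <- function(path) {
  statements <- ttl_parse(path)
  unref <- function(x) {
    # :RP_..., :DX_..., :M_... back to internal ids is not injective through
    # iri_safe; recover via lookup built from subjects where possible.
    x
  }
  ax <- list()
  add <- function(kind, subject, object) {
    ax[[length(ax) + 1L]] <<- tibble(kind = kind, subject = subject, object = object)
  }
  for (st in statements) {
    subj <- st$subject
    for (pr in st$props) {
      obj <- pr$obj
      if (pr$pred == "rdfs:subClassOf" && obj$kind == "iri") {
        if (obj$value == "skos:Concept") {
          add("skos_concept", subj, "skos:Concept")
        } else if (startsWith(obj$value, "M_")) {
          add("morph_parent", subj, obj$value)
        }
      } else if (pr$pred == "owl:equivalentClass" && obj$kind == "bnode") {
        preds <- map_chr(obj$props, "pred")
        iu <- which(preds == "owl:unionOf")
        ii <- which(preds == "owl:intersectionOf")
        if (length(iu)) {
          items <- obj$props[[iu[[1]]]]$obj$items
          named <- keep(items, function(x) x$kind == "iri")
          if (length(named)) add("rp_union", subj, named[[1]]$value)
        } else if (length(ii)) {
          items <- obj$props[[ii[[1]]]]$obj$items
          for (it in items) {
            r <- restriction_of(it)
            if (is.null(r)) next
            if (r$role == "HAS_FINDING") add("dx_finding", subj, r$filler)
            if (r$role == "PRIMARY_SITE") add("dx_site", subj, r$filler)
          }
        }
      } else if (pr$pred == "rdf:type" && obj$kind == "iri" &&
                 !obj$value %in% c("owl:Class", "owl:ObjectProperty",
                                   "owl:AnnotationProperty")) {
        add("individual_type", subj, obj$value)
      }
    }
  }
  out <- bind_rows(ax)
  if (nrow(out) == 0) {
    return(tibble(kind = character(), subject = character(), object = character()))
  }
  out |> distinct() |> arrange(.data$kind, .data$subject, .data$object)
}
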