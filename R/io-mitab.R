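MITAB28_NCOL <- 46L

# column indices for the fields the model populates; everything else is "-"
MITAB_COL <- list(
  id_a = 1L, id_b = 2L, detection = 7L, pubids = 9L, tax_a = 10L,
  tax_b = 11L, type_a = 21L, type_b = 22L, ann_a = 26L, ann_b = 27L,
  ann_i = 28L, host = 29L, negative = 36L, feat_a = 37L, feat_b = 38L,
  effect_a = 43L, effect_b = 44L, mechanism = 45L, causal = 46L
)

default_eco_mi_map <- function() {
  if (is.null(.mi2cast_cache$ecomap)) {
    path <- system.file("extdata", "eco_mi_detection.tsv",
                        package = "mi2castr")
    .mi2cast_cache$ecomap <-
      tibble::as_tibble(utils::read.delim(path, colClasses = "character"))
  }
  .mi2cast_cache$ecomap
}

sanitize_name <- function(x) gsub('[|\t"()]', " ", x)

mitab_term_cell <- function(id, ontology = NULL) {
  if (is.null(id)) return("-")
  db <- if (id$prefix == "mi") "psi-mi" else id$prefix
  inner <- paste0(toupper(id$prefix), ":", id$local_id)
  nm <- term_name(id, ontology)
  if (!is.na(nm) && nzchar(nm)) {
    sprintf('%s:"%s"(%s)', db, inner, sanitize_name(nm))
  } else {
    sprintf('%s:"%s"', db, inner)
  }
}

parse_term_cell <- function(cell, line, col) {
  if (cell == "-") return(NULL)
  m <- regmatches(cell,
                  regexec('^([^:"]+):"([^"]+)"(\\((.*)\\))?$', cell))[[1]]
  if (length(m) == 0L) {
    abort_parse(sprintf("line %d, column %d: malformed term cell '%s'",
                        line, col, cell))
  }
  db <- m[2]; inner <- m[3]
  if (grepl(":", inner, fixed = TRUE)) parse_identifier(inner)
  else identifier(db, inner)
}

encode_modification <- function(m) {
  paste(curie(m$modification_type),
        if (is.null(m$residue)) "-" else curie(m$residue),
        if (is.null(m$position)) "-" else m$position,
        sep = ";")
}

decode_modification <- function(x, line) {
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  if (length(parts) != 3L) {
    abort_parse(sprintf("line %d: malformed modification encoding '%s'",
                        line, x))
  }
  modification_state(
    modification_type = parts[1],
    residue = if (parts[2] != "-") parts[2],
    position = if (parts[3] != "-") as.integer(parts[3])
  )
}

feature_cell <- function(mods) {
  if (length(mods) == 0L) return("-")
  paste(vapply(mods, function(m) {
    pos <- if (is.null(m$position)) "?" else m$position
    res <- if (is.null(m$residue)) "" else
      sprintf("(%s)", curie(m$residue))
    sprintf('modification:"%s":%s-%s%s', curie(m$modification_type),
            pos, pos, res)
  }, character(1)), collapse = "|")
}

parse_feature_cell <- function(cell, line, col) {
  if (cell == "-") return(list())
  lapply(strsplit(cell, "|", fixed = TRUE)[[1]], function(f) {
    m <- regmatches(
      f,
      regexec('^modification:"([^"]+)":([0-9?]+)-[0-9?]+(\\(([^)]*)\\))?$',
              f))[[1]]
    if (length(m) == 0L) {
      abort_parse(sprintf("line %d, column %d: malformed feature '%s'",
                          line, col, f))
    }
    modification_state(
      modification_type = m[2],
      residue = if (nzchar(m[4])) m[5],
      position = if (m[3] != "?") as.integer(m[3])
    )
  })
}

# reserved-tag annotation cells: mi2cast:"key=value"|...
tags_cell <- function(pairs) {
  if (length(pairs) == 0L) return("-")
  paste(sprintf('mi2cast:"%s=%s"', vapply(pairs, `[[`, "", 1L),
                vapply(pairs, `[[`, "", 2L)), collapse = "|")
}

parse_tags_cell <- function(cell, line, col) {
  if (cell == "-") return(list())
  lapply(strsplit(cell, "|", fixed = TRUE)[[1]], function(t) {
    m <- regmatches(t, regexec('^mi2cast:"([^=]+)=([^"]*)"$', t))[[1]]
    if (length(m) == 0L) {
      abort_parse(sprintf("line %d, column %d: unrecognized annotation '%s'",
                          line, col, t))
    }
    list(m[2], m[3])
  })
}

tag <- function(key, value) list(key, value)

entity_tags <- function(e) {
  ctx <- e$context
  c(
    lapply(e$components, function(id) tag("component", curie(id))),
    if (!is.null(ctx$tissue)) list(tag("tissue", curie(ctx$tissue))),
    if (!is.null(ctx$cell)) list(tag("cell", curie(ctx$cell))),
    if (!is.null(ctx$compartment))
      list(tag("compartment", curie(ctx$compartment))),
    lapply(ctx$experimental_setup, function(id) tag("setup", curie(id)))
  )
}

interaction_tags <- function(stmt) {
  ictx <- stmt$evidence$interaction_context
  tme <- stmt$relation$target_modification_effect
  c(
    lapply(stmt$evidence$evidence_types,
           function(id) tag("evidence_type", curie(id))),
    if (!is.null(tme))
      list(tag("resulting_modification", encode_modification(tme))),
    if (!is.null(ictx$biological_activity))
      list(tag("activity", curie(ictx$biological_activity))),
    lapply(ictx$modifications,
           function(m) tag("modification", encode_modification(m))),
    if (!is.null(ictx$tissue)) list(tag("tissue", curie(ictx$tissue))),
    if (!is.null(ictx$cell)) list(tag("cell", curie(ictx$cell))),
    if (!is.null(ictx$compartment))
      list(tag("compartment", curie(ictx$compartment))),
    lapply(ictx$experimental_setup,
           function(id) tag("setup", curie(id)))
  )
}

#' PSI-MITAB 2.8 serialization
#'
#' Writes/reads the tab-delimited 46-column PSI-MITAB 2.8 layout, whose
#' trailing causal columns were designed to hold checklist-compliant causal
#' data: entity identifiers in the interactor columns, entity activities in
#' the biological-effect columns (43/44), the mechanism in the
#' causal-regulatory-mechanism column (45), the causal relation in the
#' causal-statement column (46), taxa in the taxid columns, prior
#' modifications in the feature columns, and references in the publication
#' column. Fields without a MITAB home (components, tissue/cell/compartment,
#' setup terms, ECO evidence types, the resulting target modification) are
#' carried losslessly in the annotation columns under a reserved
#' `mi2cast:"key=value"` tag, so the read direction inverts the mapping
#' exactly. Empty fields are rendered `-`; an ECO evidence type with a known
#' MI cross-reference is additionally surfaced in the
#' interaction-detection-method column.
#'
#' @param stmts A list of [causal_statement()] records.
#' @param path Optional output file; when omitted the lines are returned.
#' @param ontology Optional `mi2cast_ontology` used to decorate term cells
#'   with their quoted names.
#' @return `write_mitab28()` a character vector of lines;
#'   `read_mitab28()` a list of statements.
#' @examples
#' line <- write_mitab28(list(worked_example()), ontology = default_ontology())
#' length(strsplit(line, "\t")[[1]])  # 46
#' @export
write_mitab28 <- function(stmts, path = NULL, ontology = NULL) {
  ecomap <- default_eco_mi_map()
  lines <- vapply(stmts, function(s) {
    cols <- rep("-", MITAB28_NCOL)
    if (!is.null(s$source$identifier)) {
      cols[MITAB_COL$id_a] <- curie(s$source$identifier)
    }
    if (!is.null(s$target$identifier)) {
      cols[MITAB_COL$id_b] <- curie(s$target$identifier)
    }
    if (length(s$evidence$references) > 0L) {
      cols[MITAB_COL$pubids] <- paste(
        vapply(s$evidence$references, curie, character(1)), collapse = "|")
    }
    ev_curies <- vapply(s$evidence$evidence_types, curie, character(1))
    det <- ecomap$mi[match(ev_curies, ecomap$eco)]
    det <- det[!is.na(det)]
    if (length(det) > 0L) {
      cols[MITAB_COL$detection] <- mitab_term_cell(parse_identifier(det[1]),
                                                   ontology)
    }
    if (!is.null(s$source$context$taxon)) {
      cols[MITAB_COL$tax_a] <- paste0("taxid:",
                                      s$source$context$taxon$local_id)
    }
    if (!is.null(s$target$context$taxon)) {
      cols[MITAB_COL$tax_b] <- paste0("taxid:",
                                      s$target$context$taxon$local_id)
    }
    if (!is.null(s$evidence$interaction_context$taxon)) {
      cols[MITAB_COL$host] <- paste0(
        "taxid:", s$evidence$interaction_context$taxon$local_id)
    }
    cols[MITAB_COL$type_a] <- mitab_term_cell(s$source$biological_type,
                                              ontology)
    cols[MITAB_COL$type_b] <- mitab_term_cell(s$target$biological_type,
                                              ontology)
    cols[MITAB_COL$ann_a] <- tags_cell(entity_tags(s$source))
    cols[MITAB_COL$ann_b] <- tags_cell(entity_tags(s$target))
    cols[MITAB_COL$ann_i] <- tags_cell(interaction_tags(s))
    cols[MITAB_COL$negative] <- "false"
    cols[MITAB_COL$feat_a] <- feature_cell(s$source$context$modifications)
    cols[MITAB_COL$feat_b] <- feature_cell(s$target$context$modifications)
    cols[MITAB_COL$effect_a] <-
      mitab_term_cell(s$source$context$biological_activity, ontology)
    cols[MITAB_COL$effect_b] <-
      mitab_term_cell(s$target$context$biological_activity, ontology)
    cols[MITAB_COL$mechanism] <- mitab_term_cell(s$relation$mechanism,
                                                 ontology)
    cols[MITAB_COL$causal] <- mitab_term_cell(s$relation$relation_term,
                                              ontology)
    paste(cols, collapse = "\t")
  }, character(1))
  if (!is.null(path)) {
    writeLines(lines, path, useBytes = TRUE)
    return(invisible(lines))
  }
  lines
}

parse_taxid_cell <- function(cell, line, col) {
  if (cell == "-") return(NULL)
  if (!grepl("^taxid:", cell)) {
    abort_parse(sprintf("line %d, column %d: malformed taxid cell '%s'",
                        line, col, cell))
  }
  identifier("ncbitaxon", sub("^taxid:", "", cell))
}

parse_id_cell <- function(cell, line, col) {
  if (cell == "-") return(NULL)
  tryCatch(parse_identifier(cell), error = function(e) {
    abort_parse(sprintf("line %d, column %d: malformed CURIE '%s'",
                        line, col, cell))
  })
}

tags_of <- function(tags, key) {
  vals <- Filter(function(t) t[[1]] == key, tags)
  vapply(vals, `[[`, "", 2L)
}

#' @rdname write_mitab28
#' @param x A file path or a character vector of MITAB lines. Lines starting
#'   with `#` are skipped.
#' @export
read_mitab28 <- function(x) {
  if (length(x) == 1L && !grepl("\t", x) && file.exists(x)) {
    x <- readLines(x, warn = FALSE)
  }
  x <- x[nzchar(x) & !startsWith(x, "#")]
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    line <- x[[i]]
    cols <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(cols) != MITAB28_NCOL) {
      abort_parse(sprintf("line %d has %d columns, expected %d",
                          i, length(cols), MITAB28_NCOL))
    }
    a_tags <- parse_tags_cell(cols[MITAB_COL$ann_a], i, MITAB_COL$ann_a)
    b_tags <- parse_tags_cell(cols[MITAB_COL$ann_b], i, MITAB_COL$ann_b)
    i_tags <- parse_tags_cell(cols[MITAB_COL$ann_i], i, MITAB_COL$ann_i)
    read_entity <- function(idc, typec, taxc, featc, effc, tags) {
      bio_entity(
        identifier = parse_id_cell(cols[idc], i, idc),
        biological_type = parse_term_cell(cols[typec], i, typec),
        components = as.list(tags_of(tags, "component")),
        context = entity_context(
          biological_activity = parse_term_cell(cols[effc], i, effc),
          modifications = parse_feature_cell(cols[featc], i, featc),
          taxon = parse_taxid_cell(cols[taxc], i, taxc),
          tissue = one_or_null(tags_of(tags, "tissue")),
          cell = one_or_null(tags_of(tags, "cell")),
          compartment = one_or_null(tags_of(tags, "compartment")),
          experimental_setup = as.list(tags_of(tags, "setup"))
        )
      )
    }
    src <- read_entity(MITAB_COL$id_a, MITAB_COL$type_a, MITAB_COL$tax_a,
                       MITAB_COL$feat_a, MITAB_COL$effect_a, a_tags)
    tgt <- read_entity(MITAB_COL$id_b, MITAB_COL$type_b, MITAB_COL$tax_b,
                       MITAB_COL$feat_b, MITAB_COL$effect_b, b_tags)
    resmod <- one_or_null(tags_of(i_tags, "resulting_modification"))
    refs <- cols[MITAB_COL$pubids]
    out[[i]] <- causal_statement(
      source = src,
      target = tgt,
      relation = causal_relation(
        relation_term = parse_term_cell(cols[MITAB_COL$causal], i,
                                        MITAB_COL$causal),
        mechanism = parse_term_cell(cols[MITAB_COL$mechanism], i,
                                    MITAB_COL$mechanism),
        target_modification_effect =
          if (!is.null(resmod)) decode_modification(resmod, i)
      ),
      evidence = evidence_set(
        references = if (refs != "-")
          strsplit(refs, "|", fixed = TRUE)[[1]] else list(),
        evidence_types = as.list(tags_of(i_tags, "evidence_type")),
        interaction_context = entity_context(
          biological_activity = one_or_null(tags_of(i_tags, "activity")),
          modifications = lapply(tags_of(i_tags, "modification"),
                                 decode_modification, line = i),
          taxon = parse_taxid_cell(cols[MITAB_COL$host], i,
                                   MITAB_COL$host),
          tissue = one_or_null(tags_of(i_tags, "tissue")),
          cell = one_or_null(tags_of(i_tags, "cell")),
          compartment = one_or_null(tags_of(i_tags, "compartment")),
          experimental_setup = as.list(tags_of(i_tags, "setup"))
        )
      )
    )
  }
  out
}

one_or_null <- function(x) if (length(x) == 0L) NULL else x[[1L]]
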