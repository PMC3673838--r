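#' Read a study table into an evidence graph
#'
#' The canonical input is one row per study with columns `id`, `phase`,
#' `year` and optionally `label`, `seq`, `outcome`, `status`, `children`
#' (semicolon-separated ids of this study's lineage children) and
#' `same_report_children` (children published in the same report). An empty
#' cell, `-` or an en-dash means "no children". Outcome labels are parsed
#' case-insensitively. Unknown columns are kept on the study table and
#' survive a round-trip through [write_study_table()]. The JSON encoding is
#' a nested document `{phases, studies, edges}` carrying the phase schema
#' explicitly.
#'
#' @param path File path (or, for csv/tsv, literal text wrapped in [I()]).
#' @param format `"csv"`, `"tsv"` or `"json"`; inferred from the file
#'   extension when `NULL`.
#' @param phases Phase schema for csv/tsv tables (JSON documents carry
#'   their own).
#' @return A validated `aero_graph`.
#' @examples
#' path <- system.file("extdata", "moxifloxacin.csv", package = "aerograph")
#' read_study_table(path)
#' @export
read_study_table <- function(path, format = NULL, phases = aero_phases()) {
  format <- format %||% guess_format(path)
  if (format == "json") {
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    schema <- aero_phases(doc$phases$phase, doc$phases$label)
    edges <- if (!is.null(doc$edges) && length(doc$edges)) doc$edges else NULL
    return(aero_graph(doc$studies, edges, phases = schema))
  }
  delim <- c(csv = ",", tsv = "\t")[[format]]
  tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  need <- setdiff(c("id", "phase", "year"), names(tab))
  if (length(need)) {
    rlang::abort(paste0("study table is missing required column(s): ",
                        paste(need, collapse = ", ")),
                 class = "aero_error_input")
  }
  edges <- parse_children(tab)
  extra <- tab[, setdiff(names(tab), c("children", "same_report_children")),
               drop = FALSE]
  aero_graph(extra, edges, phases = phases)
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(as.character(path)))
  if (ext %in% c("csv", "tsv", "json")) return(ext)
  rlang::abort(paste0("cannot infer format from extension: ", ext),
               class = "aero_error_input")
}

split_ids <- function(cell) {
  cell <- as.character(cell)
  if (is.na(cell)) return(character())
  cell <- trimws(cell)
  if (cell %in% c("", "-", "–")) return(character())
  trimws(strsplit(cell, ";", fixed = TRUE)[[1]])
}

parse_children <- function(tab) {
  rows <- purrr::map(seq_len(nrow(tab)), function(i) {
    kids <- if ("children" %in% names(tab)) split_ids(tab$children[i]) else character()
    same <- if ("same_report_children" %in% names(tab)) {
      split_ids(tab$same_report_children[i])
    } else {
      character()
    }
    dangling <- setdiff(c(kids, same), tab$id)
    if (length(dangling)) {
      rlang::abort(paste0("row ", i, " (", tab$id[i], "): child id(s) not in table: ",
                          paste(dangling, collapse = ", ")),
                   class = "aero_error_input")
    }
    tibble::tibble(parent = tab$id[i], child = c(kids, same),
                   same_report = rep(c(FALSE, TRUE), c(length(kids), length(same))))
  })
  purrr::list_rbind(rows)
}

#' Write an evidence graph as a study table
#'
#' The inverse of [read_study_table()]: `read(write(g))` reproduces the
#' graph exactly (studies, edges, same-report flags, contemplated status).
#'
#' @param g An `aero_graph`.
#' @param path Output file; when `NULL` the serialized text is returned.
#' @param format `"csv"`, `"tsv"` or `"json"`; inferred from `path` when
#'   `NULL`.
#' @return The path (invisibly) when writing to a file, else a character
#'   string.
#' @examples
#' csv <- write_study_table(fixture_toy("figure1"), format = "csv")
#' @export
write_study_table <- function(g, path = NULL, format = NULL) {
  format <- format %||% guess_format(path)
  if (format == "json") {
    txt <- jsonlite::toJSON(list(
      phases = g$phases[, c("phase", "label", "rank")],
      studies = g$studies,
      edges = g$edges
    ), dataframe = "rows", auto_unbox = TRUE, na = "null", pretty = TRUE)
    if (is.null(path)) return(as.character(txt))
    writeLines(txt, path)
    return(invisible(path))
  }
  join <- function(ids) if (length(ids)) paste(ids, collapse = ";") else ""
  e <- g$edges
  tab <- g$studies |>
    dplyr::mutate(
      children = purrr::map_chr(
        .data$id, ~ join(e$child[e$parent == .x & !e$same_report])),
      same_report_children = purrr::map_chr(
        .data$id, ~ join(e$child[e$parent == .x & e$same_report]))
    )
  delim <- c(csv = ",", tsv = "\t")[[format]]
  if (is.null(path)) {
    return(readr::format_delim(tab, delim = delim, na = ""))
  }
  readr::write_delim(tab, path, delim = delim, na = "")
  invisible(path)
}

#' Export an evidence graph to an exchange format
#'
#' DOT (Graphviz), GraphML or nested JSON. Node attributes carry phase,
#' year, outcome and status; edges carry the same-report flag (DOT renders
#' same-report edges with `dir=none`, i.e. no arrowhead).
#'
#' @param g An `aero_graph`.
#' @param format `"dot"`, `"graphml"` or `"json"`.
#' @param path Output file; when `NULL` the document is returned as a
#'   character string.
#' @return The document text, or the path invisibly.
#' @examples
#' cat(export_graph(fixture_toy("figure1"), "dot"))
#' @export
export_graph <- function(g, format = c("dot", "graphml", "json"), path = NULL) {
  format <- match.arg(format)
  txt <- switch(format,
    dot = dot_document(g, styled = FALSE),
    json = write_study_table(g, format = "json"),
    graphml = {
      tmp <- tempfile(fileext = ".graphml")
      on.exit(unlink(tmp), add = TRUE)
      ig <- as_igraph(g)
      igraph::E(ig)$same_report <- as.integer(igraph::E(ig)$same_report)
      igraph::write_graph(ig, tmp, format = "graphml")
      paste(readLines(tmp, warn = FALSE), collapse = "\n")
    }
  )
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

dot_quote <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

# shared DOT emitter: plain attribute export, or the canonical styled view
dot_document <- function(g, styled = FALSE, style = aero_style()) {
  s <- g$studies
  e <- g$edges
  lines <- c("digraph aero {", "  rankdir=BT;")
  if (styled) {
    lines <- c(lines, "  node [style=filled, shape=circle, fontsize=10];")
  }
  for (i in seq_len(nrow(s))) {
    attrs <- c(
      paste0("phase=", dot_quote(s$phase[i])),
      paste0("year=", s$year[i]),
      paste0("outcome=", dot_quote(ifelse(is.na(s$outcome[i]), "", s$outcome[i]))),
      paste0("status=", dot_quote(s$status[i])),
      paste0("label=", dot_quote(s$id[i]))
    )
    if (styled) {
      attrs <- c(attrs, node_style_attrs(s$outcome[i], s$status[i], style))
    }
    lines <- c(lines, paste0("  ", dot_quote(s$id[i]), " [",
                             paste(attrs, collapse = ", "), "];"))
  }
  for (i in seq_len(nrow(e))) {
    attrs <- if (e$same_report[i]) " [dir=none, same_report=true]" else ""
    lines <- c(lines, paste0("  ", dot_quote(e$parent[i]), " -> ",
                             dot_quote(e$child[i]), attrs, ";"))
  }
  paste(c(lines, "}"), collapse = "\n")
}

node_style_attrs <- function(outcome, status, style) {
  if (status == "contemplated") {
    c(paste0("fillcolor=", dot_quote(style$fill_contemplated)),
      paste0("color=", dot_quote(style$border_contemplated)),
      "penwidth=2")
  } else {
    fill <- c(positive = style$fill_positive, negative = style$fill_negative,
              inconclusive = style$fill_inconclusive)[[outcome]]
    c(paste0("fillcolor=", dot_quote(fill)), "color=\"#000000\"")
  }
}
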