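#' Visual style for the canonical evidence-graph view
#'
#' Outcome fills follow the field's traffic-light convention: green for
#' positive, red for negative, yellow for inconclusive; contemplated future
#' studies are white with a blue border. Overrides can be supplied directly
#' or via a small `key=value` config file. Documented keys:
#' `fill_positive`, `fill_negative`, `fill_inconclusive`,
#' `fill_contemplated`, `border_contemplated`, `node_radius` (SVG pixels),
#' `x_offset` (fraction of a year separating same-year studies in a band).
#'
#' @param ... Named overrides of the keys above.
#' @param config_file Optional path to a `key=value` file (one per line,
#'   `#` comments allowed).
#' @return A named list of style settings.
#' @examples
#' aero_style(fill_positive = "#00aa55")
#' @export
aero_style <- function(..., config_file = NULL) {
  style <- list(
    fill_positive = "#2ca25f",
    fill_negative = "#de2d26",
    fill_inconclusive = "#fec44f",
    fill_contemplated = "#ffffff",
    border_contemplated = "#3182bd",
    node_radius = 14,
    x_offset = 0.25
  )
  if (!is.null(config_file)) {
    lines <- trimws(readLines(config_file, warn = FALSE))
    # whole-line comments only: '#' also starts hex color values
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      if (length(kv) != 2L) {
        rlang::abort(paste0("malformed style line: ", ln),
                     class = "aero_error_input")
      }
      style[[trimws(kv[1])]] <- type_coerce(trimws(kv[2]))
    }
  }
  over <- list(...)
  unknown <- setdiff(c(names(over)), names(style))
  if (length(unknown)) {
    rlang::abort(paste0("unknown style key(s): ", paste(unknown, collapse = ", ")),
                 class = "aero_error_input")
  }
  style[names(over)] <- over
  style
}

type_coerce <- function(x) {
  n <- suppressWarnings(as.numeric(x))
  if (!is.na(n)) n else x
}

#' Layered layout: time on x, phase strata on y
#'
#' Assigns each study deterministic coordinates: y is the phase rank
#' (lowest phase at the bottom) and x is the calendar year, with same-year
#' studies in one band fanned out by a fixed offset following the temporal
#' total order, so x strictly increases with [temporal_order()] within
#' every band and no two studies coincide.
#'
#' @param g An `aero_graph`.
#' @param style An [aero_style()] list (`x_offset` is used).
#' @return A tibble `id`, `phase`, `year`, `x`, `y` classed `aero_layout`.
#' @examples
#' aero_layout(fixture_toy("figure1"))
#' @export
aero_layout <- function(g, style = aero_style()) {
  ord <- temporal_order(g)
  s <- g$studies[match(ord, g$studies$id), , drop = FALSE]
  out <- s |>
    dplyr::mutate(
      y = phase_rank(g$phases, .data$phase),
      .ord = dplyr::row_number()
    ) |>
    dplyr::group_by(.data$phase, .data$year) |>
    dplyr::mutate(x = .data$year + (dplyr::row_number() - 1L) * style$x_offset) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord) |>
    dplyr::select("id", "phase", "year", "x", "y")
  class(out) <- c("aero_layout", class(out))
  out
}

#' Render the canonical evidence-graph view
#'
#' Produces the layered visualization as a document: nodes colored by
#' outcome (green/red/yellow), contemplated studies white with a blue
#' border, lineage edges arrowheaded, same-report edges plain. `"dot"`
#' emits Graphviz DOT (spline routing left to the layout engine); `"svg"`
#' emits a standalone SVG placing nodes at the [aero_layout()] coordinates.
#'
#' @param g An `aero_graph`.
#' @param target `"dot"` or `"svg"`.
#' @param path Output file; when `NULL` the document text is returned.
#' @param style An [aero_style()] list.
#' @return Document text, or the path invisibly.
#' @examples
#' svg <- aero_render(fixture_toy("figure3"), "svg")
#' @export
aero_render <- function(g, target = c("dot", "svg"), path = NULL,
                        style = aero_style()) {
  target <- match.arg(target)
  txt <- switch(target,
    dot = dot_document(g, styled = TRUE, style = style),
    svg = svg_document(g, style = style)
  )
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

svg_document <- function(g, style = aero_style()) {
  s <- g$studies
  if (nrow(s) == 0L) {
    return(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="200" ',
                  'height="100" viewBox="0 0 200 100"></svg>'))
  }
  lay <- aero_layout(g, style)
  r <- style$node_radius
  px_year <- 6 * r
  px_band <- 5 * r
  x0 <- min(lay$x)
  xs <- (lay$x - x0) * px_year + 3 * r
  ymax <- max(lay$y)
  ys <- (ymax - lay$y) * px_band + 3 * r
  w <- ceiling(max(xs) + 3 * r)
  h <- ceiling(max(ys) + 3 * r)
  pos <- stats::setNames(purrr::map2(xs, ys, c), lay$id)
  fills <- c(positive = style$fill_positive, negative = style$fill_negative,
             inconclusive = style$fill_inconclusive)
  lines <- c(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
            w, h, w, h),
    '<defs><marker id="arrow" viewBox="0 0 10 10" refX="9" refY="5" markerWidth="7" markerHeight="7" orient="auto-start-reverse"><path d="M 0 0 L 10 5 L 0 10 z"/></marker></defs>'
  )
  e <- g$edges
  for (i in seq_len(nrow(e))) {
    p <- pos[[e$parent[i]]]
    c_ <- pos[[e$child[i]]]
    # trim the segment to the node rims so the arrowhead is visible
    v <- c_ - p
    len <- sqrt(sum(v^2))
    if (len < 1e-9) next
    p2 <- p + v / len * r
    c2 <- c_ - v / len * r
    marker <- if (e$same_report[i]) "" else ' marker-end="url(#arrow)"'
    lines <- c(lines, sprintf(
      '<line x1="%.1f" y1="%.1f" x2="%.1f" y2="%.1f" stroke="#555555" stroke-width="1.5"%s/>',
      p2[1], p2[2], c2[1], c2[2], marker))
  }
  for (i in seq_len(nrow(lay))) {
    row <- s[match(lay$id[i], s$id), ]
    if (row$status == "contemplated") {
      fill <- style$fill_contemplated
      stroke <- style$border_contemplated
      swidth <- 3
    } else {
      fill <- fills[[row$outcome]]
      stroke <- "#000000"
      swidth <- 1
    }
    lines <- c(lines,
      sprintf('<circle cx="%.1f" cy="%.1f" r="%d" fill="%s" stroke="%s" stroke-width="%d"/>',
              xs[i], ys[i], r, fill, stroke, swidth),
      sprintf('<text x="%.1f" y="%.1f" text-anchor="middle" dominant-baseline="middle" font-size="%d" font-family="sans-serif">%s</text>',
              xs[i], ys[i], ceiling(0.8 * r), lay$id[i]))
  }
  paste(c(lines, "</svg>"), collapse = "\n")
}

#' Plot an evidence graph with ggplot2
#'
#' The same layered view as [aero_render()], as a ggplot: time on x, phase
#' strata on y, outcome colors, blue-bordered contemplated nodes, dashed
#' same-report edges without arrowheads.
#'
#' @param object An `aero_graph`.
#' @param ... Passed to [aero_style()].
#' @return A ggplot object.
#' @examples
#' autoplot(fixture_moxifloxacin("figure4"))
#' @method autoplot aero_graph
#' @export
autoplot.aero_graph <- function(object, ...) {
  g <- object
  style <- aero_style(...)
  lay <- aero_layout(g, style)
  nodes <- dplyr::left_join(lay, g$studies[, c("id", "outcome", "status")],
                            by = "id") |>
    dplyr::mutate(fill_key = ifelse(.data$status == "contemplated",
                                    "contemplated", .data$outcome))
  seg <- g$edges |>
    dplyr::left_join(lay[, c("id", "x", "y")], by = c(parent = "id")) |>
    dplyr::left_join(lay[, c("id", "x", "y")], by = c(child = "id"),
                     suffix = c("", "end")) |>
    dplyr::rename(xend = "xend", yend = "yend")
  fills <- c(positive = style$fill_positive, negative = style$fill_negative,
             inconclusive = style$fill_inconclusive,
             contemplated = style$fill_contemplated)
  p <- ggplot2::ggplot()
  if (nrow(seg)) {
    p <- p +
      ggplot2::geom_segment(
        data = seg[!seg$same_report, ],
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend),
        color = "grey40",
        arrow = ggplot2::arrow(length = ggplot2::unit(6, "pt"),
                               type = "closed")) +
      ggplot2::geom_segment(
        data = seg[seg$same_report, ],
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                     yend = .data$yend),
        color = "grey40", linetype = "dashed")
  }
  p +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$fill_key,
                   color = .data$status),
      shape = 21, size = 8, stroke = 1.1) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id), size = 2.6) +
    ggplot2::scale_fill_manual(values = fills, name = "outcome") +
    ggplot2::scale_color_manual(
      values = c(completed = "black",
                 contemplated = style$border_contemplated),
      name = "status") +
    ggplot2::scale_y_continuous(
      breaks = g$phases$rank, labels = g$phases$label,
      limits = range(g$phases$rank) + c(-0.5, 0.5)) +
    ggplot2::labs(x = "year", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
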