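# Multi-track protein figure. The figure is composed as a display list of
# primitive elements (rect/line/circle/text) organized into named groups,
# then emitted either as hand-written SVG (the canonical vector format:
# no timestamps, no random ids, fixed numeric formatting, so identical
# specs give byte-identical files) or replayed onto a base-graphics
# device for PDF and PNG.
#
# Tracks, top to bottom: title, secondary mutation track (if any),
# primary mutation track, backbone with domain boxes, PTM marks,
# reference-sequence letters, conservation letters, conservation score
# bars, residue-number axis. Horizontal placement of residue p is affine
# over the zoom window; a width-1 domain still spans [start-0.5, end+0.5]
# residue units so it stays visible.

CANVAS_W <- 864
MARGIN_L <- 56
MARGIN_R <- 20

TRACK_HEIGHTS <- c(title = 34, mutations_secondary = 92, mutations_primary = 92,
                   backbone = 46, ptm = 20, reference_sequence = 20,
                   conservation = 20, score = 46, axis = 34)

CONS_BIN_COLORS <- c(full = "#1a9641", high = "#fdae61", low = "#d7191c")

#' Default rendering configuration
#'
#' Flat key/value settings controlling colors and raster geometry. Any
#' subset can be overridden via [read_render_config()] or by passing a
#' named list to [render()].
#'
#' @return Named list of settings: `color_primary`, `color_secondary`,
#'   `domain_palette` (character vector cycled over domains in file
#'   order), `color_ptm`, `dpi`, `width_in`, `labels` (draw mutation
#'   labels, TRUE/FALSE).
#' @export
render_config <- function() {
  list(color_primary = "#2166ac",
       color_secondary = "#b2182b",
       domain_palette = c("#66c2a5", "#fc8d62", "#8da0cb", "#e78ac3",
                          "#a6d854", "#ffd92f"),
       color_ptm = "#7b3294",
       dpi = 150,
       width_in = 12,
       labels = TRUE)
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; '#' starts a comment. `domain_palette`
#' takes a comma-separated color list; `dpi` and `width_in` are numeric;
#' `labels` is true/false. Unknown keys are an error.
#'
#' @param path Path to the configuration file.
#' @return A full configuration list (defaults overridden by the file).
#' @export
read_render_config <- function(path) {
  cfg <- render_config()
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw) & !startsWith(raw, "#")]
  for (line in raw) {
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    if (length(kv) < 2L)
      stop(sprintf("config line not of the form key = value: '%s'", line),
           call. = FALSE)
    key <- trimws(kv[1L])
    val <- trimws(paste(kv[-1L], collapse = "="))
    if (!key %in% names(cfg))
      stop(sprintf("unknown config key '%s'", key), call. = FALSE)
    cfg[[key]] <- switch(key,
      domain_palette = trimws(strsplit(val, ",", fixed = TRUE)[[1L]]),
      dpi = as.numeric(val),
      width_in = as.numeric(val),
      labels = tolower(val) %in% c("true", "yes", "1"),
      val)
  }
  cfg
}

#' Specify a protein figure
#'
#' Collects everything one rendering needs: the protein context, one or
#' two mutation sets, domains, PTM sites, an optional conservation
#' profile, display flags and an optional zoom window.
#'
#' @param context A [protein_context()].
#' @param mutations Primary mutation data frame.
#' @param mutations2 Optional second mutation set, drawn as its own track
#'   above the primary one.
#' @param domains Optional architecture data frame.
#' @param ptms Optional integer vector of PTM positions.
#' @param profile Optional `conservation_profile`; required when
#'   `show_score` or `show_reference_sequence` is set.
#' @param show_score Draw the numeric conservation score as a bar track.
#' @param show_reference_sequence Draw the reference residue letters
#'   (only legible, and only drawn, for windows of at most 200 residues).
#' @param show_gridlines Draw vertical grid lines at the axis ticks.
#' @param zoom Optional `c(start, end)`, 1-based inclusive residue window.
#' @param track_labels Labels for the mutation tracks,
#'   `c(primary = ..., secondary = ...)`.
#' @return An object of class `plot_spec`.
#' @examples
#' ctx <- protein_context(1114, "RET")
#' mut <- data.frame(protein = "RET", gene = "RET", position = 634L,
#'                   ref = "C", alt = "R")
#' spec <- plot_spec(ctx, mut)
#' @export
plot_spec <- function(context, mutations, mutations2 = NULL, domains = NULL,
                      ptms = NULL, profile = NULL, show_score = FALSE,
                      show_reference_sequence = FALSE, show_gridlines = FALSE,
                      zoom = NULL,
                      track_labels = c(primary = "Mutations",
                                       secondary = "Mutations 2")) {
  stopifnot(inherits(context, "protein_context"))
  if (show_score && is.null(profile))
    stop("show_score requires a conservation profile", call. = FALSE)
  if (show_reference_sequence && is.null(profile))
    stop("show_reference_sequence requires a conservation profile (the letters come from the reference row)",
         call. = FALSE)
  if (!is.null(zoom)) {
    zoom <- as.integer(zoom)
    if (length(zoom) != 2L || anyNA(zoom))
      stop("zoom must be c(start, end)", call. = FALSE)
    if (zoom[1L] > zoom[2L])
      stop(sprintf("zoom window inverted: start %d > end %d", zoom[1L], zoom[2L]),
           call. = FALSE)
    if (zoom[1L] < 1L || zoom[2L] > context$length)
      stop(sprintf("zoom window [%d, %d] outside protein 1..%d",
                   zoom[1L], zoom[2L], context$length), call. = FALSE)
  }
  structure(list(context = context, mutations = mutations,
                 mutations2 = mutations2, domains = domains, ptms = ptms,
                 profile = profile, show_score = show_score,
                 show_reference_sequence = show_reference_sequence,
                 show_gridlines = show_gridlines, zoom = zoom,
                 track_labels = track_labels),
            class = "plot_spec")
}

#' @export
print.plot_spec <- function(x, ...) {
  win <- if (is.null(x$zoom)) c(1L, x$context$length) else x$zoom
  cat(sprintf("<plot_spec> %s (%d aa), window %d..%d, %d mutation(s)%s\n",
              x$context$query_name, x$context$length, win[1L], win[2L],
              nrow(x$mutations),
              if (is.null(x$mutations2)) ""
              else sprintf(" + %d secondary", nrow(x$mutations2))))
  invisible(x)
}

#' Restrict a figure to a residue window
#'
#' Returns a copy of the spec with the zoom window set; the input spec is
#' not modified and no mutations, domains or PTM sites are filtered here.
#' Clipping happens at render time, so a domain box straddling the window
#' edge is partially drawn.
#'
#' @param spec A [plot_spec()].
#' @param start,end 1-based inclusive window bounds.
#' @return A new `plot_spec` with the zoom set.
#' @export
zoom_view <- function(spec, start, end) {
  stopifnot(inherits(spec, "plot_spec"))
  zoom <- as.integer(c(start, end))
  if (length(zoom) != 2L || anyNA(zoom))
    stop("zoom bounds must be integers", call. = FALSE)
  if (zoom[1L] > zoom[2L])
    stop(sprintf("zoom window inverted: start %d > end %d", zoom[1L],
                 zoom[2L]), call. = FALSE)
  if (zoom[1L] < 1L || zoom[2L] > spec$context$length)
    stop(sprintf("zoom window [%d, %d] outside protein 1..%d",
                 zoom[1L], zoom[2L], spec$context$length), call. = FALSE)
  out <- spec
  out$zoom <- zoom
  out
}

spec_window <- function(spec) {
  if (is.null(spec$zoom)) c(1L, spec$context$length) else spec$zoom
}

#' Compute the vertical track layout of a figure
#'
#' Decides which tracks are present and assigns each a disjoint vertical
#' band (canvas coordinates, y increasing downward), plus the affine map
#' from residue units to horizontal canvas coordinates over the current
#' window.
#'
#' @param spec A [plot_spec()].
#' @return An object of class `track_layout`: a data frame with columns
#'   `track`, `y0`, `y1` (top to bottom), with attributes `window`
#'   (`c(start, end)`), `x_a`/`x_b` (residue unit u maps to
#'   `x = x_a * u + x_b`), `width` and `height` of the canvas.
#' @export
layout_tracks <- function(spec) {
  stopifnot(inherits(spec, "plot_spec"))
  win <- spec_window(spec)
  narrow <- (win[2L] - win[1L] + 1L) <= 200L
  tracks <- "title"
  if (!is.null(spec$mutations2)) tracks <- c(tracks, "mutations_secondary")
  tracks <- c(tracks, "mutations_primary", "backbone")
  if (!is.null(spec$ptms) && length(spec$ptms) > 0L) tracks <- c(tracks, "ptm")
  if (spec$show_reference_sequence && narrow)
    tracks <- c(tracks, "reference_sequence")
  if (!is.null(spec$profile)) tracks <- c(tracks, "conservation")
  if (spec$show_score) tracks <- c(tracks, "score")
  tracks <- c(tracks, "axis")
  h <- unname(TRACK_HEIGHTS[tracks])
  y1 <- cumsum(h)
  out <- data.frame(track = tracks, y0 = y1 - h, y1 = y1,
                    stringsAsFactors = FALSE)
  plot_w <- CANVAS_W - MARGIN_L - MARGIN_R
  span <- win[2L] - win[1L] + 1L
  # residue unit u in [win[1]-0.5, win[2]+0.5] maps onto the plot width
  x_a <- plot_w / span
  x_b <- MARGIN_L - x_a * (win[1L] - 0.5)
  structure(out, window = win, x_a = x_a, x_b = x_b, width = CANVAS_W,
            height = sum(h), class = c("track_layout", class(out)))
}

layout_x <- function(lay, u) attr(lay, "x_a") * u + attr(lay, "x_b")
layout_band <- function(lay, track) {
  i <- match(track, lay$track)
  c(lay$y0[i], lay$y1[i])
}

# ---- display-list construction ---------------------------------------

el_rect <- function(x, y, w, h, fill, stroke = NA, stroke_width = 1)
  list(kind = "rect", x = x, y = y, w = w, h = h, fill = fill,
       stroke = stroke, stroke_width = stroke_width)
el_line <- function(x1, y1, x2, y2, stroke, stroke_width = 1)
  list(kind = "line", x1 = x1, y1 = y1, x2 = x2, y2 = y2, stroke = stroke,
       stroke_width = stroke_width)
el_circle <- function(cx, cy, r, fill, stroke = NA)
  list(kind = "circle", cx = cx, cy = cy, r = r, fill = fill, stroke = stroke)
el_text <- function(x, y, label, size = 11, fill = "#000000",
                    anchor = "middle", rotate = 0, mono = FALSE)
  list(kind = "text", x = x, y = y, label = label, size = size, fill = fill,
       anchor = anchor, rotate = rotate, mono = mono)

grp <- function(class, attrs = character(0), elems = list(), children = list())
  list(class = class, attrs = attrs, elems = elems, children = children)

# approximate rendered width of a label, px
label_width <- function(label, size) 0.62 * size * nchar(label)

ellipsize <- function(label, max_w, size) {
  if (label_width(label, size) <= max_w) return(label)
  for (k in rev(seq_len(nchar(label) - 1L))) {
    cand <- paste0(substr(label, 1L, k), "...")
    if (label_width(cand, size) <= max_w) return(cand)
  }
  ""
}

axis_ticks <- function(win) {
  t <- pretty(win, n = 8)
  t <- t[t >= win[1L] & t <= win[2L] & t == round(t)]
  unique(as.integer(c(win[1L], t, win[2L])))
}

# One mutation track. Markers are lollipops: stem from the band bottom up
# to a head circle; mutations sharing a position stack their heads.
# Label placement is deterministic: plain above-head when labels fit,
# alternating above/below when crowded, rotated 90 degrees when denser
# still.
build_mutation_track <- function(spec, lay, mutations, which_track, color,
                                 label, cfg) {
  win <- attr(lay, "window")
  band <- layout_band(lay, which_track)
  y_base <- band[2L] - 4
  stem_h <- 30
  r <- 4
  g <- grp(class = paste0("track track-", which_track),
           attrs = c("data-label" = label))
  g$elems[[1L]] <- el_text(6, mean(band), label, size = 11, anchor = "start")
  inwin <- mutations[mutations$position >= win[1L] &
                     mutations$position <= win[2L], , drop = FALSE]
  if (nrow(inwin) == 0L) return(g)
  # stack index per position, in input order
  stack_i <- stats::ave(seq_len(nrow(inwin)), inwin$position,
                        FUN = seq_along)
  labels <- sprintf("%s%d%s", inwin$ref, inwin$position, inwin$alt)
  xs <- layout_x(lay, inwin$position)
  lab_size <- 9
  # label placement mode from the spacing of distinct marker positions
  ux <- sort(unique(xs))
  gap <- if (length(ux) > 1L) min(diff(ux)) else Inf
  wmax <- max(label_width(labels, lab_size))
  mode <- if (!cfg$labels) "none"
          else if (gap >= wmax) "above"
          else if (gap >= wmax / 2) "alternate"
          else "rotate"
  ord <- order(xs, stack_i)
  rank_at_x <- match(xs, ux)
  children <- vector("list", nrow(inwin))
  for (i in seq_len(nrow(inwin))) {
    cy <- y_base - stem_h - (stack_i[i] - 1L) * (2 * r + 2)
    m <- grp(class = paste0("marker marker-", which_track),
             attrs = c("data-position" = as.character(inwin$position[i]),
                       "data-label" = labels[i]))
    m$elems <- list(
      el_line(xs[i], y_base, xs[i], y_base - stem_h, stroke = "#555555"),
      el_circle(xs[i], cy, r, fill = color, stroke = "#333333"))
    if (mode != "none" && stack_i[i] == max(stack_i[xs == xs[i]])) {
      # label once per position, next to the topmost head
      lab <- labels[i]
      if (mode == "above") {
        m$elems[[3L]] <- el_text(xs[i], cy - r - 6, lab, size = lab_size)
      } else if (mode == "alternate") {
        up <- rank_at_x[i] %% 2L == 1L
        ly <- if (up) cy - r - 6 else y_base + 8
        m$elems[[3L]] <- el_text(xs[i], ly, lab, size = lab_size)
      } else {
        m$elems[[3L]] <- el_text(xs[i] + 3, cy - r - 4, lab, size = lab_size,
                                 anchor = "start", rotate = -90)
      }
    }
    children[[i]] <- m
  }
  g$children <- children[ord]
  g
}

build_backbone <- function(spec, lay, cfg) {
  win <- attr(lay, "window")
  band <- layout_band(lay, "backbone")
  mid <- mean(band)
  box_h <- band[2L] - band[1L] - 12
  g <- grp(class = "backbone")
  g$elems[[1L]] <- el_line(layout_x(lay, win[1L] - 0.5), mid,
                           layout_x(lay, win[2L] + 0.5), mid,
                           stroke = "#444444", stroke_width = 2)
  if (is.null(spec$domains) || nrow(spec$domains) == 0L) return(g)
  pal <- cfg$domain_palette
  children <- list()
  for (i in seq_len(nrow(spec$domains))) {
    d0 <- spec$domains$start[i] - 0.5
    d1 <- spec$domains$end[i] + 0.5
    c0 <- max(d0, win[1L] - 0.5)
    c1 <- min(d1, win[2L] + 0.5)
    if (c0 >= c1) next  # fully outside the window
    x0 <- layout_x(lay, c0); x1 <- layout_x(lay, c1)
    col <- pal[(i - 1L) %% length(pal) + 1L]
    dg <- grp(class = "domain",
              attrs = c("data-name" = spec$domains$name[i],
                        "data-start" = as.character(spec$domains$start[i]),
                        "data-end" = as.character(spec$domains$end[i])))
    dg$elems <- list(
      el_rect(x0, mid - box_h / 2, x1 - x0, box_h, fill = col,
              stroke = "#333333"),
      el_text((x0 + x1) / 2, mid,
              ellipsize(spec$domains$name[i], x1 - x0 - 4, 10), size = 10))
    children[[length(children) + 1L]] <- dg
  }
  g$children <- children
  g
}

build_ptm_track <- function(spec, lay, cfg) {
  win <- attr(lay, "window")
  band <- layout_band(lay, "ptm")
  mid <- mean(band)
  g <- grp(class = "ptm")
  g$elems[[1L]] <- el_text(6, mid, "PTM", size = 9, anchor = "start")
  sites <- spec$ptms[spec$ptms >= win[1L] & spec$ptms <= win[2L]]
  g$children <- lapply(sites, function(p)
    grp(class = "ptm-site", attrs = c("data-position" = as.character(p)),
        elems = list(el_circle(layout_x(lay, p), mid, 3,
                               fill = cfg$color_ptm))))
  g
}

cons_bin_color <- function(s)
  ifelse(s == 1, CONS_BIN_COLORS[["full"]],
         ifelse(s >= 0.5, CONS_BIN_COLORS[["high"]], CONS_BIN_COLORS[["low"]]))

build_letter_track <- function(spec, lay, track, colored) {
  win <- attr(lay, "window")
  band <- layout_band(lay, track)
  mid <- mean(band)
  prof <- spec$profile
  idx <- which(prof$position >= win[1L] & prof$position <= win[2L])
  g <- grp(class = track)
  narrow <- (win[2L] - win[1L] + 1L) <= 200L
  if (narrow) {
    g$elems <- lapply(idx, function(j)
      el_text(layout_x(lay, prof$position[j]), mid, prof$ref_letter[j],
              size = 9, mono = TRUE,
              fill = if (colored) cons_bin_color(prof$score[j]) else "#000000"))
  } else {
    # letters would be illegible: draw a per-position colored strip instead
    g$elems <- lapply(idx, function(j)
      el_rect(layout_x(lay, prof$position[j] - 0.5), band[1L] + 4,
              attr(lay, "x_a"), band[2L] - band[1L] - 8,
              fill = if (colored) cons_bin_color(prof$score[j]) else "#bbbbbb"))
  }
  g
}

build_score_track <- function(spec, lay) {
  win <- attr(lay, "window")
  band <- layout_band(lay, "score")
  inner <- band[2L] - band[1L] - 8
  prof <- spec$profile
  idx <- which(prof$position >= win[1L] & prof$position <= win[2L])
  g <- grp(class = "score")
  g$elems[[1L]] <- el_text(6, mean(band), "s", size = 9, anchor = "start")
  bars <- lapply(idx, function(j) {
    h <- prof$score[j] * inner
    el_rect(layout_x(lay, prof$position[j] - 0.5), band[2L] - 4 - h,
            attr(lay, "x_a"), h, fill = "#777777")
  })
  g$elems <- c(g$elems, bars)
  g
}

build_axis <- function(spec, lay) {
  win <- attr(lay, "window")
  band <- layout_band(lay, "axis")
  y <- band[1L] + 6
  ticks <- axis_ticks(win)
  g <- grp(class = "axis")
  g$elems[[1L]] <- el_line(layout_x(lay, win[1L] - 0.5), y,
                           layout_x(lay, win[2L] + 0.5), y, stroke = "#000000")
  for (t in ticks) {
    x <- layout_x(lay, t)
    g$elems[[length(g$elems) + 1L]] <- el_line(x, y, x, y + 5,
                                               stroke = "#000000")
    g$elems[[length(g$elems) + 1L]] <- el_text(x, y + 16, as.character(t),
                                               size = 10)
  }
  g
}

build_grid <- function(spec, lay) {
  win <- attr(lay, "window")
  axis_band <- layout_band(lay, "axis")
  g <- grp(class = "grid")
  g$elems <- lapply(axis_ticks(win), function(t)
    el_line(layout_x(lay, t), TRACK_HEIGHTS[["title"]],
            layout_x(lay, t), axis_band[1L] + 6, stroke = "#dddddd"))
  g
}

# Full display list for a spec: list of top-level groups.
build_figure <- function(spec, cfg = render_config()) {
  lay <- layout_tracks(spec)
  win <- attr(lay, "window")
  narrow <- (win[2L] - win[1L] + 1L) <= 200L
  if (spec$show_reference_sequence && !narrow)
    message(sprintf("reference-sequence track suppressed: window of %d residues exceeds the 200-residue legibility limit",
                    win[2L] - win[1L] + 1L))
  groups <- list()
  if (spec$show_gridlines)
    groups[[length(groups) + 1L]] <- build_grid(spec, lay)
  tb <- layout_band(lay, "title")
  groups[[length(groups) + 1L]] <-
    grp(class = "title",
        elems = list(el_text(CANVAS_W / 2, mean(tb),
                             spec$context$query_name, size = 16)))
  if ("mutations_secondary" %in% lay$track)
    groups[[length(groups) + 1L]] <-
      build_mutation_track(spec, lay, spec$mutations2, "mutations_secondary",
                           cfg$color_secondary,
                           spec$track_labels[["secondary"]], cfg)
  groups[[length(groups) + 1L]] <-
    build_mutation_track(spec, lay, spec$mutations, "mutations_primary",
                         cfg$color_primary, spec$track_labels[["primary"]],
                         cfg)
  groups[[length(groups) + 1L]] <- build_backbone(spec, lay, cfg)
  if ("ptm" %in% lay$track)
    groups[[length(groups) + 1L]] <- build_ptm_track(spec, lay, cfg)
  if ("reference_sequence" %in% lay$track)
    groups[[length(groups) + 1L]] <-
      build_letter_track(spec, lay, "reference_sequence", colored = FALSE)
  if ("conservation" %in% lay$track)
    groups[[length(groups) + 1L]] <-
      build_letter_track(spec, lay, "conservation", colored = TRUE)
  if ("score" %in% lay$track)
    groups[[length(groups) + 1L]] <- build_score_track(spec, lay)
  groups[[length(groups) + 1L]] <- build_axis(spec, lay)
  list(groups = groups, width = attr(lay, "width"),
       height = attr(lay, "height"))
}

# ---- SVG backend ------------------------------------------------------

fmt_num <- function(x) sprintf("%.2f", x)

xml_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  gsub(">", "&gt;", s, fixed = TRUE)
}

svg_attr <- function(name, value) sprintf(' %s="%s"', name, xml_escape(value))

svg_elem <- function(e) {
  switch(e$kind,
    rect = sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
                   fmt_num(e$x), fmt_num(e$y), fmt_num(e$w), fmt_num(e$h),
                   e$fill,
                   if (is.na(e$stroke)) ""
                   else sprintf(' stroke="%s" stroke-width="%s"', e$stroke,
                                fmt_num(e$stroke_width))),
    line = sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" stroke-width="%s"/>',
                   fmt_num(e$x1), fmt_num(e$y1), fmt_num(e$x2), fmt_num(e$y2),
                   e$stroke, fmt_num(e$stroke_width)),
    circle = sprintf('<circle cx="%s" cy="%s" r="%s" fill="%s"%s/>',
                     fmt_num(e$cx), fmt_num(e$cy), fmt_num(e$r), e$fill,
                     if (is.na(e$stroke)) ""
                     else sprintf(' stroke="%s"', e$stroke)),
    text = {
      anchor <- e$anchor
      rot <- if (e$rotate != 0)
        sprintf(' transform="rotate(%s %s %s)"', fmt_num(e$rotate),
                fmt_num(e$x), fmt_num(e$y)) else ""
      sprintf('<text x="%s" y="%s" font-family="%s" font-size="%s" fill="%s" text-anchor="%s" dominant-baseline="central"%s>%s</text>',
              fmt_num(e$x), fmt_num(e$y),
              if (e$mono) "monospace" else "sans-serif",
              fmt_num(e$size), e$fill, anchor, rot, xml_escape(e$label))
    },
    stop("unknown element kind: ", e$kind))
}

svg_group <- function(g, indent) {
  pad <- strrep(" ", indent)
  attrs <- if (length(g$attrs))
    paste0(vapply(names(g$attrs), function(nm) svg_attr(nm, g$attrs[[nm]]),
                  character(1)), collapse = "") else ""
  open <- sprintf('%s<g class="%s"%s>', pad, g$class, attrs)
  body <- vapply(g$elems, function(e) paste0(pad, "  ", svg_elem(e)),
                 character(1))
  kids <- unlist(lapply(g$children, svg_group, indent = indent + 2L))
  c(open, body, kids, sprintf("%s</g>", pad))
}

render_svg <- function(fig, path) {
  lines <- c('<?xml version="1.0" encoding="UTF-8"?>',
             sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
                     round(fig$width), round(fig$height), round(fig$width),
                     round(fig$height)),
             sprintf('  <rect x="0" y="0" width="%d" height="%d" fill="#ffffff"/>',
                     round(fig$width), round(fig$height)),
             unlist(lapply(fig$groups, svg_group, indent = 2L)),
             "</svg>")
  writeLines(lines, path)
  invisible(path)
}

# ---- base-graphics backend (PDF/PNG) ---------------------------------

draw_elem_device <- function(e) {
  switch(e$kind,
    rect = graphics::rect(e$x, e$y + e$h, e$x + e$w, e$y,
                          col = e$fill,
                          border = if (is.na(e$stroke)) NA else e$stroke,
                          lwd = if (is.na(e$stroke)) 1 else e$stroke_width),
    line = graphics::segments(e$x1, e$y1, e$x2, e$y2, col = e$stroke,
                              lwd = e$stroke_width),
    circle = graphics::symbols(e$cx, e$cy, circles = e$r, inches = FALSE,
                               add = TRUE, bg = e$fill,
                               fg = if (is.na(e$stroke)) NA else e$stroke),
    text = {
      adj <- switch(e$anchor, start = 0, middle = 0.5, end = 1)
      graphics::text(e$x, e$y, e$label, adj = c(adj, 0.5),
                     cex = e$size / 12, col = e$fill,
                     srt = if (e$rotate == 0) 0 else -e$rotate,
                     family = if (e$mono) "mono" else "sans")
    })
  invisible(NULL)
}

draw_group_device <- function(g) {
  lapply(g$elems, draw_elem_device)
  lapply(g$children, draw_group_device)
  invisible(NULL)
}

render_device <- function(fig) {
  op <- graphics::par(mar = c(0, 0, 0, 0), ps = 12)
  on.exit(graphics::par(op))
  graphics::plot.new()
  # canvas coordinates, y increasing downward as in SVG
  graphics::plot.window(xlim = c(0, fig$width), ylim = c(fig$height, 0),
                        xaxs = "i", yaxs = "i")
  lapply(fig$groups, draw_group_device)
  invisible(NULL)
}

#' Render a protein figure to a file
#'
#' Writes the multi-track figure described by a [plot_spec()] to SVG
#' (canonical vector output, byte-identical across runs for a fixed
#' spec), PDF or PNG. Only elements inside the current zoom window are
#' drawn; domain boxes straddling the window edge are clipped, not
#' dropped.
#'
#' @param spec A [plot_spec()].
#' @param path Output file path.
#' @param format One of `"svg"`, `"pdf"`, `"png"`; by default inferred
#'   from the file extension.
#' @param config Rendering configuration (see [render_config()]), or a
#'   path accepted by [read_render_config()].
#' @return Invisibly, `path`.
#' @examples
#' ctx <- protein_context(100, "demo")
#' mut <- data.frame(protein = "d", gene = "d", position = 42L,
#'                   ref = "C", alt = "R")
#' out <- tempfile(fileext = ".svg")
#' render(plot_spec(ctx, mut), out)
#' @export
render <- function(spec, path, format = NULL, config = render_config()) {
  stopifnot(inherits(spec, "plot_spec"))
  if (is.character(config)) config <- read_render_config(config)
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  if (!format %in% c("svg", "pdf", "png"))
    stop(sprintf("unsupported output format '%s' (expected svg, pdf or png)",
                 format), call. = FALSE)
  fig <- build_figure(spec, cfg = config)
  if (format == "svg") return(render_svg(fig, path))
  if (format == "pdf") {
    grDevices::pdf(path, width = fig$width / 72, height = fig$height / 72)
  } else {
    scale <- config$width_in * config$dpi / fig$width
    grDevices::png(path, width = config$width_in * config$dpi,
                   height = round(fig$height * scale), res = config$dpi,
                   type = if (capabilities("cairo")) "cairo" else
                     getOption("bitmapType", "Xlib"))
  }
  on.exit(grDevices::dev.off())
  render_device(fig)
  invisible(path)
}
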