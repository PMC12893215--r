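# Change-point connectivity graphs: supra-threshold canonical loadings of
# the retained variates drawn as concentric rings, musical variables on the
# left, physiological on the right, red positive / blue negative, with
# association-direction edges.

#' Build a connectivity graph from canonical loadings
#'
#' Keeps, per retained variate, the variables whose loading magnitude
#' strictly exceeds `threshold`, and connects every surviving musical-
#' physiological pair; the edge sign is the product of the two loading
#' signs (same sign = positive association). Raising the threshold never
#' adds nodes or edges.
#'
#' @param result a `cca_result`
#' @param retained logical retention flags per variate (default: first)
#' @param threshold display threshold on |loading| (strict)
#' @return a `connectivity_graph`: per-variate `nodes` (variable, side,
#'   loading) and `edges` (music, physio, sign); `threshold`
#' @export
build_graph <- function(result, retained = NULL, threshold = 0.3) {
  stopifnot(inherits(result, "cca_result"))
  if (is.null(retained))
    retained <- seq_along(result$cor) == 1
  keep <- which(retained)
  if (!length(keep)) stop("at least one retained variate required")
  variates <- list()
  any_node <- FALSE
  for (i in keep) {
    lx <- result$loadings_x[, i]; ly <- result$loadings_y[, i]
    nx <- names(lx)[abs(lx) > threshold]; ny <- names(ly)[abs(ly) > threshold]
    nodes <- rbind(
      if (length(nx)) data.frame(variable = nx, side = "music",
                                 loading = unname(lx[nx])),
      if (length(ny)) data.frame(variable = ny, side = "physiology",
                                 loading = unname(ly[ny])))
    edges <- if (length(nx) && length(ny))
      do.call(rbind, lapply(nx, function(a) data.frame(
        music = a, physio = ny,
        sign = sign(lx[a]) * sign(unname(ly[ny])))))
    if (!is.null(nodes) && nrow(nodes)) any_node <- TRUE
    variates[[paste0("variate", i)]] <-
      list(variate = i, cor = result$cor[i], nodes = nodes, edges = edges)
  }
  if (!any_node) warning("no loading exceeds the display threshold")
  structure(list(variates = variates, threshold = threshold),
            class = "connectivity_graph")
}

# fixed angular layout: music left semicircle, physiology right,
# alphabetical within side (reproducible figures)
graph_angles <- function(vars, side) {
  vars <- sort(vars)
  k <- length(vars)
  ang <- if (side == "music") seq(110, 250, length.out = max(k, 2))
         else seq(70, -70, length.out = max(k, 2))
  stats::setNames(ang[seq_len(k)] * pi / 180, vars)
}

#' Render a connectivity graph to SVG or PNG
#'
#' Concentric black rings (outermost = first retained variate), node
#' circles with radius proportional to |loading| and colour by sign (red
#' positive, blue negative), arrows for the dominant music-physiology pair
#' per variate, and a caption listing the dominant effects. For annotation
#' categories (no intrinsic direction) the caption states the physiological
#' direction only.
#'
#' @param graph a `connectivity_graph`
#' @param path output file path ending in `.svg` or `.png`
#' @return `path`, invisibly
#' @export
render_graph <- function(graph, path) {
  stopifnot(inherits(graph, "connectivity_graph"))
  ext <- tolower(tools::file_ext(path))
  dev <- switch(ext,
                svg = function() grDevices::svg(path, width = 7, height = 7),
                png = function() grDevices::png(path, width = 900, height = 900,
                                                res = 130),
                stop("unsupported format: ", ext))
  dev()
  on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(5, 1, 2, 1)); on.exit(graphics::par(op), add = TRUE)
  nv <- length(graph$variates)
  plot(0, 0, type = "n", xlim = c(-1.5, 1.5), ylim = c(-1.6, 1.4),
       axes = FALSE, xlab = "", ylab = "", asp = 1)
  theta <- seq(0, 2 * pi, length.out = 200)
  captions <- character(0)
  for (j in seq_len(nv)) {
    vg <- graph$variates[[j]]
    R <- 1 - (j - 1) * 0.35
    graphics::lines(R * cos(theta), R * sin(theta), col = "black")
    nodes <- vg$nodes
    if (is.null(nodes) || !nrow(nodes)) next
    for (side in c("music", "physiology")) {
      vs <- nodes$variable[nodes$side == side]
      if (!length(vs)) next
      ang <- graph_angles(vs, side)
      for (v in vs) {
        ld <- nodes$loading[nodes$variable == v & nodes$side == side][1]
        x <- R * cos(ang[[v]]); y <- R * sin(ang[[v]])
        graphics::symbols(x, y, circles = 0.03 + 0.1 * abs(ld), inches = FALSE,
                          add = TRUE, bg = if (ld > 0) "red" else "blue",
                          fg = NA)
        graphics::text(x * 1.22, y * 1.22, v, cex = 0.55)
      }
    }
    ed <- vg$edges
    if (!is.null(ed) && nrow(ed)) {
      # dominant pair: largest |loading| product
      lmag <- function(v, s) abs(nodes$loading[nodes$variable == v &
                                                 nodes$side == s][1])
      prod <- mapply(function(a, b) lmag(a, "music") * lmag(b, "physiology"),
                     ed$music, ed$physio)
      dom <- ed[which.max(prod), ]
      am <- graph_angles(nodes$variable[nodes$side == "music"], "music")
      ap <- graph_angles(nodes$variable[nodes$side == "physiology"],
                         "physiology")
      graphics::arrows(R * cos(am[[dom$music]]) * 0.85,
                       R * sin(am[[dom$music]]) * 0.85,
                       R * cos(ap[[dom$physio]]) * 0.85,
                       R * sin(ap[[dom$physio]]) * 0.85,
                       length = 0.08, col = "grey30")
      phys_dir <- ifelse(nodes$loading[nodes$variable == dom$physio &
                                         nodes$side == "physiology"][1] *
                           dom$sign > 0, "increase", "decrease")
      captions <- c(captions,
                    sprintf("V%d (r=%.2f): %s -> %s %s", vg$variate, vg$cor,
                            dom$music, dom$physio,
                            if (dom$sign > 0) "(positive)" else "(negative)"))
    }
  }
  graphics::mtext(paste(captions, collapse = "   "), side = 1, line = 1,
                  cex = 0.6)
  graphics::mtext(sprintf("|loading| > %.2f shown; red positive, blue negative",
                          graph$threshold), side = 1, line = 3, cex = 0.6)
  invisible(path)
}

#' Serialize a connectivity graph to JSON
#' @param graph a `connectivity_graph`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_graph_json <- function(graph, path) {
  jsonlite::write_json(
    list(threshold = graph$threshold,
         variates = lapply(graph$variates, function(v)
           list(variate = v$variate, cor = v$cor, nodes = v$nodes,
                edges = v$edges))),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
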