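## Rendering: ChordLayout -> SVG (hand-built, byte-deterministic) or PNG
## (same geometry redrawn on the grDevices png device).

#' Rendering specification
#'
#' @param canvasSize canvas width and height in pixels (square).
#' @param outerRadiusFraction outer sector radius as a fraction of the
#'   half-canvas (0, 1].
#' @param ringThickness sector ring thickness as a fraction of the outer
#'   radius (0, 1].
#' @param controlRadiusFraction radius fraction for the ribbon Bezier
#'   control points; 0 pulls both controls to the exact center, giving the
#'   classic chord look.
#' @param background canvas background color.
#' @param format \code{"svg"} or \code{"png"}.
#' @param pngRes raster resolution in DPI used when rasterizing to PNG.
#' @return Validated named list.
#' @export
renderSpec <- function(canvasSize = 800, outerRadiusFraction = 0.78,
                       ringThickness = 0.12, controlRadiusFraction = 0,
                       background = "#FFFFFF", format = c("svg", "png"),
                       pngRes = 96) {
  format <- match.arg(format)
  stopifnot(canvasSize > 0,
            outerRadiusFraction > 0, outerRadiusFraction <= 1,
            ringThickness > 0, ringThickness <= 1,
            controlRadiusFraction >= 0, controlRadiusFraction < 1,
            pngRes > 0)
  list(canvasSize = canvasSize, outerRadiusFraction = outerRadiusFraction,
       ringThickness = ringThickness,
       controlRadiusFraction = controlRadiusFraction,
       background = background, format = format, pngRes = pngRes)
}

## fixed 6-decimal coordinate formatting => byte-identical output
.fmt <- function(x) sprintf("%.6f", x)

## point on the circle: math angle theta (degrees, CCW from 3 o'clock),
## SVG y grows downward
.circPoint <- function(theta, r, cx, cy) {
  c(x = cx + r * cospi(theta / 180), y = cy - r * sinpi(theta / 180))
}

## SVG elliptical-arc command from current point to angle th2 at radius r;
## clockwise on screen (decreasing math angle) is sweep=1
.svgArc <- function(th1, th2, r, cx, cy) {
  p <- .circPoint(th2, r, cx, cy)
  large <- if (abs(th2 - th1) > 180) 1L else 0L
  sweep <- if (th2 < th1) 1L else 0L
  sprintf("A %s %s 0 %d %d %s %s", .fmt(r), .fmt(r), large, sweep,
          .fmt(p["x"]), .fmt(p["y"]))
}

.sectorPath <- function(thetaStart, thetaEnd, rOuter, rInner, cx, cy) {
  p1 <- .circPoint(thetaStart, rOuter, cx, cy)
  p3 <- .circPoint(thetaEnd, rInner, cx, cy)
  paste(
    sprintf("M %s %s", .fmt(p1["x"]), .fmt(p1["y"])),
    .svgArc(thetaStart, thetaEnd, rOuter, cx, cy),
    sprintf("L %s %s", .fmt(p3["x"]), .fmt(p3["y"])),
    .svgArc(thetaEnd, thetaStart, rInner, cx, cy),
    "Z")
}

.ribbonPath <- function(s1, s2, t1, t2, rIn, rCtrl, cx, cy) {
  a <- .circPoint(s1, rIn, cx, cy)
  b <- .circPoint(s2, rIn, cx, cy)
  cc <- .circPoint(t1, rIn, cx, cy)
  dd <- .circPoint(t2, rIn, cx, cy)
  ## control points pulled toward the center along each chord's midpoint
  ctrl <- function(p, q) {
    mx <- cx + ((unname(p["x"]) + unname(q["x"])) / 2 - cx) * rCtrl
    my <- cy + ((unname(p["y"]) + unname(q["y"])) / 2 - cy) * rCtrl
    c(x = mx, y = my)
  }
  c1 <- ctrl(b, cc)
  c2 <- ctrl(dd, a)
  paste(
    sprintf("M %s %s", .fmt(a["x"]), .fmt(a["y"])),
    .svgArc(s1, s2, rIn, cx, cy),
    sprintf("C %s %s %s %s %s %s", .fmt(c1["x"]), .fmt(c1["y"]),
            .fmt(c1["x"]), .fmt(c1["y"]), .fmt(cc["x"]), .fmt(cc["y"])),
    .svgArc(t1, t2, rIn, cx, cy),
    sprintf("C %s %s %s %s %s %s", .fmt(c2["x"]), .fmt(c2["y"]),
            .fmt(c2["x"]), .fmt(c2["y"]), .fmt(a["x"]), .fmt(a["y"])),
    "Z")
}

.xmlEscape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Render a chord layout
#'
#' Draws one annular-sector path per sector, one closed ribbon path per
#' dimer (two sector-edge arcs joined by cubic Bezier curves through the
#' circle interior) and one text element per label.  SVG output is
#' well-formed XML with coordinates fixed at six decimals, so identical
#' layout and spec give byte-identical files.  PNG output rasterizes the
#' same geometry on the \code{grDevices::png} device.
#'
#' @param layout a \code{\link{ChordLayout}}.
#' @param file output path.  Its extension does not override
#'   \code{spec$format}.
#' @param spec a \code{\link{renderSpec}}.
#' @return Invisibly, a summary list: element counts (\code{sectors},
#'   \code{ribbons}, \code{labels}), \code{format} and \code{file}.
#' @examples
#' layout <- computeLayout(decomposeDimers(ozoneToyTetramers()))
#' f <- tempfile(fileext = ".svg")
#' renderChord(layout, f)
#' @export
renderChord <- function(layout, file, spec = renderSpec()) {
  stopifnot(methods::is(layout, "ChordLayout"))
  if (spec$format == "png") {
    if (!capabilities("png"))
      stop(errorCondition(
        "PNG output requested but this R build has no png device",
        class = "cgpd_no_raster"))
    return(.renderPNG(layout, file, spec))
  }
  .renderSVG(layout, file, spec)
}

.renderGeom <- function(layout, spec) {
  W <- spec$canvasSize
  cx <- cy <- W / 2
  rOuter <- (W / 2) * spec$outerRadiusFraction
  rInner <- rOuter * (1 - spec$ringThickness)
  list(W = W, cx = cx, cy = cy, rOuter = rOuter, rInner = rInner,
       rLabel = rOuter * 1.05 / 0.95)  # slightly outside the ring
}

.renderSVG <- function(layout, file, spec) {
  g <- .renderGeom(layout, spec)
  s <- layout@sectors
  r <- layout@ribbons
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" ",
                   "width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">"),
            as.integer(g$W), as.integer(g$W), as.integer(g$W),
            as.integer(g$W)),
    sprintf("<rect width=\"%d\" height=\"%d\" fill=\"%s\"/>",
            as.integer(g$W), as.integer(g$W), spec$background),
    "<g id=\"ribbons\">")
  for (i in seq_len(nrow(r))) {
    lines <- c(lines, sprintf(
      "<path class=\"ribbon\" d=\"%s\" fill=\"%s\" fill-opacity=\"%s\" stroke=\"none\"/>",
      .ribbonPath(r$sourceThetaStart[i], r$sourceThetaEnd[i],
                  r$targetThetaStart[i], r$targetThetaEnd[i],
                  g$rInner, spec$controlRadiusFraction, g$cx, g$cy),
      r$color[i], .fmt(r$opacity[i])))
  }
  lines <- c(lines, "</g>", "<g id=\"sectors\">")
  for (i in seq_len(nrow(s))) {
    lines <- c(lines, sprintf(
      "<path class=\"sector\" d=\"%s\" fill=\"%s\" stroke=\"none\"/>",
      .sectorPath(s$thetaStart[i], s$thetaEnd[i], g$rOuter, g$rInner,
                  g$cx, g$cy),
      s$color[i]))
  }
  lines <- c(lines, "</g>", "<g id=\"labels\">")
  for (i in seq_len(nrow(s))) {
    th <- s$labelAngle[i]
    p <- .circPoint(th, g$rLabel, g$cx, g$cy)
    rot <- (-th) %% 360
    anchor <- "start"
    if (rot > 90 && rot < 270) { rot <- rot - 180; anchor <- "end" }
    lines <- c(lines, sprintf(
      paste0("<text class=\"label\" x=\"%s\" y=\"%s\" font-size=\"%s\" ",
             "text-anchor=\"%s\" dominant-baseline=\"middle\" ",
             "font-family=\"sans-serif\" ",
             "transform=\"rotate(%s %s %s)\">%s</text>"),
      .fmt(p["x"]), .fmt(p["y"]), .fmt(s$fontSize[i]), anchor,
      .fmt(rot), .fmt(p["x"]), .fmt(p["y"]), .xmlEscape(s$label[i])))
  }
  lines <- c(lines, "</g>", "</svg>")
  con <- file(file, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(list(sectors = nrow(s), ribbons = nrow(r), labels = nrow(s),
                 format = "svg", file = file))
}

## sample points along a circular arc (screen coordinates)
.arcPoints <- function(th1, th2, rr, cx, cy, step = 2) {
  nseg <- max(2L, ceiling(abs(th2 - th1) / step) + 1L)
  th <- seq(th1, th2, length.out = nseg)
  cbind(cx + rr * cospi(th / 180), cy - rr * sinpi(th / 180))
}

.bezierPoints <- function(p0, c1, c2, p1, nseg = 24L) {
  t <- seq(0, 1, length.out = nseg)
  bx <- (1 - t)^3 * p0[1] + 3 * (1 - t)^2 * t * c1[1] +
        3 * (1 - t) * t^2 * c2[1] + t^3 * p1[1]
  by <- (1 - t)^3 * p0[2] + 3 * (1 - t)^2 * t * c1[2] +
        3 * (1 - t) * t^2 * c2[2] + t^3 * p1[2]
  cbind(bx, by)
}

.renderPNG <- function(layout, file, spec) {
  g <- .renderGeom(layout, spec)
  s <- layout@sectors
  r <- layout@ribbons
  grDevices::png(file, width = g$W, height = g$W, res = spec$pngRes,
                 bg = spec$background)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  ## y axis flipped so screen coordinates match the SVG output
  graphics::plot.window(xlim = c(0, g$W), ylim = c(g$W, 0), asp = 1)
  for (i in seq_len(nrow(r))) {
    a <- .arcPoints(r$sourceThetaStart[i], r$sourceThetaEnd[i], g$rInner,
                    g$cx, g$cy)
    b <- .arcPoints(r$targetThetaStart[i], r$targetThetaEnd[i], g$rInner,
                    g$cx, g$cy)
    ctr <- function(p, q) c(
      g$cx + (((p[1] + q[1]) / 2) - g$cx) * spec$controlRadiusFraction,
      g$cy + (((p[2] + q[2]) / 2) - g$cy) * spec$controlRadiusFraction)
    p0 <- a[nrow(a), ]; p1 <- b[1L, ]
    q0 <- b[nrow(b), ]; q1 <- a[1L, ]
    poly <- rbind(a, .bezierPoints(p0, ctr(p0, p1), ctr(p0, p1), p1),
                  b, .bezierPoints(q0, ctr(q0, q1), ctr(q0, q1), q1))
    col <- grDevices::adjustcolor(r$color[i], alpha.f = r$opacity[i])
    graphics::polygon(poly[, 1], poly[, 2], col = col, border = NA)
  }
  for (i in seq_len(nrow(s))) {
    outer <- .arcPoints(s$thetaStart[i], s$thetaEnd[i], g$rOuter, g$cx, g$cy)
    inner <- .arcPoints(s$thetaEnd[i], s$thetaStart[i], g$rInner, g$cx, g$cy)
    graphics::polygon(rbind(outer, inner)[, 1], rbind(outer, inner)[, 2],
                      col = s$color[i], border = NA)
  }
  for (i in seq_len(nrow(s))) {
    th <- s$labelAngle[i]
    p <- .circPoint(th, g$rLabel, g$cx, g$cy)
    rot <- th %% 360
    adj <- 0
    if (rot > 90 && rot < 270) { rot <- rot - 180; adj <- 1 }
    graphics::text(p["x"], p["y"], s$label[i], srt = rot, adj = adj,
                   cex = s$fontSize[i] / 12)
  }
  invisible(list(sectors = nrow(s), ribbons = nrow(r), labels = nrow(s),
                 format = "png", file = file))
}
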