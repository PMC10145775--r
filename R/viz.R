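#' Palettes of the annular summary chart
#'
#' Type ring: dark blue = non-sedentary, standard blue = sedentary, light
#' blue = walking. Criterion rings: a five-level dark-red to dark-green
#' diverging scale over the display bins; non-walking cells reuse their type
#' color.
#'
#' @return named character vectors of hex colors.
#' @export
type_palette <- function() {
  c(walking = "#C6DBEF", sedentary = "#4292C6", non_sedentary = "#08306B")
}

#' @rdname type_palette
#' @export
bin_palette <- function() {
  c(
    well_below = "#A50026", slightly_below = "#F46D43",
    within = "#FEE08B", slightly_above = "#A6D96A",
    well_above = "#006837"
  )
}

ring_order <- function() {
  c("type", "stability", "steadiness", "sturdiness", "symmetry")
}

ring_criteria <- function() {
  c(
    stability = "rmsr_ml", steadiness = "p2cc",
    sturdiness = "rmsr_ap", symmetry = "p1cc"
  )
}

#' Build the annular summary specification
#'
#' Lays out the chart: one outer ring giving each regime's type and four
#' inner rings (stability, steadiness, sturdiness, symmetry) coloring each
#' walking regime by its display bin. Regimes are drawn clockwise from 12
#' o'clock with angular extent proportional to duration; non-walking regimes
#' carry their type color on all criterion rings.
#'
#' @param regimes labeled regimes tibble (`regime`, `start_s`, `end_s`,
#'   `label`).
#' @param scores long score tibble from [score_regimes()]; every walking
#'   regime must carry all four criteria.
#' @return an object of class `gait_summary`: `sectors` tibble (`ring`,
#'   `ring_index`, `regime`, `angle_start`, `angle_end`, `fill`, `bin`) plus
#'   the input `regimes`.
#' @export
build_summary <- function(regimes, scores) {
  stopifnot(all(c("regime", "start_s", "end_s", "label") %in% names(regimes)))
  total <- sum(regimes$end_s - regimes$start_s)
  t0 <- min(regimes$start_s)
  ang <- dplyr::mutate(regimes,
    angle_start = 360 * (.data$start_s - t0) / total,
    angle_end = 360 * (.data$end_s - t0) / total
  )
  walking <- regimes$regime[regimes$label == "walking"]
  have <- dplyr::count(
    scores[scores$regime %in% walking & scores$criterion %in% criterion_names(), ],
    .data$regime
  )
  complete <- have$regime[have$n == length(criterion_names())]
  if (!all(walking %in% complete)) {
    abort("every walking regime needs scores for all four criteria")
  }
  sectors <- list(
    dplyr::transmute(ang,
      ring = "type", ring_index = 1L, regime = .data$regime,
      angle_start = .data$angle_start, angle_end = .data$angle_end,
      fill = unname(type_palette()[.data$label]), bin = NA_character_
    )
  )
  crits <- ring_criteria()
  for (i in seq_along(crits)) {
    ring_name <- names(crits)[i]
    sc <- scores[scores$criterion == crits[[i]], c("regime", "bin")]
    cells <- dplyr::left_join(ang, sc, by = "regime")
    sectors[[i + 1]] <- dplyr::transmute(cells,
      ring = ring_name, ring_index = i + 1L, regime = .data$regime,
      angle_start = .data$angle_start, angle_end = .data$angle_end,
      fill = ifelse(.data$label == "walking",
        unname(bin_palette()[as.character(.data$bin)]),
        unname(type_palette()[.data$label])
      ),
      bin = ifelse(.data$label == "walking", as.character(.data$bin), NA)
    )
  }
  structure(
    list(sectors = dplyr::bind_rows(sectors), regimes = regimes),
    class = "gait_summary"
  )
}

#' @export
print.gait_summary <- function(x, ...) {
  cat(sprintf(
    "<gait_summary: %d regimes x %d rings>\n",
    nrow(x$regimes), length(unique(x$sectors$ring))
  ))
  invisible(x)
}

#' @describeIn build_summary tidy method: the sector table.
#' @param x a `gait_summary`.
#' @param ... unused.
#' @export
tidy.gait_summary <- function(x, ...) x$sectors

#' @describeIn build_summary ggplot2 annular chart of the summary.
#' @param object a `gait_summary`.
#' @export
autoplot.gait_summary <- function(object, ...) {
  df <- dplyr::mutate(object$sectors,
    ymin = 6 - .data$ring_index,
    ymax = 6 - .data$ring_index + 0.92
  )
  ggplot2::ggplot(df) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$angle_start, xmax = .data$angle_end,
        ymin = .data$ymin, ymax = .data$ymax, fill = .data$fill
      ),
      color = "black", linewidth = 0.3
    ) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_x_continuous(limits = c(0, 360)) +
    ggplot2::ylim(0, 6) +
    ggplot2::coord_polar(theta = "x", start = 0, direction = 1) +
    ggplot2::theme_void()
}

# point on a circle, angle measured clockwise from 12 o'clock
svg_point <- function(cx, cy, r, angle_deg) {
  a <- angle_deg * pi / 180
  c(cx + r * sin(a), cy - r * cos(a))
}

svg_sector <- function(cx, cy, r_in, r_out, a0, a1, fill) {
  a1 <- min(a1, a0 + 359.99)
  large <- if (a1 - a0 > 180) 1 else 0
  p1 <- svg_point(cx, cy, r_out, a0)
  p2 <- svg_point(cx, cy, r_out, a1)
  p3 <- svg_point(cx, cy, r_in, a1)
  p4 <- svg_point(cx, cy, r_in, a0)
  fmt <- function(v) sprintf("%.3f", v)
  d <- paste0(
    "M", fmt(p1[1]), ",", fmt(p1[2]),
    " A", fmt(r_out), ",", fmt(r_out), " 0 ", large, ",1 ",
    fmt(p2[1]), ",", fmt(p2[2]),
    " L", fmt(p3[1]), ",", fmt(p3[2]),
    " A", fmt(r_in), ",", fmt(r_in), " 0 ", large, ",0 ",
    fmt(p4[1]), ",", fmt(p4[2]), " Z"
  )
  paste0(
    "<path d=\"", d, "\" fill=\"", fill,
    "\" stroke=\"black\" stroke-width=\"1\"/>"
  )
}

#' Render the summary chart to file
#'
#' SVG output is hand-constructed vector text with stable element ordering,
#' so rendering the same spec twice yields byte-identical files; PNG is
#' rasterized from the ggplot2 version.
#'
#' @param summary a `gait_summary` from [build_summary()].
#' @param path output file path.
#' @param format `"svg"` (default) or `"png"`.
#' @param size canvas size in pixels (SVG / PNG square side).
#' @return `path`, invisibly.
#' @export
render_summary <- function(summary, path, format = c("svg", "png"), size = 500) {
  format <- match.arg(format)
  stopifnot(inherits(summary, "gait_summary"))
  if (format == "png") {
    grDevices::png(path, width = size, height = size)
    on.exit(grDevices::dev.off())
    print(autoplot(summary))
    return(invisible(path))
  }
  cx <- size / 2
  cy <- size / 2
  r_top <- 0.48 * size
  width <- 0.064 * size
  gap <- 0.008 * size
  lines <- c(
    sprintf(
      paste0(
        "<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" ",
        "height=\"%d\" viewBox=\"0 0 %d %d\">"
      ),
      size, size, size, size
    ),
    sprintf("<rect width=\"%d\" height=\"%d\" fill=\"white\"/>", size, size)
  )
  sec <- summary$sectors[order(summary$sectors$ring_index, summary$sectors$regime), ]
  for (r in seq_len(nrow(sec))) {
    i <- sec$ring_index[r]
    r_out <- r_top - (i - 1) * (width + gap)
    lines <- c(lines, svg_sector(
      cx, cy, r_out - width, r_out,
      sec$angle_start[r], sec$angle_end[r], sec$fill[r]
    ))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
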