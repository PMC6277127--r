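#' Read a vascular network from disk
#'
#' Supported formats: a single JSON document with `nodes`, `segments` and
#' `domain` members, or a CSV pair `<stem>_nodes.csv` / `<stem>_segments.csv`
#' with the same columns (control points serialized as a semicolon-delimited
#' `x,y,z;x,y,z;...` list). Round trips with [write_network()] are lossless.
#'
#' @param path JSON file path, or the CSV pair stem (with or without the
#'   `_nodes.csv` suffix).
#' @param format `"json"` or `"csv_pair"`; guessed from the extension when
#'   missing.
#' @return A validated `vascular_network`.
#' @export
read_network <- function(path, format = c("auto", "json", "csv_pair")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv_pair"
  }
  if (format == "json") {
    if (!file.exists(path)) stop("file not found: ", path)
    doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    for (part in c("nodes", "segments")) {
      if (is.null(doc[[part]])) stop("schema error: missing '", part, "' array")
    }
    nodes <- data.frame(id = as.integer(doc$nodes$id), x = doc$nodes$x_um,
                        y = doc$nodes$y_um, z = doc$nodes$z_um,
                        role = doc$nodes$role)
    segs <- data.frame(id = as.integer(doc$segments$id),
                       tail = as.integer(doc$segments$tail),
                       head = as.integer(doc$segments$head),
                       diameter = doc$segments$diameter_um,
                       length = doc$segments$length_um,
                       compartment = doc$segments$compartment)
    cps <- doc$segments$control_points
    segs$cp <- lapply(seq_len(nrow(segs)), function(i) {
      cp <- if (is.null(cps)) NULL else cps[[i]]
      if (is.null(cp) || length(cp) == 0) NULL else matrix(as.numeric(cp), ncol = 3)
    })
    dom <- doc$domain
  } else {
    stem <- sub("_nodes\\.csv$", "", sub("_segments\\.csv$", "", path))
    fn <- paste0(stem, "_nodes.csv"); fs <- paste0(stem, "_segments.csv")
    if (!file.exists(fn) || !file.exists(fs)) {
      stop("csv pair not found: ", fn, " / ", fs)
    }
    rn <- utils::read.csv(fn, stringsAsFactors = FALSE)
    rs <- utils::read.csv(fs, stringsAsFactors = FALSE)
    nodes <- data.frame(id = as.integer(rn$id), x = rn$x_um, y = rn$y_um,
                        z = rn$z_um, role = rn$role)
    segs <- data.frame(id = as.integer(rs$id), tail = as.integer(rs$tail),
                       head = as.integer(rs$head), diameter = rs$diameter_um,
                       length = rs$length_um, compartment = rs$compartment)
    segs$cp <- lapply(rs$control_points, .cp_unserialize)
    domfile <- paste0(stem, "_domain.json")
    dom <- if (file.exists(domfile)) jsonlite::fromJSON(domfile) else NULL
  }
  domain <- if (is.null(dom)) domain_descriptor() else
    domain_descriptor(kind = dom$kind, x = as.numeric(dom$x),
                      y = as.numeric(dom$y), depth = as.numeric(dom$depth),
                      tissue_volume = dom$tissue_volume)
  vascular_network(nodes, segs, domain)
}

.cp_serialize <- function(cp) {
  if (is.null(cp)) return("")
  paste(apply(cp, 1, function(p) paste(format(p, digits = 17), collapse = ",")),
        collapse = ";")
}

.cp_unserialize <- function(s) {
  if (is.na(s) || !nzchar(s)) return(NULL)
  pts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ",", fixed = TRUE)
  do.call(rbind, lapply(pts, as.numeric))
}

#' Write a vascular network to disk
#'
#' @param net A valid `vascular_network` (validated before writing; networks
#'   with non-finite diameters or lengths are refused).
#' @param path Output JSON path or CSV pair stem.
#' @param format `"json"` or `"csv_pair"`.
#' @return Invisibly, the path(s) written.
#' @export
write_network <- function(net, path, format = c("auto", "json", "csv_pair")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv_pair"
  }
  assert_valid_network(net)
  nodes <- data.frame(id = net$nodes$id, x_um = net$nodes$x,
                      y_um = net$nodes$y, z_um = net$nodes$z,
                      role = net$nodes$role)
  segs <- data.frame(id = net$segments$id, tail = net$segments$tail,
                     head = net$segments$head,
                     diameter_um = net$segments$diameter,
                     length_um = net$segments$length,
                     compartment = net$segments$compartment)
  dom <- unclass(net$domain)
  if (format == "json") {
    doc <- list(nodes = nodes, segments = cbind(
      segs, data.frame(control_points = I(lapply(net$segments$cp, function(cp) {
        if (is.null(cp)) NULL else unclass(cp)
      })))), domain = dom)
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
    invisible(path)
  } else {
    stem <- sub("_nodes\\.csv$", "", path)
    fn <- paste0(stem, "_nodes.csv"); fs <- paste0(stem, "_segments.csv")
    segs$control_points <- vapply(net$segments$cp, .cp_serialize, character(1))
    utils::write.csv(format(nodes, digits = 17, trim = TRUE), fn, row.names = FALSE, quote = TRUE)
    utils::write.csv(format(segs, digits = 17, trim = TRUE), fs, row.names = FALSE, quote = TRUE)
    jsonlite::write_json(dom, paste0(stem, "_domain.json"), auto_unbox = TRUE,
                         digits = NA)
    invisible(c(fn, fs))
  }
}

#' Export a network (and optional solution) as VTK PolyData
#'
#' Writes an ASCII VTK XML PolyData (`.vtp`) file with one polyline per
#' segment (following the Bezier control polygon where present) and
#' per-segment cell arrays: `diameter`, `compartment` (integer code) and,
#' when a solution field is supplied, `pressure` (segment-mean, mmHg),
#' `flow` (nL/s, signed) and `hematocrit`.
#'
#' @param net A `vascular_network`.
#' @param field Optional `vnet_solution` for `net`.
#' @param path Output `.vtp` path.
#' @return Invisibly, `path`.
#' @export
export_vtk <- function(net, field = NULL, path) {
  assert_valid_network(net)
  if (!is.null(field)) {
    if (length(field$Q) != nrow(net$segments) ||
        length(field$p) != nrow(net$nodes)) {
      stop("solution dimensions do not match the network")
    }
  }
  it <- match(net$segments$tail, net$nodes$id)
  ih <- match(net$segments$head, net$nodes$id)
  polys <- lapply(seq_len(nrow(net$segments)), function(i) {
    cp <- net$segments$cp[[i]]
    if (is.null(cp)) {
      rbind(c(net$nodes$x[it[i]], net$nodes$y[it[i]], net$nodes$z[it[i]]),
            c(net$nodes$x[ih[i]], net$nodes$y[ih[i]], net$nodes$z[ih[i]]))
    } else {
      bezier_points(cp, n = max(8L, nrow(cp) * 4L))
    }
  })
  pts <- do.call(rbind, polys)
  npts <- vapply(polys, nrow, integer(1))
  offs <- cumsum(npts)
  conn <- seq_len(nrow(pts)) - 1L
  comp_levels <- c("PIA", "PEA", "PEC", "CAP", "POC", "AV", "PV")
  comp_code <- match(net$segments$compartment, comp_levels)
  comp_code[is.na(comp_code)] <- 0L
  arr <- function(name, v, type = "Float64") {
    paste0('      <DataArray type="', type, '" Name="', name,
           '" format="ascii">\n        ',
           paste(format(v, digits = 9, trim = TRUE, scientific = FALSE),
                 collapse = " "),
           "\n      </DataArray>\n")
  }
  cell_data <- paste0(arr("diameter", net$segments$diameter),
                      arr("compartment", comp_code, "Int32"))
  if (!is.null(field)) {
    pm <- (field$p[it] + field$p[ih]) / 2 / 133.322
    cell_data <- paste0(cell_data,
                        arr("pressure", pm),
                        arr("flow", field$Q * 1e12),
                        arr("hematocrit", field$h))
  }
  xml <- paste0(
    '<?xml version="1.0"?>\n',
    '<VTKFile type="PolyData" version="0.1" byte_order="LittleEndian">\n',
    '  <PolyData>\n',
    '    <Piece NumberOfPoints="', nrow(pts), '" NumberOfLines="',
    length(polys), '">\n',
    '    <Points>\n',
    '      <DataArray type="Float64" NumberOfComponents="3" format="ascii">\n',
    "        ", paste(format(t(pts), digits = 9, trim = TRUE,
                             scientific = FALSE), collapse = " "), "\n",
    "      </DataArray>\n    </Points>\n",
    "    <Lines>\n",
    '      <DataArray type="Int64" Name="connectivity" format="ascii">\n',
    "        ", paste(conn, collapse = " "), "\n      </DataArray>\n",
    '      <DataArray type="Int64" Name="offsets" format="ascii">\n',
    "        ", paste(offs, collapse = " "), "\n      </DataArray>\n",
    "    </Lines>\n",
    "    <CellData>\n", cell_data, "    </CellData>\n",
    "    </Piece>\n  </PolyData>\n</VTKFile>\n")
  writeLines(xml, path)
  invisible(path)
}

# Evaluate a Bezier curve with control polygon cp (rows = points) at n
# parameter values via de Casteljau.
bezier_points <- function(cp, n = 16L) {
  ts <- seq(0, 1, length.out = n)
  out <- matrix(0, n, ncol(cp))
  for (k in seq_along(ts)) {
    p <- cp
    while (nrow(p) > 1L) {
      p <- p[-nrow(p), , drop = FALSE] * (1 - ts[k]) +
        p[-1L, , drop = FALSE] * ts[k]
    }
    out[k, ] <- p
  }
  out
}

# Arc length of a Bezier control polygon by dense polyline sampling.
bezier_arclength <- function(cp, n = 64L) {
  pts <- bezier_points(cp, n)
  sum(sqrt(rowSums(diff(pts)^2)))
}
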