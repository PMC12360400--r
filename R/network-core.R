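#' Construct a vascular network object
#'
#' A vascular network is a rooted directed tree: nodes carry 3-D positions
#' (um) and, once solved, pressures (mmHg); segments are straight cylindrical
#' vessels between nodes with a diameter, a length and a branching order
#' (order 1 = the feeding artery, order 5 = terminal arterioles). A single
#' inlet node is held at `inlet_pressure` and every terminal outlet at
#' `outlet_pressure`.
#'
#' @param nodes data.frame with columns `id`, `x`, `y`, `z` (um) and
#'   optionally `pressure` (mmHg).
#' @param segments data.frame with columns `id`, `from`, `to` (node ids),
#'   `order` (integer 1-5), `diameter` (um), `length` (um), `terminal`
#'   (logical or 0/1). Optional result columns `flow` (nl/min), `hd`
#'   (discharge hematocrit), `visc` (cP), `wall_shear` (dyn/cm^2).
#' @param inlet_node id of the root node.
#' @param inlet_pressure,outlet_pressure boundary pressures, mmHg.
#'   Defaults 40 and 24 (a 16 mmHg arteriolar pressure drop).
#' @param order_diameters named map order -> diameter (um) describing the
#'   unregulated reference diameters per branching order.
#'
#' @return An object of class `vascular_network`.
#' @seealso [validate_network()], [read_network()], [generate_arteriolar_tree()]
#' @export
vascular_network <- function(nodes, segments, inlet_node,
                             inlet_pressure = 40, outlet_pressure = 24,
                             order_diameters = c(`1` = 117, `2` = 73, `3` = 44,
                                                 `4` = 32, `5` = 22)) {
  nodes <- as.data.frame(nodes)
  segments <- as.data.frame(segments)
  if (is.null(nodes$pressure)) nodes$pressure <- NA_real_
  for (col in c("flow", "hd", "visc", "wall_shear")) {
    if (is.null(segments[[col]])) segments[[col]] <- NA_real_
  }
  segments$terminal <- as.logical(segments$terminal)
  net <- structure(
    list(nodes = nodes, segments = segments,
         inlet_node = inlet_node,
         inlet_pressure = inlet_pressure,
         outlet_pressure = outlet_pressure,
         order_diameters = order_diameters),
    class = "vascular_network")
  violations <- validate_network(net)
  if (length(violations)) {
    stop("invalid vascular network:\n  ", paste(violations, collapse = "\n  "))
  }
  net
}

#' Validate a vascular network
#'
#' Checks the structural invariants of a network: unique finite node ids and
#' positions, positive diameters and lengths, orders in 1..5, a single
#' connected rooted tree with the declared inlet, terminal flags exactly on
#' the leaf segments, and hematocrit in \[0, 1\] where present. A warning-level
#' check flags segments whose stored length is smaller than the Euclidean
#' node distance (lengths may exceed it to represent tortuosity, but should
#' not undercut it).
#'
#' @param net a `vascular_network` (or a bare list with the same fields;
#'   violations are reported rather than thrown, so partially built objects
#'   can be checked).
#' @return Character vector of human-readable violations; empty if valid.
#' @export
validate_network <- function(net) {
  v <- character()
  nd <- net$nodes; sg <- net$segments
  if (anyDuplicated(nd$id)) v <- c(v, "duplicate node ids")
  if (!all(is.finite(as.matrix(nd[, c("x", "y", "z")]))))
    v <- c(v, "non-finite node positions")
  if (nrow(sg) == 0) return(c(v, "network has no segments"))
  if (anyDuplicated(sg$id)) v <- c(v, "duplicate segment ids")
  bad <- sg$id[!(sg$diameter > 0)]
  if (length(bad)) v <- c(v, paste0("segment ", bad, ": diameter must be > 0"))
  bad <- sg$id[!(sg$length > 0)]
  if (length(bad)) v <- c(v, paste0("segment ", bad, ": length must be > 0"))
  bad <- sg$id[!(sg$order %in% 1:5)]
  if (length(bad)) v <- c(v, paste0("segment ", bad, ": order must be in 1..5"))
  bad <- sg$id[!is.na(sg$hd) & (sg$hd < 0 | sg$hd > 1)]
  if (length(bad)) v <- c(v, paste0("segment ", bad, ": hematocrit outside [0,1]"))
  if (!all(sg$from %in% nd$id) || !all(sg$to %in% nd$id))
    v <- c(v, "segment endpoint references unknown node id")
  if (!(net$inlet_node %in% nd$id)) v <- c(v, "inlet node id not present")
  if (length(v)) return(v)

  # tree topology: every node except the inlet has exactly one parent edge
  indeg <- table(factor(sg$to, levels = nd$id))
  root_in <- indeg[as.character(net$inlet_node)]
  if (root_in != 0) v <- c(v, "inlet node has an incoming segment")
  multi <- names(indeg)[indeg > 1]
  if (length(multi)) v <- c(v, paste0("node ", multi, ": multiple parent segments (cycle or merge)"))
  orphan <- names(indeg)[indeg == 0 & names(indeg) != as.character(net$inlet_node)]
  if (length(orphan)) v <- c(v, paste0("node ", orphan, ": disconnected from inlet"))
  if (nrow(sg) != nrow(nd) - 1)
    v <- c(v, sprintf("segment count (%d) != node count - 1 (%d): not a tree",
                      nrow(sg), nrow(nd) - 1))
  if (length(v)) return(v)

  # reachability from the root (guards against cycles detached from the inlet)
  reach <- reachable_nodes(sg, net$inlet_node)
  unreach <- setdiff(nd$id, reach)
  if (length(unreach)) {
    return(c(v, paste0("node ", unreach, ": not reachable from the inlet")))
  }

  # terminal flags must mark exactly the leaf segments
  has_child <- sg$to %in% sg$from
  bad <- sg$id[sg$terminal & has_child]
  if (length(bad)) v <- c(v, paste0("segment ", bad, ": flagged terminal but has children"))
  bad <- sg$id[!sg$terminal & !has_child]
  if (length(bad)) v <- c(v, paste0("segment ", bad, ": leaf segment not flagged terminal"))

  # tortuosity sanity: stored length should not undercut chord length
  pos <- nd[match(sg$from, nd$id), c("x", "y", "z")] -
    nd[match(sg$to, nd$id), c("x", "y", "z")]
  chord <- sqrt(rowSums(pos^2))
  bad <- sg$id[sg$length < chord - 1e-6]
  if (length(bad))
    v <- c(v, paste0("segment ", bad, ": length shorter than node distance"))
  v
}

reachable_nodes <- function(segments, root) {
  kids <- split(segments$to, segments$from)
  seen <- as.character(root)
  frontier <- seen
  while (length(frontier)) {
    nxt <- unlist(kids[frontier], use.names = FALSE)
    nxt <- setdiff(as.character(nxt), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  type.convert(seen, as.is = TRUE)
}

# Segment indices in root-to-leaf (topological) order.
segment_topo_order <- function(net) {
  sg <- net$segments
  ord <- integer(0)
  frontier <- which(sg$from == net$inlet_node)
  while (length(frontier)) {
    ord <- c(ord, frontier)
    frontier <- which(sg$from %in% sg$to[frontier])
  }
  ord
}

# For each terminal segment, the indices of segments on its root path.
terminal_paths <- function(net) {
  sg <- net$segments
  parent_of <- match(sg$from, sg$to)  # index of parent segment, NA at root
  lapply(which(sg$terminal), function(i) {
    path <- i
    while (!is.na(parent_of[path[1]])) path <- c(parent_of[path[1]], path)
    path
  })
}

#' @export
print.vascular_network <- function(x, ...) {
  sg <- x$segments
  cat("<vascular_network> ", nrow(x$nodes), " nodes, ", nrow(sg),
      " segments, ", sum(sg$terminal), " terminal arterioles\n", sep = "")
  cat("  boundary pressures: ", x$inlet_pressure, " -> ", x$outlet_pressure,
      " mmHg\n", sep = "")
  tab <- table(sg$order)
  cat("  segments by order: ",
      paste(sprintf("%s:%d", names(tab), tab), collapse = ", "), "\n", sep = "")
  if (any(!is.na(sg$flow)))
    cat("  solved inflow: ", signif(sum(sg$flow[sg$from == x$inlet_node]), 4),
        " nl/min\n", sep = "")
  invisible(x)
}

#' Read a vascular network from a TSV file
#'
#' The file format is UTF-8 tab-separated text with two sections introduced
#' by `#nodes` and `#segments` header lines. The nodes section has columns
#' `id x_um y_um z_um`; the segments section has
#' `id from to order diameter_um length_um terminal` with optional result
#' columns `flow_nl_min hd visc_cP`. Boundary pressures and the inlet id are
#' carried in `#inlet`, `#inlet_pressure_mmHg`, `#outlet_pressure_mmHg`
#' key-value header lines.
#'
#' @param path file path.
#' @return A validated `vascular_network`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  meta <- list(inlet = NA, inlet_pressure = 40, outlet_pressure = 24)
  sec <- NULL; node_rows <- character(); seg_rows <- character()
  node_header <- seg_header <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    if (startsWith(ln, "#inlet_pressure_mmHg")) {
      meta$inlet_pressure <- as.numeric(strsplit(ln, "\t")[[1]][2]); next
    }
    if (startsWith(ln, "#outlet_pressure_mmHg")) {
      meta$outlet_pressure <- as.numeric(strsplit(ln, "\t")[[1]][2]); next
    }
    if (startsWith(ln, "#inlet")) {
      meta$inlet <- as.integer(strsplit(ln, "\t")[[1]][2]); next
    }
    if (ln == "#nodes") { sec <- "nodes"; node_header <- NA; next }
    if (ln == "#segments") { sec <- "segments"; seg_header <- NA; next }
    if (is.null(sec)) stop("line ", i, ": content before any section header")
    if (sec == "nodes" && is.na(node_header[1])) { node_header <- ln; next }
    if (sec == "segments" && is.na(seg_header[1])) { seg_header <- ln; next }
    if (sec == "nodes") node_rows <- c(node_rows, lines[i]) else seg_rows <- c(seg_rows, lines[i])
  }
  if (!length(node_rows) || !length(seg_rows))
    stop("network file must contain non-empty #nodes and #segments sections")
  parse_tsv <- function(header, rows, what) {
    cols <- strsplit(header, "\t")[[1]]
    mat <- strsplit(rows, "\t")
    nbad <- which(lengths(mat) != length(cols))
    if (length(nbad))
      stop("malformed ", what, " row (", length(cols), " columns expected): line '",
           rows[nbad[1]], "'")
    df <- as.data.frame(do.call(rbind, mat), stringsAsFactors = FALSE)
    names(df) <- cols
    df[] <- lapply(df, function(x) {
      y <- suppressWarnings(as.numeric(x))
      if (anyNA(y)) stop("malformed numeric value in ", what, " section")
      y
    })
    df
  }
  nd <- parse_tsv(node_header, node_rows, "node")
  sg <- parse_tsv(seg_header, seg_rows, "segment")
  nodes <- data.frame(id = nd$id, x = nd$x_um, y = nd$y_um, z = nd$z_um)
  if (!is.null(nd$pressure_mmHg)) nodes$pressure <- nd$pressure_mmHg
  segments <- data.frame(id = sg$id, from = sg$from, to = sg$to,
                         order = sg$order, diameter = sg$diameter_um,
                         length = sg$length_um, terminal = sg$terminal == 1)
  if (!is.null(sg$flow_nl_min)) segments$flow <- sg$flow_nl_min
  if (!is.null(sg$hd)) segments$hd <- sg$hd
  if (!is.null(sg$visc_cP)) segments$visc <- sg$visc_cP
  if (is.na(meta$inlet)) {
    cand <- setdiff(segments$from, segments$to)
    if (length(unique(cand)) != 1)
      stop("topology error: network must have exactly one inlet node, found ",
           length(unique(cand)))
    meta$inlet <- unique(cand)
  }
  vascular_network(nodes, segments, inlet_node = meta$inlet,
                   inlet_pressure = meta$inlet_pressure,
                   outlet_pressure = meta$outlet_pressure)
}

#' Write a vascular network to a TSV file
#'
#' Inverse of [read_network()]: the written file round-trips to an equal
#' network. Solved quantities (flow, hematocrit, viscosity, pressures) are
#' written as optional columns when present. Numeric values are written with
#' 12 significant digits.
#'
#' @param net a valid `vascular_network`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "vascular_network"))
  if (nrow(net$segments) == 0) stop("refusing to write a network with no segments")
  num <- function(x) formatC(x, digits = 12, format = "g")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("#inlet\t", net$inlet_node),
               paste0("#inlet_pressure_mmHg\t", num(net$inlet_pressure)),
               paste0("#outlet_pressure_mmHg\t", num(net$outlet_pressure))), con)
  nd <- net$nodes
  has_p <- any(!is.na(nd$pressure))
  writeLines("#nodes", con)
  hdr <- c("id", "x_um", "y_um", "z_um", if (has_p) "pressure_mmHg")
  writeLines(paste(hdr, collapse = "\t"), con)
  rows <- paste(nd$id, num(nd$x), num(nd$y), num(nd$z), sep = "\t")
  if (has_p) rows <- paste(rows, num(nd$pressure), sep = "\t")
  writeLines(rows, con)
  sg <- net$segments
  has_q <- any(!is.na(sg$flow))
  writeLines("#segments", con)
  hdr <- c("id", "from", "to", "order", "diameter_um", "length_um", "terminal",
           if (has_q) c("flow_nl_min", "hd", "visc_cP"))
  writeLines(paste(hdr, collapse = "\t"), con)
  rows <- paste(sg$id, sg$from, sg$to, sg$order, num(sg$diameter),
                num(sg$length), as.integer(sg$terminal), sep = "\t")
  if (has_q) rows <- paste(rows, num(sg$flow), num(sg$hd), num(sg$visc), sep = "\t")
  writeLines(rows, con)
  invisible(path)
}

#' Read / write compartment chains
#'
#' Compartment chains (one per terminal arteriole: capillary, small-venule
#' and large-venule compartments in series) are stored as a companion TSV
#' with columns `terminal_id n_C L_C_um r_C_um n_SV L_SV_um r_SV_um n_LV
#' L_LV_um r_LV_um` plus optional solved columns `q_nl_min p_in_mmHg`.
#'
#' @param path file path.
#' @return `read_compartments()` returns a `compartment_chains` data.frame.
#' @export
read_compartments <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  names(df) <- sub("_um$", "", names(df))
  names(df) <- sub("^q_nl_min$", "q", names(df))
  names(df) <- sub("^p_in_mmHg$", "p_in", names(df))
  as_compartment_chains(df)
}

#' @rdname read_compartments
#' @param chains a `compartment_chains` data.frame.
#' @export
write_compartments <- function(chains, path) {
  df <- as.data.frame(chains)
  names(df)[match(c("L_C", "r_C", "L_SV", "r_SV", "L_LV", "r_LV"), names(df))] <-
    c("L_C_um", "r_C_um", "L_SV_um", "r_SV_um", "L_LV_um", "r_LV_um")
  if ("q" %in% names(df)) names(df)[names(df) == "q"] <- "q_nl_min"
  if ("p_in" %in% names(df)) names(df)[names(df) == "p_in"] <- "p_in_mmHg"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_compartment_chains <- function(df) {
  needed <- c("terminal_id", "n_C", "L_C", "r_C", "n_SV", "L_SV", "r_SV",
              "n_LV", "L_LV", "r_LV")
  miss <- setdiff(needed, names(df))
  if (length(miss)) stop("compartment chains missing columns: ",
                         paste(miss, collapse = ", "))
  stopifnot(all(df$n_C >= 1),
            all(df[c("L_C", "r_C", "L_SV", "r_SV", "L_LV", "r_LV")] > 0))
  class(df) <- c("compartment_chains", "data.frame")
  df
}
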