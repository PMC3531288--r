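#' Construct a cell network
#'
#' Low-level constructor; most users will call [buildChain()] or
#' [buildTStructure()].
#'
#' @param cells data.frame (or DataFrame) with columns \code{label},
#'   \code{col}, \code{row}.
#' @param couplings data.frame with columns \code{a}, \code{b}, \code{kind},
#'   \code{coefficient}.
#' @param architecture architecture tag.
#' @return a [CellNetwork-class] object.
#' @export
cellNetwork <- function(cells, couplings,
                        architecture = c("custom", "chain", "t_structure")) {
  architecture <- match.arg(architecture)
  cells <- S4Vectors::DataFrame(
    label = as.character(cells$label),
    col = as.integer(cells$col),
    row = as.integer(cells$row)
  )
  if (is.null(couplings) || nrow(couplings) == 0L) {
    couplings <- S4Vectors::DataFrame(
      a = character(0), b = character(0), kind = character(0),
      coefficient = numeric(0)
    )
  } else {
    couplings <- S4Vectors::DataFrame(
      a = as.character(couplings$a), b = as.character(couplings$b),
      kind = as.character(couplings$kind),
      coefficient = as.numeric(couplings$coefficient)
    )
  }
  new("CellNetwork", cells = cells, couplings = couplings,
      architecture = architecture)
}

#' @describeIn cellNetwork cell table accessor
#' @export
setMethod("cells", "CellNetwork", function(x) x@cells)

#' @describeIn cellNetwork coupling table accessor
#' @export
setMethod("couplings", "CellNetwork", function(x) x@couplings)

#' @describeIn cellNetwork architecture tag accessor
#' @export
setMethod("architecture", "CellNetwork", function(x) x@architecture)

setMethod("show", "CellNetwork", function(object) {
  cp <- object@couplings
  cat(sprintf("CellNetwork (%s): %d cells, %d couplings (%d edge, %d vertex)\n",
              object@architecture, nrow(object@cells), nrow(cp),
              sum(cp$kind == "edge"), sum(cp$kind == "vertex")))
})

#' Build a single chain of cells
#'
#' A finite single-file chain of \code{n_cells} cells labelled
#' \code{"1"} ... \code{"n_cells"}, with edge couplings of coefficient
#' \code{d_edge} between consecutive cells.  Terminal cells simply have one
#' coupling (zero-flux boundary; no ghost cells).
#'
#' @param n_cells number of cells (>= 2).
#' @param d_edge dimensionless edge diffusion coefficient (>= 0;
#'   default 0.6).
#' @return a [CellNetwork-class] with architecture \code{"chain"}.
#' @examples
#' buildChain(61, 0.6)
#' @export
buildChain <- function(n_cells, d_edge = 0.6) {
  if (!(length(n_cells) == 1L && is.finite(n_cells) && n_cells >= 2 &&
        n_cells == floor(n_cells))) {
    stop("n_cells must be an integer >= 2")
  }
  if (!(length(d_edge) == 1L && is.finite(d_edge) && d_edge >= 0)) {
    stop("d_edge must be a non-negative scalar")
  }
  n <- as.integer(n_cells)
  cells <- data.frame(label = as.character(seq_len(n)), col = seq_len(n),
                      row = 0L)
  couplings <- data.frame(
    a = as.character(seq_len(n - 1L)), b = as.character(seq.int(2L, n)),
    kind = "edge", coefficient = d_edge
  )
  cellNetwork(cells, couplings, architecture = "chain")
}

# Canonical coupling label, order-independent.
.pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "~")
}

# The four vertex pairs retained under the "junction" rule: the two pairs
# coupling the branch entrance to the backbone junction cells, plus the two
# coupling the cluster cells to the branch attachment cell.
.junction_vertex_pairs <- function() {
  c(.pair_key("1s", "30"), .pair_key("1s", "32"),
    .pair_key("1'", "31"), .pair_key("2'", "31"))
}

#' Build the branched "T" structure with a junction cell cluster
#'
#' The reconstructed branched architecture: a backbone chain of 61 cells
#' (labels \code{"1"} ... \code{"61"}) on lattice row 0; a 30-cell side
#' branch (labels \code{"1s"} ... \code{"30s"}) in the column of backbone
#' cell 31, rows 1 ... 30; and two cluster cells \code{"1'"} (above cell 30)
#' and \code{"2'"} (above cell 32) flanking the branch entrance, mimicking
#' the multi-cell cluster that forms where three single-file branches meet.
#' Cells 30, 31 and 32 are the backbone junction cells.
#'
#' Orthogonally adjacent cells are coupled through edge contacts with
#' coefficient \code{d_edge}.  Diagonally adjacent cells in the junction
#' area are coupled through vertex contacts with coefficient \code{dv}:
#' with \code{vertex_pairs = "junction"} (default) the four pairs
#' 1s--30, 1s--32, 1'--31 and 2'--31; with \code{vertex_pairs = "all"}
#' every diagonally adjacent pair the lattice generates (additionally
#' 1'--29, 2'--33, 1'--2s, 2'--2s).  The default keeps vertex coupling
#' confined to the junction entrance, which preserves the qualitative
#' dual-stimulation advantage (see the vignette); the uniform geometric
#' rule is retained as an option.
#'
#' @param d_edge dimensionless edge diffusion coefficient (default 0.6).
#' @param dv dimensionless vertex diffusion coefficient (>= 0).
#' @param vertex_pairs \code{"junction"} or \code{"all"}; see Details.
#' @return a [CellNetwork-class] with architecture \code{"t_structure"}.
#' @examples
#' net <- buildTStructure(0.6, 0.2)
#' nrow(cells(net))   # 93
#' @export
buildTStructure <- function(d_edge = 0.6, dv = 0.1,
                            vertex_pairs = c("junction", "all")) {
  vertex_pairs <- match.arg(vertex_pairs)
  if (!(length(d_edge) == 1L && is.finite(d_edge) && d_edge >= 0)) {
    stop("d_edge must be a non-negative scalar")
  }
  if (!(length(dv) == 1L && is.finite(dv) && dv >= 0)) {
    stop("dv must be a non-negative scalar")
  }
  cells <- rbind(
    data.frame(label = as.character(1:61), col = 1:61, row = 0L),
    data.frame(label = paste0(1:30, "s"), col = 31L, row = 1:30),
    data.frame(label = c("1'", "2'"), col = c(30L, 32L), row = 1L)
  )
  n <- nrow(cells)
  keep <- if (vertex_pairs == "junction") .junction_vertex_pairs() else NULL
  a <- character(0); b <- character(0); kind <- character(0)
  for (i in seq_len(n - 1L)) {
    dc <- abs(cells$col[(i + 1L):n] - cells$col[i])
    dr <- abs(cells$row[(i + 1L):n] - cells$row[i])
    adj_e <- which(dc + dr == 1L)
    adj_v <- which(dc == 1L & dr == 1L)
    for (j in adj_e + i) {
      a <- c(a, cells$label[i]); b <- c(b, cells$label[j])
      kind <- c(kind, "edge")
    }
    for (j in adj_v + i) {
      key <- .pair_key(cells$label[i], cells$label[j])
      if (is.null(keep) || key %in% keep) {
        a <- c(a, cells$label[i]); b <- c(b, cells$label[j])
        kind <- c(kind, "vertex")
      }
    }
  }
  couplings <- data.frame(
    a = a, b = b, kind = kind,
    coefficient = ifelse(kind == "edge", d_edge, dv)
  )
  cellNetwork(cells, couplings, architecture = "t_structure")
}

#' Validate a cell network
#'
#' Checks all structural invariants and returns a character vector of
#' violation descriptions (empty when the network is valid).  Reported, not
#' raised: callers decide what to do with violations.
#'
#' Checks: unique labels; unique positions; non-negative coefficients;
#' coupling kind matching lattice geometry (edge iff positions differ by one
#' unit in exactly one coordinate, vertex iff in both); no duplicated
#' couplings; graph connectivity; and for \code{"chain"} networks the
#' degree rule (interior cells exactly 2 couplings, terminals exactly 1,
#' all edge kind).
#'
#' @param net a [CellNetwork-class].
#' @return character vector of violations; \code{character(0)} if valid.
#' @export
validateNetwork <- function(net) {
  stopifnot(is(net, "CellNetwork"))
  v <- character(0)
  cl <- as.data.frame(net@cells)
  cp <- as.data.frame(net@couplings)
  dup <- cl$label[duplicated(cl$label)]
  if (length(dup)) {
    v <- c(v, sprintf("duplicated cell label: %s", unique(dup)))
  }
  pos <- paste(cl$col, cl$row, sep = ",")
  for (p in unique(pos[duplicated(pos)])) {
    labs <- cl$label[pos == p]
    v <- c(v, sprintf("cells %s share position (%s)",
                      paste(labs, collapse = ", "), p))
  }
  if (nrow(cp)) {
    bad <- which(cp$coefficient < 0)
    for (i in bad) {
      v <- c(v, sprintf("coupling %s-%s has negative coefficient",
                        cp$a[i], cp$b[i]))
    }
    ia <- match(cp$a, cl$label); ib <- match(cp$b, cl$label)
    miss <- which(is.na(ia) | is.na(ib))
    for (i in miss) {
      v <- c(v, sprintf("coupling %s-%s references unknown cell",
                        cp$a[i], cp$b[i]))
    }
    ok <- setdiff(seq_len(nrow(cp)), miss)
    dc <- abs(cl$col[ia[ok]] - cl$col[ib[ok]])
    dr <- abs(cl$row[ia[ok]] - cl$row[ib[ok]])
    expect <- ifelse(dc + dr == 1L, "edge",
                     ifelse(dc == 1L & dr == 1L, "vertex", "none"))
    for (j in which(expect != cp$kind[ok])) {
      i <- ok[j]
      v <- c(v, sprintf(
        "coupling %s-%s declared '%s' but geometry implies '%s'",
        cp$a[i], cp$b[i], cp$kind[i],
        ifelse(expect[j] == "none", "no adjacency", expect[j])))
    }
    key <- .pair_key(cp$a, cp$b)
    for (k in unique(key[duplicated(key)])) {
      v <- c(v, sprintf("duplicated coupling %s", k))
    }
  }
  # connectivity (couplings with coefficient 0 still count as graph links)
  if (nrow(cl) > 1L) {
    reach <- .reachable(cl$label, cp)
    if (length(reach) < nrow(cl)) {
      v <- c(v, sprintf("network not connected; unreachable cells: %s",
                        paste(setdiff(cl$label, reach), collapse = ", ")))
    }
  }
  if (net@architecture == "chain" && nrow(cp)) {
    deg <- table(factor(c(cp$a, cp$b), levels = cl$label))
    if (any(cp$kind != "edge")) {
      v <- c(v, "chain networks must contain only edge couplings")
    }
    n <- nrow(cl)
    wrong <- names(deg)[!(deg %in% c(1L, 2L))]
    terminals <- cl$label[c(1L, n)]
    bad_term <- intersect(names(deg)[deg != 1L], terminals)
    bad_int <- setdiff(names(deg)[deg != 2L], terminals)
    for (lbl in union(wrong, union(bad_term, bad_int))) {
      v <- c(v, sprintf("chain cell %s has degree %d", lbl, deg[[lbl]]))
    }
  }
  v
}

.reachable <- function(labels, cp) {
  if (nrow(cp) == 0L) return(labels[1L])
  adj <- split(c(cp$b, cp$a), c(cp$a, cp$b))
  seen <- labels[1L]
  frontier <- labels[1L]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

# Breadth-first graph distances from a set of source labels.
.graph_distances <- function(net, from) {
  cl <- net@cells$label
  cp <- as.data.frame(net@couplings)
  d <- stats::setNames(rep(Inf, length(cl)), cl)
  d[from] <- 0
  frontier <- from
  adj <- if (nrow(cp)) split(c(cp$b, cp$a), c(cp$a, cp$b)) else list()
  k <- 0
  while (length(frontier)) {
    k <- k + 1
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   names(d)[is.finite(d)])
    d[nxt] <- k
    frontier <- nxt
  }
  d
}

#' Write / read a network as JSON
#'
#' The JSON document lists cells (label, column, row) and couplings
#' (a, b, kind, coefficient).  Reading back is bit-exact on labels and exact
#' on coefficients.
#'
#' @param net a [CellNetwork-class].
#' @param path file path.
#' @return \code{writeNetworkJSON} returns \code{path} invisibly;
#'   \code{readNetworkJSON} returns a [CellNetwork-class].
#' @export
writeNetworkJSON <- function(net, path) {
  stopifnot(is(net, "CellNetwork"))
  doc <- list(
    architecture = net@architecture,
    cells = as.data.frame(net@cells),
    couplings = as.data.frame(net@couplings)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeNetworkJSON
#' @export
readNetworkJSON <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  cellNetwork(doc$cells, doc$couplings, architecture = doc$architecture)
}
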