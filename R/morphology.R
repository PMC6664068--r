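# Morphology ingestion and spatial discretization.
#
# Units used throughout the package: mV, ms, nA, uS, nF, MOhm, um.
# These are self-consistent: nA = uS * mV and ms = nF / uS.

SWC_SOMA <- 1L
SWC_AXON <- 2L
SWC_DEND <- 3L
SWC_APIC <- 4L

#' Read an SWC morphology into a section graph
#'
#' Parses the standard 7-column SWC format (`id type x y z radius parent`,
#' radius in micrometres) and splits the sample tree into unbranched sections
#' at branch points and type changes.  Axon-typed samples (type 2) and their
#' descendants are discarded by default, since only soma and dendrites are
#' simulated; axonal propagation is represented downstream as a per-connection
#' event delay.
#'
#' @param path Path to an SWC file, or a character scalar holding SWC text
#'   (recognized by embedded newlines).
#' @param keep_axon Keep axon-typed samples as ordinary (passive) cables
#'   instead of dropping them.
#' @return A `section_graph`: a list of sections, each with `id`, `type`
#'   (SWC integer type), `parent` (section id or `NA`), `points` (matrix with
#'   columns `x`, `y`, `z`, `r`; the first row of a child section is its
#'   attachment point on the parent) and `first_sample` (SWC id, used as the
#'   deterministic child visiting order).
#' @export
read_swc <- function(path, keep_axon = FALSE) {
  txt <- if (length(path) == 1L && grepl("\n", path)) {
    strsplit(path, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(path, warn = FALSE)
  }
  txt <- sub("#.*$", "", txt)
  keep <- grepl("\\S", txt)
  lines <- txt[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("SWC parse error: no samples found")

  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, 1L) != 7L)
  if (length(bad) > 0L) {
    stop(sprintf("SWC parse error at line %d: expected 7 columns", lineno[bad[1]]))
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(fields))),
              ncol = 7L, byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1]
    stop(sprintf("SWC parse error at line %d: non-numeric field", lineno[bad]))
  }
  id <- as.integer(m[, 1]); type <- as.integer(m[, 2])
  xyz <- m[, 3:5, drop = FALSE]; radius <- m[, 6]; parent <- as.integer(m[, 7])
  if (anyDuplicated(id)) stop("SWC structure error: duplicate sample ids")
  if (any(radius <= 0)) stop("SWC structure error: non-positive radius")

  idx <- match(parent, id)           # row index of parent sample, NA for roots
  roots <- which(parent == -1L)
  if (length(roots) == 0L) stop("SWC structure error: no root sample")
  if (length(roots) > 1L) stop("SWC structure error: multiple root samples")
  if (any(is.na(idx) & parent != -1L)) {
    stop("SWC structure error: parent id not found")
  }

  # drop axon samples (and anything hanging off them)
  if (!keep_axon) {
    drop <- type == SWC_AXON
    repeat {
      more <- !drop & !is.na(idx) & drop[idx]
      if (!any(more)) break
      drop <- drop | more
    }
    if (drop[roots]) stop("SWC structure error: root sample is axon-typed")
    keep_rows <- which(!drop)
    sel <- logical(length(id)); sel[keep_rows] <- TRUE
    id <- id[sel]; type <- type[sel]; xyz <- xyz[sel, , drop = FALSE]
    radius <- radius[sel]; parent <- parent[sel]
    idx <- match(parent, id)
    roots <- which(parent == -1L)
  }

  n <- length(id)
  nchild <- tabulate(idx[!is.na(idx)], nbins = n)

  # a sample opens a new section if it is the root, its parent branches, or
  # its type differs from its parent's (e.g. a dendrite leaving the soma)
  starts <- vapply(seq_len(n), function(i) {
    p <- idx[i]
    is.na(p) || nchild[p] > 1L || type[i] != type[p]
  }, TRUE)

  ord <- order(id)
  sections <- list(); sec_of_sample <- integer(n)
  for (i in ord) {
    if (!starts[i]) next
    rows <- i
    cur <- i
    repeat {
      ch <- which(!is.na(idx) & idx == cur & !starts)
      if (length(ch) != 1L) break
      rows <- c(rows, ch); cur <- ch
    }
    sid <- length(sections) + 1L
    sec_of_sample[rows] <- sid
    p <- idx[i]
    pts_rows <- if (is.na(p)) rows else c(p, rows)
    sections[[sid]] <- list(
      id = sid,
      type = type[i],
      parent = if (is.na(p)) NA_integer_ else -1L,  # resolved below
      parent_sample_row = if (is.na(p)) NA_integer_ else p,
      first_sample = id[i],
      points = cbind(x = xyz[pts_rows, 1], y = xyz[pts_rows, 2],
                     z = xyz[pts_rows, 3], r = radius[pts_rows])
    )
  }
  for (s in seq_along(sections)) {
    pr <- sections[[s]]$parent_sample_row
    if (!is.na(pr)) sections[[s]]$parent <- sec_of_sample[pr]
    sections[[s]]$parent_sample_row <- NULL
  }
  structure(list(sections = sections), class = "section_graph")
}

#' @export
print.section_graph <- function(x, ...) {
  ty <- vapply(x$sections, function(s) s$type, 1L)
  cat(sprintf("section_graph: %d sections (%d soma, %d axon, %d dend, %d apic)\n",
              length(x$sections), sum(ty == SWC_SOMA), sum(ty == SWC_AXON),
              sum(ty == SWC_DEND), sum(ty == SWC_APIC)))
  invisible(x)
}

section_path_length <- function(sec) {
  p <- sec$points
  if (nrow(p) < 2L) return(0)
  sum(sqrt(rowSums((p[-1, 1:3, drop = FALSE] - p[-nrow(p), 1:3, drop = FALSE])^2)))
}

section_diameter <- function(sec, own_only = TRUE) {
  p <- sec$points
  rows <- if (own_only && nrow(p) > 1L && !is.na(sec$parent)) 2:nrow(p) else seq_len(nrow(p))
  2 * mean(p[rows, "r"])
}

#' Axial resistance of a cylindrical compartment
#'
#' Standard cable formula `r = 4 * Ra * L / (pi * diam^2)` converted to
#' megaohms.
#'
#' @param length Compartment length (um).
#' @param diameter Compartment diameter (um).
#' @param ra Cytoplasmic resistivity (Ohm cm), default 100.
#' @return Axial resistance in MOhm.
#' @export
axial_resistance <- function(length, diameter, ra = 100) {
  if (any(length <= 0) || any(diameter <= 0) || any(ra <= 0)) {
    stop("axial_resistance: all inputs must be positive")
  }
  4 * ra * length / (pi * diameter^2) * 1e-2
}

#' Discretize a section graph into a compartment tree
#'
#' Splits every section into `ceiling(L / max_len)` equal cylinders and
#' numbers the compartments depth-first from the soma so that every
#' compartment's parent has a smaller index (the property that makes the cable
#' matrix solvable without fill-in).  Children are visited in ascending order
#' of their first SWC sample id, making the numbering reproducible.  The soma
#' is always a single compartment.
#'
#' @param graph A `section_graph` from [read_swc()].
#' @param max_len Maximum compartment length (um), default 20.
#' @param ra Cytoplasmic resistivity (Ohm cm).
#' @param cm Specific membrane capacitance (uF/cm^2).
#' @return A `compartment_tree`: list with `n`, `parent` (1-based parent index,
#'   `NA` at the root), `length` and `diam` (um), `cap` (nF), `r_axial`
#'   (MOhm between a compartment and its parent; `NA` at the root),
#'   `swc_type`, and `section` (originating section id).
#' @export
discretize <- function(graph, max_len = 20, ra = 100, cm = 1) {
  stopifnot(inherits(graph, "section_graph"))
  if (max_len <= 0) stop("discretize: max_len must be positive")
  secs <- graph$sections
  if (length(secs) == 0L) stop("discretize: empty section graph")

  children_of <- lapply(seq_along(secs), function(s) {
    ch <- which(vapply(secs, function(x) identical(x$parent, s), TRUE))
    ch[order(vapply(secs[ch], function(x) x$first_sample, 1L))]
  })
  root_sec <- which(vapply(secs, function(s) is.na(s$parent), TRUE))
  if (length(root_sec) != 1L) stop("discretize: graph must have exactly one root section")

  parent <- integer(); len <- numeric(); diam <- numeric()
  swc_type <- integer(); section <- integer()
  add_comp <- function(p, L, d, ty, sec) {
    parent <<- c(parent, p); len <<- c(len, L); diam <<- c(diam, d)
    swc_type <<- c(swc_type, ty); section <<- c(section, sec)
    length(parent)
  }

  emit_section <- function(s, parent_comp) {
    sec <- secs[[s]]
    if (is.na(sec$parent)) {             # soma: one cylinder, whatever max_len
      L <- section_path_length(sec)
      d <- section_diameter(sec, own_only = FALSE)
      if (L <= 0) L <- d                 # single-sample soma: sphere-equivalent
      last <- add_comp(NA_integer_, L, d, sec$type, s)
    } else {
      L <- section_path_length(sec)
      d <- section_diameter(sec)
      if (L <= 0) stop(sprintf("discretize: section %d has zero length", s))
      ncomp <- ceiling(L / max_len)
      seg <- L / ncomp
      last <- parent_comp
      for (i in seq_len(ncomp)) last <- add_comp(last, seg, d, sec$type, s)
    }
    for (ch in children_of[[s]]) emit_section(ch, last)
  }
  emit_section(root_sec, NA_integer_)

  area_cm2 <- pi * diam * len * 1e-8
  tree <- structure(list(
    n = length(parent), parent = parent, length = len, diam = diam,
    cap = cm * area_cm2 * 1e3,
    r_axial = ifelse(is.na(parent), NA_real_,
                     axial_resistance(len, diam, ra)),
    swc_type = swc_type, section = section, ra = ra, cm = cm
  ), class = "compartment_tree")
  validate_tree(tree)
  tree
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "compartment_tree"))
  n <- tree$n
  p <- tree$parent
  if (n < 1L) stop("compartment_tree: empty")
  if (!is.na(p[1])) stop("compartment_tree: index 1 must be the root")
  if (n > 1L) {
    if (any(is.na(p[-1]))) stop("compartment_tree: multiple roots")
    if (any(p[-1] >= seq(2L, n))) {
      stop("compartment_tree: parent index must be smaller than child index")
    }
  }
  if (any(tree$cap <= 0)) stop("compartment_tree: capacitance must be positive")
  if (n > 1L && any(tree$r_axial[-1] <= 0)) {
    stop("compartment_tree: axial resistance must be positive")
  }
  invisible(tree)
}

#' @export
print.compartment_tree <- function(x, ...) {
  cat(sprintf("compartment_tree: %d compartments, %d sections, total length %.1f um\n",
              x$n, length(unique(x$section)), sum(x$length)))
  invisible(x)
}

tree_children <- function(tree) {
  ch <- vector("list", tree$n)
  if (tree$n > 1L) {
    for (i in 2:tree$n) {
      p <- tree$parent[i]
      ch[[p]] <- c(ch[[p]], i)
    }
  }
  ch
}

#' Serialize / restore a compartment tree as JSON
#'
#' A small documented dialect used for fixtures: an object with fields `n`,
#' `parent` (0 marks the root), `length`, `diam`, `cap`, `r_axial`,
#' `swc_type`, `section`, `ra`, `cm`.
#'
#' @param tree A `compartment_tree`.
#' @return `tree_to_json()`: a JSON string; `tree_from_json()`: the tree.
#' @export
tree_to_json <- function(tree) {
  stopifnot(inherits(tree, "compartment_tree"))
  x <- unclass(tree)
  x$parent <- ifelse(is.na(x$parent), 0L, x$parent)
  x$r_axial <- ifelse(is.na(x$r_axial), 0, x$r_axial)
  jsonlite::toJSON(x, digits = NA, auto_unbox = TRUE)
}

#' @rdname tree_to_json
#' @param json JSON text produced by [tree_to_json()].
#' @export
tree_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  x$parent <- ifelse(x$parent == 0L, NA_integer_, as.integer(x$parent))
  x$r_axial <- ifelse(x$r_axial == 0, NA_real_, x$r_axial)
  x$n <- as.integer(x$n)
  tree <- structure(x, class = "compartment_tree")
  validate_tree(tree)
  tree
}
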