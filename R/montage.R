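#' @title Built-in 32-channel 10-20 montage and electrode adjacency
#' @name montage
#' @description
#' The package ships one montage, `"brainamp32"`: the standard 32-channel
#' 10-20 cap used with BrainAmp-class amplifiers (Fp1..O2, including the
#' low rim FT9/FT10/TP9/TP10). Electrode positions are stored as 2-D
#' azimuthal-equidistant ("top view") coordinates on a unit head; they are
#' used for the default adjacency graph and for distance-weighted channel
#' interpolation, not for source modelling.
NULL

# polar layout: angle in degrees from nose (clockwise positive to the right),
# radius 0.5 = ear-level ring; FT9/FT10/TP9/TP10 sit below it.
.brainamp32_polar <- function() {
  m <- rbind(
    Fp1 = c(-18, 0.52),  Fp2 = c(18, 0.52),
    F7  = c(-54, 0.52),  F3  = c(-40, 0.38),  Fz = c(0, 0.20),
    F4  = c(40, 0.38),   F8  = c(54, 0.52),
    FT9 = c(-72, 0.65),  FC5 = c(-69, 0.38),  FC1 = c(-45, 0.20),
    FC2 = c(45, 0.20),   FC6 = c(69, 0.38),   FT10 = c(72, 0.65),
    T7  = c(-90, 0.52),  C3  = c(-90, 0.20),  Cz = c(0, 0),
    C4  = c(90, 0.20),   T8  = c(90, 0.52),
    TP9 = c(-108, 0.65), CP5 = c(-111, 0.38), CP1 = c(-135, 0.20),
    CP2 = c(135, 0.20),  CP6 = c(111, 0.38),  TP10 = c(108, 0.65),
    P7  = c(-126, 0.52), P3  = c(-140, 0.38), Pz = c(180, 0.34),
    P4  = c(140, 0.38),  P8  = c(126, 0.52),
    O1  = c(-162, 0.52), Oz  = c(180, 0.48),  O2 = c(162, 0.52))
  colnames(m) <- c("angle", "radius")
  m
}

#' Electrode positions of a built-in montage
#'
#' @param montage_name montage identifier; only `"brainamp32"` is built in.
#' @return data.frame with columns `label`, `x`, `y` (2-D projected
#'   coordinates, unit head radius = 0.5 at the ear-level ring).
#' @export
#' @examples
#' head(montage_positions("brainamp32"))
montage_positions <- function(montage_name = "brainamp32") {
  if (!identical(montage_name, "brainamp32")) {
    stop("unknown montage: ", montage_name)
  }
  p <- .brainamp32_polar()
  a <- p[, "angle"] * pi / 180
  data.frame(label = rownames(p),
             x = p[, "radius"] * sin(a),
             y = p[, "radius"] * cos(a),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Channel labels of a built-in montage
#' @inheritParams montage_positions
#' @return character vector of 32 labels in cap order.
#' @export
montage_labels <- function(montage_name = "brainamp32") {
  montage_positions(montage_name)$label
}

# electrodes on the very outer rim, barely covering the scalp; excluded when
# summarising topographic maxima (as in the effect-size tables)
#' Rim electrodes excluded from topographic maxima
#' @inheritParams montage_positions
#' @return character vector of rim labels.
#' @export
montage_rim <- function(montage_name = "brainamp32") {
  if (!identical(montage_name, "brainamp32")) {
    stop("unknown montage: ", montage_name)
  }
  c("Fp1", "Fp2", "F7", "F8", "FT9", "FT10", "TP9", "TP10", "T7", "T8")
}

new_adjacency <- function(nodes, edges) {
  stopifnot(is.character(nodes))
  if (length(edges)) {
    stopifnot(ncol(edges) == 2)
    if (any(edges[, 1] == edges[, 2])) stop("adjacency has self-loops")
  }
  structure(list(nodes = nodes, edges = edges), class = "eeg_adjacency")
}

#' @export
print.eeg_adjacency <- function(x, ...) {
  cat("<eeg_adjacency> ", length(x$nodes), " nodes, ",
      nrow(x$edges), " undirected edges\n", sep = "")
  invisible(x)
}

#' Default electrode adjacency from montage geometry
#'
#' Two electrodes are neighbours when their 2-D projected distance is below
#' `factor` times the median nearest-neighbour distance of the montage.
#' The graph is symmetric and loop-free by construction. The published
#' adjacency map for this cap lives in supplementary material not reproduced
#' here; use [read_adjacency()] to supply an exact map.
#'
#' @inheritParams montage_positions
#' @param factor multiple of the median nearest-neighbour distance used as
#'   the neighbour threshold (default 1.3).
#' @return an `eeg_adjacency` object (fields `nodes`, `edges`).
#' @export
#' @examples
#' adj <- default_adjacency()
#' neighbors_of(adj, "Cz")
default_adjacency <- function(montage_name = "brainamp32", factor = 1.3) {
  pos <- montage_positions(montage_name)
  d <- as.matrix(stats::dist(pos[, c("x", "y")]))
  diag(d) <- Inf
  thr <- factor * stats::median(apply(d, 1, min))
  idx <- which(d < thr & upper.tri(d), arr.ind = TRUE)
  edges <- cbind(pos$label[idx[, 1]], pos$label[idx[, 2]])
  new_adjacency(pos$label, edges)
}

#' Read an electrode adjacency edge list
#'
#' Reads a two-column TSV of undirected electrode pairs, restricts it to
#' `labels`, and symmetrizes it. An edge naming an unknown label is an error.
#'
#' @param path TSV file with two label columns (no header required; a header
#'   line is tolerated if its fields are not in `labels`... it is not: any
#'   unknown label errors, so supply a headerless file).
#' @param labels character vector of valid channel labels.
#' @return an `eeg_adjacency` object.
#' @export
read_adjacency <- function(path, labels) {
  raw <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           col.names = c("a", "b"),
                           colClasses = "character", fill = FALSE,
                           blank.lines.skip = TRUE)
  if (nrow(raw) == 0) {
    warning("empty adjacency file: ", path)
    return(new_adjacency(labels, matrix(character(), ncol = 2)))
  }
  unknown <- setdiff(unique(c(raw$a, raw$b)), labels)
  if (length(unknown)) {
    stop("adjacency edge names unknown label(s): ",
         paste(unknown, collapse = ", "))
  }
  e <- unique(t(apply(as.matrix(raw), 1, sort)))
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  new_adjacency(labels, e)
}

#' Write an adjacency graph as a TSV edge list
#' @param adj an `eeg_adjacency` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adj, path) {
  utils::write.table(adj$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Neighbours of an electrode in an adjacency graph
#' @param adj an `eeg_adjacency` object.
#' @param label electrode label.
#' @return character vector of neighbouring labels.
#' @export
neighbors_of <- function(adj, label) {
  e <- adj$edges
  sort(unique(c(e[e[, 1] == label, 2], e[e[, 2] == label, 1])))
}

# adjacency as a named list of integer neighbour indices for fast traversal
.adjacency_index <- function(adj, labels) {
  nb <- vector("list", length(labels))
  names(nb) <- labels
  for (k in seq_len(nrow(adj$edges))) {
    a <- adj$edges[k, 1]; b <- adj$edges[k, 2]
    ia <- match(a, labels); ib <- match(b, labels)
    if (is.na(ia) || is.na(ib)) next
    nb[[ia]] <- c(nb[[ia]], ib)
    nb[[ib]] <- c(nb[[ib]], ia)
  }
  nb
}

# connected components of a node subset under the adjacency graph
.connected_components <- function(members, nb_index) {
  comps <- list()
  seen <- logical(length(nb_index))
  inset <- logical(length(nb_index))
  inset[members] <- TRUE
  for (s in members) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      comp <- c(comp, v)
      for (w in nb_index[[v]]) {
        if (inset[w] && !seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps
}
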