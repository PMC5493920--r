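# Containers for dynamic networks and plain-text I/O.
#
# A dynamic network is a sequence of T snapshots over a common node set of
# size N. Node presence can vary over time (R_it mask); dyad values are
# ordinal categories 0..M (0 = no edge). Raw weighted networks hold
# non-negative real weights instead and are turned into categorical
# networks by bin_weights().

#' Construct a dynamic network
#'
#' Bundles a sequence of network snapshots into a single object: an
#' `N x N x T` array of dyad values in `0..M` (0 means "no edge"), a node
#' presence mask, and directedness/self-loop flags.
#'
#' @param values integer array of dimension `N x N x T` with entries in
#'   `0..n_categories`. For undirected networks the array must be symmetric
#'   in its first two dimensions.
#' @param presence `N x T` binary matrix; `presence[i, t] = 1` means node `i`
#'   is part of the network at step `t`. Defaults to all-present.
#' @param directed logical; are dyads ordered?
#' @param self_loops logical; are diagonal entries `Y[i, i, t]` meaningful?
#' @param n_categories integer `M >= 1`; `M = 1` encodes a binary network.
#'   Defaults to the maximum observed value (at least 1).
#' @param node_labels,step_labels optional character labels; defaults are
#'   `"n1".."nN"` and `"1".."T"`.
#' @return an object of class `dynamic_network`.
#' @seealso [read_edge_list()], [bin_weights()]
#' @export
dynamic_network <- function(values, presence = NULL, directed = FALSE,
                            self_loops = FALSE, n_categories = NULL,
                            node_labels = NULL, step_labels = NULL) {
  values <- as_value_array(values)
  n <- dim(values)[1L]
  t_steps <- dim(values)[3L]
  if (is.null(presence)) presence <- matrix(1L, n, t_steps)
  presence <- as_presence(presence, n, t_steps)
  if (is.null(n_categories)) n_categories <- max(1L, max(values))
  n_categories <- as.integer(n_categories)
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  if (is.null(step_labels)) step_labels <- as.character(seq_len(t_steps))
  x <- structure(list(
    values = values, presence = presence,
    directed = isTRUE(directed), self_loops = isTRUE(self_loops),
    n_nodes = n, n_steps = t_steps, n_categories = n_categories,
    node_labels = as.character(node_labels),
    step_labels = as.character(step_labels)
  ), class = "dynamic_network")
  validate_dynamic_network(x)
  x
}

#' Construct a raw weighted dynamic network
#'
#' Same layout as [dynamic_network()] but entries are non-negative real
#' weights (e.g. interaction counts); 0 means "no edge observed". Use
#' [bin_weights()] to discretise into ordinal categories before fitting.
#'
#' @inheritParams dynamic_network
#' @param values numeric array `N x N x T`, entries `>= 0`.
#' @return an object of class `raw_weighted_network`.
#' @export
raw_weighted_network <- function(values, presence = NULL, directed = FALSE,
                                 self_loops = FALSE, node_labels = NULL,
                                 step_labels = NULL) {
  values <- as_value_array(values, integer_values = FALSE)
  n <- dim(values)[1L]
  t_steps <- dim(values)[3L]
  if (is.null(presence)) presence <- matrix(1L, n, t_steps)
  presence <- as_presence(presence, n, t_steps)
  if (is.null(node_labels)) node_labels <- paste0("n", seq_len(n))
  if (is.null(step_labels)) step_labels <- as.character(seq_len(t_steps))
  x <- structure(list(
    values = values, presence = presence,
    directed = isTRUE(directed), self_loops = isTRUE(self_loops),
    n_nodes = n, n_steps = t_steps,
    node_labels = as.character(node_labels),
    step_labels = as.character(step_labels)
  ), class = "raw_weighted_network")
  validate_dynamic_network(x, categorical = FALSE)
  x
}

as_value_array <- function(values, integer_values = TRUE) {
  if (is.matrix(values)) values <- array(values, c(dim(values), 1L))
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be an N x N x T array", call. = FALSE)
  if (dim(values)[1L] != dim(values)[2L])
    stop("`values` must be square in its first two dimensions", call. = FALSE)
  storage.mode(values) <- if (integer_values) "integer" else "double"
  values
}

as_presence <- function(presence, n, t_steps) {
  presence <- as.matrix(presence)
  if (!all(dim(presence) == c(n, t_steps)))
    stop("`presence` must be an N x T matrix", call. = FALSE)
  if (!all(presence %in% c(0, 1)))
    stop("`presence` must be binary", call. = FALSE)
  storage.mode(presence) <- "integer"
  presence
}

#' @keywords internal
validate_dynamic_network <- function(x, categorical = TRUE) {
  v <- x$values
  n <- x$n_nodes
  t_steps <- x$n_steps
  if (n < 2L) stop("a dynamic network needs at least 2 nodes", call. = FALSE)
  if (t_steps < 1L) stop("at least one time step is required", call. = FALSE)
  if (any(v < 0)) stop("dyad values must be non-negative", call. = FALSE)
  if (categorical) {
    if (x$n_categories < 1L) stop("n_categories must be >= 1", call. = FALSE)
    if (max(v) > x$n_categories)
      stop("dyad values exceed n_categories", call. = FALSE)
  }
  if (!x$directed) {
    for (t in seq_len(t_steps)) {
      if (!isTRUE(all.equal(v[, , t], t(v[, , t]), check.attributes = FALSE)))
        stop("undirected network has asymmetric values at step ", t,
             call. = FALSE)
    }
  }
  if (!x$self_loops) {
    for (t in seq_len(t_steps)) {
      if (any(diag(v[, , t]) != 0))
        stop("self-loops present but self_loops = FALSE (step ", t, ")",
             call. = FALSE)
    }
  }
  # values only where both endpoints are present
  for (t in seq_len(t_steps)) {
    p <- x$presence[, t]
    obs <- outer(p, p)
    if (any(v[, , t][obs == 0] != 0))
      stop("nonzero dyad value with an absent endpoint at step ", t,
           call. = FALSE)
  }
  invisible(x)
}

#' @export
print.dynamic_network <- function(x, ...) {
  cat(sprintf(
    "<dynamic_network> N = %d nodes, T = %d steps, M = %d categories\n",
    x$n_nodes, x$n_steps, x$n_categories))
  cat(sprintf("  %s, self-loops %s; %d of %d node-steps present\n",
              if (x$directed) "directed" else "undirected",
              if (x$self_loops) "allowed" else "excluded",
              sum(x$presence), length(x$presence)))
  invisible(x)
}

#' @export
print.raw_weighted_network <- function(x, ...) {
  cat(sprintf("<raw_weighted_network> N = %d nodes, T = %d steps\n",
              x$n_nodes, x$n_steps))
  cat(sprintf("  %s, self-loops %s; %d positive weights\n",
              if (x$directed) "directed" else "undirected",
              if (x$self_loops) "allowed" else "excluded",
              sum(x$values > 0)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# edge-list / presence file I/O

#' Read a time-stamped edge list
#'
#' Parses a plain-text edge list with one interaction per row:
#' `t <TAB> i <TAB> j [<TAB> w]`, where `t` is the 1-based time step, `i`
#' and `j` are node labels and `w` is an optional positive weight
#' (default 1). Lines starting with `#` are ignored. An optional presence
#' file (`node <TAB> t` rows) declares which nodes are part of the network
#' at which steps; without it every node is taken to be present at every
#' step, so absence must be declared explicitly rather than inferred from
#' isolation.
#'
#' @param path edge-list file.
#' @param n_steps total number of time steps `T` (steps with no edges are
#'   legitimate).
#' @param directed,self_loops network flags; for undirected input, listing
#'   both `(t, i, j)` and `(t, j, i)` is an error, as are duplicate rows.
#' @param presence_path optional presence file.
#' @return a [raw_weighted_network()]. Node labels are kept in first
#'   appearance order (edge file first, then presence file).
#' @export
read_edge_list <- function(path, n_steps, directed = FALSE,
                           self_loops = FALSE, presence_path = NULL) {
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) stop("n_steps must be >= 1")
  rows <- read_tsv_rows(path)
  n_fields <- lengths(rows)
  if (any(bad <- !(n_fields %in% c(3L, 4L))))
    stop("malformed row ", which(bad)[1L], " in ", path,
         ": expected 3 or 4 fields")
  et <- suppressWarnings(as.integer(vapply(rows, `[`, character(1), 1L)))
  ei <- vapply(rows, `[`, character(1), 2L)
  ej <- vapply(rows, `[`, character(1), 3L)
  ew <- rep(1, length(rows))
  has_w <- n_fields == 4L
  ew[has_w] <- suppressWarnings(
    as.numeric(vapply(rows[has_w], `[`, character(1), 4L)))
  if (anyNA(et)) stop("malformed row ", which(is.na(et))[1L],
                      ": time step is not an integer")
  if (any(bad <- et < 1L | et > n_steps))
    stop("row ", which(bad)[1L], ": time step out of range 1..", n_steps)
  if (anyNA(ew)) stop("malformed row ", which(is.na(ew))[1L],
                      ": weight is not numeric")
  if (any(bad <- ew <= 0))
    stop("row ", which(bad)[1L], ": weight must be positive")
  if (!self_loops && any(bad <- ei == ej))
    stop("row ", which(bad)[1L], ": self-loop ", ei[bad][1L],
         " but self_loops = FALSE")

  pt <- pn <- NULL
  if (!is.null(presence_path)) {
    pres_rows <- read_tsv_rows(presence_path)
    if (any(lengths(pres_rows) != 2L))
      stop("malformed presence row ", which(lengths(pres_rows) != 2L)[1L],
           ": expected 2 fields")
    pn <- vapply(pres_rows, `[`, character(1), 1L)
    pt <- suppressWarnings(as.integer(vapply(pres_rows, `[`, character(1), 2L)))
    if (anyNA(pt) || any(pt < 1L | pt > n_steps))
      stop("presence file: bad time step")
  }

  labels <- unique(c(rbind(ei, ej), pn))
  if (length(labels) < 2L)
    stop("fewer than 2 nodes in ", path,
         if (is.null(presence_path)) " (no presence file given)" else "")
  n <- length(labels)

  presence <- if (is.null(pn)) {
    matrix(1L, n, n_steps)
  } else {
    m <- matrix(0L, n, n_steps)
    m[cbind(match(pn, labels), pt)] <- 1L
    m
  }

  ii <- match(ei, labels)
  jj <- match(ej, labels)
  if (any(bad <- presence[cbind(ii, et)] == 0L | presence[cbind(jj, et)] == 0L))
    stop("edge (", ei[bad][1L], ", ", ej[bad][1L], ") at step ", et[bad][1L],
         " is incident to a node marked absent")
  key <- paste(et, ii, jj)
  if (any(bad <- duplicated(key)))
    stop("duplicate edge row (", ei[bad][1L], ", ", ej[bad][1L],
         ") at step ", et[bad][1L])
  if (!directed && any(bad <- paste(et, jj, ii) %in% key & ii != jj))
    stop("undirected input lists both orientations of (", ei[bad][1L], ", ",
         ej[bad][1L], ") at step ", et[bad][1L])

  values <- array(0, c(n, n, n_steps))
  values[cbind(ii, jj, et)] <- ew
  if (!directed) values[cbind(jj, ii, et)] <- ew

  raw_weighted_network(values, presence, directed = directed,
                       self_loops = self_loops, node_labels = labels,
                       step_labels = as.character(seq_len(n_steps)))
}

read_tsv_rows <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  lapply(lines, function(l) strsplit(trimws(l), "[ \t]+")[[1L]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a dynamic or raw network as an edge list (plus presence file)
#'
#' Inverse of [read_edge_list()]: writes `t, i, j, w` rows (undirected
#' dyads once, with `i` before `j` in internal order) and, if requested,
#' the presence table.
#'
#' @param net a `dynamic_network` or `raw_weighted_network`.
#' @param path output edge-list file.
#' @param presence_path optional output presence file.
#' @export
write_edge_list <- function(net, path, presence_path = NULL) {
  con_lines <- character(0)
  for (t in seq_len(net$n_steps)) {
    v <- net$values[, , t]
    idx <- which(v > 0, arr.ind = TRUE)
    if (!net$directed) idx <- idx[idx[, 1L] <= idx[, 2L], , drop = FALSE]
    if (nrow(idx)) {
      con_lines <- c(con_lines, sprintf(
        "%d\t%s\t%s\t%g", t,
        net$node_labels[idx[, 1L]], net$node_labels[idx[, 2L]],
        v[idx]))
    }
  }
  write_atomically(con_lines, path)
  if (!is.null(presence_path)) {
    idx <- which(net$presence == 1L, arr.ind = TRUE)
    write_atomically(
      sprintf("%s\t%d", net$node_labels[idx[, 1L]], idx[, 2L]),
      presence_path)
  }
  invisible(path)
}

write_atomically <- function(lines, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(lines, tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# weight binning

#' Bin raw edge weights into ordinal categories
#'
#' Pools all positive weights across every dyad and time step and splits
#' them into `m` equal-frequency bins (quantile thresholds). A positive
#' weight equal to a threshold goes to the lower bin; zeros stay zero, so
#' the no-edge pattern is preserved exactly. With `m = 1` every positive
#' weight becomes category 1 (binarisation). Thresholds are computed once
#' on the pooled weights, not per step, so category labels mean the same
#' thing at every time point.
#'
#' @param net a [raw_weighted_network()].
#' @param m number of categories (`M`).
#' @return a [dynamic_network()] with `n_categories = m`.
#' @export
bin_weights <- function(net, m) {
  stopifnot(inherits(net, "raw_weighted_network"))
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("m must be >= 1")
  v <- net$values
  pos <- if (net$directed) v[v > 0] else {
    keep <- array(FALSE, dim(v))
    for (t in seq_len(net$n_steps))
      keep[, , t] <- upper.tri(v[, , t], diag = net$self_loops)
    v[v > 0 & keep]
  }
  if (m > 1L && length(pos) == 0L)
    stop("no positive weights to bin with m > 1")
  out <- array(0L, dim(v))
  if (length(pos)) {
    if (m == 1L) {
      out[v > 0] <- 1L
    } else {
      srt <- sort(pos)
      n_pos <- length(srt)
      thresholds <- srt[ceiling(seq_len(m) * n_pos / m)]
      if (any(diff(thresholds) <= 0))
        stop("cannot form ", m, " non-empty bins: too few distinct weights")
      # smallest k with w <= threshold[k]; ties at a threshold -> lower bin
      idx <- which(v > 0)
      out[idx] <- m + 1L - findInterval(-v[idx], rev(-thresholds))
    }
  }
  dynamic_network(out, net$presence, directed = net$directed,
                  self_loops = net$self_loops, n_categories = m,
                  node_labels = net$node_labels,
                  step_labels = net$step_labels)
}

# ---------------------------------------------------------------------------
# membership I/O (group 0 = absent)

#' Write MAP group memberships to a TSV file
#'
#' One row per node-step: `node <TAB> t <TAB> group`, where group 0 marks
#' node-steps at which the entity is absent from the network and groups
#' `1..Q` are the fitted memberships.
#'
#' @param fit a `dynsbm_fit` (see [fit_dynsbm()]) or an `N x T` membership
#'   matrix with rownames.
#' @param path output file.
#' @export
write_memberships <- function(fit, path) {
  z <- if (inherits(fit, "dynsbm_fit")) fit$map_memberships else as.matrix(fit)
  labels <- rownames(z) %||% paste0("n", seq_len(nrow(z)))
  lines <- character(0)
  for (i in seq_len(nrow(z)))
    lines <- c(lines, sprintf("%s\t%d\t%d", labels[i], seq_len(ncol(z)), z[i, ]))
  write_atomically(lines, path)
  invisible(path)
}

#' Read a membership TSV written by [write_memberships()]
#'
#' @param path membership file (`node, t, group` rows).
#' @return integer `N x T` matrix with node labels as rownames; 0 = absent.
#' @export
read_memberships <- function(path) {
  rows <- read_tsv_rows(path)
  node <- vapply(rows, `[`, character(1), 1L)
  t <- as.integer(vapply(rows, `[`, character(1), 2L))
  g <- as.integer(vapply(rows, `[`, character(1), 3L))
  labels <- unique(node)
  z <- matrix(NA_integer_, length(labels), max(t),
              dimnames = list(labels, NULL))
  z[cbind(match(node, labels), t)] <- g
  if (anyNA(z)) stop("membership file does not cover every node-step")
  z
}
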