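# Post-fit group-level summaries: connectivity/intensity tables, alluvial
# membership flows, stability statistics and contingency tables against
# external labels.

#' Group-pair connectivity and intensity table
#'
#' For every group pair `(q, l)` and step `t`, tallies the dyads whose
#' endpoints carry those labels: how many such dyads are possible, what
#' proportion carry no edge (sparsity), and how the present edges split
#' over the `M` intensity categories. For undirected networks dyads are
#' unordered (within-group cells count `choose(n_q, 2)` pairs, plus the
#' `n_q` self-loops when enabled) and the table is symmetric in `(q, l)`;
#' for directed networks rows are the source group. Cells with no
#' possible dyad report `n_possible = 0` and `NA` proportions rather than
#' fabricating zeros.
#'
#' @param net a [dynamic_network()].
#' @param z membership matrix (0 = absent), e.g. `fit$map_memberships`.
#' @return data frame of class `connectivity_table` with columns `q`, `l`,
#'   `t`, `n_possible`, `n_present`, `prop_absent`, `prop_cat_1` ..
#'   `prop_cat_M`.
#' @export
connectivity_summary <- function(net, z) {
  z <- as.matrix(z)
  q_max <- max(z)
  m <- net$n_categories
  rows <- list()
  for (t in seq_len(net$n_steps)) {
    for (g in seq_len(q_max)) for (l in seq_len(q_max)) {
      ig <- which(z[, t] == g)
      il <- which(z[, t] == l)
      if (net$directed) {
        n_poss <- length(ig) * length(il) - (if (g == l) length(ig) else 0L) +
          (if (net$self_loops && g == l) length(ig) else 0L)
        cnt <- integer(m + 1L)
        if (length(ig) && length(il)) {
          vals <- net$values[ig, il, t, drop = FALSE]
          cnt <- tabulate(as.vector(vals) + 1L, nbins = m + 1L)
          if (g == l) {
            di <- net$values[cbind(ig, ig, t)]
            cnt <- cnt - tabulate(di + 1L, nbins = m + 1L)
            if (net$self_loops) cnt <- cnt + tabulate(di + 1L, nbins = m + 1L)
          }
        }
      } else {
        if (g == l) {
          n_poss <- choose(length(ig), 2L) +
            (if (net$self_loops) length(ig) else 0L)
          cnt <- integer(m + 1L)
          if (length(ig) >= 2L) {
            vals <- net$values[ig, ig, t, drop = FALSE][, , 1L]
            cnt <- tabulate(vals[upper.tri(vals)] + 1L, nbins = m + 1L)
          }
          if (net$self_loops && length(ig))
            cnt <- cnt + tabulate(net$values[cbind(ig, ig, t)] + 1L,
                                  nbins = m + 1L)
        } else {
          n_poss <- length(ig) * length(il)
          cnt <- if (length(ig) && length(il))
            tabulate(as.vector(net$values[ig, il, t, drop = FALSE]) + 1L,
                     nbins = m + 1L) else integer(m + 1L)
        }
      }
      n_present <- sum(cnt[-1L])
      row <- data.frame(q = g, l = l, t = t,
                        n_possible = as.integer(round(n_poss)),
                        n_present = n_present,
                        prop_absent = if (n_poss > 0) cnt[1L] / n_poss
                                      else NA_real_)
      for (mm in seq_len(m))
        row[[paste0("prop_cat_", mm)]] <-
          if (n_present > 0) cnt[mm + 1L] / n_present else NA_real_
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("connectivity_table", "data.frame")
  out
}

#' Alluvial membership flows between consecutive steps
#'
#' Counts, for every consecutive step pair, how many nodes move from each
#' group to each group, with group 0 collecting absent node-steps (so
#' arrivals appear as `0 -> q` flows and departures as `q -> 0`). Row
#' totals over the destination group reproduce the group sizes at `t`;
#' every step pair sums to `N`.
#'
#' @param z membership matrix (0 = absent).
#' @return data frame of class `alluvial_flows` with columns `t`
#'   (source step), `from`, `to`, `count`, covering all group pairs in
#'   `0..Q`.
#' @export
alluvial_flows <- function(z) {
  z <- as.matrix(z)
  t_steps <- ncol(z)
  if (t_steps < 2L)
    return(structure(data.frame(t = integer(0), from = integer(0),
                                to = integer(0), count = integer(0)),
                     class = c("alluvial_flows", "data.frame")))
  q_max <- max(z)
  grid <- expand.grid(from = 0:q_max, to = 0:q_max)
  rows <- lapply(seq_len(t_steps - 1L), function(t) {
    cnt <- table(factor(z[, t], levels = 0:q_max),
                 factor(z[, t + 1L], levels = 0:q_max))
    data.frame(t = t, from = grid$from, to = grid$to,
               count = as.integer(cnt[cbind(grid$from + 1L, grid$to + 1L)]))
  })
  structure(do.call(rbind, rows),
            class = c("alluvial_flows", "data.frame"))
}

#' Membership stability statistics
#'
#' A node "never switches" iff its group is identical across all of its
#' present steps; occupancy is the fraction of present steps spent in the
#' modal group (ties toward the lowest group index). The never-switching
#' fraction is invariant under group relabelling.
#'
#' @param z membership matrix (0 = absent).
#' @return list with `fraction_never_switching` and `per_node`, a data
#'   frame with columns `node`, `modal_group`, `occupancy`,
#'   `occupancy_steps`, `n_switches`, `never_switched`.
#' @export
stability_stats <- function(z) {
  z <- as.matrix(z)
  labels <- rownames(z) %||% paste0("n", seq_len(nrow(z)))
  per <- lapply(seq_len(nrow(z)), function(i) {
    g <- z[i, z[i, ] > 0L]
    if (length(g) == 0L) return(NULL)   # never-present node
    tab <- table(g)
    modal <- as.integer(names(tab)[which.max(tab)])  # first max = lowest group
    data.frame(node = labels[i], modal_group = modal,
               occupancy = max(tab) / length(g),
               occupancy_steps = as.integer(max(tab)),
               n_switches = sum(diff(g) != 0L),
               never_switched = all(g == g[1L]))
  })
  per <- do.call(rbind, per)
  list(fraction_never_switching = mean(per$never_switched), per_node = per)
}

#' Contingency table of modal groups against external labels
#'
#' Keeps the nodes whose modal-group occupancy is at least
#' `min_occupancy_steps` present steps and which carry an external label,
#' then cross-tabulates the modal dynamic-SBM group (rows) against the
#' external label (columns).
#'
#' @param z membership matrix (0 = absent) with node labels as rownames.
#' @param labels named character vector, `node -> external label`
#'   (a subset of nodes).
#' @param min_occupancy_steps stability filter, in number of steps.
#' @return a `table` (possibly empty).
#' @export
cross_tabulate <- function(z, labels, min_occupancy_steps = 0L) {
  st <- stability_stats(z)$per_node
  st <- st[st$occupancy_steps >= min_occupancy_steps &
             st$node %in% names(labels), , drop = FALSE]
  table(dynsbm_group = st$modal_group,
        external = unname(labels[st$node]))
}

#' Write a connectivity table, flows or stability summary as CSV
#'
#' @param x a `connectivity_table`, `alluvial_flows` data frame, or the
#'   `per_node` component of [stability_stats()].
#' @param path output file.
#' @export
write_summary_csv <- function(x, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  utils::write.csv(as.data.frame(x), tmp, row.names = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# optional plotting (convenience; the tables above are the tested output)

#' Stacked connectivity/intensity plot
#'
#' Mirrors the classic group-pair panel display: a `Q x Q` facet grid
#' with time on the x-axis; the white area is the proportion of absent
#' dyads, shaded areas the proportions of present edges in each intensity
#' category. Requires ggplot2.
#'
#' @param tab a `connectivity_table` from [connectivity_summary()].
#' @return a ggplot object.
#' @export
plot_connectivity <- function(tab) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_connectivity requires the ggplot2 package")
  m <- sum(grepl("^prop_cat_", names(tab)))
  long <- do.call(rbind, lapply(seq_len(m), function(mm) {
    data.frame(q = tab$q, l = tab$l, t = tab$t,
               category = factor(mm, levels = seq_len(m)),
               prop = (1 - tab$prop_absent) * tab[[paste0("prop_cat_", mm)]])
  }))
  long$prop[is.na(long$prop)] <- 0
  ggplot2::ggplot(long, ggplot2::aes(x = t, y = prop, fill = category)) +
    ggplot2::geom_area(position = "stack") +
    ggplot2::facet_grid(q ~ l) +
    ggplot2::scale_fill_brewer(palette = "Blues", direction = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time step", y = "proportion of possible dyads",
                  fill = "intensity")
}

#' Alluvial plot of membership flows
#'
#' Simple segment-based rendering of the flows returned by
#' [alluvial_flows()]: groups (0 = absent) on the y-axis, steps on the
#' x-axis, one segment per flow with width proportional to its count.
#' Requires ggplot2.
#'
#' @param flows an `alluvial_flows` data frame.
#' @return a ggplot object.
#' @export
plot_alluvial <- function(flows) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_alluvial requires the ggplot2 package")
  df <- flows[flows$count > 0, , drop = FALSE]
  ggplot2::ggplot(df) +
    ggplot2::geom_segment(ggplot2::aes(x = t, xend = t + 1L,
                                       y = from, yend = to,
                                       linewidth = count, alpha = count)) +
    ggplot2::scale_y_continuous(breaks = 0:max(df$to, df$from)) +
    ggplot2::labs(x = "time step", y = "group (0 = absent)",
                  linewidth = "nodes", alpha = "nodes")
}
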