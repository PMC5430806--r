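#' Build the time-adjusted dyadic contact matrix for one camp
#'
#' `W[i, j]` is the dyad's interaction *rate*: number of dyad-slot events
#' divided by the dyad's daytime co-presence hours
#' ([dyad_overlap_hours()]), so people who arrived late or left early are
#' not penalized. Dyads with zero co-presence get weight 0; if events exist
#' for such a dyad a warning is raised (this indicates inconsistent
#' presence data). The matrix is symmetric with a zero diagonal.
#'
#' @param dyad_slots dyad-slot events ([collapse_to_dyad_slots()]) or a
#'   count table with columns `id_a, id_b, events` (and optionally
#'   `overlap_hours`, e.g. from [simulate_dyad_counts()]).
#' @param presence presence data frame for the camp; ignored when
#'   `dyad_slots` already carries `overlap_hours`.
#' @param roster roster data frame (needs `id`, `camp_id`).
#' @param camp camp id.
#' @param window daytime clock-hour window.
#' @return object of class `contact_matrix`: list with `ids`, symmetric
#'   rate matrix `W`, overlap-hours matrix `hours`, and `camp_id`.
#' @export
build_contact_matrix <- function(dyad_slots, presence, roster, camp,
                                 window = c(5, 20)) {
  ids <- sort(roster$id[roster$camp_id == camp])
  if (!length(ids)) stop("no roster entries for camp ", camp)
  n <- length(ids)

  has_counts <- "events" %in% names(dyad_slots)
  if (has_counts) {
    ev <- dyad_slots
  } else {
    key <- paste(dyad_slots$id_a, dyad_slots$id_b, sep = "\r")
    tab <- table(key)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    ev <- data.frame(id_a = vapply(parts, `[`, "", 1),
                     id_b = vapply(parts, `[`, "", 2),
                     events = as.integer(tab), stringsAsFactors = FALSE)
  }
  unknown <- setdiff(unique(c(ev$id_a, ev$id_b)), roster$id)
  if (length(unknown)) {
    stop("events reference ids missing from roster: ",
         paste(unknown, collapse = ", "))
  }
  in_camp <- ev$id_a %in% ids & ev$id_b %in% ids
  ev <- ev[in_camp & ev$events > 0, , drop = FALSE]

  counts <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(ev)) {
    ia <- match(ev$id_a, ids)
    ib <- match(ev$id_b, ids)
    counts[cbind(ia, ib)] <- counts[cbind(ia, ib)] + ev$events
    counts[cbind(ib, ia)] <- counts[cbind(ia, ib)]
  }

  hours <- matrix(0, n, n, dimnames = list(ids, ids))
  if (has_counts && "overlap_hours" %in% names(dyad_slots)) {
    ov <- dyad_slots[dyad_slots$id_a %in% ids & dyad_slots$id_b %in% ids, ,
                     drop = FALSE]
    ia <- match(ov$id_a, ids)
    ib <- match(ov$id_b, ids)
    hours[cbind(ia, ib)] <- ov$overlap_hours
    hours[cbind(ib, ia)] <- ov$overlap_hours
  } else {
    for (i in seq_len(n - 1)) {
      pi <- presence[presence$individual == ids[i], , drop = FALSE]
      for (j in seq(i + 1, n)) {
        pj <- presence[presence$individual == ids[j], , drop = FALSE]
        hours[i, j] <- hours[j, i] <- dyad_overlap_hours(pi, pj, window)
      }
    }
  }

  zero_ov <- hours == 0 & counts > 0
  if (any(zero_ov)) {
    warning("events recorded for ", sum(zero_ov[upper.tri(zero_ov)]),
            " dyad(s) with zero co-presence in camp ", camp,
            "; their weights are set to 0")
  }
  W <- ifelse(hours > 0, counts / hours, 0)
  diag(W) <- 0
  out <- list(ids = ids, W = W, hours = hours, camp_id = camp)
  class(out) <- "contact_matrix"
  out
}

#' Convert a contact matrix to a proximity network
#'
#' Applies the node filter used throughout the analysis: only individuals
#' aged 12 years or older enter the social network (younger children are
#' care recipients rather than social actors in these camps). Edges are the
#' strictly positive contact rates; the network may be disconnected.
#'
#' @param matrix a `contact_matrix`.
#' @param roster roster with `id` and `age`.
#' @param min_age age cutoff in years (default 12).
#' @return object of class `proximity_network`: list with `ids`, `ages`,
#'   weight matrix `W` and `camp_id`.
#' @export
to_network <- function(matrix, roster, min_age = 12) {
  stopifnot(inherits(matrix, "contact_matrix") ||
              (is.list(matrix) && !is.null(matrix$W)))
  ages <- roster$age[match(matrix$ids, roster$id)]
  keep <- !is.na(ages) & ages >= min_age
  out <- list(ids = matrix$ids[keep],
              ages = ages[keep],
              W = matrix$W[keep, keep, drop = FALSE],
              camp_id = matrix$camp_id)
  class(out) <- "proximity_network"
  out
}

#' @export
print.proximity_network <- function(x, ...) {
  ne <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("Proximity network '%s': %d nodes (age >= 12), %d weighted edges\n",
              x$camp_id, length(x$ids), ne))
  invisible(x)
}

#' Edge threshold used for degree centrality
#'
#' In small camps nearly everyone has some interaction with everyone else,
#' so raw degree is uninformative. Degree is therefore counted over ties
#' whose weight *strictly exceeds* a fraction (default 1%) of the camp
#' network's total summed edge weight. Only degree uses the thresholded
#' network; all other measures use the full weighted network.
#'
#' `mode = "ego"` is an alternative reading of the rule in which an edge is
#' kept when it exceeds the fraction of either endpoint's strength.
#'
#' @param network a `proximity_network`.
#' @param fraction threshold fraction in (0, 1).
#' @param mode `"camp_total"` (default) or `"ego"`.
#' @return a `proximity_network` with sub-threshold edges removed.
#' @export
threshold_for_degree <- function(network, fraction = 0.01,
                                 mode = c("camp_total", "ego")) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1)
  W <- network$W
  if (mode == "camp_total") {
    total <- sum(W) / 2
    keep <- W > fraction * total
  } else {
    s <- rowSums(W)
    keep <- W > fraction * s[row(W)] | W > fraction * s[col(W)]
  }
  W[!keep] <- 0
  # symmetry is preserved in camp_total mode; enforce it for ego mode
  W <- pmax(W, t(W))
  out <- network
  out$W <- W
  out
}

#' Write a weighted edge list CSV (`id_a,id_b,weight`)
#'
#' @param network a `proximity_network`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_edge_list <- function(network, path) {
  W <- network$W
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  out <- data.frame(id_a = network$ids[idx[, 1]],
                    id_b = network$ids[idx[, 2]],
                    weight = W[idx])
  out <- out[order(out$id_a, out$id_b), , drop = FALSE]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a camp network as GraphML
#'
#' Minimal GraphML writer (undirected, one `weight` edge attribute) so camp
#' networks can be inspected in standard graph tools.
#'
#' @inheritParams write_edge_list
#' @export
write_graphml <- function(network, path) {
  W <- network$W
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="w" for="edge" attr.name="weight" attr.type="double"/>',
    sprintf('  <graph id="%s" edgedefault="undirected">', network$camp_id)
  ), con)
  for (id in network$ids) {
    writeLines(sprintf('    <node id="%s"/>', id), con)
  }
  idx <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(idx)) {
    for (k in seq_len(nrow(idx))) {
      writeLines(sprintf(
        '    <edge source="%s" target="%s"><data key="w">%.10g</data></edge>',
        network$ids[idx[k, 1]], network$ids[idx[k, 2]],
        W[idx[k, 1], idx[k, 2]]), con)
    }
  }
  writeLines(c("  </graph>", "</graphml>"), con)
  invisible(path)
}
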