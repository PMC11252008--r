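## Bouton-spine connectivity through cleft mediation: for each cleft, the
## mask is dilated by a 1-voxel ball and all boutons and spines overlapping
## by at least one voxel are listed; if several boutons overlap, only the
## one with the largest overlap is retained (the spine side is not
## restricted). Degree summaries count distinct partners.

#' Cleft-mediated bouton-spine interaction graph
#'
#' @param pscrs A [PSCRSet-class].
#' @param boutons,spines [LabelMap-class] objects on the cleft grid.
#' @param pscrDilation Ball radius for the cleft dilation (default 1).
#' @return An [InteractionGraph-class]: edges (pscr_id, bouton_id,
#'   spine_id) plus bouton-only contacts for clefts touching no spine.
#' @export
interactionEdges <- function(pscrs, boutons, spines, pscrDilation = 1) {
  stopifnot(is(pscrs, "PSCRSet"), is(boutons, "LabelMap"),
            is(spines, "LabelMap"))
  plab <- pscrs@labels@data
  if (!identical(dim(plab), dim(boutons@data)) ||
      !identical(dim(plab), dim(spines@data)))
    stop("grid mismatch")
  edges <- list(); bonly <- list()
  for (pid in pscrs@segments$id) {
    dil <- .binary_dilate(plab == pid, pscrDilation)
    btab <- table(boutons@data[dil & boutons@data > 0L])
    stab <- table(spines@data[dil & spines@data > 0L])
    if (!length(btab)) next
    ## largest-overlap bouton; ties toward the lowest label
    bids <- as.integer(names(btab))
    bid <- bids[which.max(as.integer(btab))]
    sids <- as.integer(names(stab))
    if (!length(sids)) {
      bonly[[length(bonly) + 1L]] <- data.frame(pscr_id = pid, bouton_id = bid)
      next
    }
    for (sid in sids)
      edges[[length(edges) + 1L]] <- data.frame(pscr_id = pid,
        bouton_id = bid, spine_id = sid)
  }
  emptyE <- data.frame(pscr_id = integer(), bouton_id = integer(),
                       spine_id = integer())
  emptyB <- data.frame(pscr_id = integer(), bouton_id = integer())
  new("InteractionGraph",
      edges = if (length(edges)) do.call(rbind, edges) else emptyE,
      boutonOnly = if (length(bonly)) do.call(rbind, bonly) else emptyB)
}

#' Partner-count distributions of an interaction graph
#'
#' Multiple clefts between the same bouton-spine pair count once: degrees
#' are numbers of distinct partners. Returns per-bouton spine counts,
#' per-spine bouton counts, and their distributions as counts and fractions.
#'
#' @param graph An [InteractionGraph-class].
#' @param excludeBoutons,excludeSpines Optional label vectors to drop from
#'   the summaries (e.g. structures only partially inside the volume).
#' @return list(per_bouton, per_spine, bouton_degree_distribution,
#'   spine_degree_distribution).
#' @export
degreeSummaries <- function(graph, excludeBoutons = integer(),
                            excludeSpines = integer()) {
  stopifnot(is(graph, "InteractionGraph"))
  e <- graph@edges
  e <- e[!(e$bouton_id %in% excludeBoutons) &
         !(e$spine_id %in% excludeSpines), , drop = FALSE]
  pairs <- unique(e[, c("bouton_id", "spine_id")])
  if (!nrow(pairs)) {
    emp <- data.frame(id = integer(), degree = integer())
    dis <- data.frame(degree = integer(), count = integer(),
                      fraction = numeric())
    return(list(per_bouton = emp, per_spine = emp,
                bouton_degree_distribution = dis,
                spine_degree_distribution = dis))
  }
  per_b <- stats::aggregate(spine_id ~ bouton_id, pairs, length)
  names(per_b) <- c("id", "degree")
  per_s <- stats::aggregate(bouton_id ~ spine_id, pairs, length)
  names(per_s) <- c("id", "degree")
  dist_of <- function(d) {
    tab <- table(d$degree)
    data.frame(degree = as.integer(names(tab)), count = as.integer(tab),
               fraction = as.integer(tab) / nrow(d))
  }
  list(per_bouton = per_b, per_spine = per_s,
       bouton_degree_distribution = dist_of(per_b),
       spine_degree_distribution = dist_of(per_s))
}
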