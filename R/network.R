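#' Build the bipartite patient-article retrieval network
#'
#' Patients and articles are nodes; an edge links a patient to each article
#' retrieved in that patient's top three results. The graph summarises how a
#' patient population maps onto the case-report corpus.
#'
#' @param retrievals named list: patient_id -> character vector of up to 3
#'   retrieved doc_ids.
#' @return An undirected igraph with vertex attributes \code{type} (FALSE =
#'   patient, TRUE = article) and \code{name}.
#' @export
build_network <- function(retrievals) {
  sizes <- lengths(retrievals)
  if (any(sizes > 3)) {
    stop("patient(s) with more than 3 retrieved articles: ",
         paste(names(retrievals)[sizes > 3], collapse = ", "), call. = FALSE)
  }
  patients <- names(retrievals)
  articles <- sort(unique(unlist(retrievals, use.names = FALSE)))
  if (length(intersect(patients, articles)) > 0) {
    stop("patient and article identifiers overlap", call. = FALSE)
  }
  edges <- do.call(rbind, lapply(patients, function(p) {
    if (length(retrievals[[p]]) == 0) return(NULL)
    cbind(p, retrievals[[p]])
  }))
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, length(patients), name = patients, type = FALSE)
  g <- igraph::add_vertices(g, length(articles), name = articles, type = TRUE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, t(matrix(match(edges, igraph::V(g)$name),
                                       ncol = 2)))
  }
  g
}

#' Summary statistics of a retrieval network
#'
#' Counts retrieved articles (article nodes with degree >= 1) and the mean
#' number of patients connected to each retrieved article; the identity
#' mean_article_degree * n_articles = n_edges always holds.
#'
#' @param net bipartite igraph from \code{\link{build_network}}.
#' @return List: n_patients, n_articles, n_edges, mean_article_degree.
#' @export
network_stats <- function(net) {
  if (igraph::vcount(net) == 0) stop("empty network", call. = FALSE)
  if (!igraph::is_bipartite(net)) stop("network is not bipartite", call. = FALSE)
  art <- igraph::V(net)[igraph::V(net)$type]
  deg <- igraph::degree(net, art)
  retrieved <- deg[deg >= 1]
  list(
    n_patients = sum(!igraph::V(net)$type),
    n_articles = length(retrieved),
    n_edges = igraph::ecount(net),
    mean_article_degree = if (length(retrieved) > 0) mean(retrieved) else 0
  )
}

#' Community detection on the retrieval network
#'
#' Greedy modularity maximisation (multilevel agglomeration) on the
#' bipartite graph itself, no projection. The optimiser is sensitive to
#' vertex order, so it is run over several seeded random vertex permutations
#' and the highest-modularity partition is kept; results are deterministic
#' for a fixed seed. Returns the community membership of every node and the
#' achieved modularity.
#'
#' @param net bipartite igraph from \code{\link{build_network}}.
#' @param seed integer seed.
#' @param restarts number of random-permutation restarts (default 20).
#' @return List: \code{membership} (named integer vector) and
#'   \code{modularity}.
#' @export
detect_communities <- function(net, seed = 1L, restarts = 20L) {
  best <- with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      g2 <- igraph::permute(net, sample(igraph::vcount(net)))
      comm <- igraph::cluster_louvain(g2)
      mod <- igraph::modularity(comm)
      if (is.null(best) || mod > best$modularity + 1e-12) {
        best <- list(membership = stats::setNames(igraph::membership(comm),
                                                  igraph::V(g2)$name),
                     modularity = mod)
      }
    }
    best
  })
  # canonical vertex order and community numbering (by first appearance)
  memb <- best$membership[igraph::V(net)$name]
  relabel <- stats::setNames(seq_along(unique(memb)), unique(memb))
  list(membership = stats::setNames(as.integer(relabel[as.character(memb)]),
                                    igraph::V(net)$name),
       modularity = best$modularity)
}

#' Seeded uniform sample of patients
#'
#' Utility for analysing a subset of a large population (e.g. 500 patients).
#'
#' @param patient_ids character vector.
#' @param n sample size (clamped to the population size).
#' @param seed integer seed.
#' @return Character vector of sampled ids.
#' @export
sample_patients <- function(patient_ids, n = 500L, seed = 1L) {
  n <- min(n, length(patient_ids))
  with_seed(seed, sample(patient_ids, n))
}

#' Export a retrieval network
#'
#' Writes GraphML plus an edge-list CSV.
#'
#' @param net igraph network.
#' @param graphml_path,edgelist_path output paths (NULL to skip either).
#' @return Invisibly, the network.
#' @export
write_network <- function(net, graphml_path = NULL, edgelist_path = NULL) {
  if (!is.null(graphml_path)) {
    igraph::write_graph(net, graphml_path, format = "graphml")
  }
  if (!is.null(edgelist_path)) {
    el <- igraph::as_edgelist(net)
    utils::write.csv(data.frame(patient_id = el[, 1], doc_id = el[, 2]),
                     edgelist_path, row.names = FALSE)
  }
  invisible(net)
}
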