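# Hypergeometric over-representation analysis against gene-set
# collections and the bipartite enrichment network with hub genes.

#' Gene-set collection
#'
#' Named gene sets (e.g., Hallmark, GO:BP/MF/CC) together with the gene
#' universe against which over-representation is tested. Genes of a set
#' outside the universe are dropped with a warning; ORA p-values depend on
#' the universe, which here defaults to what the caller measured (the
#' panel genes) rather than the whole genome.
#'
#' @param sets Named list of character vectors of gene symbols.
#' @param universe Character vector of universe genes.
#' @param label Collection label.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe, label = "collection") {
  if (length(sets) == 0 || is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be a non-empty named list")
  universe <- unique(as.character(universe))
  sets <- lapply(sets, function(s) {
    s <- unique(as.character(s))
    out <- intersect(s, universe)
    if (length(out) < length(s))
      warning("dropping set genes outside the universe")
    out
  })
  if (any(lengths(sets) == 0))
    stop("sets empty after intersecting with the universe: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  structure(list(sets = sets, universe = universe, label = label),
            class = "gene_set_collection")
}

#' Read a GMT gene-set file
#'
#' @param path GMT file (set name, description, then member genes,
#'   tab-separated).
#' @param universe Universe genes; defaults to the union of all set
#'   members.
#' @param label Collection label (defaults to the file name).
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path, universe = NULL, label = basename(path)) {
  sets <- if (requireNamespace("fgsea", quietly = TRUE)) {
    fgsea::gmtPathways(path)
  } else {
    ln <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
    stats::setNames(lapply(ln, function(x) x[-(1:2)]),
                    vapply(ln, `[`, character(1), 1))
  }
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe, label)
}

#' Write a gene-set collection as GMT
#' @param collection A `gene_set_collection`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  writeLines(vapply(names(collection$sets), function(nm)
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

#' Over-representation analysis
#'
#' Upper-tail hypergeometric test of a query gene list against every set
#' in a collection: with universe size N, set size K, query size n and
#' overlap x, p = P(X >= x). P-values are Benjamini-Hochberg adjusted
#' across the collection; sets with adjusted p below `alpha` are flagged
#' significant. The gene ratio is x / n.
#'
#' @param query Character vector of query genes (intersected with the
#'   universe; an empty intersection is an error).
#' @param collection A [gene_set_collection()].
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @return data.frame with `set`, `set_size`, `overlap`, `gene_ratio`,
#'   `p`, `p_adjust`, `significant`, `genes` (overlapping genes,
#'   comma-separated), sorted by adjusted then raw p then set name.
#' @export
ora <- function(query, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  query <- intersect(query, collection$universe)
  if (length(query) == 0)
    stop("query has no genes in the universe")
  N <- length(collection$universe)
  n <- length(query)
  res <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    hit <- intersect(query, set)
    x <- length(hit)
    # P(X >= x) for X ~ Hypergeometric(N, K, n)
    p <- stats::phyper(x - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = x, gene_ratio = x / n,
               p = p, genes = paste(sort(hit), collapse = ","))
  })
  out <- do.call(rbind, res)
  out$p_adjust <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adjust < alpha
  out <- out[order(out$p_adjust, out$p, out$set), ]
  rownames(out) <- NULL
  out[, c("set", "set_size", "overlap", "gene_ratio", "p", "p_adjust",
          "significant", "genes")]
}

#' Bipartite enrichment network with hub genes
#'
#' Builds the gene/gene-set network from the top significant ORA results:
#' nodes are the top `top_k` significant sets (by adjusted p, ties broken
#' by raw p then name) plus their overlapping query genes; edges are set
#' membership. Hub genes are gene nodes ranked by degree (the number of
#' top sets they belong to). The force-directed layout is
#' presentation-only and seeded for reproducibility.
#'
#' @param results An [ora()] result.
#' @param top_k Number of top significant sets to keep (default 15).
#' @param seed Layout seed.
#' @return A list with `graph` (igraph, node attribute `type` in
#'   {set, gene}), `hub_genes` (data.frame gene/degree, decreasing),
#'   `edges` (data.frame set/gene) and `layout` (coordinates). With no
#'   significant sets, an empty graph with a warning.
#' @export
build_enrichment_network <- function(results, top_k = 15, seed = 1) {
  sig <- results[results$significant, ]
  if (nrow(sig) == 0) {
    warning("no significant sets; returning an empty network")
    return(list(graph = igraph::make_empty_graph(directed = FALSE),
                hub_genes = data.frame(gene = character(0),
                                       degree = integer(0)),
                edges = data.frame(set = character(0), gene = character(0)),
                layout = NULL))
  }
  top <- utils::head(sig, top_k)  # ora() output is already sorted
  edges <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
    g <- strsplit(top$genes[i], ",", fixed = TRUE)[[1]]
    g <- g[nzchar(g)]
    if (length(g) == 0) return(NULL)
    data.frame(set = top$set[i], gene = g)
  }))
  if (is.null(edges))
    return(list(graph = igraph::make_empty_graph(directed = FALSE),
                hub_genes = data.frame(gene = character(0),
                                       degree = integer(0)),
                edges = data.frame(set = character(0), gene = character(0)),
                layout = NULL))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$type <- ifelse(igraph::V(g)$name %in% top$set, "set", "gene")
  gene_nodes <- igraph::V(g)$name[igraph::V(g)$type == "gene"]
  deg <- igraph::degree(g)[gene_nodes]
  hubs <- data.frame(gene = names(deg), degree = as.integer(deg),
                     row.names = NULL)
  hubs <- hubs[order(-hubs$degree, hubs$gene), ]
  rownames(hubs) <- NULL
  set.seed(seed)
  lay <- igraph::layout_with_fr(g)
  list(graph = g, hub_genes = hubs, edges = edges, layout = lay)
}
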