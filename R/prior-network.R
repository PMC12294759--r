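#' Read a GMT gene-set file
#'
#' Parses the standard tab-separated GMT format: one gene set per line, with
#' the set name in the first field, a free-text description in the second, and
#' member genes in the remaining fields.
#'
#' @param path Path to a GMT file.
#' @return A named list mapping set names to character vectors of member
#'   genes. Duplicate genes within a set are collapsed, keeping first
#'   appearance order. Sets may overlap.
#' @examples
#' gmt <- tempfile(fileext = ".gmt")
#' writeLines(c("P1\tdesc\tg1\tg2", "P2\tdesc\tg2\tg3"), gmt)
#' read_gmt(gmt)
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    stop("GMT file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("GMT file is empty: ", path, call. = FALSE)
  }
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("Malformed GMT line ", i, ": expected >= 3 tab-separated fields, got ",
           length(fields), call. = FALSE)
    }
    nms[i] <- fields[1]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    sets[[i]] <- unique(members)
  }
  if (anyDuplicated(nms)) {
    stop("Duplicate gene-set names in GMT file: ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "), call. = FALSE)
  }
  names(sets) <- nms
  sets
}

#' Read a two-column child/parent pathway edge list
#'
#' @param path TSV file with a header and two columns: child pathway and
#'   parent superpathway.
#' @return A data.frame with columns \code{child} and \code{parent}.
#' @export
read_pathway_edges <- function(path) {
  if (!file.exists(path)) {
    stop("Edge file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    stop("Edge file must have two columns (child, parent): ", path,
         call. = FALSE)
  }
  data.frame(child = as.character(df[[1]]), parent = as.character(df[[2]]),
             stringsAsFactors = FALSE)
}

# Kahn topological check on a child->parent edge frame; TRUE if acyclic.
.edges_acyclic <- function(edges) {
  nodes <- unique(c(edges$child, edges$parent))
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  for (p in edges$parent) indeg[p] <- indeg[p] + 1L
  queue <- nodes[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]; seen <- seen + 1L
    outs <- edges$parent[edges$child == n]
    for (p in outs) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  seen == length(nodes)
}

#' Build a layered pathway hierarchy
#'
#' Assembles the layered prior-knowledge structure used to constrain network
#' connectivity: layer 1 holds genes, layer 2 pathways, layer 3 (and beyond)
#' superpathways. Connectivity between adjacent layers comes from gene-set
#' membership (genes to pathways) and explicit child/parent edge lists
#' (pathways upward).
#'
#' Pathways with no parent in the edge list are attached to a synthetic root
#' superpathway named \code{"_ROOT"}, so incomplete hierarchy files remain
#' usable. Hierarchies of depth 2 (genes and pathways only) are allowed by
#' passing \code{pathway_edges = NULL}; deeper hierarchies by passing a list
#' of edge frames, one per adjacent layer pair above the pathways.
#'
#' @param gene_sets Named list mapping pathway names to gene character
#'   vectors, as returned by [read_gmt()].
#' @param pathway_edges \code{NULL}, a data.frame with columns
#'   \code{child}/\code{parent}, or a list of such data.frames for deeper
#'   hierarchies.
#' @return An object of class \code{pathway_hierarchy} with elements
#'   \code{layers} (list of character vectors, genes first) and \code{edges}
#'   (data.frame with \code{child}, \code{parent}, \code{layer}; \code{layer}
#'   is the index of the child's layer).
#' @examples
#' h <- build_hierarchy(list(P1 = c("g1", "g2"), P2 = c("g2", "g3")),
#'                      data.frame(child = c("P1", "P2"), parent = "SP1"))
#' h$layers
#' @export
build_hierarchy <- function(gene_sets, pathway_edges = NULL) {
  if (!is.list(gene_sets) || is.null(names(gene_sets)) ||
      any(!nzchar(names(gene_sets)))) {
    stop("gene_sets must be a named list of gene vectors", call. = FALSE)
  }
  if (anyDuplicated(names(gene_sets))) {
    stop("Duplicate pathway names in gene_sets", call. = FALSE)
  }
  gene_sets <- lapply(gene_sets, function(g) unique(as.character(g)))
  genes <- unique(unlist(gene_sets, use.names = FALSE))
  if (length(genes) == 0L) {
    stop("Resulting gene layer is empty: no genes in any set", call. = FALSE)
  }
  pathways <- names(gene_sets)

  gene_edges <- do.call(rbind, lapply(pathways, function(p) {
    if (length(gene_sets[[p]]) == 0L) return(NULL)
    data.frame(child = gene_sets[[p]], parent = p, layer = 1L,
               stringsAsFactors = FALSE)
  }))

  layers <- list(sort(genes), sort(pathways))
  edges <- gene_edges

  if (!is.null(pathway_edges)) {
    edge_list <- if (is.data.frame(pathway_edges)) list(pathway_edges) else pathway_edges
    for (li in seq_along(edge_list)) {
      ef <- edge_list[[li]]
      ef <- data.frame(child = as.character(ef[[1]]),
                       parent = as.character(ef[[2]]),
                       stringsAsFactors = FALSE)
      ef <- unique(ef)
      if (!.edges_acyclic(ef)) {
        stop("Cycle detected among pathway edges at level ", li, call. = FALSE)
      }
      child_layer <- layers[[li + 1L]]
      unknown <- setdiff(ef$child, child_layer)
      if (length(unknown)) {
        stop("Edge children not present in layer ", li + 1L, ": ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      orphans <- setdiff(child_layer, ef$child)
      if (length(orphans)) {
        ef <- rbind(ef, data.frame(child = orphans, parent = "_ROOT",
                                   stringsAsFactors = FALSE))
      }
      parents <- sort(unique(ef$parent))
      layers[[li + 2L]] <- parents
      edges <- rbind(edges,
                     data.frame(child = ef$child, parent = ef$parent,
                                layer = li + 1L, stringsAsFactors = FALSE))
    }
  }

  h <- structure(list(layers = layers, edges = edges),
                 class = "pathway_hierarchy")
  validate_hierarchy(h)
  h
}

#' Validate a pathway hierarchy
#'
#' Checks the structural invariants: unique entity names within each layer,
#' all edges connecting adjacent layers, every entity above the gene layer
#' having at least one child, and every gene at least one parent.
#'
#' @param h A \code{pathway_hierarchy}.
#' @return \code{h}, invisibly; errors if an invariant is violated.
#' @export
validate_hierarchy <- function(h) {
  stopifnot(inherits(h, "pathway_hierarchy"))
  n_layers <- length(h$layers)
  if (n_layers < 2L) stop("Hierarchy needs at least 2 layers", call. = FALSE)
  for (l in seq_len(n_layers)) {
    if (anyDuplicated(h$layers[[l]])) {
      stop("Duplicate entity names in layer ", l, call. = FALSE)
    }
  }
  for (l in seq_len(n_layers - 1L)) {
    e <- h$edges[h$edges$layer == l, , drop = FALSE]
    if (nrow(e) == 0L) stop("No edges between layers ", l, " and ", l + 1L,
                            call. = FALSE)
    if (!all(e$child %in% h$layers[[l]]) || !all(e$parent %in% h$layers[[l + 1L]])) {
      stop("Edge endpoints not in the adjacent layers (layer ", l, ")",
           call. = FALSE)
    }
    childless <- setdiff(h$layers[[l + 1L]], e$parent)
    if (length(childless)) {
      stop("Entities with no child in layer ", l + 1L, ": ",
           paste(childless, collapse = ", "), call. = FALSE)
    }
    parentless <- setdiff(h$layers[[l]], e$child)
    if (length(parentless)) {
      stop("Entities with no parent in layer ", l, ": ",
           paste(parentless, collapse = ", "), call. = FALSE)
    }
  }
  invisible(h)
}

#' @export
print.pathway_hierarchy <- function(x, ...) {
  cat("Pathway hierarchy with", length(x$layers), "layers\n")
  nm <- c("genes", "pathways", paste0("superpathways.", seq_len(max(0, length(x$layers) - 2L))))
  for (l in seq_along(x$layers)) {
    cat(sprintf("  layer %d (%s): %d entities\n", l, nm[l], length(x$layers[[l]])))
  }
  cat("  edges:", nrow(x$edges), "\n")
  invisible(x)
}

#' Build binary connectivity masks from a hierarchy
#'
#' Converts a validated hierarchy into the stack of binary mask matrices that
#' define network connectivity: mask \code{l} has one row per layer-(l+1)
#' entity and one column per layer-l entity, with a 1 wherever the column
#' entity is a child of the row entity. Entities are sorted lexicographically
#' within each layer so the matrices (and everything downstream) are
#' reproducible bit-for-bit from the same inputs.
#'
#' @param h A \code{pathway_hierarchy}.
#' @return An object of class \code{mask_stack}: a list with element
#'   \code{masks}, an ordered list of 0/1 matrices with row/column dimnames.
#' @export
build_masks <- function(h) {
  validate_hierarchy(h)
  masks <- vector("list", length(h$layers) - 1L)
  for (l in seq_along(masks)) {
    children <- sort(h$layers[[l]])
    parents <- sort(h$layers[[l + 1L]])
    m <- matrix(0, nrow = length(parents), ncol = length(children),
                dimnames = list(parents, children))
    e <- h$edges[h$edges$layer == l, , drop = FALSE]
    m[cbind(match(e$parent, parents), match(e$child, children))] <- 1
    masks[[l]] <- m
  }
  ms <- structure(list(masks = masks), class = "mask_stack")
  validate_masks(ms)
  ms
}

#' Validate a mask stack
#'
#' @param ms A \code{mask_stack}.
#' @return \code{ms}, invisibly; errors on non-binary entries, shape
#'   mismatches between consecutive masks, or all-zero rows/columns.
#' @export
validate_masks <- function(ms) {
  stopifnot(inherits(ms, "mask_stack"))
  for (l in seq_along(ms$masks)) {
    m <- ms$masks[[l]]
    if (!all(m %in% c(0, 1))) stop("Mask ", l, " has non-binary entries", call. = FALSE)
    if (any(rowSums(m) == 0)) stop("Mask ", l, " has an all-zero row", call. = FALSE)
    if (any(colSums(m) == 0)) stop("Mask ", l, " has an all-zero column", call. = FALSE)
    if (l > 1L && ncol(m) != nrow(ms$masks[[l - 1L]])) {
      stop("Mask ", l, " column count does not match mask ", l - 1L,
           " row count", call. = FALSE)
    }
  }
  invisible(ms)
}

#' @export
print.mask_stack <- function(x, ...) {
  cat("Mask stack with", length(x$masks), "layers\n")
  for (l in seq_along(x$masks)) {
    m <- x$masks[[l]]
    cat(sprintf("  mask %d: %d x %d, nnz = %d (density %.3f)\n",
                l, nrow(m), ncol(m), sum(m != 0), mean(m != 0)))
  }
  invisible(x)
}

#' Count trainable parameters of a masked network
#'
#' Sums the unmasked weights and per-layer biases of the sparse hidden stack
#' plus the dense classification head. The sparse count is always at most
#' the dense count for the same layer widths; the prior knowledge on the
#' edges is exactly what buys the reduction.
#'
#' @param ms A \code{mask_stack}.
#' @param n_classes Number of output classes.
#' @return Integer parameter count.
#' @examples
#' h <- build_hierarchy(list(P1 = c("g1", "g2"), P2 = c("g2", "g3")),
#'                      data.frame(child = c("P1", "P2"), parent = "SP1"))
#' parameter_count(build_masks(h), n_classes = 4)
#' @export
parameter_count <- function(ms, n_classes) {
  validate_masks(ms)
  stopifnot(n_classes >= 1)
  nnz <- sum(vapply(ms$masks, function(m) sum(m != 0), numeric(1)))
  biases <- sum(vapply(ms$masks, nrow, numeric(1)))
  last_width <- nrow(ms$masks[[length(ms$masks)]])
  as.integer(nnz + biases + n_classes * last_width + n_classes)
}

#' Write mask matrices to TSV files
#'
#' One file per layer (\code{mask_1.tsv}, ...) with row and column name
#' headers and 0/1 values.
#'
#' @param ms A \code{mask_stack}.
#' @param dir Output directory (created if needed).
#' @return Character vector of file paths, invisibly.
#' @export
write_masks <- function(ms, dir) {
  validate_masks(ms)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(length(ms$masks))
  for (l in seq_along(ms$masks)) {
    paths[l] <- file.path(dir, sprintf("mask_%d.tsv", l))
    utils::write.table(ms$masks[[l]], paths[l], sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(paths)
}
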