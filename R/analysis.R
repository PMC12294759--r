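#' Rank entities by mean absolute attribution
#'
#' Ranking scores are the mean of absolute sample-level attributions, taken
#' over the retained samples (optionally restricted to one class). Ordering
#' is by descending score with lexicographic tie-break on entity name, so
#' rankings are stable and reproducible.
#'
#' @param a An \code{attribution_result} from [attribute_dataset()], or a
#'   samples-by-entities numeric matrix.
#' @param class Optional class label; restricts to samples of that class.
#' @return A \code{ranked_genes} data.frame with columns \code{entity} and
#'   \code{score}, sorted; attributes record the method/class tags and the
#'   tie-break rule.
#' @export
rank_genes <- function(a, class = NULL) {
  if (inherits(a, "attribution_result")) {
    scores <- a$scores
    if (!is.null(class)) {
      keep <- a$classes == class
      if (!any(keep)) stop("No retained samples of class ", class, call. = FALSE)
      scores <- scores[keep, , drop = FALSE]
    }
    method <- a$method
  } else {
    scores <- as.matrix(a)
    method <- "custom"
  }
  if (nrow(scores) < 1L) stop("Need at least one sample", call. = FALSE)
  s <- colMeans(abs(scores))
  ord <- order(-s, colnames(scores))
  out <- data.frame(entity = colnames(scores)[ord], score = unname(s[ord]),
                    stringsAsFactors = FALSE)
  structure(out, class = c("ranked_genes", "data.frame"),
            method = method, target_class = class %||% "all",
            tie_break = "lexicographic")
}

.check_ranked <- function(r) {
  stopifnot(is.data.frame(r), all(c("entity", "score") %in% names(r)))
  r
}

# Min-max scale to [0,1]; a degenerate (constant) range maps to all zeros.
.minmax <- function(v) {
  rng <- range(v)
  if (diff(rng) == 0) return(rep(0, length(v)))
  (v - rng[1]) / diff(rng)
}

#' Composite score across two attribution methods
#'
#' Combines two per-gene rankings (typically integrated gradients and
#' Shapley values) into a total score. Because the two methods live on
#' different scales, each method's mean-absolute-attribution vector is
#' min–max scaled to [0, 1] first (a constant vector maps to zeros), then
#' the scaled scores are summed and re-ranked.
#'
#' @param ig,sv Two \code{ranked_genes} objects over the same gene universe.
#' @return A \code{ranked_genes} data.frame of summed scaled scores.
#' @export
total_score <- function(ig, sv) {
  .check_ranked(ig); .check_ranked(sv)
  if (!setequal(ig$entity, sv$entity)) {
    stop("Gene universes differ between the two rankings", call. = FALSE)
  }
  genes <- sort(ig$entity)
  v1 <- .minmax(ig$score[match(genes, ig$entity)])
  v2 <- .minmax(sv$score[match(genes, sv$entity)])
  s <- v1 + v2
  ord <- order(-s, genes)
  structure(data.frame(entity = genes[ord], score = s[ord],
                       stringsAsFactors = FALSE),
            class = c("ranked_genes", "data.frame"),
            method = "total", scaling = "minmax-per-method",
            tie_break = "lexicographic")
}

#' Top-k overlap between two rankings
#'
#' For each k, the intersection fraction \eqn{|top_k(A) \cap top_k(B)| / k}
#' between the heads of two ranked lists — the agreement statistic used to
#' compare attribution methods and disease categories. A Jaccard variant
#' (\eqn{|A \cap B| / |A \cup B|}) is available.
#'
#' @param a,b \code{ranked_genes} objects (or data.frames with an
#'   \code{entity} column, already ordered).
#' @param ks Integer vector of list depths (default 10, 30, 50, 100).
#' @param measure \code{"intersection"} (default) or \code{"jaccard"}.
#' @return A data.frame with columns \code{k} and \code{overlap}, fractions
#'   in [0, 1].
#' @export
topk_overlap <- function(a, b, ks = c(10, 30, 50, 100),
                         measure = c("intersection", "jaccard")) {
  measure <- match.arg(measure)
  .check_ranked(a); .check_ranked(b)
  ks <- as.integer(ks)
  if (any(ks < 1L) || any(ks > nrow(a)) || any(ks > nrow(b))) {
    stop("k must be between 1 and the length of both rankings", call. = FALSE)
  }
  ov <- vapply(ks, function(k) {
    ta <- a$entity[seq_len(k)]; tb <- b$entity[seq_len(k)]
    inter <- length(intersect(ta, tb))
    if (measure == "intersection") inter / k
    else inter / length(union(ta, tb))
  }, numeric(1))
  data.frame(k = ks, overlap = ov)
}

#' Select the top fraction of a ranking
#'
#' Returns the head of the ranking containing \code{ceiling(fraction * N)}
#' entities — e.g. the top 5\% of genes fed into pathway enrichment.
#'
#' @param r A \code{ranked_genes} object.
#' @param fraction Fraction in (0, 1] (default 0.05).
#' @return Character vector of selected entity names, in rank order.
#' @export
select_top_fraction <- function(r, fraction = 0.05) {
  .check_ranked(r)
  stopifnot(fraction > 0, fraction <= 1)
  n <- ceiling(fraction * nrow(r))
  r$entity[seq_len(n)]
}

#' Refine a ranking through a gene filter
#'
#' Applies a deterministic keep/drop predicate to a ranked gene list,
#' preserving the ranking order among kept genes. The filter stands in for
#' any external curation step (e.g. semantic filtering of candidates); a
#' character vector acts as a keep-list, and a function is called per gene
#' and must return a single logical.
#'
#' @param r A \code{ranked_genes} object.
#' @param filter Character vector of genes to keep, or a predicate
#'   \code{function(gene) TRUE/FALSE}.
#' @return Character vector of kept genes in rank order; a warning is
#'   emitted when everything is dropped. The drop decisions are attached as
#'   the \code{"dropped"} attribute.
#' @export
refine_genes <- function(r, filter) {
  .check_ranked(r)
  genes <- r$entity
  if (is.character(filter)) {
    keep <- genes %in% filter
  } else if (is.function(filter)) {
    keep <- vapply(genes, function(g) {
      res <- tryCatch(filter(g), error = function(e) {
        stop("Gene filter failed on gene ", g, ": ", conditionMessage(e),
             call. = FALSE)
      })
      if (!is.logical(res) || length(res) != 1L || is.na(res)) {
        stop("Gene filter returned a non-logical result for gene ", g,
             call. = FALSE)
      }
      res
    }, logical(1))
  } else {
    stop("filter must be a keep-list or a predicate function", call. = FALSE)
  }
  kept <- genes[keep]
  if (length(kept) == 0L) warning("Gene filter dropped every gene")
  structure(kept, dropped = genes[!keep])
}

#' Rank pathways by conductance
#'
#' Ranks the neurons of a pathway-layer conductance attribution by the mean
#' absolute total conductance across retained samples, returning the top
#' pathways driving the target class.
#'
#' @param p An \code{attribution_result} with \code{method =
#'   "conductance"}, or a samples-by-pathways conductance matrix.
#' @param top_n Number of pathways to return (default 5); the full ranking
#'   is returned when \code{top_n} exceeds the pathway count.
#' @param class Optional class restriction, as in [rank_genes()].
#' @return A \code{ranked_genes} data.frame of at most \code{top_n} rows.
#' @export
pathway_conductance_ranking <- function(p, top_n = 5, class = NULL) {
  r <- rank_genes(p, class = class)
  utils::head(r, min(top_n, nrow(r)))
}

#' @export
print.ranked_genes <- function(x, n = 10, ...) {
  cat(sprintf("Ranked list (%d entities, method %s, class %s)\n",
              nrow(x), attr(x, "method") %||% "?",
              attr(x, "target_class") %||% "?"))
  print.data.frame(utils::head(x, n), row.names = FALSE)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more\n")
  invisible(x)
}
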