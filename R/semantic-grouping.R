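#' Default melanoma-flavored keyword lexicon
#'
#' Ordered keyword list for semantic grouping of enrichment terms, shipped
#' for demonstrations; real analyses should supply their own lexicon as
#' data. The order matters: a term matching several keywords is assigned to
#' the first.
#'
#' @return character vector of keywords.
#' @export
defaultLexicon <- function() {
  c("telomere", "DNA repair", "DNA damage", "pigment", "melanin", "ageing",
    "antigen", "cell cycle", "adhesion", "migration", "calcium",
    "autophagy", "differentiation", "stress", "transcription", "apoptosis")
}

#' Filter enrichment terms by term size and intersection size
#'
#' Keeps the most specific terms: term size below \code{maxTermSize}
#' (comparator configurable, strict \code{<} by default; published analyses
#' vary between < and <=) and intersection size strictly greater than
#' \code{minIntersection} (terms with intersection <= the cut are removed).
#' Idempotent.
#'
#' @param terms data.frame with columns \code{term_id}, \code{term_name},
#'   \code{adjusted_p_value}, \code{term_size}, \code{intersection_size}
#'   (the g:Profiler export column names).
#' @param maxTermSize upper cut on term size (Inf to disable).
#' @param minIntersection terms with intersection_size <= this are removed
#'   (0 to disable).
#' @param sizeComparator "lt" (strict, default) or "le".
#' @return filtered data.frame.
#' @export
filterTerms <- function(terms, maxTermSize = Inf, minIntersection = 0,
                        sizeComparator = c("lt", "le")) {
  sizeComparator <- match.arg(sizeComparator)
  .assert(maxTermSize >= 0 && minIntersection >= 0,
          "thresholds must be >= 0")
  .assert(all(terms$intersection_size <= terms$term_size),
          "intersection_size exceeds term_size")
  keepSize <- if (sizeComparator == "lt") terms$term_size < maxTermSize
              else terms$term_size <= maxTermSize
  terms[keepSize & terms$intersection_size > minIntersection, , drop = FALSE]
}

#' Group enrichment terms into keyword-defined semantic classes
#'
#' Each term is assigned to the first lexicon keyword found as a
#' case-insensitive substring of its name; terms matching no keyword go to
#' the "unassigned" bucket. Groups carry the number of member terms, their
#' percentage of the filtered term set, and the smallest adjusted p among
#' members.
#'
#' @param terms filtered term data.frame, see [filterTerms()].
#' @param lexicon ordered, nonempty keyword vector.
#' @return list with \code{groups} (data.frame: keyword, n_terms,
#'   pct_of_filtered, min_p_adj), \code{assignment} (named keyword per
#'   term_id) and \code{unassigned} (term ids in the unassigned bucket).
#' @export
groupByKeywords <- function(terms, lexicon = defaultLexicon()) {
  .assert(length(lexicon) > 0, "lexicon must be nonempty")
  nm <- tolower(as.character(terms$term_name))
  assign <- rep(NA_character_, nrow(terms))
  for (kw in lexicon) {
    hit <- is.na(assign) & grepl(tolower(kw), nm, fixed = TRUE)
    assign[hit] <- kw
  }
  total <- nrow(terms)
  mkRow <- function(kw, idx) {
    data.frame(keyword = kw, n_terms = length(idx),
               pct_of_filtered = if (total > 0) 100 * length(idx) / total else NA_real_,
               min_p_adj = if (length(idx) > 0)
                 min(terms$adjusted_p_value[idx]) else NA_real_,
               stringsAsFactors = FALSE)
  }
  groups <- do.call(rbind, lapply(lexicon, function(kw) {
    idx <- which(!is.na(assign) & assign == kw)
    if (length(idx) == 0) NULL else mkRow(kw, idx)
  }))
  if (is.null(groups))
    groups <- data.frame(keyword = character(), n_terms = integer(),
                         pct_of_filtered = numeric(), min_p_adj = numeric(),
                         stringsAsFactors = FALSE)
  names(assign) <- terms$term_id
  list(groups = groups,
       assignment = assign,
       unassigned = terms$term_id[is.na(assign)])
}

#' Select the top semantic groups covering a share of the enrichment
#'
#' Groups are sorted by member count (descending; ties by smaller minimum
#' adjusted p, then keyword alphabetically) and the shortest prefix whose
#' cumulative percentage strictly exceeds \code{coverage * 100} is returned.
#' If all groups together do not exceed the coverage (a large unassigned
#' bucket), every group is returned with a warning.
#'
#' @param groups the \code{groups} data.frame from [groupByKeywords()].
#' @param coverage fraction of the filtered enrichment to cover, default 0.5.
#' @return the selected rows of \code{groups}, in selection order.
#' @export
topGroups <- function(groups, coverage = 0.5) {
  .assert(nrow(groups) > 0 && sum(groups$n_terms) > 0,
          "no terms in any group")
  ord <- order(-groups$n_terms, groups$min_p_adj, groups$keyword)
  g <- groups[ord, , drop = FALSE]
  cum <- cumsum(g$pct_of_filtered)
  need <- which(cum > coverage * 100)
  if (length(need) == 0) {
    warning("groups never exceed the requested coverage; returning all")
    return(g)
  }
  out <- g[seq_len(need[1]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Connected components of terms under ontology parent-child relations
#'
#' Builds the undirected graph of the filtered terms with an edge per
#' parent-child relation and reports its connected components, ranked by
#' size (ties by smallest member id), each annotated with its smallest
#' adjusted p and smallest term size. Relations mentioning unknown term ids
#' are ignored with a warning.
#'
#' @param terms filtered term data.frame.
#' @param relations data.frame with columns \code{parent_id},
#'   \code{child_id}.
#' @return data.frame with \code{component}, \code{n_terms},
#'   \code{min_p_adj}, \code{min_term_size}, \code{members} (';'-joined ids).
#' @export
termDagComponents <- function(terms, relations) {
  ids <- as.character(terms$term_id)
  known <- relations$parent_id %in% ids & relations$child_id %in% ids
  if (any(!known))
    warning(sprintf("%d relation(s) referencing unknown term ids ignored",
                    sum(!known)))
  rel <- relations[known, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    rel[, c("parent_id", "child_id")], directed = FALSE,
    vertices = data.frame(name = ids))
  g <- igraph::simplify(g)
  rep <- .componentReport(g)
  memb <- strsplit(rep$members, ";", fixed = TRUE)
  data.frame(component = rep$component,
             n_terms = rep$n_nodes,
             min_p_adj = vapply(memb, function(m)
               min(terms$adjusted_p_value[match(m, ids)]), numeric(1)),
             min_term_size = vapply(memb, function(m)
               min(terms$term_size[match(m, ids)]), numeric(1)),
             members = rep$members,
             stringsAsFactors = FALSE)
}
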